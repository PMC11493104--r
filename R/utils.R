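# Internal helpers: classed errors, local RNG scope, sequence matrices.

# All user-facing errors carry a package condition class so callers (and the
# test suite) can distinguish failure modes without string matching.
hap_error <- function(msg, class) {
  stop(structure(
    class = c(class, "haplotrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. Every stochastic operation in the package routes through this.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    hap_error("`seed` must be a single non-missing number", "haplotrace_seed_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Character matrix (n x L) from a vector of equal-length sequence strings.
seq_char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

is_unambiguous <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
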