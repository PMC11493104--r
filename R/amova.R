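# Pairwise Hamming distances and single-level analysis of molecular
# variance (AMOVA) with a permutation null for the Phi statistic.

#' Pairwise Hamming distance matrix
#'
#' Number of mismatching sites for every pair of sequences. Sequences must be
#' unambiguous (`A/C/G/T` only). Computed via one-hot encoding and
#' `tcrossprod`, so it scales to hundreds of specimens.
#'
#' @param aln a `hap_alignment`, or a (named) character vector of
#'   equal-length sequences.
#' @param normalize divide by the alignment length to obtain proportions.
#' @return Symmetric numeric matrix with specimen ids as dimnames and
#'   attributes `L` (alignment length) and `normalized`.
#' @export
hamming_matrix <- function(aln, normalize = FALSE) {
  if (inherits(aln, "hap_alignment")) {
    seqs <- aln$seqs
  } else {
    seqs <- aln
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    if (length(unique(nchar(seqs))) != 1L) {
      hap_error("sequences have unequal lengths", "haplotrace_shape_error")
    }
  }
  if (!all(is_unambiguous(seqs))) {
    hap_error("ambiguous characters present; Hamming distances require A/C/G/T",
              "haplotrace_alphabet_error")
  }
  L <- nchar(seqs[[1]])
  m <- seq_char_matrix(seqs)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    X <- (m == b) * 1
    matches <- matches + tcrossprod(X)
  }
  D <- L - matches
  dimnames(D) <- list(names(seqs), names(seqs))
  diag(D) <- 0
  if (normalize) D <- D / L
  attr(D, "L") <- L
  attr(D, "normalized") <- normalize
  D
}

# Sums of squares from a matrix of squared distances and a population
# factor. Following the molecular-variance convention for sequence data the
# number of substitutions between two sequences plays the role of the
# squared Euclidean distance.
amova_ss <- function(delta2, pop) {
  n <- nrow(delta2)
  ss_total <- sum(delta2[upper.tri(delta2)]) / n
  ss_within <- 0
  for (p in levels(pop)) {
    idx <- which(pop == p)
    if (length(idx) > 1) {
      sub <- delta2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phi_from_ss <- function(ss, pop, n) {
  sizes <- table(pop)
  P <- length(sizes)
  df_among <- P - 1L
  df_within <- n - P
  sigma2_w <- ss[["within"]] / df_within
  n_bar <- (n - sum(sizes^2) / n) / (P - 1)
  sigma2_a <- (ss[["among"]] / df_among - sigma2_w) / n_bar
  phi <- sigma2_a / (sigma2_a + sigma2_w)
  list(df_among = df_among, df_within = df_within,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w, n_bar = n_bar, phi = phi)
}

#' Single-level AMOVA with permutation test
#'
#' Partitions molecular variance among and within populations from a matrix
#' of pairwise substitution counts, treating the count of differences between
#' two sequences as their squared distance (the standard convention for
#' sequence data). Reports sums of squares, variance components
#' \eqn{\sigma^2_a, \sigma^2_w}, the \eqn{\Phi_{ST}} statistic
#' \eqn{\sigma^2_a / (\sigma^2_a + \sigma^2_w)}, and a permutation p-value
#' obtained by shuffling individuals across populations with group sizes held
#' fixed. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{\Phi^* \ge \Phi\}) / (1 + n_{perm})}, which never
#' returns zero.
#'
#' If every pairwise distance is zero the decomposition is degenerate:
#' \eqn{\Phi} is reported as 0 with `degenerate = TRUE` and no permutations
#' are run (`p_value = NA`).
#'
#' @param dist symmetric matrix of pairwise distances (substitution counts).
#' @param labels population assignment, one label per row of `dist`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream (required).
#' @return An object of class `amova_result`.
#' @export
amova_one_level <- function(dist, labels, n_perm = 1000L, seed) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (length(labels) != n) {
    hap_error("`labels` must have one entry per row of `dist`",
              "haplotrace_shape_error")
  }
  pop <- factor(labels)
  sizes <- table(pop)
  if (length(sizes) < 2L) {
    hap_error("AMOVA needs at least two populations", "haplotrace_value_error")
  }
  if (any(sizes == 0L)) {
    hap_error("every population must have at least one member",
              "haplotrace_value_error")
  }
  if (length(sizes) >= n) {
    hap_error("number of populations must be smaller than sample size",
              "haplotrace_value_error")
  }

  ss <- amova_ss(D, pop)
  degenerate <- all(D[upper.tri(D)] == 0)

  if (degenerate) {
    comp <- phi_from_ss(ss, pop, n)
    res <- list(
      df_among = comp$df_among, df_within = comp$df_within,
      df_total = n - 1L,
      ss_among = 0, ss_within = 0, ss_total = 0,
      sigma2_among = 0, sigma2_within = 0,
      pct_variation = c(among = 0, within = 100),
      phi_st = 0, p_value = NA_real_,
      n_permutations = 0L, seed = seed, degenerate = TRUE
    )
    class(res) <- "amova_result"
    return(res)
  }

  comp <- phi_from_ss(ss, pop, n)
  phi_obs <- comp$phi

  perm_phi <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      ssp <- amova_ss(D, pop[idx])
      phi_from_ss(ssp, pop[idx], n)$phi
    }, numeric(1))
  })
  p <- (1 + sum(perm_phi >= phi_obs)) / (1 + n_perm)

  tot_var <- comp$sigma2_a + comp$sigma2_w
  res <- list(
    df_among = comp$df_among, df_within = comp$df_within, df_total = n - 1L,
    ss_among = unname(ss[["among"]]), ss_within = unname(ss[["within"]]),
    ss_total = unname(ss[["total"]]),
    sigma2_among = comp$sigma2_a, sigma2_within = comp$sigma2_w,
    pct_variation = c(among = 100 * comp$sigma2_a / tot_var,
                      within = 100 * comp$sigma2_w / tot_var),
    phi_st = phi_obs, p_value = p,
    n_permutations = as.integer(n_perm), seed = seed, degenerate = FALSE
  )
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance (single level)\n")
  print(amova_table(x), row.names = FALSE)
  cat(sprintf("Phi_ST = %.5f, p %s (%d permutations)%s\n",
              x$phi_st,
              if (is.na(x$p_value)) "= NA" else sprintf("= %.4g", x$p_value),
              x$n_permutations,
              if (x$degenerate) " [degenerate: all distances zero]" else ""))
  invisible(x)
}

#' AMOVA results as a source/df/SS table
#'
#' @param res an `amova_result`.
#' @return data.frame with columns Source, df, `Sum of squares`, `Sigma 2`,
#'   `%Variation`, p.
#' @export
amova_table <- function(res) {
  stopifnot(inherits(res, "amova_result"))
  data.frame(
    Source = c("Among populations", "Within populations", "Total"),
    df = c(res$df_among, res$df_within, res$df_total),
    `Sum of squares` = c(res$ss_among, res$ss_within, res$ss_total),
    `Sigma 2` = c(res$sigma2_among, res$sigma2_within, NA),
    `%Variation` = c(res$pct_variation[["among"]], res$pct_variation[["within"]], NA),
    p = c(res$p_value, NA, NA),
    check.names = FALSE
  )
}
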