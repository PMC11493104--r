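# Shared fixtures and independent oracles, built in code at test time.

# Write a small FASTA to a temp file.
write_fasta_tmp <- function(ids, seqs, wrap = FALSE) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[i]
    body <- if (wrap) {
      starts <- seq(1, nchar(s), by = 10)
      substring(s, starts, pmin(starts + 9, nchar(s)))
    } else s
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  writeLines(lines, path)
  path
}

write_meta_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

make_meta <- function(ids, country, location = country,
                      status = "native", host = "", year = 2000L) {
  data.frame(specimen_id = ids, country = country, location = location,
             status = status, host = host, year = year,
             stringsAsFactors = FALSE)
}

# Random unambiguous sequences of length L (call under a fixed seed).
random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Oracle: per-site loop Hamming distance.
hamming_oracle <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- strsplit(seqs[[i]], "")[[1]]
    b <- strsplit(seqs[[j]], "")[[1]]
    D[i, j] <- sum(a != b)
  }
  D
}

# Oracle: union of all minimum spanning trees by exhaustive enumeration of
# edge subsets of size n-1 (feasible for n <= 7).
msn_oracle <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ne <- nrow(pairs)
  combos <- utils::combn(ne, n - 1)
  is_spanning_tree <- function(es) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in es) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) return(FALSE)
      parent[rj] <- ri
    }
    TRUE
  }
  weights <- apply(combos, 2, function(es) sum(D[pairs[es, , drop = FALSE]]))
  trees <- apply(combos, 2, is_spanning_tree)
  if (!any(trees)) return(NULL)
  minw <- min(weights[trees])
  in_union <- rep(FALSE, ne)
  for (k in which(trees & weights == minw)) in_union[combos[, k]] <- TRUE
  e <- data.frame(from = labs[pairs[in_union, 1]],
                  to = labs[pairs[in_union, 2]],
                  weight = D[pairs[in_union, , drop = FALSE]],
                  stringsAsFactors = FALSE)
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[order(e$weight, e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# Oracle: AMOVA sums of squares from explicit coordinates. Each sequence is
# one-hot encoded scaled by 1/sqrt(2) so squared Euclidean distance equals
# the Hamming substitution count; sums of squared deviations from (group)
# centroids then give SS_total and SS_within directly.
amova_ss_oracle <- function(seqs, labels) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  X <- NULL
  for (b in c("A", "C", "G", "T")) X <- cbind(X, (m == b) / sqrt(2))
  centroid <- colMeans(X)
  ss_total <- sum(sweep(X, 2, centroid)^2)
  ss_within <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# Random additive tree and its exact leaf-to-leaf distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.5, 3))
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, dist = D[sort(rownames(D)), sort(rownames(D))])
}
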