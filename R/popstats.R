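# Per-population diversity statistics: haplotype diversity, nucleotide
# diversity, maximum pairwise divergence, and the group summary table.

#' Unbiased haplotype (gene) diversity
#'
#' \eqn{H = \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)} with
#' \eqn{\hat p_i = c_i / n}: the probability that two sequences drawn without
#' replacement carry different haplotypes. The \eqn{n/(n-1)} factor is the
#' standard small-sample correction.
#'
#' @param counts positive integer haplotype counts; `sum(counts)` must be
#'   at least 2. The statistic is undefined for a single sequence and an
#'   error of class `haplotrace_undefined_stat` is raised rather than
#'   reporting 0.
#' @return H in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts <= 0) || any(counts != floor(counts))) {
    hap_error("`counts` must be positive integers", "haplotrace_value_error")
  }
  n <- sum(counts)
  if (n < 2) {
    hap_error("haplotype diversity is undefined for n < 2",
              "haplotrace_undefined_stat")
  }
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity (pi, per site)
#'
#' Mean number of pairwise nucleotide differences per site over all
#' \eqn{\binom{n}{2}} sequence pairs:
#' \eqn{\pi = \frac{1}{L} \binom{n}{2}^{-1} \sum_{i<j} d_{ij}}.
#' No small-sample correction is applied.
#'
#' Supply either a specimen-level distance matrix (`counts = NULL`) or a
#' haplotype-level distance matrix together with haplotype `counts`, in which
#' case pairs within a haplotype contribute zero differences.
#'
#' @param dist symmetric matrix of pairwise substitution counts.
#' @param L alignment length in bp (taken from `attr(dist, "L")` if absent).
#' @param counts optional haplotype counts aligned with `dist` rows.
#' @return pi per site (>= 0).
#' @export
nucleotide_diversity <- function(dist, L = attr(dist, "L"), counts = NULL) {
  D <- as.matrix(dist)
  if (is.null(L) || L <= 0) {
    hap_error("alignment length L must be positive", "haplotrace_value_error")
  }
  if (is.null(counts)) {
    n <- nrow(D)
    if (n < 2) hap_error("pi is undefined for n < 2", "haplotrace_undefined_stat")
    total <- sum(D[upper.tri(D)])
  } else {
    counts <- as.numeric(counts)
    stopifnot(length(counts) == nrow(D))
    n <- sum(counts)
    if (n < 2) hap_error("pi is undefined for n < 2", "haplotrace_undefined_stat")
    cc <- tcrossprod(counts)
    total <- sum((cc * D)[upper.tri(D)])
  }
  total / choose(n, 2) / L
}

#' Maximum pairwise divergence (percent)
#'
#' Largest pairwise distance in the sample, expressed as a percentage of the
#' alignment length: \eqn{\max_{i<j} d_{ij} / L \times 100}.
#'
#' @inheritParams nucleotide_diversity
#' @return percent in `[0, 100]`.
#' @export
max_pairwise_divergence <- function(dist, L = attr(dist, "L"), counts = NULL) {
  D <- as.matrix(dist)
  if (is.null(L) || L <= 0) {
    hap_error("alignment length L must be positive", "haplotrace_value_error")
  }
  if (is.null(counts)) {
    n <- nrow(D)
    if (n < 2) hap_error("undefined for n < 2", "haplotrace_undefined_stat")
    mx <- if (n == 1) 0 else max(D[upper.tri(D)])
  } else {
    counts <- as.numeric(counts)
    stopifnot(length(counts) == nrow(D))
    if (sum(counts) < 2) hap_error("undefined for n < 2", "haplotrace_undefined_stat")
    present <- counts > 0
    Dp <- D[present, present, drop = FALSE]
    mx <- if (sum(present) < 2) 0 else max(Dp[upper.tri(Dp)])
  }
  mx / L * 100
}

#' Per-group diversity summary table
#'
#' One row per geographic group over analysis specimens: sample size `n`,
#' number of haplotypes, number of private haplotypes (those found in no
#' other group), maximum pairwise divergence (%), haplotype diversity,
#' nucleotide diversity, one count column per invasive haplotype, and the
#' percentage of specimens carrying invasive haplotypes. Groups with a single
#' specimen get `NA` for the three diversity statistics (the estimators are
#' undefined, which is not the same as observing zero diversity).
#'
#' @param catalog a `haplotype_catalog`.
#' @param meta the specimen table the catalog was built with.
#' @param grouping `"country"` or `"location"`.
#' @return A data.frame; attribute `"L"` carries the alignment length.
#' @export
summarize_groups <- function(catalog, meta, grouping = c("country", "location")) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  grouping <- match.arg(grouping)
  meta <- validate_specimen_table(meta)

  freq <- group_frequency_table(catalog, meta, grouping)
  freq <- freq[rowSums(freq) > 0, , drop = FALSE]
  # outgroup records are excluded from population statistics by design and
  # do not count as an emptied group
  empty <- setdiff(unique(meta[[grouping]][meta$status != "outgroup"]),
                   rownames(freq))
  hapD <- hamming_matrix(representative_alignment(catalog))
  L <- catalog$L
  inv_labels <- names(catalog$classification)[catalog$classification == "invasive"]
  # A haplotype is private to a group iff it occurs there and nowhere else.
  present_in <- colSums(freq > 0)

  rows <- lapply(rownames(freq), function(g) {
    cnt <- freq[g, ]
    n <- sum(cnt)
    occ <- cnt > 0
    out <- data.frame(
      group = g,
      n = n,
      n_haps = sum(occ),
      n_private = sum(occ & present_in == 1L),
      max_pwd_pct = if (n >= 2) max_pairwise_divergence(hapD, L, counts = cnt) else NA_real_,
      hap_div = if (n >= 2) haplotype_diversity(cnt[occ]) else NA_real_,
      nuc_div = if (n >= 2) nucleotide_diversity(hapD, L, counts = cnt) else NA_real_,
      stringsAsFactors = FALSE
    )
    for (lab in inv_labels) out[[lab]] <- unname(cnt[lab])
    out$pct_invasive <- 100 * sum(cnt[inv_labels]) / n
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "L") <- L
  if (length(empty)) {
    warning(sprintf("omitting empty group(s): %s", paste(empty, collapse = ", ")))
  }
  out
}

#' Round a diversity summary for report output
#'
#' Print precision: 4 decimals for haplotype diversity, 6 for nucleotide
#' diversity, 3 for maximum pairwise divergence, 1 for percentages.
#'
#' @param summary data.frame from [summarize_groups()].
#' @return The rounded data.frame.
#' @export
format_summary_table <- function(summary) {
  summary$hap_div <- round(summary$hap_div, 4)
  summary$nuc_div <- round(summary$nuc_div, 6)
  summary$max_pwd_pct <- round(summary$max_pwd_pct, 3)
  summary$pct_invasive <- round(summary$pct_invasive, 1)
  summary
}
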