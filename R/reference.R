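# Published per-country haplotype counts for the global Liriomyza
# huidobrensis COI/tRNA-Leu/COII survey, and a synthetic dataset constructor
# that realizes those counts so the full pipeline can be exercised against
# the printed summary statistics. The sequences themselves are synthetic
# stand-ins (the survey's real sequences are not bundled); only the count
# structure is reproduced.

#' Published per-country haplotype counts (invasion survey)
#'
#' Counts of the four globally shared ("invasive") haplotypes Hap-A..Hap-D
#' and of private haplotypes per country, from the global
#' *L. huidobrensis* mtDNA survey (403 field-collected specimens, 2181 bp).
#' Central American countries are recorded as `introduced`, the survey's
#' own conclusion about their status.
#'
#' @return data.frame with columns `country`, `status`, `n`, `hapA`..`hapD`
#'   (invasive haplotype carriers), `n_private` (number of private
#'   haplotypes).
#' @export
invasion_survey_counts <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
country      status      n  hapA hapB hapC hapD n_private
Argentina    native      9     0    0    0    0    5
Colombia     native     22     0    0    0    0    8
Ecuador      native     49     4    0    0    0   13
Peru         native     93    32    7    1    1   15
CostaRica    introduced 17    15    0    0    0    2
Guatemala    introduced 42    37    4    0    0    1
Panama       introduced  7     7    0    0    0    0
Canada       introduced  9     7    1    0    0    1
China        introduced  9     9    0    0    0    0
Indonesia    introduced 17     8    4    0    0    1
Israel       introduced 13     9    1    1    1    1
Italy        introduced  9     8    1    0    0    0
Malaysia     introduced  2     2    0    0    0    0
Philippines  introduced 60    60    0    0    0    0
SouthAfrica  introduced 31    31    0    0    0    0
SriLanka     introduced 14    14    0    0    0    0
")
  df
}

# Partition the non-invasive remainder of a country across its private
# haplotypes: the first private haplotype takes the surplus, the rest are
# singletons. This reproduces the count vectors that determine the printed
# haplotype diversities where they are determined (e.g. one private
# haplotype, or all-singleton privates).
private_partition <- function(remainder, n_private) {
  if (n_private == 0L) return(integer(0))
  c(remainder - (n_private - 1L), rep(1L, n_private - 1L))
}

#' Synthetic dataset realizing the published survey counts
#'
#' Builds an alignment and specimen table whose haplotype frequency
#' structure matches [invasion_survey_counts()]: four shared haplotypes with
#' the printed per-country counts plus per-country private haplotypes
#' partitioned as surplus-plus-singletons. Sequences are synthetic: each
#' haplotype differs from a common base at its own unique sites.
#'
#' @param L sequence length for the synthetic haplotypes (default 400;
#'   enough unique sites for all haplotypes).
#' @return List with `alignment`, `meta`, and `counts` (the count table).
#' @export
reference_dataset <- function(L = 400L) {
  counts <- invasion_survey_counts()
  n_countries <- nrow(counts)
  n_shared <- 4L
  total_private <- sum(counts$n_private)
  if (L < n_shared + total_private + 1L) {
    hap_error("L too small for distinct reference haplotypes",
              "haplotrace_capacity_error")
  }
  base <- strsplit(paste(rep("ACGT", ceiling(L / 4)), collapse = ""), "")[[1]][1:L]
  flip <- function(ch) c(A = "C", C = "G", G = "T", T = "A")[[ch]]
  hap_at <- function(sites) {
    s <- base
    for (k in sites) s[k] <- flip(s[k])
    paste0(s, collapse = "")
  }
  shared_seqs <- c(hapA = paste0(base, collapse = ""),
                   hapB = hap_at(1L), hapC = hap_at(2L), hapD = hap_at(3L))
  next_site <- n_shared

  ids <- character(0); seqs <- character(0); country <- character(0)
  status <- character(0)
  for (i in seq_len(n_countries)) {
    row <- counts[i, ]
    cseqs <- character(0)
    # shared haplotypes in A..D order so that first-occurrence tie-breaks
    # are deterministic
    for (h in c("hapA", "hapB", "hapC", "hapD")) {
      cseqs <- c(cseqs, rep(shared_seqs[[h]], row[[h]]))
    }
    remainder <- row$n - sum(row[, c("hapA", "hapB", "hapC", "hapD")])
    part <- private_partition(remainder, row$n_private)
    for (cnt in part) {
      next_site <- next_site + 1L
      cseqs <- c(cseqs, rep(hap_at(next_site), cnt))
    }
    stopifnot(length(cseqs) == row$n)
    cids <- sprintf("%s_%03d", row$country, seq_len(row$n))
    ids <- c(ids, cids); seqs <- c(seqs, cseqs)
    country <- c(country, rep(row$country, row$n))
    status <- c(status, rep(row$status, row$n))
  }
  aln <- alignment(ids, seqs)
  meta <- data.frame(specimen_id = ids, country = country,
                     location = country, status = status,
                     host = "", year = NA_integer_, stringsAsFactors = FALSE)
  list(alignment = aln, meta = meta, counts = counts)
}
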