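# Collapsing aligned sequences into haplotypes, abundance labelling, and the
# private / shared-native / invasive classification.

#' Collapse an alignment into a labelled haplotype catalog
#'
#' Two specimens share a haplotype iff their (unambiguous) sequences are
#' identical. Haplotypes are ranked by their abundance among *analysis*
#' specimens (those whose status is not in `exclude_status`; interception and
#' outgroup records are catalogued but never counted), ties broken by first
#' occurrence in input order. Haplotypes satisfying the invasive rule (see
#' [classify_haplotypes()]) are labelled `Hap-A`, `Hap-B`, ... in rank order;
#' all others receive zero-padded numeric labels `H01`, `H02`, ...
#'
#' @param aln a `hap_alignment`; sequences must be unambiguous (`A/C/G/T`).
#' @param meta specimen table covering every id in `aln`.
#' @param exclude_status statuses excluded from abundance ranking and
#'   classification. Default `c("interception", "outgroup")`.
#' @param grouping `"country"` or `"location"`: the geographic unit used for
#'   the default classification stored in the catalog.
#' @param allow_unmatched if `FALSE` (default), specimens present in exactly
#'   one of alignment/metadata raise an error; if `TRUE`, alignment-only
#'   specimens are dropped with a warning and metadata-only rows ignored.
#' @return An object of class `haplotype_catalog`: a list with
#'   `haplotypes` (data.frame: `label`, `seq`, `n_analysis`, `n_total`),
#'   `members` (named list label -> specimen ids), `assignment` (named
#'   character specimen -> label), `classification` (named character label ->
#'   `private`/`shared_native`/`invasive`), `excluded_ids`, `grouping`, `L`.
#' @export
collapse_and_label <- function(aln, meta,
                               exclude_status = c("interception", "outgroup"),
                               grouping = c("country", "location"),
                               allow_unmatched = FALSE) {
  stopifnot(inherits(aln, "hap_alignment"))
  grouping <- match.arg(grouping)
  meta <- validate_specimen_table(meta)

  only_aln <- setdiff(aln$ids, meta$specimen_id)
  if (length(only_aln)) {
    if (!allow_unmatched) {
      hap_error(paste0("specimens in alignment but not metadata: ",
                       paste(only_aln, collapse = ", ")),
                "haplotrace_join_error")
    }
    warning(sprintf("dropping %d specimens absent from metadata", length(only_aln)))
    keep <- !(aln$ids %in% only_aln)
    aln <- alignment(aln$ids[keep], aln$seqs[keep])
  }
  only_meta <- setdiff(meta$specimen_id, aln$ids)
  if (length(only_meta) && !allow_unmatched) {
    hap_error(paste0("specimens in metadata but not alignment: ",
                     paste(only_meta, collapse = ", ")),
              "haplotrace_join_error")
  }

  if (!all(is_unambiguous(aln$seqs))) {
    hap_error("alignment contains ambiguous sites; run filter_and_trim() first",
              "haplotrace_alphabet_error")
  }

  status <- meta$status[match(aln$ids, meta$specimen_id)]
  excluded_ids <- aln$ids[status %in% exclude_status]

  # Partition specimens by identical sequence, preserving first occurrence.
  key <- factor(aln$seqs, levels = unique(unname(aln$seqs)))
  members <- split(aln$ids, key)
  hap_seq <- levels(key)
  analysis_ids <- setdiff(aln$ids, excluded_ids)
  n_analysis <- vapply(members, function(m) sum(m %in% analysis_ids), integer(1))
  n_total <- lengths(members)
  first_idx <- vapply(members, function(m) match(m[1], aln$ids), integer(1))

  rank_order <- order(-n_analysis, first_idx)
  members <- members[rank_order]
  hap_seq <- hap_seq[rank_order]
  n_analysis <- n_analysis[rank_order]
  n_total <- n_total[rank_order]

  # Provisional catalog to drive classification (labels not yet final).
  tmp_labels <- sprintf("tmp%04d", seq_along(hap_seq))
  names(members) <- tmp_labels
  cls <- classify_members(members, meta, grouping, analysis_ids)

  labels <- character(length(hap_seq))
  inv <- which(cls == "invasive")
  labels[inv] <- paste0("Hap-", make_letter_labels(length(inv)))
  rest <- which(cls != "invasive")
  width <- max(2L, nchar(length(rest)))
  labels[rest] <- sprintf("H%0*d", width, seq_along(rest))

  names(members) <- labels
  names(cls) <- labels
  assignment <- stats::setNames(
    rep(labels, lengths(members)), unlist(members, use.names = FALSE))
  # Restore input specimen order in the assignment map.
  assignment <- assignment[aln$ids]

  structure(list(
    haplotypes = data.frame(label = labels, seq = hap_seq,
                            n_analysis = unname(n_analysis),
                            n_total = unname(n_total),
                            stringsAsFactors = FALSE),
    members = members,
    assignment = assignment,
    classification = cls,
    excluded_ids = excluded_ids,
    grouping = grouping,
    L = aln$L
  ), class = "haplotype_catalog")
}

make_letter_labels <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(k)]
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat(sprintf("<haplotype_catalog> %d haplotypes, %d analysis specimens (%d excluded), L = %d\n",
              nrow(x$haplotypes), sum(x$haplotypes$n_analysis),
              length(x$excluded_ids), x$L))
  cls <- table(factor(x$classification,
                      levels = c("invasive", "shared_native", "private")))
  cat(sprintf("  invasive: %d  shared_native: %d  private: %d\n",
              cls[["invasive"]], cls[["shared_native"]], cls[["private"]]))
  invisible(x)
}

# Core classification rule on a members list. A haplotype is
#  - private:       found in exactly one group (or in none of the analysis
#                    specimens, e.g. carried only by interceptions);
#  - invasive:      found in >= 2 groups AND carried by >= 1 specimen with
#                    status "introduced";
#  - shared_native: found in >= 2 groups but never in an introduced specimen.
# Excluded (interception/outgroup) specimens never contribute.
classify_members <- function(members, meta, grouping, analysis_ids) {
  grp <- meta[[grouping]][match(analysis_ids, meta$specimen_id)]
  names(grp) <- analysis_ids
  stat <- meta$status[match(analysis_ids, meta$specimen_id)]
  names(stat) <- analysis_ids
  vapply(members, function(m) {
    m <- m[m %in% analysis_ids]
    n_groups <- length(unique(grp[m]))
    if (n_groups <= 1L) return("private")
    if (any(stat[m] == "introduced")) "invasive" else "shared_native"
  }, character(1))
}

#' Classify haplotypes as private, shared-native, or invasive
#'
#' Applies the geographic classification rule: a haplotype observed in two or
#' more groups that is carried by at least one introduced specimen is
#' *invasive*; one observed in two or more groups but never in an introduced
#' population is *shared_native*; anything confined to a single group is
#' *private* (including haplotypes found only in introduced populations).
#' Interception and outgroup specimens never contribute.
#'
#' @param catalog a `haplotype_catalog`.
#' @param meta the specimen table the catalog was built with.
#' @param grouping `"country"` or `"location"`.
#' @return Named character vector label -> classification.
#' @export
classify_haplotypes <- function(catalog, meta, grouping = c("country", "location")) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  grouping <- match.arg(grouping)
  meta <- validate_specimen_table(meta)
  all_ids <- unlist(catalog$members, use.names = FALSE)
  analysis_ids <- setdiff(all_ids, catalog$excluded_ids)
  classify_members(catalog$members, meta, grouping, analysis_ids)
}

#' Haplotype frequency table by group
#'
#' Counts of each haplotype among analysis specimens, one row per group.
#' Row sums equal group sample sizes; the global sum equals the number of
#' analysis specimens.
#'
#' @param catalog a `haplotype_catalog`.
#' @param meta the specimen table the catalog was built with.
#' @param grouping `"country"` or `"location"`.
#' @return Integer matrix, rows = groups (in order of first appearance in
#'   `meta`), columns = haplotype labels (catalog order).
#' @export
group_frequency_table <- function(catalog, meta, grouping = c("country", "location")) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  grouping <- match.arg(grouping)
  meta <- validate_specimen_table(meta)
  all_ids <- unlist(catalog$members, use.names = FALSE)
  ids <- setdiff(all_ids, catalog$excluded_ids)
  grp <- meta[[grouping]][match(ids, meta$specimen_id)]
  lab <- catalog$assignment[ids]
  groups_in_order <- unique(meta[[grouping]][meta$specimen_id %in% ids])
  tab <- table(factor(grp, levels = groups_in_order),
               factor(lab, levels = catalog$haplotypes$label))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Per-group composition of every haplotype, including excluded specimens
#'
#' Used for network/tree node composition, where interception specimens are
#' retained (unlike frequency tables and classification).
#'
#' @inheritParams group_frequency_table
#' @return Integer matrix rows = groups, columns = haplotype labels.
#' @export
haplotype_composition <- function(catalog, meta, grouping = c("country", "location")) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  grouping <- match.arg(grouping)
  meta <- validate_specimen_table(meta)
  ids <- unlist(catalog$members, use.names = FALSE)
  grp <- meta[[grouping]][match(ids, meta$specimen_id)]
  lab <- catalog$assignment[ids]
  tab <- table(factor(grp, levels = unique(meta[[grouping]][meta$specimen_id %in% ids])),
               factor(lab, levels = catalog$haplotypes$label))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Representative alignment of a catalog (one sequence per haplotype)
#'
#' @param catalog a `haplotype_catalog`.
#' @return A `hap_alignment` whose ids are the haplotype labels.
#' @export
representative_alignment <- function(catalog) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  alignment(catalog$haplotypes$label, catalog$haplotypes$seq)
}
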