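# Reading, validating, filtering and writing aligned sequence data and
# specimen metadata.

ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

SPECIMEN_STATUSES <- c("native", "introduced", "interception", "outgroup")

REQUIRED_META_COLS <- c("specimen_id", "country", "location", "status",
                        "host", "year")

#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-length uppercase DNA sequences
#' keyed by unique specimen identifiers. Sequences may contain IUPAC
#' ambiguity codes, `N`, and the gap character `-`; downstream analyses
#' require the unambiguous alphabet `A/C/G/T` and reject the rest via
#' [filter_and_trim()].
#'
#' @param ids character vector of unique specimen identifiers.
#' @param seqs character vector of DNA sequences, same length as `ids`.
#' @return An object of class `hap_alignment` with fields `ids`, `seqs`
#'   (named by id) and `L` (alignment length in bp).
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0L) {
    hap_error("alignment has no sequences", "haplotrace_empty_error")
  }
  if (length(ids) != length(seqs)) {
    hap_error("`ids` and `seqs` differ in length", "haplotrace_shape_error")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    hap_error(paste0("duplicate specimen ids: ", paste(dup, collapse = ", ")),
              "haplotrace_duplicate_id_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    hap_error(sprintf("sequences have unequal lengths (%s)",
                      paste(sort(unique(lens)), collapse = ", ")),
              "haplotrace_shape_error")
  }
  if (lens[1] == 0L) {
    hap_error("alignment length is zero", "haplotrace_shape_error")
  }
  bad <- grepl(sprintf("[^%s]", paste(c(ALLOWED_CHARS[ALLOWED_CHARS != "-"], "\\-"),
                                      collapse = "")), seqs)
  if (any(bad)) {
    hap_error(paste0("non-IUPAC characters in sequences for: ",
                     paste(ids[bad], collapse = ", ")),
              "haplotrace_alphabet_error")
  }
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids), L = lens[1]),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences, %d bp\n", length(x$ids), x$L))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences are case-normalized to uppercase and file order is preserved.
#' All records must have identical length.
#'
#' @param path path to a FASTA file (single-line or wrapped).
#' @return A `hap_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    hap_error(paste0("file not found: ", path), "haplotrace_io_error")
  }
  dna <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                  error = function(e) hap_error(
                    paste0("could not parse FASTA: ", conditionMessage(e)),
                    "haplotrace_empty_error"))
  if (length(dna) == 0L) {
    hap_error(paste0("no FASTA records in ", path), "haplotrace_empty_error")
  }
  seqs <- vapply(as.character(dna), paste0, character(1), collapse = "")
  alignment(names(dna), seqs)
}

#' Read a specimen metadata table
#'
#' The table is tab-separated with header columns `specimen_id`, `country`,
#' `location`, `status`, `host`, `year`. `status` must be one of `native`,
#' `introduced`, `interception`, `outgroup`. Extra columns are preserved.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with one row per specimen.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) {
    hap_error(paste0("file not found: ", path), "haplotrace_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  validate_specimen_table(df)
}

#' Validate a specimen table held in memory
#'
#' @param df data.frame with the columns described in [read_specimen_table()].
#' @return The validated data.frame (year coerced to integer, empty -> NA).
#' @export
validate_specimen_table <- function(df) {
  missing_cols <- setdiff(REQUIRED_META_COLS, names(df))
  if (length(missing_cols)) {
    hap_error(paste0("missing required columns: ",
                     paste(missing_cols, collapse = ", ")),
              "haplotrace_schema_error")
  }
  if (anyDuplicated(df$specimen_id)) {
    dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
    hap_error(paste0("duplicate specimen ids: ", paste(dup, collapse = ", ")),
              "haplotrace_duplicate_id_error")
  }
  bad <- !(df$status %in% SPECIMEN_STATUSES)
  if (any(bad)) {
    hap_error(sprintf("status values outside {%s}: %s",
                      paste(SPECIMEN_STATUSES, collapse = ", "),
                      paste(unique(df$status[bad]), collapse = ", ")),
              "haplotrace_status_error")
  }
  df$year <- suppressWarnings(as.integer(df$year))
  rownames(df) <- NULL
  df
}

#' Filter ambiguous specimens and trim the alignment window
#'
#' Restricts every sequence to the 0-based half-open window `[start, end)`
#' and, when `drop_ambiguous` is set, removes specimens whose windowed
#' sequence contains anything outside `A/C/G/T` (IUPAC ambiguity codes, `N`
#' and gaps all count as ambiguous: the statistics downstream are defined on
#' confirmed sites only).
#'
#' @param aln a `hap_alignment`.
#' @param start 0-based inclusive window start. Default 0.
#' @param end 0-based exclusive window end. Default the alignment length.
#' @param drop_ambiguous drop specimens with ambiguous sites in the window.
#' @return A list with `alignment` (the trimmed `hap_alignment`) and
#'   `rejected_ids` (character vector of removed specimens).
#' @export
filter_and_trim <- function(aln, start = 0L, end = aln$L, drop_ambiguous = TRUE) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (!(start >= 0 && start < end && end <= aln$L)) {
    hap_error(sprintf("invalid window [%s, %s) for alignment of length %d",
                      format(start), format(end), aln$L),
              "haplotrace_bounds_error")
  }
  win <- substr(aln$seqs, start + 1L, end)
  keep <- if (drop_ambiguous) is_unambiguous(win) else rep(TRUE, length(win))
  if (!any(keep)) {
    hap_error("all specimens rejected: window leaves an empty alignment",
              "haplotrace_empty_error")
  }
  list(
    alignment = alignment(aln$ids[keep], win[keep]),
    rejected_ids = aln$ids[!keep]
  )
}

#' Write one representative sequence per haplotype as FASTA
#'
#' Headers are the haplotype labels; the output round-trips through
#' [read_alignment()].
#'
#' @param catalog a `haplotype_catalog` from [collapse_and_label()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  h <- catalog$haplotypes
  if (nrow(h) == 0L) {
    hap_error("catalog is empty", "haplotrace_empty_error")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", h$label, "\n", h$seq), con, sep = "\n")
  invisible(path)
}

#' Write an alignment as FASTA
#'
#' @param aln a `hap_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", unname(aln$seqs)), con, sep = "\n")
  invisible(path)
}

#' Write a specimen table as TSV
#'
#' @param meta specimen data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
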