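# Orchestration: run the full analysis (haplotype catalog, summary table,
# AMOVAs, network, tree) and write a reproducible report bundle.

log_stage <- function(fmt, ...) message(sprintf(paste0("[haplotrace] ", fmt), ...))

#' Run the full phylogeographic analysis pipeline
#'
#' Stages: read/validate inputs, optional filtering and trimming, haplotype
#' collapsing and classification, per-group diversity summary, one AMOVA per
#' country sampled at two or more locations, minimum-spanning haplotype
#' network, and a neighbor-joining tree with bootstrap supports (rooted on
#' the outgroup when present). Interception specimens are excluded from the
#' summary table, classification and AMOVA, but retained in the network and
#' tree; an outgroup specimen appears only in the tree.
#'
#' The bundle written to `outdir`: `haplotypes.fasta`, `summary_table.tsv`,
#' `classification.tsv`, `amova_<country>.tsv` (one per eligible country),
#' `network_edges.tsv`, `network_nodes.tsv`, `tree.nwk`, `run.json`. Reruns
#' with the same inputs and parameters are byte-identical.
#'
#' @param alignment a `hap_alignment` or path to a FASTA file.
#' @param meta a specimen data.frame or path to a TSV file.
#' @param outdir output directory (created if needed).
#' @param grouping `"country"` or `"location"` for summary/classification.
#' @param trim optional `c(start, end)` 0-based half-open window passed to
#'   [filter_and_trim()]; ambiguous specimens are always dropped.
#' @param n_perm AMOVA permutations (default 1000).
#' @param bootstrap NJ bootstrap replicates (default 1000; 0 disables).
#' @param seed integer seed covering all stochastic stages (required).
#' @param cluster_cut edge weight regarded as a long mutational branch when
#'   reporting network clusters (default 6).
#' @param epsilon minimum-spanning-network relaxation (default 0).
#' @param outgroup specimen id of the outgroup record, or `NULL`; defaults
#'   to the single specimen with status `"outgroup"` if present.
#' @return Invisibly, a list with the catalog, summary, amova results,
#'   network, clusters, tree, and output paths.
#' @export
run_pipeline <- function(alignment, meta, outdir,
                         grouping = c("country", "location"),
                         trim = NULL, n_perm = 1000L, bootstrap = 1000L,
                         seed, cluster_cut = 6L, epsilon = 0,
                         outgroup = NULL) {
  grouping <- match.arg(grouping)
  if (missing(seed)) hap_error("`seed` is required", "haplotrace_seed_error")
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(meta)) meta <- read_specimen_table(meta)
  meta <- validate_specimen_table(meta)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list()

  log_stage("input: %d sequences of %d bp, %d metadata rows",
            length(alignment$ids), alignment$L, nrow(meta))

  rejected <- character(0)
  if (!is.null(trim)) {
    ft <- filter_and_trim(alignment, trim[1], trim[2], drop_ambiguous = TRUE)
    alignment <- ft$alignment
    rejected <- ft$rejected_ids
  } else if (!all(is_unambiguous(alignment$seqs))) {
    ft <- filter_and_trim(alignment, 0L, alignment$L, drop_ambiguous = TRUE)
    alignment <- ft$alignment
    rejected <- ft$rejected_ids
  }
  if (length(rejected)) {
    log_stage("filter: removed %d specimens with ambiguous sites", length(rejected))
    meta <- meta[meta$specimen_id %in% alignment$ids, , drop = FALSE]
  }

  if (is.null(outgroup)) {
    og <- meta$specimen_id[meta$status == "outgroup"]
    if (length(og) == 1L) outgroup <- og
  }

  log_stage("collapse: building haplotype catalog (grouping = %s)", grouping)
  catalog <- collapse_and_label(alignment, meta, grouping = grouping)
  outgroup_hap <- if (!is.null(outgroup)) unname(catalog$assignment[outgroup]) else NULL

  paths$haplotypes <- file.path(outdir, "haplotypes.fasta")
  write_haplotype_fasta(catalog, paths$haplotypes)

  log_stage("stats: per-%s diversity summary", grouping)
  summary <- summarize_groups(catalog, meta, grouping = grouping)
  paths$summary <- file.path(outdir, "summary_table.tsv")
  utils::write.table(format_summary_table(summary), paths$summary,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  paths$classification <- file.path(outdir, "classification.tsv")
  utils::write.table(
    data.frame(haplotype = names(catalog$classification),
               classification = unname(catalog$classification)),
    paths$classification, sep = "\t", quote = FALSE, row.names = FALSE)

  # AMOVA per country sampled at >= 2 locations (analysis specimens only).
  analysis_meta <- meta[meta$status %in% c("native", "introduced"), , drop = FALSE]
  amovas <- list()
  k <- 0L
  for (ct in unique(analysis_meta$country)) {
    sub <- analysis_meta[analysis_meta$country == ct, , drop = FALSE]
    locs <- unique(sub$location)
    if (length(locs) < 2L || nrow(sub) <= length(locs)) next
    k <- k + 1L
    log_stage("amova: %s across %d locations (n = %d, %d permutations)",
              ct, length(locs), nrow(sub), n_perm)
    D <- hamming_matrix(alignment$seqs[sub$specimen_id])
    res <- amova_one_level(D, sub$location, n_perm = n_perm, seed = seed + k)
    amovas[[ct]] <- res
    p <- file.path(outdir, paste0("amova_", ct, ".tsv"))
    paths[[paste0("amova_", ct)]] <- p
    utils::write.table(amova_table(res), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }

  log_stage("network: minimum-spanning network (epsilon = %g)", epsilon)
  net <- haplotype_network(catalog, meta, grouping = grouping,
                           epsilon = epsilon,
                           drop_labels = outgroup_hap %||% character(0))
  clusters <- network_clusters(net, cut = cluster_cut)
  paths$network_edges <- file.path(outdir, "network_edges.tsv")
  utils::write.table(net$edges, paths$network_edges, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$network_nodes <- file.path(outdir, "network_nodes.tsv")
  nodes <- net$nodes
  nodes$cluster <- unname(clusters[nodes$label])
  comp <- t(net$composition)
  colnames(comp) <- paste0("n_", colnames(comp))
  nodes <- cbind(nodes, comp[nodes$label, , drop = FALSE])
  utils::write.table(nodes, paths$network_nodes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  reps <- representative_alignment(catalog)
  tree <- NULL
  if (length(reps$ids) >= 3L) {
    log_stage("tree: neighbor joining over %d haplotypes (B = %d)",
              length(reps$ids), bootstrap)
    if (bootstrap > 0 && length(reps$ids) >= 4L) {
      tree <- bootstrap_support(reps, B = bootstrap, seed = seed)
    } else {
      tree <- neighbor_joining(hamming_matrix(reps))
    }
    if (!is.null(outgroup_hap) && outgroup_hap %in% tree$tip.label) {
      tree <- root_with_outgroup(tree, outgroup_hap)
    }
    paths$tree <- file.path(outdir, "tree.nwk")
    writeLines(to_newick(tree), paths$tree)
  } else {
    log_stage("tree: skipped (fewer than 3 haplotypes)")
  }

  run_info <- list(
    parameters = list(grouping = grouping, trim = trim, n_perm = n_perm,
                      bootstrap = bootstrap, cluster_cut = cluster_cut,
                      epsilon = epsilon, outgroup = outgroup),
    seeds = list(master = seed,
                 amova = if (k > 0) seed + seq_len(k) else integer(0),
                 bootstrap = seed),
    versions = list(package = as.character(utils::packageVersion("haplotrace")),
                    R = R.version.string),
    counts = list(n_specimens = length(alignment$ids),
                  n_analysis = sum(catalog$haplotypes$n_analysis),
                  n_haplotypes = nrow(catalog$haplotypes),
                  n_rejected = length(rejected))
  )
  paths$run <- file.path(outdir, "run.json")
  jsonlite::write_json(run_info, paths$run, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)

  log_stage("done: %d artifacts in %s", length(paths), outdir)
  invisible(list(catalog = catalog, summary = summary, amova = amovas,
                 network = net, clusters = clusters, tree = tree,
                 paths = paths))
}
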