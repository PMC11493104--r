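# Neighbor-joining trees over haplotypes with bootstrap support, outgroup
# rooting, and newick serialization. Tree inference and manipulation are
# delegated to ape; this module adds branch-length clamping, seeded
# column-resampling bootstrap, and pendant-edge rooting.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration on the Q-criterion (via [ape::nj()]). Negative
#' branch lengths, which NJ can produce on non-additive matrices, are
#' clamped to zero; the unclamped values are retained in the attribute
#' `raw_edge_lengths`.
#'
#' @param dist symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  D <- as.matrix(dist)
  if (nrow(D) < 3L) {
    hap_error("neighbor joining needs at least 3 taxa", "haplotrace_value_error")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  tr <- ape::nj(stats::as.dist(D))
  attr(tr, "raw_edge_lengths") <- tr$edge.length
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree from Hamming distances for each replicate, and scores each internal
#' edge of the reference tree by the percentage of replicates in which its
#' bipartition is recovered. Fully reproducible from `seed`.
#'
#' @param aln a `hap_alignment` of haplotype representatives (unambiguous).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param normalize use proportional distances (substitutions per site);
#'   the NJ topology is unaffected, default `FALSE`.
#' @return The reference NJ `phylo` tree with `node.label` set to support
#'   percentages (root label `NA`) and attributes `supports` (numeric, one
#'   per internal node) and `zero_length_internal` (logical flag per internal
#'   node marking zero-length edges, whose support is not meaningful).
#' @export
bootstrap_support <- function(aln, B, seed, normalize = FALSE) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (B < 1) hap_error("B must be >= 1", "haplotrace_value_error")
  m <- seq_char_matrix(aln$seqs)
  ref <- neighbor_joining(hamming_matrix(aln, normalize = normalize))

  boots <- local_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      seqs <- apply(m[, cols, drop = FALSE], 1, paste0, collapse = "")
      names(seqs) <- aln$ids
      neighbor_joining(hamming_matrix(seqs, normalize = normalize))
    })
  })

  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  supports <- 100 * counts / B
  supports[is.na(counts)] <- NA_real_

  # Internal edges of length zero carry no signal; flag them.
  ntip <- length(ref$tip.label)
  internal_nodes <- ntip + seq_len(ref$Nnode)
  zero_flag <- vapply(internal_nodes, function(nd) {
    k <- which(ref$edge[, 2] == nd)
    length(k) == 1L && ref$edge.length[k] == 0
  }, logical(1))

  ref$node.label <- ifelse(is.na(supports), "", format(supports, trim = TRUE))
  attr(ref, "supports") <- supports
  attr(ref, "zero_length_internal") <- zero_flag
  ref
}

#' Root a tree on the outgroup's pendant edge
#'
#' Places the root at the midpoint of the edge subtending the outgroup leaf,
#' preserving ingroup bipartitions.
#'
#' @param tree a `phylo` tree.
#' @param outgroup_label tip label of the outgroup taxon.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  stopifnot(inherits(tree, "phylo"))
  if (!(outgroup_label %in% tree$tip.label)) {
    hap_error(paste0("outgroup not among tips: ", outgroup_label),
              "haplotrace_value_error")
  }
  tr <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  root_node <- length(tr$tip.label) + 1L
  ch <- which(tr$edge[, 1] == root_node)
  if (length(ch) == 2L) {
    tot <- sum(tr$edge.length[ch])
    tr$edge.length[ch] <- tot / 2
  }
  tr
}

#' Serialize a tree to newick text
#'
#' Branch lengths are included; bootstrap supports (if present as node
#' labels) appear as internal node labels. The output parses back (e.g. via
#' [ape::read.tree()]) to a tree with identical bipartitions.
#'
#' @param tree a `phylo` tree.
#' @return A single newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
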