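# Minimum-spanning haplotype network (union of all minimum spanning trees)
# and mutational-branch cluster detection.

# Small union-find over integer indices.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Minimum-spanning haplotype network
#'
#' Builds the network whose edge set, at `epsilon = 0`, is exactly the union
#' of all minimum spanning trees of the complete graph over haplotypes
#' weighted by mutational distance: an edge `(u, v)` of weight `w` is
#' included iff `u` and `v` cannot be connected using only edges of weight
#' `< w`. With `epsilon > 0` the connectivity threshold is relaxed to
#' `< w - epsilon`, admitting additional near-minimal edges. The construction
#' proceeds in Kruskal rounds over increasing weight levels, with all edges
#' of a level tested against the same connectivity state, so the result is
#' deterministic and independent of input order.
#'
#' @param dist symmetric matrix of pairwise mutational distances over
#'   haplotypes (labelled dimnames).
#' @param epsilon non-negative relaxation parameter; default 0.
#' @param sizes optional named vector of haplotype sizes (member counts)
#'   stored on the nodes.
#' @param composition optional matrix (groups x haplotypes) stored for
#'   reporting.
#' @return An object of class `haplo_network`: list with `nodes`
#'   (data.frame `label`, `size`), `edges` (data.frame `from`, `to`,
#'   `weight`, sorted by weight then labels, with `from < to`), `epsilon`,
#'   and optional `composition`.
#' @export
minimum_spanning_network <- function(dist, epsilon = 0, sizes = NULL,
                                     composition = NULL) {
  D <- as.matrix(dist)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("h", seq_len(nrow(D)))
  }
  if (epsilon < 0) hap_error("epsilon must be >= 0", "haplotrace_value_error")
  labs <- rownames(D)
  n <- length(labs)
  ord <- order(labs)  # canonical node order, input-order invariant
  D <- D[ord, ord, drop = FALSE]
  labs <- labs[ord]

  nodes <- data.frame(label = labs,
                      size = if (is.null(sizes)) rep(1L, n) else
                        as.integer(sizes[labs]),
                      stringsAsFactors = FALSE)

  if (n == 1L) {
    return(structure(list(
      nodes = nodes,
      edges = data.frame(from = character(0), to = character(0),
                         weight = numeric(0), stringsAsFactors = FALSE),
      epsilon = epsilon, composition = composition
    ), class = "haplo_network"))
  }

  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ew <- D[upper.tri(D)]
  eo <- order(ew, pairs[, 1], pairs[, 2])
  pairs <- pairs[eo, , drop = FALSE]
  ew <- ew[eo]

  parent <- uf_new(n)
  ptr <- 1L          # next graph edge not yet merged into the test state
  included <- logical(length(ew))
  for (w in unique(ew)) {
    # connectivity state: all graph edges with weight < w - epsilon
    while (ptr <= length(ew) && ew[ptr] < w - epsilon) {
      parent <- uf_union(parent, pairs[ptr, 1], pairs[ptr, 2])
      ptr <- ptr + 1L
    }
    lvl <- which(ew == w)
    included[lvl] <- vapply(lvl, function(k) {
      uf_find(parent, pairs[k, 1]) != uf_find(parent, pairs[k, 2])
    }, logical(1))
  }

  keep <- which(included)
  edges <- data.frame(from = labs[pairs[keep, 1]],
                      to = labs[pairs[keep, 2]],
                      weight = ew[keep], stringsAsFactors = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 composition = composition),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes, %d edges (epsilon = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Clusters separated by long mutational branches
#'
#' Connected components of the network after removing every edge whose
#' weight is `>= cut`. Components are numbered in order of decreasing total
#' membership (sum of node sizes), ties broken by smallest node label.
#'
#' @param net a `haplo_network`.
#' @param cut minimum branch length (substitutions) regarded as "long";
#'   must be >= 1. `Inf` keeps every edge.
#' @return Named integer vector node label -> cluster id.
#' @export
network_clusters <- function(net, cut) {
  stopifnot(inherits(net, "haplo_network"))
  if (!is.numeric(cut) || length(cut) != 1L || cut < 1) {
    hap_error("`cut` must be a single value >= 1", "haplotrace_bounds_error")
  }
  labs <- net$nodes$label
  n <- length(labs)
  parent <- uf_new(n)
  e <- net$edges[net$edges$weight < cut, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    parent <- uf_union(parent, match(e$from[k], labs), match(e$to[k], labs))
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp_sizes <- tapply(net$nodes$size, roots, sum)
  comp_minlab <- tapply(labs, roots, min)
  comp_order <- order(-as.numeric(comp_sizes), comp_minlab)
  rank <- stats::setNames(seq_along(comp_order),
                          names(comp_sizes)[comp_order])
  stats::setNames(as.integer(rank[as.character(roots)]), labs)
}

#' Build the haplotype network for a catalog
#'
#' Convenience wrapper: Hamming distances over haplotype representatives
#' (outgroup haplotypes excluded by default; interception-only haplotypes
#' retained), node sizes from total membership, per-group composition
#' attached.
#'
#' @param catalog a `haplotype_catalog`.
#' @param meta the specimen table the catalog was built with.
#' @param grouping grouping for the composition table.
#' @param epsilon relaxation parameter, see [minimum_spanning_network()].
#' @param drop_labels haplotype labels to exclude (e.g. the outgroup).
#' @return A `haplo_network`.
#' @export
haplotype_network <- function(catalog, meta, grouping = "country",
                              epsilon = 0, drop_labels = character(0)) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  keep <- !(catalog$haplotypes$label %in% drop_labels)
  reps <- alignment(catalog$haplotypes$label[keep], catalog$haplotypes$seq[keep])
  D <- hamming_matrix(reps)
  sizes <- stats::setNames(catalog$haplotypes$n_total[keep],
                           catalog$haplotypes$label[keep])
  comp <- haplotype_composition(catalog, meta, grouping)[, keep, drop = FALSE]
  minimum_spanning_network(D, epsilon = epsilon, sizes = sizes,
                           composition = comp)
}
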