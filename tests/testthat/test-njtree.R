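test_that("NJ recovers the additive 4-taxon tree exactly", {
  # distances from the tree ((A:1,B:2):1,(C:3,D:4))
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  # topology AB|CD and exact path lengths
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[labs, labs]),
               unname(D))
  bp <- ape::prop.part(ape::unroot(tr))
  pair_sets <- lapply(bp, function(p) sort(attr(bp, "labels")[p]))
  expect_true(any(vapply(pair_sets, identical, logical(1), c("A", "B"))) ||
                any(vapply(pair_sets, identical, logical(1), c("C", "D"))))
})

test_that("NJ solves the 3-taxon star exactly", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), class = "haplotrace_value_error")
})

test_that("NJ is exact on random additive matrices (topology and branch lengths)", {
  set.seed(73)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    case <- random_additive_case(n)
    tr <- neighbor_joining(case$dist)
    labs <- rownames(case$dist)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs],
                 case$dist, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(case$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative branch lengths are clamped with raw values retained", {
  # non-additive matrix known to produce a negative NJ branch
  labs <- paste0("t", 1:4)
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(labs, labs))
  D[1, 3] <- D[3, 1] <- 2  # break additivity hard
  tr <- neighbor_joining(D)
  raw <- attr(tr, "raw_edge_lengths")
  expect_true(all(tr$edge.length >= 0))
  expect_equal(length(raw), length(tr$edge.length))
  if (any(raw < 0)) expect_true(any(tr$edge.length == 0))
})

test_that("NJ on ultrametric distances matches single-linkage topology", {
  set.seed(79)
  for (rep in 1:5) {
    # build an ultrametric tree, derive distances, compare topologies
    tr0 <- ape::rcoal(5)
    D <- ape::cophenetic.phylo(tr0)
    labs <- sort(rownames(D))
    D <- D[labs, labs]
    nj_tr <- neighbor_joining(D)
    hc <- hclust(as.dist(D), method = "single")
    hc_tr <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(nj_tr), ape::unroot(hc_tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support separates clearly distinct clades and is seeded", {
  # two 3-leaf clades separated by 20 fixed differences over L = 200
  base <- strrep("A", 200)
  far <- paste0(strrep("C", 20), strrep("A", 180))
  jig <- function(s, at) { substr(s, at, at) <- "G"; s }
  seqs <- c(x1 = base, x2 = jig(base, 50), x3 = jig(base, 60),
            y1 = far, y2 = jig(far, 100), y3 = jig(far, 110))
  aln <- alignment(names(seqs), unname(seqs))
  tr <- bootstrap_support(aln, B = 100, seed = 5)
  sup <- attr(tr, "supports")
  # the edge separating the two clades is the bipartition {x*} | {y*}
  bp <- ape::prop.part(tr)
  labs <- attr(bp, "labels")
  sep <- which(vapply(bp, function(p) {
    s <- sort(labs[p])
    identical(s, c("x1", "x2", "x3")) || identical(s, c("y1", "y2", "y3"))
  }, logical(1)))
  expect_true(length(sep) >= 1)
  expect_true(all(sup[sep] >= 95))
  # reproducibility
  tr2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(attr(tr2, "supports"), sup)

  # B = 1: supports are 0 or 100 (or NA on untestable splits)
  tr1 <- bootstrap_support(aln, B = 1, seed = 9)
  s1 <- attr(tr1, "supports")
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("identical sequences give flagged zero-length internal edges", {
  # three identical sequences force an arbitrarily resolved clade with a
  # zero-length internal edge
  seqs <- c(a = "AAAAAAAA", b = "AAAAAAAA", e = "AAAAAAAA",
            c = "AAAACCCC", d = "CCCCCCCC")
  aln <- alignment(names(seqs), unname(seqs))
  tr <- bootstrap_support(aln, B = 10, seed = 2)
  expect_true(any(attr(tr, "zero_length_internal")))
})

test_that("rooting bisects the outgroup pendant edge and preserves bipartitions", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  root_node <- length(rooted$tip.label) + 1L
  ch <- which(rooted$edge[, 1] == root_node)
  expect_equal(rooted$edge.length[ch][1], rooted$edge.length[ch][2])
  # unrooting recovers the original bipartitions
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(rooted), ape::unroot(tr)), 0)
  expect_error(root_with_outgroup(tr, "Z"), class = "haplotrace_value_error")
})

test_that("a divergent outgroup is the first split after rooting", {
  cfg <- sim_config(seed = 17,
                    native_sizes = list(5L, 5L, 5L),
                    introduced_sizes = c(10L))
  sim <- simulate_dataset(cfg)
  cat <- collapse_and_label(sim$alignment, sim$meta)
  og_hap <- unname(cat$assignment["OUTGROUP"])
  reps <- representative_alignment(cat)
  D <- hamming_matrix(reps)
  # outgroup sits at >= 5.4% divergence from every ingroup haplotype
  expect_true(all(D[og_hap, setdiff(rownames(D), og_hap)] / cat$L >= 0.054))
  rooted <- root_with_outgroup(neighbor_joining(D), og_hap)
  root_node <- length(rooted$tip.label) + 1L
  ch_nodes <- rooted$edge[rooted$edge[, 1] == root_node, 2]
  tip_children <- rooted$tip.label[ch_nodes[ch_nodes <= length(rooted$tip.label)]]
  expect_true(og_hap %in% tip_children)
})

test_that("newick round-trips with identical bipartitions and supports on internal edges", {
  set.seed(83)
  for (rep in 1:5) {
    case <- random_additive_case(6)
    tr <- neighbor_joining(case$dist)
    txt <- to_newick(tr)
    back <- ape::read.tree(text = txt)
    skip_if_not_installed("phangorn")
    expect_equal(phangorn::RF.dist(back, tr), 0)
  }
  # 3-taxon star serialization
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- to_newick(neighbor_joining(D))
  expect_match(txt, "^\\(.*A:1.*\\);$|^\\(.*C:3.*\\);$")
  # supports appear as internal node labels only
  seqs <- c(a = "AAAATTTT", b = "AAAATTTA", c = "CCCCTTTT", d = "CCCCTTTA")
  trb <- bootstrap_support(alignment(names(seqs), unname(seqs)), B = 20, seed = 1)
  back <- ape::read.tree(text = to_newick(trb))
  expect_true(!is.null(back$node.label))
})
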