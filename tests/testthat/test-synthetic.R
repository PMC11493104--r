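test_that("generator bookkeeping matches the configuration", {
  cfg <- sim_config(seed = 1, native_sizes = list(20L, 20L, 20L),
                    introduced_sizes = c(30L), outgroup = FALSE)
  sim <- simulate_dataset(cfg)
  expect_equal(length(sim$alignment$ids), 90L)
  expect_equal(as.integer(table(sim$meta$status)[c("introduced", "native")]),
               c(30L, 60L))
  expect_equal(sim$alignment$L, 2181L)
  expect_setequal(sim$truth$specimen_id, sim$meta$specimen_id)
  expect_true(all(sim$truth$pathway %in%
                    c("native", "exported", "singleton-derivative")))
})

test_that("the top exported haplotype dominates introduced populations", {
  cfg <- sim_config(seed = 2, singleton_rate = 0,
                    introduced_sizes = c(60L))
  sim <- simulate_dataset(cfg)
  intro <- sim$truth[sim$meta$status[match(sim$truth$specimen_id,
                                           sim$meta$specimen_id)] == "introduced", ]
  top_freq <- mean(intro$true_hap == sim$exported[1])
  expect_gte(top_freq, 0.8)   # binomial 99% band at n = 60, p = 0.9
  expect_lte(top_freq, 1.0)
})

test_that("dominance 1 with no singletons gives monomorphic introduced populations", {
  cfg <- sim_config(seed = 3, dominance = 1, singleton_rate = 0,
                    introduced_sizes = c(25L))
  sim <- simulate_dataset(cfg)
  cat <- collapse_and_label(sim$alignment, sim$meta)
  s <- summarize_groups(cat, sim$meta)
  intro_rows <- s[grepl("^Introduced", s$group), ]
  expect_equal(intro_rows$n_haps, 1L)
  expect_equal(intro_rows$hap_div, 0)
  expect_equal(intro_rows$nuc_div, 0)
})

test_that("between-region divergence is respected in the truth haplotype pool", {
  cfg <- sim_config(seed = 4)
  sim <- simulate_dataset(cfg)
  pool <- sim$pool[!names(sim$pool) %in% "OUT"]
  region <- sub("H.*", "", sub("^SGT.*", "R3", names(pool)))
  D <- hamming_matrix(pool)
  cross <- D[region == "R1", region != "R1"]
  expect_true(all(cross >= cfg$between_region_steps))
  for (r in c("R2", "R3")) {
    cr <- D[region == r, region != r]
    expect_true(all(cr >= cfg$between_region_steps))
  }
})

test_that("identical seeds give byte-identical files; different seeds differ", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  d3 <- file.path(tempdir(), "sim_c")
  cfg <- sim_config(seed = 5, native_sizes = list(5L, 5L, 8L),
                    introduced_sizes = c(10L))
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  simulate_dataset(sim_config(seed = 6, native_sizes = list(5L, 5L, 8L),
                              introduced_sizes = c(10L)), dir = d3)
  for (f in c("alignment.fasta", "specimens.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "alignment.fasta")),
                         readLines(file.path(d3, "alignment.fasta"))))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_dataset(sim_config(seed = 7, native_sizes = list(4L, 4L, 6L),
                                        introduced_sizes = c(5L))))
  expect_identical(.Random.seed, before)
})

test_that("capacity violations raise errors", {
  expect_error(sim_config(seed = 1, L = 30L),
               class = "haplotrace_capacity_error")
  expect_error(simulate_dataset(sim_config(seed = 1, L = 150L,
                                           outgroup_divergence = 0.5)),
               class = "haplotrace_capacity_error")
  expect_error(sim_config(seed = 1, dominance = 0),
               class = "haplotrace_value_error")
  expect_error(sim_config(), class = "haplotrace_seed_error")
})

test_that("pipeline-on-simulation recovery: classification, clusters, structure", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_dataset(cfg)
  cat <- collapse_and_label(sim$alignment, sim$meta)

  # every exported haplotype with a sampled introduced carrier is invasive;
  # every region-restricted haplotype is private
  hap_of <- function(sid) unname(cat$assignment[sid])
  intro_ids <- sim$meta$specimen_id[sim$meta$status == "introduced"]
  exported_carried <- unique(sim$truth$true_hap[
    sim$truth$specimen_id %in% intro_ids & sim$truth$pathway == "exported"])
  for (h in exported_carried) {
    sid <- sim$truth$specimen_id[sim$truth$true_hap == h][1]
    expect_equal(unname(cat$classification[hap_of(sid)]), "invasive")
  }
  native_restricted <- setdiff(
    unique(sim$truth$true_hap[sim$truth$region %in% c("R1", "R2")]),
    sim$exported)
  for (h in native_restricted) {
    sid <- sim$truth$specimen_id[sim$truth$true_hap == h][1]
    expect_equal(unname(cat$classification[hap_of(sid)]), "private")
  }

  # network clusters at cut = between_region_steps / 2 recover the regions
  og_hap <- unname(cat$assignment["OUTGROUP"])
  net <- haplotype_network(cat, sim$meta, drop_labels = og_hap)
  cl <- network_clusters(net, cut = cfg$between_region_steps / 2)
  expect_equal(max(cl), cfg$n_regions)
  # cluster assignment matches region truth
  truth_region <- sim$truth$region[match(sim$truth$specimen_id,
                                         sim$truth$specimen_id)]
  first_member <- vapply(names(cl), function(lab) cat$members[[lab]][1], character(1))
  reg_of_node <- sim$truth$region[match(first_member, sim$truth$specimen_id)]
  expect_equal(length(unique(paste(cl, reg_of_node))), cfg$n_regions)
})

test_that("native structure exceeds introduced structure (Phi comparison)", {
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 100 + s,
                      native_sizes = list(12L, 12L, 12L),
                      introduced_sizes = c(15L, 15L), outgroup = FALSE)
    sim <- simulate_dataset(cfg)
    m <- sim$meta
    two_native <- m$specimen_id[m$country %in% c("NativeA", "NativeB")]
    Dn <- hamming_matrix(sim$alignment$seqs[two_native])
    phi_native <- amova_one_level(Dn, m$country[match(two_native, m$specimen_id)],
                                  n_perm = 9, seed = s)$phi_st
    intro <- m$specimen_id[m$status == "introduced"]
    Di <- hamming_matrix(sim$alignment$seqs[intro])
    res_i <- amova_one_level(Di, m$country[match(intro, m$specimen_id)],
                             n_perm = 9, seed = s)
    phi_intro <- res_i$phi_st
    if (phi_native > phi_intro) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})
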