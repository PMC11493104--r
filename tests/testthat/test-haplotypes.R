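test_that("collapse groups identical sequences and ranks by abundance", {
  # 7 identical + 2 distinct singletons -> 3 haplotypes with counts (7,1,1)
  ids <- sprintf("s%d", 1:9)
  seqs <- c(rep("AAAA", 7), "CCCC", "GGGG")
  meta <- make_meta(ids, "Canada", status = "introduced")
  cat <- collapse_and_label(alignment(ids, seqs), meta)
  expect_equal(nrow(cat$haplotypes), 3L)
  expect_equal(cat$haplotypes$n_analysis, c(7L, 1L, 1L))

  # all identical -> one haplotype
  cat1 <- collapse_and_label(alignment(ids, rep("ACGT", 9)), meta)
  expect_equal(nrow(cat1$haplotypes), 1L)
  expect_equal(cat1$haplotypes$n_analysis, 9L)
})

test_that("labels are assigned in descending abundance order", {
  counts <- c(60, 31, 14)
  seqs <- rep(c("TTTT", "CCCC", "GGGG"), counts)
  # interleave input order so ranking cannot ride on file order
  set.seed(5)
  ord <- sample(seq_along(seqs))
  ids <- sprintf("s%03d", seq_along(seqs))
  meta <- make_meta(ids, "X")
  cat <- collapse_and_label(alignment(ids, seqs[ord]), meta)
  expect_equal(cat$haplotypes$n_analysis, c(60L, 31L, 14L))
  expect_equal(cat$haplotypes$seq[1], "TTTT")
})

test_that("collapse is a partition of analysis specimens and a fixed point", {
  set.seed(7)
  pool <- random_seqs(4, 20)
  ids <- sprintf("s%02d", 1:30)
  seqs <- sample(pool, 30, replace = TRUE)
  meta <- make_meta(ids, rep(c("P", "Q"), 15))
  cat <- collapse_and_label(alignment(ids, seqs), meta)
  mem <- unlist(cat$members, use.names = FALSE)
  expect_setequal(mem, ids)
  expect_equal(anyDuplicated(mem), 0L)
  expect_equal(sum(cat$haplotypes$n_analysis), 30L)
  # collapsing the representative alignment yields one haplotype per record
  reps <- representative_alignment(cat)
  meta2 <- make_meta(reps$ids, "Z")
  cat2 <- collapse_and_label(reps, meta2)
  expect_equal(nrow(cat2$haplotypes), length(reps$ids))
  expect_true(all(cat2$haplotypes$n_analysis == 1L))
})

test_that("join mismatches error unless allow_unmatched", {
  aln <- alignment(c("a", "b"), c("ACGT", "ACGT"))
  meta <- make_meta("a", "X")
  expect_error(collapse_and_label(aln, meta), class = "haplotrace_join_error")
  expect_warning(cat <- collapse_and_label(aln, meta, allow_unmatched = TRUE))
  expect_equal(sum(cat$haplotypes$n_total), 1L)
})

test_that("classification implements the private/shared_native/invasive rule", {
  ids <- sprintf("s%d", 1:8)
  seqs <- c("AAAA", "AAAA",   # hap1: Peru(native) + Philippines(introduced)
            "CCCC",           # hap2: Colombia only
            "GGGG",           # hap3: Israel(introduced) only
            "TTTT", "TTTT",   # hap4: Peru + Argentina, both native
            "ACGT", "ACGT")   # hap5: interceptions only
  meta <- make_meta(ids,
                    country = c("Peru", "Philippines", "Colombia", "Israel",
                                "Peru", "Argentina", "Kenya", "Kenya"),
                    status = c("native", "introduced", "native", "introduced",
                               "native", "native", "interception", "interception"))
  cat <- collapse_and_label(alignment(ids, seqs), meta)
  cls <- cat$classification
  hap_of <- function(id) unname(cat$assignment[id])
  expect_equal(unname(cls[hap_of("s1")]), "invasive")
  expect_equal(unname(cls[hap_of("s3")]), "private")
  expect_equal(unname(cls[hap_of("s4")]), "private")
  expect_equal(unname(cls[hap_of("s5")]), "shared_native")
  # interception-only haplotype is catalogued but confined to one group
  expect_equal(unname(cls[hap_of("s7")]), "private")
  # classification is exhaustive and exclusive
  expect_true(all(cls %in% c("private", "shared_native", "invasive")))
  expect_equal(length(cls), nrow(cat$haplotypes))
  # interceptions excluded from abundance ranking
  expect_equal(cat$haplotypes$n_analysis[cat$haplotypes$label == hap_of("s7")], 0L)
})

test_that("invasive haplotypes get letter labels, the rest zero-padded numerics", {
  ids <- sprintf("s%d", 1:7)
  seqs <- c("AAAA", "AAAA", "AAAA", "CCCC", "CCCC", "GGGG", "TTTT")
  meta <- make_meta(ids,
                    country = c("Peru", "Peru", "China", "Peru", "Brazil",
                                "Peru", "Peru"),
                    status = c("native", "native", "introduced", "native",
                               "native", "native", "native"))
  cat <- collapse_and_label(alignment(ids, seqs), meta)
  labs <- cat$haplotypes$label
  expect_equal(labs[1], "Hap-A")             # most abundant, invasive
  expect_true(all(grepl("^H\\d+$", labs[-1])))
})

test_that("group frequency table has consistent margins and order invariance", {
  set.seed(13)
  pool <- random_seqs(5, 12)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  seqs <- sample(pool, n, replace = TRUE)
  country <- sample(c("P", "Q", "R"), n, replace = TRUE)
  meta <- make_meta(ids, country)
  aln <- alignment(ids, seqs)
  cat <- collapse_and_label(aln, meta)
  ft <- group_frequency_table(cat, meta)
  expect_equal(unname(rowSums(ft)), unname(as.integer(table(factor(country, levels = rownames(ft))))))
  expect_equal(sum(ft), n)

  # permuting specimen input order leaves the table unchanged
  perm <- sample(n)
  cat2 <- collapse_and_label(alignment(ids[perm], seqs[perm]), meta)
  ft2 <- group_frequency_table(cat2, meta)
  expect_equal(ft2[rownames(ft), colnames(ft)], ft)

  # single specimen
  m1 <- make_meta("x", "G")
  c1 <- collapse_and_label(alignment("x", "ACGT"), m1)
  f1 <- group_frequency_table(c1, m1)
  expect_equal(unname(f1["G", ]), 1L)
})

test_that("classify_haplotypes honours the grouping argument", {
  ids <- c("a", "b")
  seqs <- c("AAAA", "AAAA")
  meta <- make_meta(ids, country = c("Peru", "Peru"),
                    location = c("Lima", "Huancayo"))
  cat <- collapse_and_label(alignment(ids, seqs), meta)
  expect_equal(unname(classify_haplotypes(cat, meta, "country")), "private")
  expect_equal(unname(classify_haplotypes(cat, meta, "location")), "shared_native")
})
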