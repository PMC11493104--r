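# Seeded generator of synthetic invasion-genetics datasets: divergent native
# regional haplotype pools, bottlenecked introduced populations dominated by
# one exported haplotype, rare one-step derivatives, and an optional distant
# outgroup. Mutations are placed at globally unique sites (infinite-sites
# approximation), so Hamming distance between any two haplotypes equals the
# number of mutation events separating them and truth distances are exact.

#' Simulation configuration
#'
#' Defaults emulate the structure of a continental-scale mtDNA invasion
#' survey: three divergent native regions, a large native source country
#' sampled at three locations (one of them the export hub), four introduced
#' countries dominated by a single exported haplotype, and a distant
#' outgroup.
#'
#' @param L sequence length in bp (default 2181).
#' @param n_regions number of native regions, one country per region.
#' @param between_region_steps minimum number of substitutions separating
#'   regional ancestral haplotypes (default 12). Each regional ancestor is
#'   placed `ceiling(between_region_steps / 2)` unique substitutions from a
#'   common root, so inter-region distances are at least this value.
#' @param within_region_haps haplotypes per regional pool, recycled across
#'   regions (default `c(5, 14, 19)`). Pools are star radiations: each
#'   non-ancestral haplotype derives directly from the regional ancestor by
#'   1--`max_within_steps` substitutions at fresh sites.
#' @param native_sizes list of per-location sample sizes, one vector per
#'   region; the last region is the invasion source and its first location
#'   the export hub. Default `list(9, c(16, 16, 17), c(31, 31, 31))`.
#' @param introduced_sizes sample sizes of introduced countries (one
#'   location each). Default `c(60, 31, 17, 13)`.
#' @param n_invasive_haps number of exported haplotypes (default 4); these
#'   are the source region's ancestor and its first derivatives.
#' @param dominance expected frequency of the top exported haplotype within
#'   introduced populations and the export hub (default 0.9).
#' @param singleton_rate probability an introduced specimen carries a new
#'   one-step derivative of its drawn haplotype (default 0.03).
#' @param geometric_ratio ratio of the geometric frequency series used
#'   within native pools (default 0.5): one common haplotype plus
#'   progressively rarer ones.
#' @param max_within_steps maximum substitutions from the regional ancestor
#'   per pool haplotype (default 3).
#' @param outgroup include a single outgroup record (default `TRUE`).
#' @param outgroup_divergence proportion of sites at which the outgroup
#'   differs from the root (default 0.056).
#' @param seed integer seed; required, the generator is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 2181L,
                       n_regions = 3L,
                       between_region_steps = 12L,
                       within_region_haps = c(5L, 14L, 19L),
                       native_sizes = list(9L, c(16L, 16L, 17L), c(31L, 31L, 31L)),
                       introduced_sizes = c(60L, 31L, 17L, 13L),
                       n_invasive_haps = 4L,
                       dominance = 0.9,
                       singleton_rate = 0.03,
                       geometric_ratio = 0.5,
                       max_within_steps = 3L,
                       outgroup = TRUE,
                       outgroup_divergence = 0.056,
                       seed) {
  if (missing(seed)) hap_error("`seed` is required", "haplotrace_seed_error")
  if (!(dominance > 0 && dominance <= 1)) {
    hap_error("dominance must be in (0, 1]", "haplotrace_value_error")
  }
  if (singleton_rate < 0 || singleton_rate >= 1) {
    hap_error("singleton_rate must be in [0, 1)", "haplotrace_value_error")
  }
  if (between_region_steps < 1) {
    hap_error("between_region_steps must be >= 1", "haplotrace_value_error")
  }
  if (L < between_region_steps * n_regions) {
    hap_error("L too small for the requested between-region divergence",
              "haplotrace_capacity_error")
  }
  k <- rep_len(as.integer(within_region_haps), n_regions)
  if (n_invasive_haps > k[n_regions]) {
    hap_error("n_invasive_haps exceeds the source region's pool size",
              "haplotrace_value_error")
  }
  if (length(native_sizes) != n_regions) {
    hap_error("native_sizes must have one entry per region",
              "haplotrace_value_error")
  }
  structure(list(
    L = as.integer(L), n_regions = as.integer(n_regions),
    between_region_steps = as.integer(between_region_steps),
    within_region_haps = k,
    native_sizes = lapply(native_sizes, as.integer),
    introduced_sizes = as.integer(introduced_sizes),
    n_invasive_haps = as.integer(n_invasive_haps),
    dominance = dominance, singleton_rate = singleton_rate,
    geometric_ratio = geometric_ratio,
    max_within_steps = as.integer(max_within_steps),
    outgroup = outgroup, outgroup_divergence = outgroup_divergence,
    seed = as.integer(seed)
  ), class = "sim_config")
}

mutate_at <- function(seq_chars, sites) {
  for (s in sites) {
    seq_chars[s] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[s]), 1L)
  }
  seq_chars
}

#' Simulate an invasion-genetics dataset
#'
#' Generates an alignment, a specimen metadata table, and a machine-readable
#' truth table under the structure described in [sim_config()]. Native
#' populations draw from their region's haplotype pool with geometric
#' frequencies (each region's ancestor is guaranteed present in its sample);
#' the export hub and introduced populations draw the exported haplotypes
#' with the configured dominance (each exported haplotype is guaranteed
#' present in the hub sample — that is where they were exported from), plus
#' rare one-step singleton derivatives. Byte-identical outputs for the same
#' seed.
#'
#' @param config a `sim_config`.
#' @param dir optional directory; when given, writes `alignment.fasta`,
#'   `specimens.tsv`, and `truth.tsv` there.
#' @return List with `alignment` (`hap_alignment`), `meta` (specimen
#'   data.frame), `truth` (data.frame specimen_id, true_hap, region,
#'   pathway), and `pool` (named character vector of pool haplotype
#'   sequences, including the outgroup).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    L <- cfg$L
    # Deterministic site budget under the infinite-sites approximation.
    anc_steps <- ceiling(cfg$between_region_steps / 2)
    n_introduced <- sum(cfg$introduced_sizes)
    budget <- cfg$n_regions * anc_steps +
      sum((cfg$within_region_haps - 1L) * cfg$max_within_steps) +
      (if (cfg$outgroup) round(cfg$outgroup_divergence * L) else 0L) +
      n_introduced  # worst case: every introduced specimen a singleton
    if (budget > L) {
      hap_error(sprintf("site budget %d exceeds alignment length %d",
                        budget, L), "haplotrace_capacity_error")
    }

    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    site_order <- sample.int(L)
    site_ptr <- 0L
    take_sites <- function(k) {
      out <- site_order[site_ptr + seq_len(k)]
      site_ptr <<- site_ptr + k
      out
    }

    # Regional pools: ancestor + star radiation at globally unique sites.
    pool_seqs <- character(0)
    pool_region <- character(0)
    for (r in seq_len(cfg$n_regions)) {
      anc <- mutate_at(root, take_sites(anc_steps))
      k <- cfg$within_region_haps[r]
      seqs <- vector("list", k)
      seqs[[1]] <- anc
      if (k > 1) {
        for (h in 2:k) {
          steps <- sample.int(cfg$max_within_steps, 1L)
          seqs[[h]] <- mutate_at(anc, take_sites(steps))
        }
      }
      ids <- sprintf("R%dH%02d", r, seq_len(k))
      pool_seqs <- c(pool_seqs,
                     stats::setNames(vapply(seqs, paste0, character(1),
                                            collapse = ""), ids))
      pool_region <- c(pool_region, stats::setNames(rep(sprintf("R%d", r), k), ids))
    }

    src <- cfg$n_regions
    exported <- sprintf("R%dH%02d", src, seq_len(cfg$n_invasive_haps))
    geo <- function(k) cfg$geometric_ratio^(seq_len(k) - 1)

    country_names <- c(paste0("Native", LETTERS[seq_len(cfg$n_regions)]),
                       paste0("Introduced", LETTERS[seq_along(cfg$introduced_sizes)]))

    specimen <- list()  # rows: id, country, location, status, hap_id
    add <- function(country, location, status, hap_ids) {
      specimen[[length(specimen) + 1L]] <<- data.frame(
        country = country, location = location, status = status,
        hap_id = hap_ids, stringsAsFactors = FALSE)
    }

    draw_exported_resid <- function(k) {
      # residual exported haplotypes 2..n, geometric weights
      if (cfg$n_invasive_haps == 1L) return(rep(exported[1], k))
      sample(exported[-1], k, replace = TRUE,
             prob = geo(cfg$n_invasive_haps - 1L))
    }

    # Native regions.
    for (r in seq_len(cfg$n_regions)) {
      country <- country_names[r]
      k <- cfg$within_region_haps[r]
      pool_ids <- sprintf("R%dH%02d", r, seq_len(k))
      sizes <- cfg$native_sizes[[r]]
      n_loc <- length(sizes)
      # haplotype 1 (the regional ancestor) is available to every location;
      # the rest are assigned round-robin, giving among-location structure.
      loc_pool <- lapply(seq_len(n_loc), function(l) {
        extra <- if (k > 1) pool_ids[-1][(seq_len(k - 1) - 1) %% n_loc + 1 == l] else character(0)
        c(pool_ids[1], extra)
      })
      for (l in seq_len(n_loc)) {
        loc <- sprintf("%s-P%d", country, l)
        n <- sizes[l]
        if (r == src && l == 1L) {
          # Export hub: every exported haplotype present by construction,
          # remainder drawn with the configured dominance.
          forced <- exported
          n_draw <- n - length(forced)
          if (n_draw < 0) hap_error("hub sample smaller than exported set",
                                    "haplotrace_value_error")
          u <- stats::runif(n_draw)
          drawn <- ifelse(u < cfg$dominance, exported[1], NA)
          n_resid <- sum(is.na(drawn))
          if (n_resid) drawn[is.na(drawn)] <- draw_exported_resid(n_resid)
          add(country, loc, "native", c(forced, drawn))
        } else {
          pool_l <- loc_pool[[l]]
          draws <- sample(pool_l, n - 1L, replace = TRUE, prob = geo(length(pool_l)))
          # ancestor guaranteed present in each location's sample
          add(country, loc, "native", c(pool_ids[1], draws))
        }
      }
    }

    # Introduced countries: dominance draw over the exported set, plus rare
    # one-step singleton derivatives at fresh sites.
    singleton_counter <- 0L
    singleton_seqs <- character(0)
    singleton_parent <- character(0)
    for (j in seq_along(cfg$introduced_sizes)) {
      country <- country_names[cfg$n_regions + j]
      n <- cfg$introduced_sizes[j]
      u <- stats::runif(n)
      base <- ifelse(u < cfg$dominance, exported[1], NA)
      n_resid <- sum(is.na(base))
      if (n_resid) base[is.na(base)] <- draw_exported_resid(n_resid)
      is_sgt <- stats::runif(n) < cfg$singleton_rate
      hap_ids <- base
      for (i in which(is_sgt)) {
        singleton_counter <- singleton_counter + 1L
        sid <- sprintf("SGT%03d", singleton_counter)
        parent_seq <- strsplit(pool_seqs[[base[i]]], "")[[1]]
        singleton_seqs[sid] <- paste0(mutate_at(parent_seq, take_sites(1L)),
                                      collapse = "")
        singleton_parent[sid] <- base[i]
        hap_ids[i] <- sid
      }
      add(country, sprintf("%s-P1", country), "introduced", hap_ids)
    }

    spec <- do.call(rbind, specimen)
    spec$specimen_id <- sprintf("S%04d", seq_len(nrow(spec)))

    all_haps <- c(pool_seqs, singleton_seqs)
    hap_region <- c(pool_region,
                    stats::setNames(rep(sprintf("R%d", src),
                                        length(singleton_seqs)),
                                    names(singleton_seqs)))

    ids <- spec$specimen_id
    seqs <- unname(all_haps[spec$hap_id])
    meta <- data.frame(specimen_id = ids, country = spec$country,
                       location = spec$location, status = spec$status,
                       host = "synthetic-host", year = 2000L,
                       stringsAsFactors = FALSE)
    pathway <- ifelse(spec$status == "native", "native",
                      ifelse(grepl("^SGT", spec$hap_id),
                             "singleton-derivative", "exported"))
    truth <- data.frame(specimen_id = ids, true_hap = spec$hap_id,
                        region = hap_region[spec$hap_id],
                        pathway = pathway, stringsAsFactors = FALSE)

    if (cfg$outgroup) {
      og_seq <- paste0(mutate_at(root, take_sites(round(cfg$outgroup_divergence * L))),
                       collapse = "")
      ids <- c(ids, "OUTGROUP")
      seqs <- c(seqs, og_seq)
      meta <- rbind(meta, data.frame(
        specimen_id = "OUTGROUP", country = "outgroup", location = "outgroup",
        status = "outgroup", host = "", year = NA_integer_,
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        specimen_id = "OUTGROUP", true_hap = "OUT", region = "outgroup",
        pathway = "native", stringsAsFactors = FALSE))
      all_haps <- c(all_haps, OUT = og_seq)
    }

    aln <- alignment(ids, seqs)
    rownames(truth) <- NULL

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_alignment(aln, file.path(dir, "alignment.fasta"))
      write_specimen_table(meta, file.path(dir, "specimens.tsv"))
      utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    list(alignment = aln, meta = meta, truth = truth, pool = all_haps,
         exported = exported, config = cfg)
  })
}
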