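test_that("founders carry one eos and one neogaeus haplome from the pools", {
  set.seed(23)
  pools <- default_allele_pools()
  founders <- generate_founder_lineages(5, pools)
  for (f in founders) {
    # nine allele slots: two per both-genomes locus, one per eos-specific
    expect_equal(sum(lengths(f)), 9)
    for (loc in locus_panel()$locus) {
      if (loc %in% gynoclone:::both_genome_loci()) {
        expect_length(f[[loc]], 2)
        expect_true(any(f[[loc]] %in% pools[[loc]]$eos))
        expect_true(any(f[[loc]] %in% pools[[loc]]$neo))
      } else {
        expect_length(f[[loc]], 1)
        expect_true(f[[loc]] %in% pools[[loc]]$eos)
      }
    }
  }
  # pairwise distinct at more loci than the clustering tolerance
  for (i in 1:4) for (j in (i + 1):5) {
    ndiff <- sum(vapply(locus_panel()$locus, function(loc) {
      !identical(founders[[i]][[loc]], founders[[j]][[loc]])
    }, logical(1)))
    expect_gt(ndiff, 2)
  }

  tiny <- lapply(default_allele_pools(), function(p) lapply(p, `[`, 1))
  expect_error(generate_founder_lineages(3, tiny), "pools too small")
})

test_that("stepwise mutation is a single-step walk with the declared rate", {
  g <- base_hybrid_alleles()
  expect_identical(mutate_genotype(g, 0, 1000), g)

  # a forced mutation moves a single-copy locus by exactly one step
  set.seed(29)
  for (r in 1:20) {
    m <- suppressWarnings(mutate_genotype(g, 1, 1))
    expect_equal(abs(m[["Pho-60"]] - g[["Pho-60"]]), 1)
  }

  # expected number of mutated loci per individual: 6 * (1 - (1 - mu)^t)
  set.seed(31)
  ndiff <- vapply(1:400, function(r) {
    m <- mutate_genotype(g, 5e-4, 200)
    sum(vapply(names(g), function(loc) !identical(m[[loc]], g[[loc]]),
               logical(1)))
  }, numeric(1))
  expected <- 6 * (1 - (1 - 5e-4)^200)
  expect_equal(mean(ndiff), expected,
               tolerance = 3 * sd(ndiff) / sqrt(400) / expected)

  expect_warning(mutate_genotype(g, 0.5, 10), "expected mutations")
})

test_that("a mutation-free, diploid-only survey reproduces founders exactly", {
  cfg <- synthetic_config(mutation_rate = 0, triploid_fraction = 0, seed = 37)
  cfg$events$time_bp <- 0L
  sv <- generate_survey(cfg)
  expect_true(all(infer_ploidy(sv$genotypes) == "2n"))
  for (sid in unique(sv$genotypes$site_id)) {
    g <- sv$genotypes[sv$genotypes$site_id == sid, ]
    res <- call_lineages(g)
    truth <- sv$site_truth$n_lineages_sample[sv$site_truth$site_id == sid]
    expect_equal(nrow(res$lineages), truth)
  }
})

test_that("ground truth covers every sampled hybrid and survey files round-trip", {
  sv <- generate_survey(synthetic_config(seed = 41))
  expect_setequal(sv$truth$individual_id, sv$genotypes$individual_id)
  expect_true(all(sv$truth$true_ploidy %in% c("2n", "3n")))
  # inferred triploids are a subset of the true ones (dosage masking can
  # hide a sperm allele, never invent one)
  inferred <- infer_ploidy(sv$genotypes)
  truth_pl <- sv$truth$true_ploidy[match(sv$genotypes$individual_id,
                                         sv$truth$individual_id)]
  expect_true(all(truth_pl[inferred == "3n"] == "3n"))
  # sites without a founding event sampled no hybrids
  no_event <- setdiff(sv$sites$site_id, unique(sv$truth$site_id))
  expect_true(all(sv$sites$n_hyb[sv$sites$site_id %in% no_event] == 0))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(sv$genotypes, tmp)
  expect_equal(nrow(read_genotype_table(tmp)), nrow(sv$genotypes))
})

test_that("called lineage counts track the truth within one lineage", {
  # one site, five founders, a recent event, survey defaults otherwise
  sites1 <- tibble::tibble(site_id = "SYN-A", lat = 46.5, lon = -70.2,
                           network = "SJ", lgs_category = "130-140",
                           deme_size = 500L, n_eos = 15L, n_neo = 5L)
  ev1 <- tibble::tibble(site_id = "SYN-A", event_id = "E1",
                        time_bp = 200L, n_founders = 5L)
  n_rep <- 60L
  ok <- vapply(seq_len(n_rep), function(r) {
    cfg <- synthetic_config(sites = sites1, events = ev1, seed = 5000 + r)
    sv <- generate_survey(cfg)
    res <- call_lineages(sv$genotypes)
    abs(nrow(res$lineages) - sv$site_truth$n_lineages_sample[1]) <= 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("lineages seeded across networks are called widespread end to end", {
  # the same founder lineages planted in two networks ~80 km apart, plus a
  # purely local event at a third site
  des <- default_synthetic_sites()
  sites <- des$sites[c(1, 5, 6), ]
  cfg <- synthetic_config(
    sites = sites,
    events = tibble::tibble(
      site_id = c("SYN-S1", "SYN-N1", "SYN-N2"),
      event_id = c("E1", "E1", "E2"),
      time_bp = c(0L, 0L, 0L), n_founders = c(3L, 3L, 4L),
      founder_group = c("PLEISTO", "PLEISTO", "SYN-N2:E2")),
    mutation_rate = 0, triploid_fraction = 0, seed = 43)
  sv <- generate_survey(cfg)
  res <- call_lineages(sv$genotypes)
  grp <- pool_sites(sv$sites, res$occurrences)
  ranges <- classify_lineages(res$lineages, grp, sv$sites)
  shared <- ranges$n_sites >= 2
  expect_true(any(shared))
  expect_true(all(ranges$classification[shared] == "widespread"))
  expect_true(all(ranges$cross_network[shared]))
  expect_true(all(ranges$classification[!shared] == "private"))
})
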