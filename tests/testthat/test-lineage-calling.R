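test_that("ploidy is inferred from allele counts per locus class", {
  g <- make_hybrids(
    list(),                                      # plain diploid
    list(`Seat412` = c(100L, 104L, 200L)),       # 3 alleles, both-genomes
    list(`Pho-1` = c(152L, 158L)),               # 2 alleles, eos-specific
    list(`Seat412` = c(100L, 200L))              # diploid again
  )
  expect_equal(infer_ploidy(g), c("2n", "3n", "3n", "2n"))

  empty <- genotype_table("i1", "S1", "HYB", list(list()))
  expect_equal(infer_ploidy(empty), "unknown")
})

test_that("consensus is the invariant allele, the mode, or the tie-broken minimum", {
  identical5 <- make_hybrids(list(), list(), list(), list(), list())
  cons <- consensus_genotype(identical5)
  expect_equal(cons[["Seat412"]], c(100L, 200L))
  expect_equal(cons[["Pho-60"]], 150L)
  expect_length(attr(cons, "ties"), 0)

  # one variant among five: the majority allele wins
  one_var <- make_hybrids(list(), list(), list(), list(),
                          list(`Pho-60` = 151L))
  expect_equal(consensus_genotype(one_var)[["Pho-60"]], 150L)

  # a 1:1 tie goes to the smallest allele and is flagged
  tied <- make_hybrids(list(`Pho-60` = 151L), list(`Pho-60` = 150L))
  cons_t <- consensus_genotype(tied)
  expect_equal(cons_t[["Pho-60"]], 150L)
  expect_true("Pho-60" %in% attr(cons_t, "ties"))

  expect_error(consensus_genotype(make_hybrids()), "zero members")
})

test_that("step-tolerant single linkage groups variants but splits true lineages", {
  # identical genotypes collapse to one lineage with no variants
  same <- make_hybrids(list(), list(), list())
  lin <- cluster_lineages(same)
  expect_equal(nrow(lin), 1)
  expect_equal(lin$n_diploids, 3L)
  expect_equal(lin$n_variants, 0L)

  # one step at two loci: still one lineage, two members flagged variant-free
  near <- make_hybrids(list(), list(`Pho-60` = 151L, `Pho-1` = 153L))
  expect_equal(nrow(cluster_lineages(near)), 1)

  # two steps at three loci exceeds both defaults: two lineages
  far <- make_hybrids(list(), list(`Pho-60` = 152L, `Pho-1` = 154L,
                                   `Pho-2` = 156L))
  expect_equal(nrow(cluster_lineages(far)), 2)

  expect_error(
    cluster_lineages(make_hybrids(list(`Seat412` = c(100L, 104L, 200L)))),
    "mixed ploidy")
})

test_that("clustering partitions the input and ignores row order and ids", {
  sv <- generate_survey(synthetic_config(seed = 11))
  g <- sv$genotypes[sv$genotypes$site_id == "SYN-N1", ]
  g2n <- g[infer_ploidy(g) == "2n", ]
  lin <- cluster_lineages(g2n)
  expect_equal(sum(lin$n_diploids), nrow(g2n))
  expect_setequal(unlist(lin$diploid_members), g2n$individual_id)

  perm <- g2n[sample.int(nrow(g2n)), ]
  lin_p <- cluster_lineages(perm)
  part <- function(l) sort(vapply(l$diploid_members, function(m) {
    paste(sort(m), collapse = "+")
  }, character(1)))
  expect_equal(part(lin_p), part(lin))
})

test_that("lineage calling recovers founders exactly when mutation is off", {
  cfg <- synthetic_config(
    sites = tibble::tibble(site_id = "SYN-A", lat = 46, lon = -70,
                           network = "SJ", lgs_category = "130-140",
                           deme_size = 200L, n_eos = 10L, n_neo = 5L),
    events = tibble::tibble(site_id = "SYN-A", event_id = "E1",
                            time_bp = 0L, n_founders = 5L),
    mutation_rate = 0, triploid_fraction = 0, sample_n = 30L, seed = 21)
  sv <- generate_survey(cfg)
  res <- call_lineages(sv$genotypes)
  expect_equal(nrow(res$lineages), 5)
  expect_equal(nrow(res$lineages), sv$site_truth$n_lineages_sample[1])
})

test_that("triploids join their lineage, found new ones, or are deduplicated", {
  dip <- make_hybrids(list(), list(), list())
  lineages <- cluster_lineages(dip)
  cons <- lineages$consensus[[1]]

  # consensus plus an eos sperm allele at every locus
  tri_alleles <- list(
    `Seat412` = sort(c(cons[["Seat412"]], 110L)),
    `Ca-12` = sort(c(cons[["Ca-12"]], 112L)),
    `Pho-60` = sort(c(cons[["Pho-60"]], 160L)),
    `Pho-1` = sort(c(cons[["Pho-1"]], 162L)),
    `Pho-2` = sort(c(cons[["Pho-2"]], 164L)),
    `Rhca-20` = sort(c(cons[["Rhca-20"]], 114L)))
  tri <- genotype_table("t1", "S1", "HYB", list(tri_alleles))
  asg <- assign_triploids(tri, lineages)
  expect_equal(asg$assigned_lineage, lineages$lineage_id[1])
  expect_equal(asg$sperm_origin, "eos")

  # a triploid far from any consensus founds a new lineage; an identical
  # twin joins the same new lineage rather than adding another
  alien <- list(`Seat412` = c(130L, 131L, 230L), `Ca-12` = c(132L, 232L),
                `Pho-60` = 180L, `Pho-1` = 182L, `Pho-2` = c(184L, 190L),
                `Rhca-20` = c(134L, 234L))
  tri2 <- genotype_table(c("t2", "t3"), c("S1", "S1"), c("HYB", "HYB"),
                         list(alien, alien))
  asg2 <- assign_triploids(tri2, lineages)
  expect_equal(asg2$assigned_lineage, c("NEW:1", "NEW:1"))

  res <- call_lineages(dplyr::bind_rows(dip, tri2))
  expect_equal(nrow(res$lineages), 2)  # one diploid lineage + one NEW
})
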