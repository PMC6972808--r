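# Synthetic latitudinal surveys with ground truth. Each site carries founding
# hybridization events at specified times before present; every event seeds a
# set of founder genotypes (one C. eos haplome + one C. neogaeus haplome per
# founder), lineage labels then drift in a single-deme clonal Wright-Fisher
# population, stepwise microsatellite mutation accrues along each sampled
# individual's generation count, a fraction of sampled hybrids are converted
# to triploids by appending a sperm haplome, and per-site samples are emitted
# in the survey interchange formats together with true lineage labels.
#
# Allele scores are stored as distinct fragment sizes (as scored on a gel):
# the eos and neogaeus default pools are widely separated so that haplomes
# remain identifiable, which real allele distributions need not guarantee.

#' Default per-species allele pools
#'
#' Synthetic pools of allele scores, one eos pool and (for both-genomes loci)
#' one neogaeus pool per locus, separated widely enough that single-step
#' mutation never makes the two haplomes collide.
#'
#' @return Named list per locus with components `eos` and (where applicable)
#'   `neo`, each an integer vector of allele scores.
#' @export
default_allele_pools <- function() {
  pools <- lapply(panel_loci(), function(loc) {
    if (loc %in% both_genome_loci()) {
      list(eos = 100L + 2L * (0:11), neo = 200L + 2L * (0:11))
    } else {
      list(eos = 150L + 2L * (0:11))
    }
  })
  names(pools) <- panel_loci()
  pools
}

# length-safe uniform draw from an allele pool (sample() would treat a
# single-element pool as a range)
pick_allele <- function(v) v[sample.int(length(v), 1)]

default_synthetic_sites <- function() {
  sites <- tibble::tibble(
    site_id = c("SYN-S1", "SYN-S2", "SYN-M1", "SYN-M2",
                "SYN-N1", "SYN-N2", "SYN-F1", "SYN-F2"),
    lat = c(45.1, 45.3, 45.7, 45.9, 46.5, 47.0, 48.1, 48.4),
    lon = c(-72.3, -71.9, -70.9, -70.8, -70.2, -69.9, -68.5, -68.2),
    network = c("SF", "SF", "CH", "CH", "SJ", "OU", "RM", "MI"),
    lgs_category = c("150-160", "150-160", "140-150", "140-150",
                     "130-140", "130-140", "120-130", "120-130"),
    deme_size = 500L,
    n_eos = c(20L, 15L, 10L, 12L, 18L, 15L, 10L, 12L),
    n_neo = c(0L, 2L, 4L, 5L, 8L, 6L, 3L, 2L)
  )
  # southern sites record old hybridization pulses, mid-latitude sites
  # younger ones, one northern site a very recent event, the far-north pair
  # none at all
  events <- tibble::tibble(
    site_id = c("SYN-S1", "SYN-S2", "SYN-M1", "SYN-M2", "SYN-N1"),
    event_id = paste0("E", 1:5),
    time_bp = c(8000L, 8000L, 4000L, 4000L, 200L),
    n_founders = c(30L, 30L, 30L, 30L, 5L)
  )
  list(sites = sites, events = events)
}

#' Synthetic survey configuration
#'
#' Defaults emulate the study conditions of a 500-km latitudinal transect:
#' deme size 500, founding events whose ages decrease northward (8,000
#' generations in the 150-160 day LGS band, 4,000 at 140-150 days, 200 at
#' 130-140 days, none in the far north), stepwise mutation at 5e-4 per locus
#' per generation, 20% triploids among sampled hybrids, and samples of 24
#' hybrids per occupied site.
#'
#' @param sites Site design tibble (`site_id`, `lat`, `lon`, `network`,
#'   `lgs_category`, `deme_size`, `n_eos`, `n_neo`).
#' @param events Event tibble (`site_id`, `event_id`, `time_bp`,
#'   `n_founders`, optionally `founder_group`): events sharing a
#'   `founder_group` seed the same founder genotypes, emulating a widespread
#'   (migrant) lineage planted in several sites; by default every event has
#'   its own founders (purely local hybridization).
#' @param mutation_rate Stepwise mutation probability per allele per
#'   generation.
#' @param triploid_fraction Probability that a sampled hybrid is triploid.
#' @param sample_n Hybrids sampled per occupied site.
#' @param allele_pools Per-locus species allele pools
#'   (see [default_allele_pools()]).
#' @param max_variable_loci Founders are kept pairwise distinct at more than
#'   this many loci so lineage calling is well-posed (matches
#'   [clustering_params()]).
#' @param seed Integer seed.
#' @return A validated configuration list.
#' @export
synthetic_config <- function(sites = default_synthetic_sites()$sites,
                             events = default_synthetic_sites()$events,
                             mutation_rate = 5e-4,
                             triploid_fraction = 0.2,
                             sample_n = 24L,
                             allele_pools = default_allele_pools(),
                             max_variable_loci = 2L,
                             seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            triploid_fraction >= 0, triploid_fraction <= 1,
            sample_n >= 1, all(events$n_founders >= 1))
  if (!all(events$site_id %in% sites$site_id)) {
    stop("event refers to unknown site")
  }
  if (!("founder_group" %in% names(events))) {
    events$founder_group <- paste(events$site_id, events$event_id, sep = ":")
  }
  for (grp in unique(events$founder_group)) {
    if (length(unique(events$n_founders[events$founder_group == grp])) > 1) {
      stop("events sharing founder group '", grp,
           "' must agree on n_founders")
    }
  }
  if (any(sample_n > sites$deme_size)) {
    stop("sample_n exceeds deme size")
  }
  list(sites = sites, events = events, mutation_rate = mutation_rate,
       triploid_fraction = triploid_fraction,
       sample_n = as.integer(sample_n), allele_pools = allele_pools,
       max_variable_loci = as.integer(max_variable_loci),
       seed = as.integer(seed))
}

#' Generate founder genotypes for one hybridization event
#'
#' Each founder is a single F1 hybrid: one *C. eos* haplome (an allele at all
#' six loci) plus one *C. neogaeus* haplome (an allele at the three
#' both-genomes loci), drawn from the species pools. Founders are kept
#' pairwise distinct at more than `max_variable_loci` loci by rejection
#' sampling, so distinct founding lineages can never be merged by the
#' lineage caller's step tolerance.
#'
#' @param n_founders Number of founding lineages (>= 1).
#' @param pools Allele pools (see [default_allele_pools()]).
#' @param max_variable_loci Distinctness threshold (default 2).
#' @return A list of bare founder genotypes (named list locus -> sorted
#'   integer alleles).
#' @export
generate_founder_lineages <- function(n_founders,
                                      pools = default_allele_pools(),
                                      max_variable_loci = 2L) {
  draw_one <- function() {
    g <- lapply(panel_loci(), function(loc) {
      p <- pools[[loc]]
      if (loc %in% both_genome_loci()) {
        sort(c(pick_allele(p$eos), pick_allele(p$neo)))
      } else {
        pick_allele(p$eos)
      }
    })
    names(g) <- panel_loci()
    g
  }
  n_diff_loci <- function(a, b) {
    sum(vapply(panel_loci(), function(loc) {
      !identical(a[[loc]], b[[loc]])
    }, logical(1)))
  }
  founders <- list()
  for (i in seq_len(n_founders)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      cand <- draw_one()
      if (all(vapply(founders, function(f) {
        n_diff_loci(cand, f) > max_variable_loci
      }, logical(1)))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("allele pools too small to draw ", n_founders,
           " founders pairwise distinct at more than ", max_variable_loci,
           " loci")
    }
    founders[[i]] <- cand
  }
  founders
}

#' Apply stepwise mutation to a genotype
#'
#' Strict single-step model: each locus mutates with probability `mu` per
#' generation; a mutation event moves one randomly chosen allele of the
#' locus one unit up or down with equal probability. The number of events
#' per locus over `generations` is binomial and displacements accumulate as
#' independent +/-1 steps. An allele pushed to zero or below is reflected
#' back above zero.
#'
#' @param g A bare genotype (named list locus -> integer alleles).
#' @param mu Mutation probability per locus per generation.
#' @param generations Number of generations of mutation accrual.
#' @return The mutated bare genotype.
#' @export
mutate_genotype <- function(g, mu, generations) {
  if (mu * generations >= 1) {
    warning("expected mutations per locus >= 1 (mu * generations = ",
            mu * generations, "); variants may exceed the step tolerance")
  }
  if (mu == 0 || generations == 0) return(g)
  out <- lapply(panel_loci(), function(loc) {
    v <- as.integer(g[[loc]])
    if (length(v) == 0) return(v)
    k <- stats::rbinom(1, generations, mu)
    for (ev in seq_len(k)) {
      i <- if (length(v) == 1) 1L else sample.int(length(v), 1)
      v[i] <- v[i] + sample(c(-1L, 1L), 1)
      if (v[i] <= 0) v[i] <- 2L - v[i]  # reflect back to a positive score
    }
    sort(unique(v))
  })
  names(out) <- panel_loci()
  out
}

# Genealogy-aware retrospective mutation. The sampled members of one clonal
# lineage are related by a within-lineage coalescent: in a lineage with c
# copies, k sampled branches coalesce at rate choose(k, 2) / c per
# generation, and any branches still separate at the founding event attach
# to the founder. Mutations are dropped on every branch of this genealogy
# (so variants on internal branches are shared by all descendants) and
# genotypes are read off at the tips. Returns a list of n bare genotypes.
mutate_along_genealogy <- function(founder_g, n, copies, age, mu) {
  if (n == 1) {
    return(list(mutate_genotype(founder_g, mu, age)))
  }
  # children[[i]]: indices (tips 1..n or internal nodes) merged at node i
  node_time <- rep(0, n)
  node_children <- vector("list", n)
  active <- seq_len(n)
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    rate <- min(1, choose(k, 2) / max(copies, 1))
    t <- t + stats::rgeom(1, rate) + 1
    if (t >= age) break
    pair <- sample(active, 2)
    node_time <- c(node_time, t)
    node_children <- c(node_children, list(pair))
    active <- c(setdiff(active, pair), length(node_time))
  }
  # remaining branches attach to the founder at the event age
  node_time <- c(node_time, age)
  node_children <- c(node_children, list(active))
  root <- length(node_time)
  geno <- vector("list", root)
  geno[[root]] <- founder_g
  # walk the tree root-down; children were appended in time order, so a
  # reverse index sweep visits every parent before its children
  for (p in rev(seq_len(root))) {
    for (ch in node_children[[p]]) {
      branch <- node_time[p] - node_time[ch]
      geno[[ch]] <- suppressWarnings(mutate_genotype(geno[[p]], mu, branch))
    }
  }
  geno[seq_len(n)]
}

# Single-deme clonal drift of lineage labels: per-lineage copy numbers after
# `generations` of multinomial Wright-Fisher resampling at constant size N.
drift_label_counts <- function(n_lineages, deme_size, generations) {
  counts <- tabulate(sample.int(n_lineages, deme_size, replace = TRUE),
                     nbins = n_lineages)
  for (g in seq_len(generations)) {
    counts <- as.integer(stats::rmultinom(1, deme_size, counts / deme_size))
  }
  counts
}

# Append a sperm haplome to a diploid bare genotype. Eos sperm contributes an
# allele at every locus; neogaeus sperm only at both-genomes loci. Alleles are
# stored as distinct sizes, so a sperm allele equal to an existing one is
# dosage-masked and leaves the observed genotype unchanged.
add_sperm_haplome <- function(g, origin, pools) {
  out <- g
  loci <- if (origin == "eos") panel_loci() else both_genome_loci()
  for (loc in loci) {
    p <- if (origin == "eos") pools[[loc]]$eos else pools[[loc]]$neo
    out[[loc]] <- sort(unique(c(out[[loc]], pick_allele(p))))
  }
  out
}

#' Generate a complete synthetic survey with ground truth
#'
#' Runs the generative model site by site: founder genotypes per event,
#' single-deme clonal drift of lineage labels for the event's age, stepwise
#' mutation along each sampled individual's generation count, triploid
#' conversion by sperm-haplome addition (eos sperm with probability equal to
#' the local eos share of parental fish), and a sample of `sample_n` hybrids
#' per occupied site.
#'
#' @param cfg A [synthetic_config()] list.
#' @return A list with `genotypes` (genotype tibble), `sites` (site tibble
#'   with realized `n_hyb`), `truth` (per sampled hybrid: `individual_id`,
#'   `site_id`, `true_lineage`, `event_id`, `true_ploidy`), and
#'   `site_truth` (per site: distinct founding lineages surviving in the
#'   population and present in the sample).
#' @export
generate_survey <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  # founder genotypes are drawn once per founder group, so events sharing a
  # group plant the very same lineages (widespread-lineage scenario)
  group_founders <- list()
  for (grp in unique(cfg$events$founder_group)) {
    nf <- cfg$events$n_founders[cfg$events$founder_group == grp][1]
    f <- generate_founder_lineages(nf, cfg$allele_pools,
                                   cfg$max_variable_loci)
    names(f) <- sprintf("%s:F%02d", grp, seq_along(f))
    group_founders[[grp]] <- f
  }
  geno_rows <- list(); truth_rows <- list(); site_truth_rows <- list()
  for (s in seq_len(nrow(cfg$sites))) {
    site <- cfg$sites[s, ]
    ev <- cfg$events[cfg$events$site_id == site$site_id, , drop = FALSE]
    if (nrow(ev) == 0) {
      site_truth_rows[[s]] <- tibble::tibble(
        site_id = site$site_id, n_lineages_population = 0L,
        n_lineages_sample = 0L)
      next
    }
    # population: one drifted deme per event, concatenated
    pop_lineage <- character(0); pop_event <- character(0)
    founders <- list()
    for (e in seq_len(nrow(ev))) {
      f <- group_founders[[ev$founder_group[e]]]
      founders <- c(founders, f)
      counts <- drift_label_counts(ev$n_founders[e], site$deme_size,
                                   ev$time_bp[e])
      pop_lineage <- c(pop_lineage, rep.int(names(f), counts))
      pop_event <- c(pop_event, rep.int(ev$event_id[e], sum(counts)))
    }
    ages <- stats::setNames(rep(ev$time_bp, times = ev$n_founders),
                            names(founders))
    copies <- table(pop_lineage)
    pick <- sample.int(length(pop_lineage), cfg$sample_n)
    eos_share <- if (site$n_eos + site$n_neo > 0) {
      site$n_eos / (site$n_eos + site$n_neo)
    } else 0.5
    ids <- sprintf("%s_h%02d", gsub("[^A-Za-z0-9]", "", site$site_id),
                   seq_len(cfg$sample_n))
    # realized genotypes: a within-lineage coalescent genealogy per sampled
    # lineage, with stepwise mutation dropped on its branches
    alleles <- vector("list", cfg$sample_n)
    for (lin in unique(pop_lineage[pick])) {
      idx <- which(pop_lineage[pick] == lin)
      alleles[idx] <- mutate_along_genealogy(
        founders[[lin]], length(idx), as.integer(copies[[lin]]),
        ages[[lin]], cfg$mutation_rate)
    }
    ploidy_true <- character(cfg$sample_n)
    for (i in seq_len(cfg$sample_n)) {
      g <- alleles[[i]]
      if (stats::runif(1) < cfg$triploid_fraction) {
        origin <- if (stats::runif(1) < eos_share) "eos" else "neogaeus"
        g <- add_sperm_haplome(g, origin, cfg$allele_pools)
        ploidy_true[i] <- "3n"
      } else {
        ploidy_true[i] <- "2n"
      }
      alleles[[i]] <- g
    }
    geno_rows[[s]] <- genotype_table(
      ids, rep(site$site_id, cfg$sample_n), rep("HYB", cfg$sample_n),
      alleles)
    truth_rows[[s]] <- tibble::tibble(
      individual_id = ids, site_id = site$site_id,
      true_lineage = pop_lineage[pick], event_id = pop_event[pick],
      true_ploidy = ploidy_true)
    site_truth_rows[[s]] <- tibble::tibble(
      site_id = site$site_id,
      n_lineages_population = length(unique(pop_lineage)),
      n_lineages_sample = length(unique(pop_lineage[pick])))
  }
  sampled <- dplyr::bind_rows(truth_rows)
  sites_out <- cfg$sites
  sites_out$n_hyb <- vapply(sites_out$site_id, function(id) {
    sum(sampled$site_id == id)
  }, integer(1))
  sites_out$lgs_category <- normalize_lgs(sites_out$lgs_category)
  list(genotypes = dplyr::bind_rows(geno_rows),
       sites = sites_out[, c("site_id", "lat", "lon", "network",
                             "lgs_category", "n_eos", "n_hyb", "n_neo")],
       truth = sampled,
       site_truth = dplyr::bind_rows(site_truth_rows))
}
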