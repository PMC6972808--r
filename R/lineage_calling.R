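# Clonal lineage calling. Diploid hybrid genotypes are grouped by
# single-linkage on a step-distance graph: two genotypes are joined when they
# are identical everywhere except at a small number of loci, each within a
# small number of stepwise-mutation units. Each connected component is a
# lineage, summarized by a consensus genotype (invariant allele where the
# locus is invariant, modal allele where it varies). Triploids, which carry a
# lineage's consensus plus an incorporated sperm haplome, are then assigned
# back to lineages.

#' Clustering parameters for lineage calling
#'
#' @param max_step_per_locus Maximum stepwise-mutation distance tolerated at a
#'   variable locus (1 unit = 1 mutational step).
#' @param max_variable_loci Maximum number of loci allowed to differ between
#'   two genotypes of the same lineage.
#' @param tie_break How consensus ties are resolved; only `"smallest-allele"`
#'   is implemented.
#' @return A named list of validated parameters.
#' @export
clustering_params <- function(max_step_per_locus = 1L, max_variable_loci = 2L,
                              tie_break = "smallest-allele") {
  stopifnot(max_step_per_locus >= 1, max_variable_loci >= 1)
  tie_break <- match.arg(tie_break, "smallest-allele")
  list(max_step_per_locus = as.integer(max_step_per_locus),
       max_variable_loci = as.integer(max_variable_loci),
       tie_break = tie_break)
}

# Step distance between two allele multisets at one locus. Unphased pairs at
# both-genomes loci are compared under the optimal matching (min over the two
# pairings). NA when either side is missing; Inf when sizes differ.
locus_step_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  if (length(a) != length(b)) return(Inf)
  if (length(a) == 1) return(abs(a - b))
  if (length(a) == 2) {
    return(min(abs(a[1] - b[1]) + abs(a[2] - b[2]),
               abs(a[1] - b[2]) + abs(a[2] - b[1])))
  }
  # length 3: minimum over all allele matchings
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(p) sum(abs(a - b[p])), numeric(1)))
}

# Per-locus distances between two rows of a genotype tibble.
genotype_distances <- function(g, i, j) {
  vapply(panel_loci(), function(loc) {
    locus_step_distance(g[[loc]][[i]], g[[loc]][[j]])
  }, numeric(1))
}

# Do two genotypes belong to the same lineage under the step rule? Missing
# loci are non-informative and excluded from the comparison.
same_lineage_edge <- function(d, params) {
  d <- d[!is.na(d)]
  diff <- d[d > 0]
  length(diff) <= params$max_variable_loci &&
    all(diff <= params$max_step_per_locus)
}

#' Infer hybrid ploidy from allele counts
#'
#' A hybrid is scored triploid when any both-genomes locus shows three
#' distinct alleles, or any eos-specific locus shows two (the *C. neogaeus*
#' haplome cannot contribute there, so a second allele must be an incorporated
#' sperm haplome). Otherwise the genotype is diploid-compatible: a triploid
#' whose sperm allele coincides with an existing allele (dosage masking) is
#' indistinguishable from a diploid on sizes alone.
#'
#' @param g A genotype tibble of hybrids.
#' @return Character vector of `"2n"`, `"3n"` or `"unknown"` (all loci
#'   missing), one per row.
#' @export
infer_ploidy <- function(g) {
  if (!all(g$biotype == "HYB")) stop("ploidy inference applies to hybrids")
  vapply(seq_len(nrow(g)), function(i) {
    sizes <- vapply(panel_loci(), function(loc) length(g[[loc]][[i]]),
                    integer(1))
    if (all(sizes == 0)) return("unknown")
    tri <- any(sizes[both_genome_loci()] >= 3) ||
      any(sizes[eos_specific_loci()] >= 2)
    if (tri) "3n" else "2n"
  }, character(1))
}

#' Consensus genotype of a lineage
#'
#' Per locus and haplome slot (alleles sorted within a locus), the consensus
#' is the unique allele where the members are invariant and the modal allele
#' where they vary. Ties are broken to the smallest allele and the tied loci
#' are recorded in the `"ties"` attribute.
#'
#' @param g A genotype tibble of the diploid members of one lineage.
#' @param params A [clustering_params()] list.
#' @return A bare genotype (named list locus -> sorted integer alleles) with
#'   attribute `ties`.
#' @export
consensus_genotype <- function(g, params = clustering_params()) {
  if (nrow(g) == 0) stop("cannot take the consensus of zero members")
  cons <- lapply(panel_loci(), function(loc) {
    vecs <- Filter(function(v) length(v) > 0, g[[loc]])
    if (length(vecs) == 0) return(integer(0))
    sizes <- unique(lengths(vecs))
    if (length(sizes) > 1) {
      stop("members disagree on allele count at ", loc)
    }
    vapply(seq_len(sizes), function(slot) {
      slot_alleles <- vapply(vecs, `[[`, integer(1), slot)
      tab <- table(slot_alleles)
      min(as.integer(names(tab)[tab == max(tab)]))
    }, integer(1))
  })
  names(cons) <- panel_loci()
  # tie flags per locus (a slot-level tie rolls up to the locus)
  ties <- panel_loci()[vapply(panel_loci(), function(loc) {
    vecs <- Filter(function(v) length(v) > 0, g[[loc]])
    if (length(vecs) <= 1) return(FALSE)
    any(vapply(seq_along(cons[[loc]]), function(slot) {
      slot_alleles <- vapply(vecs, `[[`, integer(1), slot)
      tab <- table(slot_alleles)
      sum(tab == max(tab)) > 1 && length(tab) > 1
    }, logical(1)))
  }, logical(1))]
  attr(cons, "ties") <- ties
  cons
}

#' Cluster diploid hybrid genotypes into clonal lineages
#'
#' Single-linkage connected components of the graph whose edges join
#' genotypes within `max_step_per_locus` mutational steps at no more than
#' `max_variable_loci` loci (identical elsewhere). Output order is
#' deterministic: by first site then consensus genotype.
#'
#' @param g A genotype tibble of diploid hybrids (`ploidy` `"2n"` or
#'   diploid-compatible).
#' @param params A [clustering_params()] list.
#' @return A lineage tibble: `lineage_id`, `consensus` (list of bare
#'   genotypes), `diploid_members`, `triploid_members`, `n_diploids`,
#'   `n_triploids`, `n_variants` (members differing from the consensus),
#'   `sites` (list of site sets).
#' @export
cluster_lineages <- function(g, params = clustering_params()) {
  if (nrow(g) == 0) stop("no genotypes to cluster")
  if (!all(g$biotype == "HYB")) stop("lineage calling applies to hybrids")
  pl <- infer_ploidy(g)
  if (any(pl == "3n")) {
    stop("mixed ploidy input: call lineages from diploids, then assign ",
         "triploids with assign_triploids()")
  }
  n <- nrow(g)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (same_lineage_edge(genotype_distances(g, i, j), params)) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership

  rows <- lapply(unique(comp), function(k) {
    idx <- which(comp == k)
    members <- g[idx, , drop = FALSE]
    cons <- consensus_genotype(members, params)
    nvar <- sum(vapply(idx, function(i) {
      d <- vapply(panel_loci(), function(loc) {
        locus_step_distance(g[[loc]][[i]], cons[[loc]])
      }, numeric(1))
      any(d[!is.na(d)] > 0)
    }, logical(1)))
    tibble::tibble(
      first_site = min(g$site_id[idx]),
      consensus_key = format_genotype(cons),
      consensus = list(cons),
      diploid_members = list(g$individual_id[idx]),
      n_diploids = length(idx),
      n_variants = nvar,
      sites = list(sort(unique(g$site_id[idx])))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), first_site, consensus_key)
  out$lineage_id <- sprintf("L%03d", seq_len(nrow(out)))
  out$triploid_members <- rep(list(character(0)), nrow(out))
  out$n_triploids <- 0L
  out[, c("lineage_id", "consensus", "diploid_members", "triploid_members",
          "n_diploids", "n_triploids", "n_variants", "sites")]
}

# Minimal distance between a triploid's multiset and a consensus multiset at
# one locus, allowing removal of `drop` alleles from the triploid (the
# candidate sperm allele). Inf when no removal reconciles the sizes.
triploid_locus_distance <- function(tri, cons, allow_drop) {
  if (length(cons) == 0 || length(tri) == 0) return(NA_real_)
  extra <- length(tri) - length(cons)
  if (extra == 0) return(locus_step_distance(tri, cons))
  if (extra == 1 && allow_drop) {
    return(min(vapply(seq_along(tri), function(k) {
      locus_step_distance(tri[-k], cons)
    }, numeric(1))))
  }
  Inf
}

# Distance profile of a triploid against one lineage consensus under a sperm
# origin hypothesis ("eos": the sperm haplome may add an allele at every
# locus; "neogaeus": only at both-genomes loci).
triploid_match <- function(g, row, cons, origin, params) {
  droppable <- if (origin == "eos") panel_loci() else both_genome_loci()
  d <- vapply(panel_loci(), function(loc) {
    triploid_locus_distance(g[[loc]][[row]], cons[[loc]],
                            loc %in% droppable)
  }, numeric(1))
  dd <- d[!is.na(d)]
  diff <- dd[dd > 0]
  ok <- length(diff) <= params$max_variable_loci &&
    all(diff <= params$max_step_per_locus)
  list(ok = ok, n_diff = length(diff), total = sum(diff))
}

#' Assign triploid hybrids to called lineages
#'
#' A triploid matches a lineage when removing one candidate sperm allele per
#' locus (consistently with a single genome of origin) leaves the lineage
#' consensus within the same step tolerance used for clustering. Triploids
#' matching no lineage are additional lineages (`NEW`), deduplicated by
#' genotype; triploids matching two or more lineages equally well are
#' `AMBIGUOUS` and excluded from lineage counts.
#'
#' @param g A genotype tibble of triploid hybrids.
#' @param lineages A lineage tibble from [cluster_lineages()].
#' @param params A [clustering_params()] list.
#' @return An assignment tibble: `triploid_id`, `site_id`,
#'   `assigned_lineage` (a lineage id, `"NEW:<k>"`, or `"AMBIGUOUS"`),
#'   `sperm_origin` (`"eos"`, `"neogaeus"`, `"ambiguous"`).
#' @export
assign_triploids <- function(g, lineages, params = clustering_params()) {
  if (nrow(g) == 0) {
    return(tibble::tibble(triploid_id = character(0), site_id = character(0),
                          assigned_lineage = character(0),
                          sperm_origin = character(0)))
  }
  pl <- infer_ploidy(g)
  if (any(pl == "2n")) stop("assign_triploids() expects triploid genotypes")
  res <- lapply(seq_len(nrow(g)), function(i) {
    # sperm origin evidence independent of lineage: an extra allele at an
    # eos-specific locus can only be an eos sperm haplome
    eos_extra <- any(vapply(eos_specific_loci(), function(loc) {
      length(g[[loc]][[i]]) >= 2
    }, logical(1)))
    best <- NULL
    for (L in seq_len(nrow(lineages))) {
      for (origin in c("eos", "neogaeus")) {
        if (origin == "neogaeus" && eos_extra) next
        m <- triploid_match(g, i, lineages$consensus[[L]], origin, params)
        if (!m$ok) next
        cand <- list(lineage = L, origin = origin,
                     score = c(m$n_diff, m$total))
        if (is.null(best)) {
          best <- list(cand)
        } else {
          # lexicographic score: number of differing loci, then total steps
          if (cand$score[1] < best[[1]]$score[1] ||
              (cand$score[1] == best[[1]]$score[1] &&
               cand$score[2] < best[[1]]$score[2])) {
            best <- list(cand)
          } else if (all(cand$score == best[[1]]$score)) {
            best <- c(best, list(cand))
          }
        }
      }
    }
    if (is.null(best)) {
      return(list(assigned = "NEW", origin = if (eos_extra) "eos" else
        "ambiguous"))
    }
    lins <- unique(vapply(best, function(b) b$lineage, numeric(1)))
    if (length(lins) > 1) {
      return(list(assigned = "AMBIGUOUS", origin = "ambiguous"))
    }
    origins <- unique(vapply(best, function(b) b$origin, character(1)))
    list(assigned = lineages$lineage_id[lins],
         origin = if (length(origins) == 1) origins else "ambiguous")
  })
  assigned <- vapply(res, `[[`, character(1), "assigned")
  origin <- vapply(res, `[[`, character(1), "origin")
  # deduplicate NEW triploids by genotype: identical unmatched triploids are
  # one additional lineage, not several
  new_idx <- which(assigned == "NEW")
  if (length(new_idx) > 0) {
    keys <- vapply(new_idx, function(i) format_genotype(as_bare_genotype(g, i)),
                   character(1))
    assigned[new_idx] <- paste0("NEW:", match(keys, unique(keys)))
  }
  tibble::tibble(triploid_id = g$individual_id, site_id = g$site_id,
                 assigned_lineage = assigned, sperm_origin = origin)
}

#' Call clonal lineages from a mixed-ploidy hybrid genotype table
#'
#' Convenience pipeline: infers ploidy, clusters the diploid(-compatible)
#' hybrids into lineages, assigns the triploids, and appends unmatched
#' triploid genotypes as additional lineages.
#'
#' @param g A genotype tibble of hybrids.
#' @param params A [clustering_params()] list.
#' @return A list with `lineages` (including NEW-triploid lineages),
#'   `assignments` (triploid assignment tibble) and `occurrences`
#'   (lineage x site presence tibble).
#' @export
call_lineages <- function(g, params = clustering_params()) {
  g <- g[g$biotype == "HYB", , drop = FALSE]
  if (nrow(g) == 0) stop("no hybrid genotypes supplied")
  pl <- infer_ploidy(g)
  dip <- g[pl != "3n" & pl != "unknown", , drop = FALSE]
  tri <- g[pl == "3n", , drop = FALSE]
  lineages <- cluster_lineages(dip, params)
  assignments <- assign_triploids(tri, lineages, params)
  # attach assigned triploids to their lineages
  for (i in seq_len(nrow(assignments))) {
    a <- assignments$assigned_lineage[i]
    if (a %in% lineages$lineage_id) {
      k <- match(a, lineages$lineage_id)
      lineages$triploid_members[[k]] <- c(lineages$triploid_members[[k]],
                                          assignments$triploid_id[i])
      lineages$n_triploids[k] <- lineages$n_triploids[k] + 1L
      lineages$sites[[k]] <- sort(unique(c(lineages$sites[[k]],
                                           assignments$site_id[i])))
    }
  }
  # NEW triploid genotypes become additional lineages (one per distinct
  # genotype; the diploid part of the hybrid genotype is unknown)
  new_keys <- unique(assignments$assigned_lineage[
    startsWith(assignments$assigned_lineage, "NEW:")])
  if (length(new_keys) > 0) {
    extra <- lapply(new_keys, function(key) {
      idx <- which(assignments$assigned_lineage == key)
      row1 <- match(assignments$triploid_id[idx[1]], tri$individual_id)
      tibble::tibble(
        lineage_id = sprintf("T%03d", match(key, new_keys)),
        consensus = list(as_bare_genotype(tri, row1)),
        diploid_members = list(character(0)),
        triploid_members = list(assignments$triploid_id[idx]),
        n_diploids = 0L,
        n_triploids = length(idx),
        n_variants = 0L,
        sites = list(sort(unique(assignments$site_id[idx])))
      )
    })
    lineages <- dplyr::bind_rows(lineages, dplyr::bind_rows(extra))
  }
  occurrences <- tidyr::unnest(
    lineages[, c("lineage_id", "sites")], "sites")
  names(occurrences) <- c("lineage_id", "site_id")
  list(lineages = lineages, assignments = assignments,
       occurrences = occurrences)
}
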