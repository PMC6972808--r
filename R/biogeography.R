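# Geography of lineages. Geographically close sites in the same hydrographic
# network that harbor the very same hybrid assemblage are pooled (they record
# the same local hybridization events); lineages confined to one pooled group
# are "private" (local hybridization), while lineages shared between distant
# sites -- a fortiori between networks -- are widespread Pleistocene-migrant
# candidates. Occupancy and diversity are then aggregated over the four LGS
# categories.

#' Site-pooling parameters
#'
#' @param max_distance_km Great-circle distance (km) below which two sites may
#'   be pooled. The survey design gives no threshold; 10 km is the default and
#'   is reported with the output.
#' @param require_same_network Pool only within a hydrographic network.
#' @param require_identical_assemblage Pool only sites with identical lineage
#'   assemblages.
#' @return A named list of validated parameters.
#' @export
pooling_params <- function(max_distance_km = 10,
                           require_same_network = TRUE,
                           require_identical_assemblage = TRUE) {
  stopifnot(max_distance_km > 0)
  list(max_distance_km = max_distance_km,
       require_same_network = require_same_network,
       require_identical_assemblage = require_identical_assemblage)
}

#' Pool geographically close, assemblage-identical sites
#'
#' Two sites share a pooled group when they lie in the same network, their
#' great-circle (haversine) distance is within `max_distance_km`, and they
#' harbor identical lineage assemblages; groups are the transitive closure
#' (connected components) of this relation.
#'
#' @param sites A site tibble with `site_id`, `lat`, `lon`, `network`.
#' @param occurrences A tibble of `lineage_id`, `site_id` presences covering
#'   all occupied sites.
#' @param params A [pooling_params()] list.
#' @return A tibble `site_id`, `pooled_group`.
#' @export
pool_sites <- function(sites, occurrences, params = pooling_params()) {
  if (anyNA(sites$lat) || anyNA(sites$lon)) {
    stop("site(s) missing coordinates: ",
         paste(sites$site_id[is.na(sites$lat) | is.na(sites$lon)],
               collapse = ", "))
  }
  n <- nrow(sites)
  assemblage <- vapply(sites$site_id, function(s) {
    paste(sort(occurrences$lineage_id[occurrences$site_id == s]),
          collapse = "|")
  }, character(1))
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (params$require_same_network &&
            sites$network[i] != sites$network[j]) next
        if (params$require_identical_assemblage &&
            assemblage[i] != assemblage[j]) next
        d_km <- geosphere::distHaversine(
          c(sites$lon[i], sites$lat[i]),
          c(sites$lon[j], sites$lat[j])) / 1000
        if (d_km <= params$max_distance_km) edges <- c(edges, i, j)
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  # deterministic group labels: number groups by their first site in input
  relabel <- match(comp, unique(comp))
  tibble::tibble(site_id = sites$site_id,
                 pooled_group = sprintf("G%03d", relabel))
}

#' Classify lineages as private or widespread
#'
#' A lineage is private when all its occurrences fall within a single pooled
#' group of sites; otherwise it is widespread, a Pleistocene-migrant
#' candidate, additionally flagged `cross_network` when it spans two or more
#' hydrographic networks.
#'
#' @param lineages A lineage tibble (needs `lineage_id` and a `sites`
#'   list-column), or any tibble of `lineage_id`/`sites`.
#' @param grouping The `site_id` -> `pooled_group` tibble from
#'   [pool_sites()].
#' @param sites A site tibble with `site_id` and `network`.
#' @return A range tibble: `lineage_id`, `n_sites`, `n_groups`, `networks`
#'   (list-column), `classification`, `cross_network`.
#' @export
classify_lineages <- function(lineages, grouping, sites) {
  rows <- lapply(seq_len(nrow(lineages)), function(i) {
    occ <- lineages$sites[[i]]
    if (length(occ) == 0) {
      stop("lineage ", lineages$lineage_id[i], " has no occurrences")
    }
    gidx <- match(occ, grouping$site_id)
    if (anyNA(gidx)) {
      stop("pooling does not cover site(s): ",
           paste(occ[is.na(gidx)], collapse = ", "))
    }
    groups <- unique(grouping$pooled_group[gidx])
    nets <- sort(unique(sites$network[match(occ, sites$site_id)]))
    tibble::tibble(
      lineage_id = lineages$lineage_id[i],
      sites = list(occ),
      n_sites = length(occ),
      n_groups = length(groups),
      networks = list(nets),
      classification = if (length(groups) == 1) "private" else "widespread",
      cross_network = length(nets) >= 2
    )
  })
  dplyr::bind_rows(rows)
}

#' Site occupancy by LGS category
#'
#' Counts occupied (sampled count > 0) and unoccupied sites per LGS category
#' for one biotype, rows ordered from the southernmost (150-160 days)
#' category to the northernmost (120-130 days).
#'
#' @param sites A site tibble with `lgs_category` and the biotype count
#'   columns `n_eos`, `n_hyb`, `n_neo`.
#' @param biotype `"EOS"`, `"HYB"` or `"NEO"`.
#' @return A tibble `lgs_category`, `occupied`, `unoccupied`.
#' @export
occupancy_by_category <- function(sites, biotype = c("EOS", "HYB", "NEO")) {
  biotype <- match.arg(biotype)
  col <- c(EOS = "n_eos", HYB = "n_hyb", NEO = "n_neo")[[biotype]]
  occ <- sites[[col]] > 0
  cat <- factor(as.character(sites$lgs_category), levels = lgs_levels())
  tibble::tibble(
    lgs_category = lgs_levels(),
    occupied = as.integer(tapply(occ, cat, sum, default = 0L)[lgs_levels()]),
    unoccupied = as.integer(tapply(!occ, cat, sum, default = 0L)[lgs_levels()])
  )
}

#' Private-lineage diversity by LGS category
#'
#' Aggregates private-lineage counts over the four LGS categories and
#' reports per-site means (count / number of sites in the category). Accepts
#' either a survey summary carrying per-site `n_private` counts, or a range
#' tibble from [classify_lineages()] together with the site table (each
#' private lineage is then attributed to the category of its sites).
#'
#' @param x Either a summary tibble with `site_id`, `lgs_category`,
#'   `n_private`, or a range tibble from [classify_lineages()] with a
#'   `networks`/`sites` structure.
#' @param sites Site tibble; required when `x` is a range tibble.
#' @return A tibble `lgs_category`, `n_sites`, `n_private`,
#'   `mean_per_site`, southernmost category first.
#' @export
diversity_by_category <- function(x, sites = NULL) {
  if ("n_private" %in% names(x)) {
    summary <- x
  } else {
    if (is.null(sites)) stop("sites required when x is a range tibble")
    if (!("sites" %in% names(x))) stop("range tibble needs a 'sites' column")
    per_site <- stats::setNames(rep(0L, nrow(sites)), sites$site_id)
    priv <- x[x$classification == "private", , drop = FALSE]
    for (i in seq_len(nrow(priv))) {
      # a private lineage's sites all lie in one pooled group, hence in one
      # category; attribute it to its first site
      s <- priv$sites[[i]][1]
      per_site[s] <- per_site[s] + 1L
    }
    summary <- tibble::tibble(site_id = sites$site_id,
                              lgs_category = sites$lgs_category,
                              n_private = as.integer(per_site))
  }
  cat <- factor(as.character(summary$lgs_category), levels = lgs_levels())
  n_sites <- as.integer(table(cat)[lgs_levels()])
  n_priv <- as.integer(tapply(summary$n_private, cat, sum,
                              default = 0L)[lgs_levels()])
  tibble::tibble(
    lgs_category = lgs_levels(),
    n_sites = n_sites,
    n_private = n_priv,
    mean_per_site = n_priv / n_sites
  )
}
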