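# Readers and writers for the survey's tab-separated interchange formats, plus
# the embedded per-site summary of the 51-site latitudinal transect that
# anchors the in-survey checks.

KNOWN_NETWORKS <- c("RI", "YA", "SF", "CH", "SJ", "OU", "LO", "RM", "MI")

#' Parse degree-minute-second coordinates to decimal degrees
#'
#' Accepts typographic glyphs (45°03′01″) as well as ASCII quotes
#' (45:03:01, 45 03 01, 45d03'01"). Seconds and minutes may be omitted.
#'
#' @param x Character vector of DMS strings (or already-decimal numbers).
#' @return Numeric decimal degrees.
#' @export
#' @examples
#' parse_dms("45°03′01″") # 45.0503
parse_dms <- function(x) {
  vapply(as.character(x), function(s) {
    s0 <- trimws(s)
    if (grepl("^-?[0-9]+(\\.[0-9]+)?$", s0)) return(as.numeric(s0))
    neg <- grepl("^-", s0) || grepl("[SW]$", s0, ignore.case = TRUE)
    parts <- regmatches(s0, gregexpr("[0-9]+(\\.[0-9]+)?", s0))[[1]]
    if (length(parts) < 1 || length(parts) > 3) {
      stop("cannot parse coordinate: ", s)
    }
    parts <- as.numeric(parts)
    val <- parts[1] + ifelse(length(parts) >= 2, parts[2] / 60, 0) +
      ifelse(length(parts) >= 3, parts[3] / 3600, 0)
    if (neg) -val else val
  }, numeric(1), USE.NAMES = FALSE)
}

# Expand a pooled site label into its member labels.
# "RI-2-4" -> RI-2, RI-3, RI-4 (range); "SF-4,5,7,8" -> SF-4, SF-5, SF-7, SF-8.
expand_pooled_members <- function(site_id) {
  s <- gsub("\\s+", "", site_id)
  m <- regexec("^([A-Z]+)-(.+)$", s)[[1]]
  if (m[1] == -1) return(s)
  prefix <- regmatches(s, regexec("^([A-Z]+)-", s))[[1]][2]
  rest <- sub("^[A-Z]+-", "", s)
  if (grepl(",", rest)) {
    nums <- strsplit(rest, ",")[[1]]
    return(paste0(prefix, "-", nums))
  }
  if (grepl("^[0-9]+-[0-9]+$", rest)) {
    bounds <- as.integer(strsplit(rest, "-")[[1]])
    return(paste0(prefix, "-", seq(bounds[1], bounds[2])))
  }
  s
}

site_network <- function(site_id) {
  net <- sub("-.*$", "", gsub("\\s+", "", site_id))
  bad <- !(net %in% KNOWN_NETWORKS)
  if (any(bad)) {
    stop("unknown hydrographic network prefix: ",
         paste(unique(net[bad]), collapse = ", "))
  }
  net
}

#' Read a site table
#'
#' Expects a TSV with columns `site_id`, `lat`, `lon`, `network`,
#' `lgs_category`, `n_eos`, `n_hyb`, `n_neo`. Coordinates may be decimal
#' degrees or DMS text; they are normalized to decimal degrees (western
#' longitudes negative when given as positive "W" magnitudes are left to the
#' caller's convention). LGS categories are validated against the four bins.
#'
#' @param path Path to a tab-separated site table.
#' @return A site tibble.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("site_id", "lat", "lon", "network", "lgs_category",
           "n_eos", "n_hyb", "n_neo")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("site table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id: ", tab$site_id[duplicated(tab$site_id)][1])
  }
  tibble::tibble(
    site_id = tab$site_id,
    lat = parse_dms(tab$lat),
    lon = parse_dms(tab$lon),
    network = tab$network,
    lgs_category = normalize_lgs(tab$lgs_category),
    n_eos = as.integer(tab$n_eos),
    n_hyb = as.integer(tab$n_hyb),
    n_neo = as.integer(tab$n_neo)
  )
}

#' Read a genotype table
#'
#' Expects a TSV with columns `individual_id`, `site_id`, `biotype`, then one
#' column per panel locus holding comma-joined allele scores ("178,182");
#' "." marks a missing locus. Rows violating the allele-count bounds (at most
#' 3 at a both-genomes locus, at most 2 at an eos-specific locus) are
#' rejected with the offending line number.
#'
#' @param path Path to a tab-separated genotype table.
#' @return A genotype tibble (see [genotype_table()]).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("individual_id", "site_id", "biotype")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("genotype table lacks column(s): ",
                             paste(miss, collapse = ", "))
  unknown <- setdiff(setdiff(names(tab), c(req, "ploidy")), panel_loci())
  if (length(unknown) > 0) stop("unknown locus column(s): ",
                                paste(unknown, collapse = ", "))
  miss_loc <- setdiff(panel_loci(), names(tab))
  if (length(miss_loc) > 0) stop("genotype table lacks locus column(s): ",
                                 paste(miss_loc, collapse = ", "))
  alleles <- lapply(seq_len(nrow(tab)), function(i) {
    a <- list()
    for (loc in panel_loci()) {
      cell <- tab[[loc]][i]
      if (is.na(cell) || cell == "." || cell == "") next
      v <- suppressWarnings(as.integer(strsplit(cell, ",")[[1]]))
      if (anyNA(v)) {
        stop(sprintf("malformed allele field '%s' at line %d (locus %s)",
                     cell, i + 1L, loc))
      }
      if (length(v) > 3) {
        stop(sprintf(
          "line %d: %d alleles at %s exceeds the triploid bound of 3",
          i + 1L, length(v), loc))
      }
      a[[loc]] <- v
    }
    a
  })
  ploidy <- if ("ploidy" %in% names(tab)) tab$ploidy else NULL
  genotype_table(tab$individual_id, tab$site_id, tab$biotype, alleles,
                 ploidy = ploidy)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: allele list-columns are rendered as
#' comma-joined scores with "." for missing loci.
#'
#' @param g A genotype tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(g, path) {
  out <- g[, c("individual_id", "site_id", "biotype", "ploidy")]
  for (loc in panel_loci()) {
    out[[loc]] <- vapply(g[[loc]], function(v) {
      if (length(v) == 0) "." else paste(v, collapse = ",")
    }, character(1))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write any result table
#'
#' Serializes a tibble or data frame to TSV with a deterministic column
#' order (as given). List-columns are flattened to comma-joined strings so
#' the file can be re-read; an empty result writes a header-only file.
#'
#' @param results A data frame or tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results)) stop("results must be a data frame")
  out <- results
  for (nm in names(out)) {
    if (is.list(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(v) {
        paste(as.character(v), collapse = ",")
      }, character(1))
    } else if (is.factor(out[[nm]])) {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load the embedded 51-site survey summary
#'
#' Returns the per-site summary of the 500-km latitudinal transect of
#' southeastern Quebec shipped with the package: coordinates, hydrographic
#' network, LGS category, numbers of *C. eos*, hybrid and *C. neogaeus*
#' individuals sampled, the number of private hybrid lineages, and the
#' letters (A-H) of any widespread lineages present. Pooled sites (e.g.
#' `SF-4,5,7,8`) are single rows; `pooled_members` preserves the original
#' labels.
#'
#' @return A survey-summary tibble with one row per site (51 rows).
#' @export
#' @examples
#' s <- load_table1_summary()
#' sum(s$n_private) # 70 private lineages
load_table1_summary <- function() {
  path <- system.file("extdata", "table1_sites.tsv", package = "gynoclone")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  id <- gsub("\\s+", "", tab$site_id)
  tibble::tibble(
    site_id = id,
    network = site_network(id),
    lat = parse_dms(tab$lat_dms),
    lon = -parse_dms(tab$lon_dms),  # printed as western magnitudes
    lgs_category = normalize_lgs(tab$lgs_category),
    n_eos = as.integer(tab$n_eos),
    n_hyb = as.integer(tab$n_hyb),
    n_neo = as.integer(tab$n_neo),
    n_private = as.integer(tab$n_private),
    shared_lineages = lapply(tab$shared_lineages, function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ",")[[1]]
    }),
    pooled_members = lapply(id, expand_pooled_members),
    sampling_ref = as.integer(tab$sampling_ref)
  )
}
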