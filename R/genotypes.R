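# Multilocus genotype container: a tibble with one row per individual and one
# list-column of integer allele scores per panel locus. Allele scores are plain
# integers; whether they are repeat counts or fragment sizes is a table-header
# dialect flag, and one unit is always interpreted as one mutational step.

#' Build a multilocus genotype table
#'
#' Assembles per-individual genotypes into the standard container used by all
#' downstream operations: a tibble with identifier columns followed by one
#' list-column of integer allele scores per locus. An empty integer vector
#' denotes a missing (unscored) locus.
#'
#' @param individual_id Character vector of individual identifiers.
#' @param site_id Character vector of site identifiers.
#' @param biotype Character vector, each `"EOS"`, `"NEO"` or `"HYB"`.
#' @param alleles A list (one element per individual) of named lists mapping
#'   locus name to an integer vector of 1-3 allele scores; omitted loci are
#'   treated as missing.
#' @param ploidy Optional character vector (`"2n"`, `"3n"`, `"unknown"`);
#'   defaults to `"unknown"` and is typically filled by [infer_ploidy()].
#' @return A genotype tibble.
#' @export
genotype_table <- function(individual_id, site_id, biotype, alleles,
                           ploidy = NULL) {
  n <- length(individual_id)
  stopifnot(length(site_id) == n, length(biotype) == n, length(alleles) == n)
  if (!all(biotype %in% c("EOS", "NEO", "HYB"))) {
    stop("biotype must be one of EOS, NEO, HYB")
  }
  if (is.null(ploidy)) ploidy <- rep("unknown", n)
  out <- tibble::tibble(
    individual_id = as.character(individual_id),
    site_id = as.character(site_id),
    biotype = biotype,
    ploidy = ploidy
  )
  for (loc in panel_loci()) {
    out[[loc]] <- lapply(alleles, function(a) {
      v <- a[[loc]]
      if (is.null(v)) integer(0) else sort(as.integer(v))
    })
  }
  validate_genotypes(out)
  out
}

# Check structural invariants: every panel locus present, allele multisets
# within the ploidy bounds (3n bounds when ploidy is unknown, since dosage
# masking means sizes alone cannot rule triploidy out).
validate_genotypes <- function(g) {
  missing_loc <- setdiff(panel_loci(), names(g))
  if (length(missing_loc) > 0) {
    stop("genotype table lacks locus column(s): ",
         paste(missing_loc, collapse = ", "))
  }
  for (loc in panel_loci()) {
    sizes <- lengths(g[[loc]])
    cap <- ifelse(g$ploidy == "2n", max_alleles(loc, "2n"),
                  max_alleles(loc, "3n"))
    bad <- which(sizes > cap)
    if (length(bad) > 0) {
      stop(sprintf(
        "individual %s has %d alleles at %s (at most %d allowed for ploidy %s)",
        g$individual_id[bad[1]], sizes[bad[1]], loc, cap[bad[1]],
        g$ploidy[bad[1]]))
    }
  }
  invisible(g)
}

# Extract the allele multiset (sorted integer vector) of one individual at one
# locus; length 0 means missing.
alleles_at <- function(g, row, locus) g[[locus]][[row]]

# A bare genotype: named list locus -> sorted integer vector. Used for
# consensus genotypes and founders, where no individual metadata applies.
as_bare_genotype <- function(g, row) {
  out <- lapply(panel_loci(), function(loc) g[[loc]][[row]])
  names(out) <- panel_loci()
  out
}

# Render a bare genotype as a stable string ("178,182|140|..."), used for
# deterministic ordering and deduplication.
format_genotype <- function(bare) {
  paste(vapply(panel_loci(), function(loc) {
    v <- bare[[loc]]
    if (length(v) == 0) "." else paste(v, collapse = ",")
  }, character(1)), collapse = "|")
}
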