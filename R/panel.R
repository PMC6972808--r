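# Marker panel for the Chrosomus eos-neogaeus complex.
#
# Hybrids carry one haploid C. eos genome and one haploid C. neogaeus genome
# ("haplomes"). Three microsatellite loci amplify both genomes and three are
# specific to the C. eos genome, so a diploid hybrid genotype occupies nine
# haplome slots: six for eos (3 shared loci + 3 eos-specific) and three for
# neogaeus (shared loci only).

#' Microsatellite locus panel
#'
#' Returns the default six-locus panel used to genotype clonal hybrids:
#' `Seat412`, `Ca-12` and `Rhca-20` amplify both parental genomes
#' (`both-genomes`), while `Pho-60`, `Pho-1` and `Pho-2` amplify only the
#' *C. eos* genome (`eos-specific`).
#'
#' @return A tibble with columns `locus` and `specificity`.
#' @export
#' @examples
#' locus_panel()
locus_panel <- function() {
  tibble::tibble(
    locus = c("Seat412", "Ca-12", "Pho-60", "Pho-1", "Pho-2", "Rhca-20"),
    specificity = c("both-genomes", "both-genomes", "eos-specific",
                    "eos-specific", "eos-specific", "both-genomes")
  )
}

panel_loci <- function() locus_panel()$locus

both_genome_loci <- function() {
  p <- locus_panel()
  p$locus[p$specificity == "both-genomes"]
}

eos_specific_loci <- function() {
  p <- locus_panel()
  p$locus[p$specificity == "eos-specific"]
}

# Maximum number of distinct allele sizes scorable at a locus for a ploidy.
max_alleles <- function(locus, ploidy) {
  eos_only <- locus %in% eos_specific_loci()
  if (ploidy == "3n") ifelse(eos_only, 2L, 3L) else ifelse(eos_only, 1L, 2L)
}

#' Length-of-growing-season categories, south to north
#'
#' The four 10-day LGS bins used to stratify sites along the latitudinal
#' transect. Southern (warmer) sites have the longest growing season, so the
#' south-to-north ordering runs from `150-160` down to `120-130` days.
#'
#' @return Character vector of the four categories, southernmost first.
#' @export
lgs_levels <- function() c("150-160", "140-150", "130-140", "120-130")

# Normalize en-dash and whitespace in LGS labels, validate against the 4 bins.
normalize_lgs <- function(x) {
  y <- gsub("–", "-", trimws(x))
  bad <- !(y %in% lgs_levels())
  if (any(bad)) {
    stop("unknown LGS category: ", paste(unique(y[bad]), collapse = ", "),
         " (expected one of ", paste(lgs_levels(), collapse = ", "), ")")
  }
  factor(y, levels = lgs_levels())
}
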