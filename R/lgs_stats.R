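# Statistical battery for the latitudinal survey: exact r x 2 contingency
# tests of occupancy evenness, Yates-corrected 2 x 2 chi-square for biotype
# abundance, a sites-proportional goodness-of-fit for diversity contrasts,
# Mann-Whitney U for per-site counts, LOESS with GCV-selected span for the
# diversity-latitude relationship, and an OLS check that lineage counts are
# not driven by sampling effort. Two-sided p-values throughout; no
# multiple-testing correction is applied.

#' Fisher's exact test for an r x 2 occupancy table
#'
#' Two-sided Freeman-Halton test: the p-value sums the probabilities of all
#' margin-fixed tables no more probable than the observed one. Rows with a
#' zero marginal carry no information and may be present or absent without
#' changing the result.
#'
#' @param table An r x 2 matrix of non-negative integer counts
#'   (occupied/unoccupied per stratum).
#' @return The two-sided p-value.
#' @export
fisher_exact_rx2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("contingency table entries must be non-negative")
  if (ncol(table) != 2) stop("expected an r x 2 table")
  stats::fisher.test(table)$p.value
}

#' Yates-corrected 2 x 2 chi-square test
#'
#' Continuity-corrected statistic `sum((|O - E| - 0.5)^2 / E)` with expected
#' counts from the margins, 1 degree of freedom.
#'
#' @param table A 2 x 2 matrix of non-negative counts.
#' @return A list with `chi2`, `df` and `p`.
#' @export
chisq_yates_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2 x 2 table")
  if (any(table < 0)) stop("entries must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in 2 x 2 table")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Goodness-of-fit chi-square with sites-proportional expectations
#'
#' Tests observed counts per group against expectations proportional to a
#' weight per group (here, the number of sites per LGS category):
#' `E_i = sum(O) * w_i / sum(w)`, statistic `sum((O - E)^2 / E)` with
#' `length(O) - 1` degrees of freedom and no continuity correction.
#'
#' @param observed Non-negative counts per group.
#' @param weights Positive weights (e.g. sites per group), same length.
#' @return A list with `chi2`, `df` and `p`.
#' @export
chisq_gof_proportional <- function(observed, weights) {
  if (length(observed) != length(weights) || length(observed) < 2) {
    stop("observed and weights must be equal-length vectors (>= 2 groups)")
  }
  if (sum(observed) <= 0) stop("no observations")
  if (any(weights == 0 & observed > 0)) {
    stop("zero weight with nonzero observed count")
  }
  fit <- suppressWarnings(
    stats::chisq.test(observed, p = weights / sum(weights)))
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration when the pooled sample is small (n1 + n2 <= 25) and
#' tie-free; otherwise the tie-corrected normal approximation with continuity
#' correction. The method used is reported.
#'
#' @param x,y Numeric vectors (e.g. per-site private-lineage counts of two
#'   latitudinal groups).
#' @return A list with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 25
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(fit$statistic), p = fit$p.value,
       method = if (exact) "exact" else "normal")
}

#' LOESS with GCV-selected span
#'
#' Local polynomial regression (tricube weights) whose span is chosen to
#' minimize the generalized cross-validation score
#' `GCV = n * RSS / (n - trace(hat))^2` over a grid of spans. Spans leaving
#' fewer points in a window than the local fit needs are dropped from the
#' grid with a warning (span floor raised).
#'
#' @param x,y Numeric vectors (e.g. latitude and private-lineage count).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param span_grid Candidate spans (default `seq(0.2, 1, by = 0.05)`).
#' @return A list with `span`, `degree`, `fitted`, `gcv` and the full
#'   `gcv_table` (span, gcv).
#' @export
loess_gcv <- function(x, y, degree = 2, span_grid = seq(0.2, 1, by = 0.05)) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 8) stop("at least 8 points are required")
  ctl <- stats::loess.control(surface = "direct", statistics = "exact",
                              trace.hat = "exact")
  fits <- lapply(span_grid, function(s) {
    tryCatch(
      suppressWarnings(stats::loess(y ~ x, span = s, degree = degree,
                                    family = "gaussian", control = ctl)),
      error = function(e) NULL)
  })
  gcv <- vapply(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    rss <- sum(stats::residuals(f)^2)
    n * rss / (n - f$trace.hat)^2
  }, numeric(1))
  if (all(is.na(gcv))) stop("no span in the grid yields a valid fit")
  if (anyNA(gcv)) {
    warning("span floor raised: spans ",
            paste(span_grid[is.na(gcv)], collapse = ", "),
            " leave too few points for the local fit")
  }
  best <- which.min(gcv)
  list(span = span_grid[best], degree = degree,
       fitted = stats::fitted(fits[[best]]), gcv = gcv[best],
       gcv_table = tibble::tibble(span = span_grid, gcv = gcv))
}

#' Sampling-effort regression check
#'
#' Ordinary least-squares regression of the number of lineages detected per
#' site on the number of hybrid individuals sampled; a small R-squared and a
#' non-significant slope indicate lineage counts are not an artifact of
#' uneven sampling effort.
#'
#' @param lineage_counts Lineages detected per site.
#' @param sample_sizes Hybrid individuals sampled per site (same length).
#' @return A list with `r2`, `p` (slope test), `slope` and `n`.
#' @export
sampling_effort_check <- function(lineage_counts, sample_sizes) {
  if (length(lineage_counts) != length(sample_sizes)) {
    stop("inputs must be paired")
  }
  if (length(lineage_counts) < 3) stop("need at least 3 sites")
  if (stats::sd(lineage_counts) == 0) {
    # a constant response carries no effort signal; lm would return
    # numerical noise for the 0/0 coefficient of determination
    return(list(r2 = 0, p = 1, slope = 0, n = length(lineage_counts)))
  }
  fit <- summary(stats::lm(lineage_counts ~ sample_sizes))
  list(r2 = fit$r.squared, p = fit$coefficients[2, 4],
       slope = fit$coefficients[2, 1], n = length(lineage_counts))
}

#' Full statistical report for a survey summary
#'
#' Runs the whole battery on a per-site survey summary (as returned by
#' [load_table1_summary()] or assembled from a genotype-level pipeline):
#' occupancy evenness per biotype (Fisher), abundance contrasts (Yates
#' chi-square), southern-categories diversity contrast (proportional
#' goodness-of-fit, with and without the high-diversity outlier site),
#' south-vs-north Mann-Whitney, the LOESS diversity-latitude fit and the
#' sampling-effort check.
#'
#' @param summary A survey-summary tibble (needs `lat`, `lgs_category`,
#'   `n_eos`, `n_hyb`, `n_neo`, `n_private`, `shared_lineages`).
#' @param outlier_site Site excluded in the secondary diversity contrast
#'   (default `"CH-4"`; set `NULL` to skip).
#' @return A nested list of results, suitable for JSON serialization.
#' @export
survey_statistics <- function(summary, outlier_site = "CH-4") {
  occ <- lapply(c(EOS = "EOS", HYB = "HYB", NEO = "NEO"), function(b) {
    tab <- occupancy_by_category(summary, b)
    m <- as.matrix(tab[, c("occupied", "unoccupied")])
    list(table = tab, fisher_p = fisher_exact_rx2(m),
         n_occupied = sum(tab$occupied))
  })
  n_sites <- nrow(summary)
  yates_eos_vs_neo <- chisq_yates_2x2(rbind(
    c(occ$EOS$n_occupied, n_sites - occ$EOS$n_occupied),
    c(occ$NEO$n_occupied, n_sites - occ$NEO$n_occupied)))
  yates_eos_vs_hyb <- chisq_yates_2x2(rbind(
    c(occ$EOS$n_occupied, n_sites - occ$EOS$n_occupied),
    c(occ$HYB$n_occupied, n_sites - occ$HYB$n_occupied)))
  div <- diversity_by_category(summary)
  gof_south <- chisq_gof_proportional(div$n_private[1:2], div$n_sites[1:2])
  gof_south_no_outlier <- NULL
  if (!is.null(outlier_site) && outlier_site %in% summary$site_id) {
    trimmed <- summary[summary$site_id != outlier_site, , drop = FALSE]
    div2 <- diversity_by_category(trimmed)
    gof_south_no_outlier <- chisq_gof_proportional(div2$n_private[1:2],
                                                   div2$n_sites[1:2])
  }
  southern <- summary$lgs_category %in% lgs_levels()[1:2]
  mw <- mann_whitney_u(summary$n_private[southern],
                       summary$n_private[!southern])
  lo <- loess_gcv(summary$lat, summary$n_private)
  hyb_sites <- summary$n_hyb > 0
  effort <- sampling_effort_check(
    summary$n_private[hyb_sites] + lengths(summary$shared_lineages[hyb_sites]),
    summary$n_hyb[hyb_sites])
  list(
    occupancy = occ,
    abundance_eos_vs_neo = yates_eos_vs_neo,
    abundance_eos_vs_hyb = yates_eos_vs_hyb,
    diversity = div,
    diversity_gof_south = gof_south,
    diversity_gof_south_no_outlier = gof_south_no_outlier,
    south_vs_north_mw = mw,
    loess = lo[c("span", "degree", "gcv")],
    sampling_effort = effort
  )
}
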