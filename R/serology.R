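# ELISA calibration, cutoffs, positivity classification, and the
# correlation analyses (overall and two-regime split).

#' Fit a linear ELISA calibration
#'
#' Least-squares line through calibrator points (OD, assigned units). With
#' two calibrators this is the exact interpolating line; with more,
#' ordinary least squares.
#'
#' @param od calibrator optical densities (strictly increasing, length >= 2).
#' @param units assigned units for each calibrator.
#' @return object of class `"elisa_calibration"` with `slope`, `intercept`
#'   and the calibrator points.
#' @export
elisa_calibration <- function(od, units) {
  if (length(od) < 2L || length(od) != length(units)) {
    pz_stop("uncalibrated_assay", "need >= 2 calibrator (OD, units) points")
  }
  if (is.unsorted(od, strictly = TRUE)) {
    pz_stop("uncalibrated_assay", "calibrator ODs must be strictly increasing")
  }
  fit <- stats::lm(units ~ od)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 od = od, units = units),
            class = "elisa_calibration")
}

#' Convert optical densities to units
#'
#' Applies the fitted calibration line; results are clamped at 0 so
#' readings at or below the blank map to 0 units.
#'
#' @param od sample optical densities.
#' @param cal an [elisa_calibration()].
#' @return numeric units, same length as `od`.
#' @examples
#' cal <- elisa_calibration(c(0.05, 1.05), c(0, 100))
#' od_to_units(0.55, cal)  # 50
#' @export
od_to_units <- function(od, cal) {
  if (!inherits(cal, "elisa_calibration")) {
    pz_stop("uncalibrated_assay", "cal must be an elisa_calibration")
  }
  pmax(0, cal$intercept + cal$slope * od)
}

#' Percentile cutoff from a healthy reference population
#'
#' Empirical quantile (linear interpolation between order statistics,
#' [stats::quantile()] type 7) of reference-population antibody levels;
#' the conventional 99th percentile by default.
#'
#' @param values reference units (length >= 20).
#' @param q quantile (default 0.99).
#' @return cutoff in units.
#' @export
percentile_cutoff <- function(values, q = 0.99) {
  if (length(values) < 20L) {
    pz_stop("too_few_reference", "need >= 20 reference values")
  }
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Default assay positivity cutoffs (units)
#'
#' 99th-percentile-derived cutoffs: 20 U for IgA anti-B2GP1 (and IgA
#' anticardiolipin), 23.8 U for IgA anti-D1, 22 U for IgA anti-D4/5, and
#' 18 U for the IgG/IgM assays.
#'
#' @param ... named cutoffs overriding or extending the defaults.
#' @return named numeric vector.
#' @export
cutoff_set <- function(...) {
  cuts <- c(anti_b2gp1_iga = 20, anti_d1_iga = 23.8, anti_d4_5_iga = 22,
            anti_b2gp1_igg = 18, anti_b2gp1_igm = 18,
            acl_igg = 18, acl_igm = 18)
  over <- c(...)
  if (length(over)) cuts[names(over)] <- over
  if (any(cuts <= 0)) pz_stop("bad_config", "cutoffs must be positive")
  cuts
}

#' Classify serum positivity against assay cutoffs
#'
#' A serum is positive for an assay when its level is strictly greater than
#' the assay cutoff ("higher than" the cutoff).
#'
#' @param panel data.frame with `id`, optional `group`, and one numeric
#'   column per assay, in units.
#' @param cutoffs named cutoffs as from [cutoff_set()]; every assay column
#'   to classify must have a cutoff.
#' @return data.frame of logical flags (one column per classified assay)
#'   keyed by `id`.
#' @export
classify_positivity <- function(panel, cutoffs = cutoff_set()) {
  assays <- intersect(names(cutoffs), names(panel))
  if (!length(assays)) {
    pz_stop("missing_assay", "panel has no column matching a cutoff name")
  }
  out <- data.frame(id = panel$id)
  for (a in assays) out[[a]] <- panel[[a]] > cutoffs[[a]]
  out
}

hinkle_label <- function(r) {
  a <- abs(r)
  if (a < 0.3) "negligible" else if (a < 0.5) "low" else if (a < 0.7)
    "moderate" else if (a < 0.9) "high" else "very high"
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson's r with two-sided p-value and a confidence interval from the
#' Fisher z-transform (`atanh(r) +/- z * 1/sqrt(n-3)`), plus a Hinkle
#' rule-of-thumb strength label.
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @param conf confidence level (default 0.95).
#' @return object of class `"correlation_result"`: `r`, `ci`, `p`, `n`,
#'   `label`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) pz_stop("constant_input", "need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pz_stop("constant_input", "constant input vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  structure(list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
                 p = ct$p.value, n = length(x), conf = conf,
                 label = hinkle_label(unname(ct$estimate))),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R = %.3f (%g%% CI: %.3f to %.3f; p = %.3g; n = %d) [%s]\n",
              x$r, 100 * x$conf, x$ci[1], x$ci[2], x$p, x$n, x$label))
  invisible(x)
}

#' Two-regime correlation split
#'
#' Operationalizes the visual two-pattern reading of a scatter (a strongly
#' correlated majority plus a low-response subgroup with no correlation):
#' a deterministic grid search over horizontal boundaries `y = c`, with
#' candidate `c` at each observed `y` value. Sera with `y <= c` form group
#' B ("low"), the rest group A; the boundary maximizing `|r_A - r_B|`
#' subject to both groups containing at least `min_frac * n` sera is
#' selected (ties -> lowest boundary). The split is a heuristic and is
#' labelled as such; when the achieved `|r_A - r_B|` falls below `margin`
#' it is flagged non-informative.
#'
#' @param x,y numeric vectors (n >= 20).
#' @param min_frac minimum fraction of sera per group (default 0.15).
#' @param margin `|r_A - r_B|` below which the split is flagged
#'   non-informative (default 0.3).
#' @return object of class `"split_correlation"`: `boundary`, `group`
#'   (factor "A"/"B" per serum), `r_A`, `r_B` ([pearson_ci()] results),
#'   `delta`, `informative`.
#' @export
split_correlation <- function(x, y, min_frac = 0.15, margin = 0.3) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 20L) pz_stop("no_feasible_split", "need n >= 20")
  min_n <- ceiling(min_frac * n)
  cand <- sort(unique(y))
  best <- NULL
  for (c0 in cand) {
    low <- y <= c0
    n_b <- sum(low)
    if (n_b < min_n || n - n_b < min_n) next
    if (stats::sd(x[low]) == 0 || stats::sd(y[low]) == 0 ||
        stats::sd(x[!low]) == 0 || stats::sd(y[!low]) == 0) next
    d <- abs(stats::cor(x[!low], y[!low]) - stats::cor(x[low], y[low]))
    if (is.null(best) || d > best$delta + 1e-12) {
      best <- list(boundary = c0, delta = d)
    }
  }
  if (is.null(best)) {
    pz_stop("no_feasible_split",
            "no boundary leaves both groups above the minimum size")
  }
  low <- y <= best$boundary
  res <- list(
    boundary = best$boundary,
    group = factor(ifelse(low, "B", "A"), levels = c("A", "B")),
    r_A = pearson_ci(x[!low], y[!low]),
    r_B = pearson_ci(x[low], y[low]),
    delta = best$delta,
    informative = best$delta >= margin,
    margin = margin
  )
  class(res) <- "split_correlation"
  res
}

#' @export
print.split_correlation <- function(x, ...) {
  cat(sprintf("heuristic two-regime split at y <= %.4g (%s)\n", x$boundary,
              if (x$informative) "informative" else "non-informative"))
  cat(sprintf("  group A (n=%d): r = %.3f\n", x$r_A$n, x$r_A$r))
  cat(sprintf("  group B (n=%d): r = %.3f\n", x$r_B$n, x$r_B$r))
  cat(sprintf("  |r_A - r_B| = %.3f (margin %.2f)\n", x$delta, x$margin))
  invisible(x)
}

#' Compare two groups (categorical or scaled)
#'
#' For a 2x2 (or r x c) contingency table: Pearson's chi-squared test,
#' replaced by Fisher's exact test when any expected cell count is 5 or
#' less. For two numeric samples: Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param a either a contingency table/matrix, or the first numeric sample.
#' @param b the second numeric sample (ignored for tables).
#' @return list `method`, `statistic` (NA for Fisher), `p`.
#' @export
group_compare <- function(a, b = NULL) {
  if (is.matrix(a) || is.table(a)) {
    tab <- as.matrix(a)
    if (any(dim(tab) < 2L) || any(tab < 0) || sum(tab) == 0) {
      pz_stop("degenerate_table", "need a non-degenerate r x c table")
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 5)) {
      ft <- stats::fisher.test(tab)
      return(list(method = "fisher", statistic = NA_real_, p = ft$p.value))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(method = "chisq", statistic = unname(ct$statistic), p = ct$p.value))
  }
  if (is.null(b)) pz_stop("degenerate_table", "need a table or two samples")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(method = "mann-whitney", statistic = unname(wt$statistic), p = wt$p.value)
}

#' Read an ELISA panel TSV
#'
#' @param path TSV with columns `id`, optional `group`, and numeric assay
#'   columns in units (or OD, to be converted with [od_to_units()]).
#' @export
read_elisa_tsv <- function(path) {
  df <- pz_read_tsv(path)
  if (!"id" %in% names(df)) pz_stop("bad_table", "ELISA panel needs an id column")
  num <- setdiff(names(df), c("id", "group"))
  if (any(vapply(df[num], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    pz_stop("bad_table", "negative assay values")
  }
  df
}
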