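#' Assay quantification
#'
#' Quantifies the wet-lab validation readouts of the screen: fluorescence
#' tubulin-polymerization time courses (normalized to a paclitaxel
#' reference, summarized by Vmax and the maximum end-point MEP, compared to
#' a DMSO control by fold changes), microtubule-phenotype abnormality
#' scores, depolymerization-challenge state proportions, and compound
#' potency: EC50 on the proliferation rate (log-linear interpolation of
#' per-dose growth slopes) and EC50 on cell death at a fixed time
#' (four-parameter logistic fit).
#'
#' @name assay_analysis
NULL

#' Normalize polymerization curves to a reference condition
#'
#' The reference (paclitaxel-like) final reading maps to 100% and the
#' lowest reading across all curves of the run maps to 0%:
#' `norm(t) = 100 (F(t) - Fmin) / (Fref(t_end) - Fmin)`.
#'
#' @param curves Data frame with columns `time_min`, `condition`,
#'   `reading_au`.
#' @param tax_reference Condition label of the reference curve.
#' @return The input with a `value_pct` column added.
#' @export
normalize_polymerization <- function(curves, tax_reference = "TAX") {
  stopifnot(all(c("time_min", "condition", "reading_au") %in%
                  names(curves)))
  if (!tax_reference %in% curves$condition) {
    stop("reference condition '", tax_reference, "' not present",
         call. = FALSE)
  }
  fmin <- min(curves$reading_au)
  ref <- curves[curves$condition == tax_reference, , drop = FALSE]
  fref_end <- ref$reading_au[which.max(ref$time_min)]
  denom <- fref_end - fmin
  if (denom <= 0) {
    stop("degenerate normalization: reference final reading equals the ",
         "run minimum", call. = FALSE)
  }
  curves$value_pct <- 100 * (curves$reading_au - fmin) / denom
  curves
}

#' Vmax and maximum end-point of a normalized curve
#'
#' Vmax is the steepest least-squares slope over any window of `window`
#' consecutive points (%/min); MEP is the normalized value at the final
#' time point.
#'
#' @param times Time points (minutes, strictly increasing).
#' @param values Normalized readings (%).
#' @param window Number of consecutive points per slope window (default 3).
#' @return List with `vmax` and `mep`.
#' @export
curve_stats <- function(times, values, window = 3L) {
  n <- length(times)
  stopifnot(n == length(values), window >= 2L)
  if (n < window) {
    stop("need at least ", window, " points, got ", n, call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- times[idx]
    vv <- values[idx]
    sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  list(vmax = max(slopes), mep = values[n])
}

#' Fold changes of curve statistics versus the DMSO control
#'
#' `fc = stat / dmso_stat` for Vmax and MEP. Classification relative to the
#' threshold (default 1): `"enhancer"` when both fold changes exceed it,
#' `"suppressor"` when both fall below, otherwise `"mixed"`.
#'
#' @param stats,dmso Lists with `vmax` and `mep` (see [curve_stats()]).
#' @param threshold Effect threshold on the fold changes.
#' @return List with `fc_vmax`, `fc_mep`, `classification`.
#' @export
fold_changes <- function(stats, dmso, threshold = 1) {
  if (dmso$vmax == 0 || dmso$mep == 0) {
    stop("DMSO statistic is zero; fold change undefined", call. = FALSE)
  }
  fc_v <- stats$vmax / dmso$vmax
  fc_m <- stats$mep / dmso$mep
  cls <- if (fc_v > threshold && fc_m > threshold) "enhancer"
         else if (fc_v < threshold && fc_m < threshold) "suppressor"
         else "mixed"
  list(fc_vmax = fc_v, fc_mep = fc_m, classification = cls)
}

#' Microtubule abnormality score
#'
#' Total abnormality count over all categories divided by the number of
#' cells scored; a cell may contribute to several categories, so scores
#' above 1 are possible.
#'
#' @param counts Numeric vector of per-category abnormality counts.
#' @param n_cells Number of cells scored.
#' @return Abnormalities per cell.
#' @export
phenotype_score <- function(counts, n_cells) {
  stopifnot(all(counts >= 0))
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  sum(counts) / n_cells
}

#' Proportions of polymerized vs soluble microtubule states
#'
#' @param n_polymerized Cells with polymerized microtubules.
#' @param n_total Total cells scored.
#' @return Named vector `(polymerized, soluble)` summing to 1.
#' @export
polymer_state_proportions <- function(n_polymerized, n_total) {
  if (n_total <= 0 || n_polymerized < 0 || n_polymerized > n_total) {
    stop("need 0 <= n_polymerized <= n_total with n_total > 0",
         call. = FALSE)
  }
  p <- n_polymerized / n_total
  c(polymerized = p, soluble = 1 - p)
}

not_assigned <- function(reason) {
  list(ec50 = NA_real_, assigned = FALSE, reason = reason)
}

#' EC50 on the proliferation rate
#'
#' Fits a least-squares growth slope per concentration, targets half the
#' vehicle slope, and interpolates the crossing concentration linearly in
#' log10 concentration between the bracketing doses. Returns an explicit
#' not-assigned state when no bracketing pair exists or the vehicle slope
#' is non-positive.
#'
#' @param series Data frame with columns `time_h`, `concentration_um`,
#'   `confluence_pct` (treated wells, >= 2 concentrations).
#' @param vehicle Data frame with `time_h`, `confluence_pct` (vehicle
#'   wells).
#' @return List with `ec50` (uM or `NA`), `assigned`, `reason` (when not
#'   assigned), `slopes` (per-dose) and `vehicle_slope`.
#' @export
growth_ec50 <- function(series, vehicle) {
  fit_slope <- function(t, y) {
    if (length(t) < 2L) return(NA_real_)
    unname(coef(lm(y ~ t))[2])
  }
  v_slope <- fit_slope(vehicle$time_h, vehicle$confluence_pct)
  doses <- sort(unique(series$concentration_um))
  if (length(doses) < 2L) {
    stop("need at least 2 concentrations", call. = FALSE)
  }
  slopes <- vapply(doses, function(d) {
    sub <- series[series$concentration_um == d, , drop = FALSE]
    fit_slope(sub$time_h, sub$confluence_pct)
  }, numeric(1))
  base <- list(slopes = setNames(slopes, doses), vehicle_slope = v_slope)
  if (!is.finite(v_slope) || v_slope <= 0) {
    return(c(not_assigned("non-positive vehicle growth slope"), base))
  }
  target <- 0.5 * v_slope
  ec50 <- NA_real_
  for (i in seq_len(length(doses) - 1L)) {
    s1 <- slopes[i]; s2 <- slopes[i + 1L]
    if (is.finite(s1) && is.finite(s2) && s1 >= target && s2 < target) {
      frac <- (s1 - target) / (s1 - s2)
      lc <- log10(doses[i]) + frac * (log10(doses[i + 1L]) - log10(doses[i]))
      ec50 <- 10^lc
      break
    }
  }
  if (!is.finite(ec50)) {
    return(c(not_assigned("no dose pair brackets the half-vehicle slope"),
             base))
  }
  c(list(ec50 = unname(ec50), assigned = TRUE, reason = NULL), base)
}

# 4PL response on log10 concentration:
# y = floor + (ceiling - floor) / (1 + 10^(hill * (log_ec50 - x)))
fourpl <- function(x, floor., ceiling., log_ec50, hill) {
  floor. + (ceiling. - floor.) / (1 + 10^(hill * (log_ec50 - x)))
}

#' EC50 on cell death at a fixed time
#'
#' Four-parameter logistic fit of the dead-cell fraction against log10
#' concentration (floor constrained >= 0); the EC50 is the fitted midpoint.
#' Returns an explicit not-assigned state with fewer than 4 concentrations,
#' on non-convergence, or when the fitted response span (ceiling - floor)
#' is below 10% of the admissible response range (i.e. < 0.1 on the
#' fraction scale), indicating an effectively flat dose response.
#'
#' @param doses Concentrations (uM; > 0).
#' @param dead_fraction Responses in `[0, 1]`, same length as `doses`
#'   (replicates allowed as repeated doses).
#' @return List with `ec50` (uM or `NA`), `assigned`, `reason`, and `fit`
#'   diagnostics (parameters, residual standard error) when fitted.
#' @export
death_ec50 <- function(doses, dead_fraction) {
  stopifnot(length(doses) == length(dead_fraction), all(doses > 0))
  if (length(unique(doses)) < 4L) {
    return(not_assigned("fewer than 4 concentrations"))
  }
  x <- log10(doses)
  y <- dead_fraction
  start <- list(floor. = max(min(y), 0), ceiling. = max(y),
                log_ec50 = median(x), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fourpl(x, floor., ceiling., log_ec50, hill),
      start = start,
      lower = c(floor. = 0, ceiling. = 0, log_ec50 = min(x) - 3,
                hill = 0.05),
      upper = c(floor. = 1, ceiling. = 1.5, log_ec50 = max(x) + 3,
                hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(not_assigned("sigmoidal fit did not converge"))
  p <- coef(fit)
  span <- p[["ceiling."]] - p[["floor."]]
  if (span < 0.1) {
    return(not_assigned("fitted response span below 10% of range"))
  }
  list(
    ec50 = unname(10^p[["log_ec50"]]),
    assigned = TRUE,
    reason = NULL,
    fit = list(parameters = p,
               sigma = tryCatch(summary(fit)$sigma, error = function(e) NA))
  )
}

#' Summarize a polymerization run into a per-condition table
#'
#' Convenience wrapper: normalize, compute per-condition curve statistics
#' and fold changes against the DMSO control.
#'
#' @param curves Long data frame (`time_min`, `condition`, `reading_au`).
#' @param tax_reference Reference condition label (maps to 100%).
#' @param dmso_label Control condition label.
#' @param window Vmax window (points).
#' @return Data frame (condition, vmax, mep, fc_vmax, fc_mep,
#'   classification).
#' @export
polymerization_table <- function(curves, tax_reference = "TAX",
                                 dmso_label = "DMSO", window = 3L) {
  norm <- normalize_polymerization(curves, tax_reference)
  conds <- unique(norm$condition)
  stats <- lapply(conds, function(cd) {
    sub <- norm[norm$condition == cd, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    curve_stats(sub$time_min, sub$value_pct, window = window)
  })
  names(stats) <- conds
  if (!dmso_label %in% conds) {
    stop("DMSO control '", dmso_label, "' not present", call. = FALSE)
  }
  dmso <- stats[[dmso_label]]
  rows <- lapply(conds, function(cd) {
    fc <- fold_changes(stats[[cd]], dmso)
    data.frame(condition = cd, vmax = stats[[cd]]$vmax,
               mep = stats[[cd]]$mep, fc_vmax = fc$fc_vmax,
               fc_mep = fc$fc_mep, classification = fc$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
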