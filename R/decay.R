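#' Relative abundance from a qPCR decay series
#'
#' Replicate Cq values are averaged per timepoint (averaging Cq is
#' averaging on the log-abundance scale) and converted to abundance
#' relative to t = 0: R(t) = E^-(Cq(t) - Cq(0)), so R(0) = 1 by
#' construction.
#'
#' @param s a [decay_series()].
#' @return data.frame with columns `time` and `R`.
#' @export
relative_abundance <- function(s) {
  stopifnot(inherits(s, "decay_series"))
  mcq <- colMeans(s$cq)
  data.frame(time = s$times, R = s$efficiency^(-(mcq - mcq[1])))
}

#' Fit an mRNA half-life to an inhibitor time course
#'
#' In `"abundance"` mode (default) the natural log of the
#' efficiency-adjusted relative abundance is regressed on time through the
#' origin, ln R(t) = -slope * t, which for exponential decay recovers the
#' decay rate exactly. In `"literal"` mode the classical transform
#' y(t) = ln(Cq(t)/Cq(0)) * (-10) is regressed on time (with intercept) and
#' the slope sign-flipped to a positive decay rate. Either way the
#' half-life is t1/2 = ln(2) / slope; a non-positive slope yields an
#' infinite half-life with a warning flag rather than an error.
#'
#' @param s a [decay_series()].
#' @param mode `"abundance"` or `"literal"`.
#' @return object of class `decay_fit`: `slope` (1/min), `slope_se`,
#'   `t_half` (min), `mode`, `gene_id`, `temperature`, `warn_nonpositive`.
#' @export
fit_half_life <- function(s, mode = c("abundance", "literal")) {
  stopifnot(inherits(s, "decay_series"))
  mode <- match.arg(mode)
  t <- s$times
  if (length(t) < 3) stop("fit_half_life: need >= 3 timepoints")
  mcq <- colMeans(s$cq)
  if (mode == "abundance") {
    y <- -(mcq - mcq[1]) * log(s$efficiency)  # ln R(t)
    slope <- -sum(t * y) / sum(t^2)           # through the origin
    res <- y + slope * t
    slope_se <- sqrt(sum(res^2) / (length(t) - 1)) / sqrt(sum(t^2))
  } else {
    if (any(mcq <= 0)) stop("fit_half_life: literal mode needs positive Cq")
    y <- log(mcq / mcq[1]) * (-10)
    fit <- stats::lm(y ~ t)
    slope <- -unname(stats::coef(fit)[2])
    slope_se <- unname(summary(fit)$coefficients[2, 2])
  }
  warn <- slope <= 0
  t_half <- if (warn) Inf else log(2) / slope
  structure(list(slope = slope, slope_se = slope_se, t_half = t_half,
                 mode = mode, gene_id = s$gene_id,
                 temperature = s$temperature, warn_nonpositive = warn),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s at %g degC [%s]: slope %.4g/min (se %.3g), t1/2 %s min%s\n",
              x$gene_id, x$temperature, x$mode, x$slope, x$slope_se,
              if (is.finite(x$t_half)) sprintf("%.2f", x$t_half) else "Inf",
              if (x$warn_nonpositive) " (non-positive slope)" else ""))
  invisible(x)
}

#' @method coef decay_fit
#' @export
coef.decay_fit <- function(object, ...) {
  c(slope = object$slope, t_half = object$t_half)
}

#' Compare transcript stability between 22 and 4 degC
#'
#' Student's (equal-variance) two-sample t-test on per-replicate decay
#' slopes; reports the half-life difference computed from the group mean
#' slopes alongside the p-value.
#'
#' @param fits_22,fits_4 lists of [fit_half_life()] objects, one per
#'   biological replicate, at each temperature; at least 2 each.
#' @param var_equal equal-variance (Student's) test by default; set FALSE
#'   for Welch.
#' @return list of class `stability_comparison`: mean slopes, half-lives
#'   from mean slopes, `delta_t_half` (4 degC minus 22 degC), `t`, `df`,
#'   `p`.
#' @export
compare_stability <- function(fits_22, fits_4, var_equal = TRUE) {
  s22 <- vapply(fits_22, function(f) f$slope, numeric(1))
  s4 <- vapply(fits_4, function(f) f$slope, numeric(1))
  if (length(s22) < 2 || length(s4) < 2)
    stop("compare_stability: need >= 2 replicate fits per temperature")
  tt <- stats::t.test(s4, s22, var.equal = var_equal)
  th <- function(sl) if (mean(sl) > 0) log(2) / mean(sl) else Inf
  structure(list(mean_slope_22 = mean(s22), mean_slope_4 = mean(s4),
                 t_half_22 = th(s22), t_half_4 = th(s4),
                 delta_t_half = th(s4) - th(s22),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("<stability_comparison> t1/2 22C %.1f min vs 4C %.1f min (delta %.1f), t=%.3g, p=%.3g\n",
              x$t_half_22, x$t_half_4, x$delta_t_half, x$t, x$p))
  invisible(x)
}

#' Delta-delta-Cq fold change between conditions
#'
#' Per replicate, deltaCq = Cq(target) - Cq(reference); the
#' delta-delta-Cq is the mean treated deltaCq minus the mean control
#' deltaCq, and the fold change E^-(ddCq), adjusted to the primer
#' efficiency E. Significance is a Student's t-test on the replicate
#' deltaCq values.
#'
#' @param q data.frame with columns `condition`, `cq_target`,
#'   `cq_reference` (one row per replicate).
#' @param control control condition label.
#' @param treatment treated condition label; defaults to the single other
#'   condition present.
#' @param efficiency amplification factor per cycle.
#' @param var_equal Student's (TRUE) vs Welch (FALSE) t-test.
#' @return list with `ddcq`, `fold`, `p`, and per-group mean deltaCq.
#' @export
ddcq_fold_change <- function(q, control, treatment = NULL, efficiency = 2,
                             var_equal = TRUE) {
  stopifnot(all(c("condition", "cq_target", "cq_reference") %in% names(q)))
  if (is.null(treatment)) {
    others <- setdiff(unique(q$condition), control)
    if (length(others) != 1)
      stop("ddcq_fold_change: specify `treatment` (found ",
           length(others), " non-control conditions)")
    treatment <- others
  }
  dcq <- q$cq_target - q$cq_reference
  dc <- dcq[q$condition == control]
  dt <- dcq[q$condition == treatment]
  if (length(dc) < 2 || length(dt) < 2)
    stop("ddcq_fold_change: need >= 2 replicates per condition")
  ddcq <- mean(dt) - mean(dc)
  p <- if (stats::sd(dc) == 0 && stats::sd(dt) == 0) {
    if (ddcq == 0) 1 else 0   # degenerate noise-free input
  } else stats::t.test(dt, dc, var.equal = var_equal)$p.value
  list(ddcq = ddcq, fold = efficiency^(-ddcq), p = p,
       mean_dcq_control = mean(dc), mean_dcq_treatment = mean(dt))
}
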