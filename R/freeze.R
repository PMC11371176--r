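#' Percent electrolyte leakage
#'
#' Leakage is the conductivity measured before flash freezing as a
#' percentage of the total conductivity after flash freezing:
#' 100 * before / after. Values outside [0, 100] (before > after) are
#' clamped and flagged via the `clamped` attribute.
#'
#' @param cond_before,cond_after conductivities (arbitrary units);
#'   `cond_after` must be > 0.
#' @return numeric vector of percentages with a logical `clamped`
#'   attribute.
#' @export
electrolyte_leakage <- function(cond_before, cond_after) {
  if (any(cond_after <= 0)) stop("electrolyte_leakage: cond_after must be > 0")
  raw <- 100 * cond_before / cond_after
  out <- pmin(100, pmax(0, raw))
  attr(out, "clamped") <- raw != out
  if (any(raw != out))
    warning("electrolyte_leakage: ", sum(raw != out),
            " value(s) outside [0, 100] clamped")
  out
}

# One nlsLM attempt; returns NULL on failure.
try_4pl <- function(df, start, lower, upper) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      el ~ bottom + (top - bottom) / (1 + exp(hill * (temperature - lt50))),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  fit
}

#' Fit a four-parameter logistic LT50 curve to leakage data
#'
#' Least-squares fit of
#' EL(T) = bottom + (top - bottom) / (1 + exp(hill * (T - lt50)))
#' with hill > 0, so leakage rises as temperature falls. Initialisation is
#' multi-start: a data-driven guess (asymptotes from the data extremes,
#' midpoint from interpolation) followed by a grid of lt50 starts over
#' -2 .. -10 degC; the converged fit with the lowest residual sum of
#' squares wins. `lt50` is the curve inflection; `el50_abs` is the
#' temperature where the fitted curve crosses 50% absolute leakage (the
#' dashed-line threshold of leakage figures), which coincides with `lt50`
#' when the asymptotes are symmetric about 50.
#'
#' @param data data.frame with columns `temperature` and `el_percent` (or
#'   `cond_before`/`cond_after`, converted via [electrolyte_leakage()]).
#' @param constraints optional list with `lower`/`upper` named vectors over
#'   `bottom`, `top`, `hill`, `lt50` (e.g. to bound the asymptotes in
#'   [0, 100]); by default only hill > 0 is enforced.
#' @param lt50_grid extra lt50 starting values.
#' @param extra_starts optional list of full start vectors tried as well.
#' @return object of class `lt50_fit` with `coefficients` (bottom, top,
#'   lt50, hill), `el50_abs`, `rss`, `df_residual`, `n`, `fitted`, `data`.
#' @export
fit_lt50 <- function(data, constraints = NULL, lt50_grid = seq(-2, -10),
                     extra_starts = NULL) {
  if (!("el_percent" %in% names(data))) {
    if (all(c("cond_before", "cond_after") %in% names(data))) {
      data$el_percent <- as.numeric(
        electrolyte_leakage(data$cond_before, data$cond_after))
    } else stop("fit_lt50: need el_percent or cond_before/cond_after columns")
  }
  if (length(unique(data$temperature)) < 5)
    stop("fit_lt50: need >= 5 distinct temperatures")
  df <- data.frame(temperature = data$temperature, el = data$el_percent)
  lower <- c(bottom = -Inf, top = -Inf, hill = 1e-6, lt50 = -Inf)
  upper <- c(bottom = Inf, top = Inf, hill = Inf, lt50 = Inf)
  if (!is.null(constraints)) {
    if (!is.null(constraints$lower)) lower[names(constraints$lower)] <- constraints$lower
    if (!is.null(constraints$upper)) upper[names(constraints$upper)] <- constraints$upper
  }
  b0 <- max(min(df$el), lower["bottom"])
  t0 <- min(max(df$el), upper["top"])
  if (t0 <= b0) { b0 <- lower["bottom"]; t0 <- upper["top"] }
  # data-driven lt50 guess: temperature whose mean leakage is nearest midmost
  agg <- stats::aggregate(el ~ temperature, df, mean)
  mid0 <- agg$temperature[which.min(abs(agg$el - (b0 + t0) / 2))]
  starts <- c(
    list(c(bottom = unname(b0), top = unname(t0), hill = 1, lt50 = mid0)),
    lapply(lt50_grid, function(g)
      c(bottom = unname(b0), top = unname(t0), hill = 1, lt50 = g)),
    extra_starts
  )
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    fit <- try_4pl(df, as.list(st), lower, upper)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss - 1e-12) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("fit_lt50: no start converged (", length(starts), " starts tried); ",
         "check that leakage spans a sigmoid over the temperature range")
  cf <- stats::coef(best)
  el50 <- if (cf["bottom"] < 50 && cf["top"] > 50) {
    unname(cf["lt50"] + log((cf["top"] - cf["bottom"]) / (50 - cf["bottom"]) - 1) / cf["hill"])
  } else NA_real_
  structure(list(coefficients = cf[c("bottom", "top", "lt50", "hill")],
                 el50_abs = el50, rss = best_rss,
                 df_residual = nrow(df) - 4L, n = nrow(df),
                 fitted = stats::fitted(best), data = df),
            class = "lt50_fit")
}

#' @export
print.lt50_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<lt50_fit> LT50 %.2f degC (EL=50%% at %s degC); bottom %.1f%%, top %.1f%%, hill %.2f; RSS %.3g on %d df\n",
              cf["lt50"],
              if (is.na(x$el50_abs)) "NA" else sprintf("%.2f", x$el50_abs),
              cf["bottom"], cf["top"], cf["hill"], x$rss, x$df_residual))
  invisible(x)
}

#' @method coef lt50_fit
#' @export
coef.lt50_fit <- function(object, ...) object$coefficients

#' @method predict lt50_fit
#' @export
predict.lt50_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  cf <- object$coefficients
  logistic_el(temp, cf["bottom"], cf["top"], cf["lt50"], cf["hill"])
}

#' @method plot lt50_fit
#' @export
plot.lt50_fit <- function(x, ...) {
  graphics::plot(x$data$temperature, x$data$el, xlab = "temperature (degC)",
                 ylab = "electrolyte leakage (%)", ...)
  tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(temperature = tt)))
  graphics::abline(h = 50, lty = 2)
  invisible(x)
}

#' Extra sum-of-squares F-test between two leakage curves
#'
#' Compares the null model (one shared four-parameter logistic for the
#' pooled data, N - 4 residual df) against the alternative of separate
#' curves per genotype (N - 8 df):
#' F = ((RSS_shared - RSS_separate) / 4) / (RSS_separate / (N - 8)),
#' with the p-value from the F(4, N - 8) distribution. Starting values are
#' cross-seeded between the shared and separate fits so the nesting
#' RSS_shared >= RSS_separate holds.
#'
#' @param a,b data.frames of leakage measurements for the two genotypes
#'   (as accepted by [fit_lt50()]).
#' @param constraints passed on to [fit_lt50()].
#' @return list of class `lt50_comparison`: the two fits, shared fit,
#'   `rss_shared`, `rss_separate`, `df_shared`, `df_separate`, `F`, `p`,
#'   and `delta_lt50`.
#' @export
compare_curves <- function(a, b, constraints = NULL) {
  fa <- fit_lt50(a, constraints)
  fb <- fit_lt50(b, constraints)
  pooled <- rbind(fa$data, fb$data)
  names(pooled) <- c("temperature", "el_percent")
  n <- nrow(pooled)
  if (n <= 8) stop("compare_curves: need N > 8 observations for residual df")
  shared <- fit_lt50(pooled, constraints,
                     extra_starts = list(fa$coefficients[c("bottom", "top", "hill", "lt50")],
                                         fb$coefficients[c("bottom", "top", "hill", "lt50")]))
  # re-seed the separate fits with the shared optimum so nesting holds
  fa2 <- fit_lt50(a, constraints,
                  extra_starts = list(shared$coefficients[c("bottom", "top", "hill", "lt50")]))
  fb2 <- fit_lt50(b, constraints,
                  extra_starts = list(shared$coefficients[c("bottom", "top", "hill", "lt50")]))
  if (fa2$rss < fa$rss) fa <- fa2
  if (fb2$rss < fb$rss) fb <- fb2
  rss_sep <- fa$rss + fb$rss
  df_sep <- n - 8L
  df_sh <- n - 4L
  Fstat <- max(0, ((shared$rss - rss_sep) / (df_sh - df_sep)) / (rss_sep / df_sep))
  p <- stats::pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE)
  structure(list(fit_a = fa, fit_b = fb, fit_shared = shared,
                 rss_shared = shared$rss, rss_separate = rss_sep,
                 df_shared = df_sh, df_separate = df_sep,
                 F = Fstat, p = p,
                 delta_lt50 = unname(fb$coefficients["lt50"] - fa$coefficients["lt50"])),
            class = "lt50_comparison")
}

#' Evaluate the extra sum-of-squares F statistic from fixed RSS values
#'
#' The arithmetic core of [compare_curves()], exposed for direct use:
#' F = ((rss_shared - rss_separate) / (df_shared - df_separate)) /
#' (rss_separate / df_separate), p from F(df_shared - df_separate,
#' df_separate).
#'
#' @param rss_shared,rss_separate residual sums of squares of the nested
#'   and full models.
#' @param df_shared,df_separate their residual degrees of freedom.
#' @return list with `F` and `p`.
#' @export
extra_ss_ftest <- function(rss_shared, rss_separate, df_shared, df_separate) {
  stopifnot(df_shared > df_separate, df_separate > 0)
  Fstat <- ((rss_shared - rss_separate) / (df_shared - df_separate)) /
    (rss_separate / df_separate)
  list(F = Fstat,
       p = stats::pf(Fstat, df_shared - df_separate, df_separate,
                     lower.tail = FALSE))
}

#' @export
print.lt50_comparison <- function(x, ...) {
  cat(sprintf("<lt50_comparison> LT50 %.2f vs %.2f degC (delta %.2f); F(%d,%d)=%.3g, p=%.3g\n",
              x$fit_a$coefficients["lt50"], x$fit_b$coefficients["lt50"],
              x$delta_lt50, x$df_shared - x$df_separate, x$df_separate,
              x$F, x$p))
  invisible(x)
}
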