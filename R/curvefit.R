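# Variable-slope sigmoid growth-curve fitting, QC and morphology triage.

#' Construct a growth curve
#'
#' A growth curve is one well's OD750 time series plus provenance. Times must
#' be strictly increasing and OD values non-negative and finite.
#'
#' @param times_h sampling times in hours.
#' @param od750 optical density values at 750 nm.
#' @param well,plate,condition_id,species_id,replicate provenance fields.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(times_h, od750, well = NA, plate = NA,
                         condition_id = NA, species_id = NA, replicate = NA) {
  times_h <- as.numeric(times_h)
  od750 <- as.numeric(od750)
  if (length(times_h) != length(od750)) stop("times and OD must match in length")
  if (any(!is.finite(times_h)) || is.unsorted(times_h, strictly = TRUE)) {
    stop("times must be finite and strictly increasing")
  }
  if (any(!is.finite(od750))) stop("non-finite OD750 values")
  if (any(od750 < 0)) stop("negative OD750 values")
  structure(list(times_h = times_h, od750 = od750, well = well, plate = plate,
                 condition_id = condition_id, species_id = species_id,
                 replicate = replicate),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve: %d points over %.1f h, OD750 %.3f-%.3f\n",
              length(x$times_h), diff(range(x$times_h)),
              min(x$od750), max(x$od750)))
  invisible(x)
}

#' The variable-slope (Hill) sigmoid growth model
#'
#' `Y = kt0 + (ktn - kt0) / (1 + 10^((t50 - t) * hill))`, with `kt0` the
#' baseline OD750, `ktn` the plateau, `t50` the inflection time (h) and
#' `hill` the steepness. With `log_time = TRUE` the abscissa is `log10(t)`
#' and `t50` is interpreted on that scale (the dose-response convention).
#'
#' @param t times in hours.
#' @param kt0,ktn,t50,hill model parameters.
#' @param log_time interpret the time axis on a log10 scale.
#' @return Model OD750 values.
#' @export
sigmoid_od <- function(t, kt0, ktn, t50, hill, log_time = FALSE) {
  x <- if (log_time) log10(pmax(t, .Machine$double.eps)) else t
  kt0 + (ktn - kt0) / (1 + 10^((t50 - x) * hill))
}

sigmoid_start <- function(t, y, log_time = FALSE) {
  x <- if (log_time) log10(pmax(t, .Machine$double.eps)) else t
  kt0 <- y[1L]
  ktn <- max(y)
  half <- kt0 + (ktn - kt0) / 2
  i <- which(y >= half)[1L]
  t50 <- if (is.na(i) || i == 1L) stats::median(x) else {
    # linear interpolation to the half-rise time
    x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L] + 1e-12) * (x[i] - x[i - 1L])
  }
  # max observed slope -> hill via dY/dt|t50 = (ktn - kt0) * ln(10) * hill / 4
  sl <- max(diff(y) / diff(x), na.rm = TRUE)
  hill <- 4 * sl / ((ktn - kt0 + 1e-9) * log(10))
  c(kt0 = kt0, ktn = ktn, t50 = t50, hill = max(hill, 1e-3))
}

#' Fit the variable-slope sigmoid to a growth curve
#'
#' Least-squares fit of the four-parameter sigmoid by Levenberg-Marquardt
#' with data-driven initial values and jittered multi-start. A fit is
#' labelled `"not_converged"` when the optimiser fails or the series has no
#' variance, and `"ambiguous"` when the parameters are effectively
#' unidentified (any standard error above 10x its estimate, or a gradient
#' condition number above 1e8). Only `"converged"` fits should reach the
#' growth-rate stage; [qc_filter()] enforces this together with the
#' goodness-of-fit thresholds.
#'
#' @param curve a [growth_curve()] (or anything with `times_h` and `od750`).
#' @param n_starts maximum number of jittered restarts after the data-driven
#'   start (a restart is only spent when the incumbent fit is poor).
#' @param log_time fit on a log10 time axis (see [sigmoid_od()]).
#' @param se_ratio_max,kappa_max thresholds for the `"ambiguous"` label.
#' @return Object of class `growth_fit`: coefficients (`kt0`, `ktn`, `t50`,
#'   `hill`), `r2`, `abs_ss` (raw residual sum of squares, OD^2 units),
#'   `status`, `fitted_values`, standard errors and the input curve.
#' @export
#' @examples
#' tt <- seq(0, 72, by = 3)
#' y <- sigmoid_od(tt, 0.1, 1.0, 30, 0.1)
#' fit <- fit_sigmoid(growth_curve(tt, y))
#' coef(fit)
fit_sigmoid <- function(curve, n_starts = 5L, log_time = FALSE,
                        se_ratio_max = 10, kappa_max = 1e8) {
  if (!inherits(curve, "growth_curve")) {
    curve <- growth_curve(curve$times_h, curve$od750)
  }
  t <- curve$times_h
  y <- curve$od750
  if (length(t) < 6L) stop("need at least 6 points to fit")
  sstot <- sum((y - mean(y))^2)
  out <- list(coefficients = c(kt0 = NA_real_, ktn = NA_real_,
                               t50 = NA_real_, hill = NA_real_),
              se = rep(NA_real_, 4L), r2 = NA_real_, abs_ss = NA_real_,
              status = "not_converged", fitted_values = rep(NA_real_, length(y)),
              curve = curve, log_time = log_time, df.residual = length(y) - 4L)
  class(out) <- "growth_fit"
  if (sstot <= .Machine$double.eps) {
    out$reason <- "no variance in OD series"
    return(out)
  }
  start <- sigmoid_start(t, y, log_time)
  dat <- data.frame(t = t, y = y)
  one_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ sigmoid_od(t, kt0, ktn, t50, hill, log_time = log_time),
        data = dat, start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
  }
  best <- one_fit(start)
  best_ss <- if (is.null(best)) Inf else sum(stats::resid(best)^2)
  # spend restarts only while the fit is still poor
  set <- c(0.5, 2, 0.8, 1.25, 1.5)
  for (i in seq_len(n_starts)) {
    if (is.finite(best_ss) && best_ss / sstot < 1e-4) break
    st <- start
    st["hill"] <- start["hill"] * set[(i - 1L) %% length(set) + 1L]
    st["t50"] <- start["t50"] * c(0.8, 1.2, 0.9, 1.1, 1)[(i - 1L) %% 5L + 1L]
    f <- one_fit(st)
    if (!is.null(f)) {
      ss <- sum(stats::resid(f)^2)
      if (ss < best_ss) {
        best <- f
        best_ss <- ss
      }
    }
  }
  if (is.null(best)) {
    out$reason <- "optimiser failed from all starts"
    return(out)
  }
  cf <- stats::coef(best)
  fitted_values <- as.numeric(stats::fitted(best))
  ssr <- sum((y - fitted_values)^2)
  out$coefficients[] <- cf[c("kt0", "ktn", "t50", "hill")]
  out$fitted_values <- fitted_values
  out$abs_ss <- ssr
  out$r2 <- 1 - ssr / sstot
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) rep(NA_real_, 4L))
  out$se[] <- se[c("kt0", "ktn", "t50", "hill")]
  grad <- best$m$gradient()
  kap <- tryCatch(kappa(grad, exact = TRUE), error = function(e) Inf)
  ratio <- abs(out$se) / pmax(abs(out$coefficients), 1e-12)
  out$status <- if (any(!is.finite(se)) || kap > kappa_max ||
                    any(ratio > se_ratio_max, na.rm = TRUE)) "ambiguous" else "converged"
  if (out$status == "ambiguous") out$reason <- "parameters unidentified"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Variable-slope sigmoid growth fit\n")
  cat(sprintf("  status: %s;  R2 = %s;  abs SS = %s\n", x$status,
              formatC(x$r2, digits = 4), formatC(x$abs_ss, digits = 4)))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
fitted.growth_fit <- function(object, ...) object$fitted_values

#' @export
residuals.growth_fit <- function(object, ...) {
  object$curve$od750 - object$fitted_values
}

#' @export
predict.growth_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted_values)
  cf <- object$coefficients
  sigmoid_od(times, cf["kt0"], cf["ktn"], cf["t50"], cf["hill"],
             log_time = object$log_time)
}

#' @export
summary.growth_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, r2 = object$r2, abs_ss = object$abs_ss,
                 status = object$status), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Variable-slope sigmoid growth fit\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("status %s, R2 %.4f, abs SS %.4f\n", x$status, x$r2, x$abs_ss))
  invisible(x)
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$curve$times_h, x$curve$od750, xlab = "time (h)",
                 ylab = expression(OD[750]), pch = 16, col = "firebrick", ...)
  if (all(is.finite(x$fitted_values))) {
    tt <- seq(min(x$curve$times_h), max(x$curve$times_h), length.out = 200)
    graphics::lines(tt, predict(x, tt), lwd = 2)
  }
  invisible(x)
}

#' Quality-control filter for growth-curve fits
#'
#' A fit passes QC when it converged cleanly, its R-square exceeds `r2_min`
#' (default 0.85) and its absolute sum of squared residuals is below
#' `abs_ss_max` (default 0.1 OD^2). All violated rules are reported.
#'
#' @param fit a `growth_fit`.
#' @param r2_min minimum R-square (exclusive).
#' @param abs_ss_max maximum absolute sum of squares (exclusive).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty when passing).
#' @export
qc_filter <- function(fit, r2_min = 0.85, abs_ss_max = 0.1) {
  reasons <- character()
  if (fit$status != "converged") {
    reasons <- c(reasons, paste0("status ", fit$status))
  }
  if (!isTRUE(fit$r2 > r2_min)) {
    reasons <- c(reasons, sprintf("r2 <= %.2f", r2_min))
  }
  if (!isTRUE(fit$abs_ss < abs_ss_max)) {
    reasons <- c(reasons, sprintf("abs_ss >= %.2f", abs_ss_max))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Default morphology-triage thresholds
#'
#' @param rise_min minimum total OD rise for a well to count as growing.
#' @param decline_min post-peak fractional decline (of peak, on a smoothed
#'   series) that flags a death phase.
#' @param circ_band period band (h) scanned for circadian oscillation.
#' @param circ_weak,circ_strong residual band-power fractions for the weak
#'   and strong circadian labels.
#' @param circ_amp_min minimum oscillation amplitude (OD units) — guards
#'   against flagging pure measurement noise whose spectrum happens to peak
#'   in the band.
#' @param lag_min lag estimate (h) beyond which a curve is labelled long-lag.
#' @param od_review_max maximum-OD threshold below which a curve is flagged
#'   for manual review (low plateau).
#' @return Named list of thresholds.
#' @export
morphology_thresholds <- function(rise_min = 0.05, decline_min = 0.2,
                                  circ_band = c(20, 28), circ_weak = 0.2,
                                  circ_strong = 0.5, circ_amp_min = 0.01,
                                  lag_min = 15, od_review_max = 0.8) {
  list(rise_min = rise_min, decline_min = decline_min, circ_band = circ_band,
       circ_weak = circ_weak, circ_strong = circ_strong,
       circ_amp_min = circ_amp_min, lag_min = lag_min,
       od_review_max = od_review_max)
}

# moving-average smoother (window in samples, odd), edges shrunk
smooth_ma <- function(y, k = 7L) {
  n <- length(y)
  if (n < 3L) return(y)
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Periodicity score of a residual series
#'
#' Fraction of the residual periodogram power falling in a period band
#' (default 20-28 h), plus the implied oscillation amplitude of the dominant
#' in-band component. Requires a regular sampling grid.
#'
#' @param times_h sampling times (regular grid).
#' @param resid residual series.
#' @param band period band in hours.
#' @return List with `score` (band power / total power), `amplitude` (OD
#'   units) and `period_h` of the dominant in-band component.
#' @export
circadian_score <- function(times_h, resid, band = c(20, 28)) {
  n <- length(resid)
  if (n < 8L) return(list(score = 0, amplitude = 0, period_h = NA_real_))
  dt <- stats::median(diff(times_h))
  z <- stats::fft(resid - mean(resid))
  j <- seq_len(floor(n / 2))
  power <- Mod(z[j + 1L])^2
  period <- n * dt / j
  inband <- period >= band[1] & period <= band[2]
  tot <- sum(power)
  if (tot <= .Machine$double.eps || !any(inband)) {
    return(list(score = 0, amplitude = 0, period_h = NA_real_))
  }
  score <- sum(power[inband]) / tot
  jmax <- j[inband][which.max(power[inband])]
  amplitude <- 2 * Mod(z[jmax + 1L]) / n
  list(score = score, amplitude = amplitude, period_h = n * dt / jmax)
}

#' Classify a growth curve's morphology
#'
#' Rule cascade over the raw curve and its sigmoid fit, mirroring the manual
#' triage of typical 96-well growth-curve shapes: (1) no growth when the
#' smoothed OD rise is below `rise_min`; (2) death phase when the smoothed
#' series falls from its peak by more than `decline_min` of the peak;
#' (3) strong/weak circadian oscillation by the residual band-power score at
#' ~24 h (with an amplitude guard); (4) long lag when the fitted takeoff
#' (`t50 - 2/hill`) exceeds `lag_min`; (5) low plateau (flag for manual
#' review, not exclusion) when the maximum OD is below `od_review_max`;
#' (6) robust otherwise. Wells failing [qc_filter()] with no morphological
#' explanation are labelled `ambiguous_excluded`. Labels `no_growth`,
#' `death_phase` and `ambiguous_excluded` are excluded from downstream
#' effects analysis.
#'
#' @param curve a [growth_curve()].
#' @param fit the corresponding [fit_sigmoid()] result.
#' @param thresholds see [morphology_thresholds()].
#' @param qc result of [qc_filter()] (computed from `fit` if omitted).
#' @return Object of class `curve_class`: `label`, `reasons`, `excluded`,
#'   `review` (manual-review flag).
#' @export
classify_morphology <- function(curve, fit, thresholds = morphology_thresholds(),
                                qc = qc_filter(fit)) {
  th <- thresholds
  y <- curve$od750
  sm <- smooth_ma(y)
  reasons <- character()
  label <- NULL
  rise <- max(sm) - sm[1L]
  if (rise < th$rise_min) {
    label <- "no_growth"
    reasons <- sprintf("OD rise %.3f < %.3f", rise, th$rise_min)
  }
  if (is.null(label)) {
    ipk <- which.max(sm)
    decline <- (sm[ipk] - min(sm[ipk:length(sm)])) / sm[ipk]
    if (decline > th$decline_min) {
      label <- "death_phase"
      reasons <- sprintf("post-peak decline %.0f%% of peak", 100 * decline)
    }
  }
  if (is.null(label)) {
    res <- if (all(is.finite(fit$fitted_values))) y - fit$fitted_values else y - sm
    cs <- circadian_score(curve$times_h, res, th$circ_band)
    if (cs$amplitude >= th$circ_amp_min && cs$score >= th$circ_strong) {
      label <- "circadian_strong"
      reasons <- sprintf("band power %.2f, amplitude %.3f", cs$score, cs$amplitude)
    } else if (cs$amplitude >= th$circ_amp_min && cs$score >= th$circ_weak) {
      label <- "circadian_weak"
      reasons <- sprintf("band power %.2f, amplitude %.3f", cs$score, cs$amplitude)
    }
  }
  if (is.null(label) && fit$status == "converged") {
    cf <- fit$coefficients
    lag_est <- cf[["t50"]] - 2 / cf[["hill"]]
    if (is.finite(lag_est) && lag_est > th$lag_min) {
      label <- "long_lag"
      reasons <- sprintf("lag estimate %.1f h > %.1f h", lag_est, th$lag_min)
    }
  }
  review <- FALSE
  if (is.null(label)) {
    if (max(y) < th$od_review_max) {
      label <- "low_plateau"
      reasons <- sprintf("max OD %.2f < %.2f (manual review)", max(y), th$od_review_max)
      review <- TRUE
    }
  }
  if (is.null(label)) {
    if (!qc$pass) {
      label <- "ambiguous_excluded"
      reasons <- qc$reasons
    } else {
      label <- "robust"
    }
  }
  excluded <- label %in% c("no_growth", "death_phase", "ambiguous_excluded")
  structure(list(label = label, reasons = reasons, excluded = excluded,
                 review = review), class = "curve_class")
}

#' @export
print.curve_class <- function(x, ...) {
  cat(sprintf("curve class: %s%s\n", x$label,
              if (x$excluded) " (excluded)" else if (x$review) " (review)" else ""))
  if (length(x$reasons)) cat("  ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Fit, QC and classify a set of wells
#'
#' Convenience wrapper applying [fit_sigmoid()], [qc_filter()] and
#' [classify_morphology()] to a list of growth curves.
#'
#' @param curves list of [growth_curve()] objects.
#' @param r2_min,abs_ss_max QC thresholds (see [qc_filter()]).
#' @param thresholds morphology thresholds.
#' @param ... passed to [fit_sigmoid()].
#' @return List with `fits` (the `growth_fit` objects) and `table`, a data
#'   frame of per-well parameters, goodness of fit, QC verdicts and classes.
#' @export
fit_wells <- function(curves, r2_min = 0.85, abs_ss_max = 0.1,
                      thresholds = morphology_thresholds(), ...) {
  fits <- lapply(curves, fit_sigmoid, ...)
  rows <- Map(function(curve, fit) {
    qc <- qc_filter(fit, r2_min, abs_ss_max)
    cl <- classify_morphology(curve, fit, thresholds, qc)
    data.frame(
      plate = curve$plate, well = curve$well,
      condition_id = curve$condition_id, species_id = curve$species_id,
      replicate = curve$replicate,
      kt0 = fit$coefficients[["kt0"]], ktn = fit$coefficients[["ktn"]],
      t50 = fit$coefficients[["t50"]], hill = fit$coefficients[["hill"]],
      r2 = fit$r2, abs_ss = fit$abs_ss, status = fit$status,
      qc_pass = qc$pass, class = cl$label, excluded = cl$excluded,
      reasons = paste(c(qc$reasons, cl$reasons), collapse = "; "),
      stringsAsFactors = FALSE)
  }, curves, fits)
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(fits = fits, table = table)
}
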