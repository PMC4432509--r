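# Specific growth rates on the fitted 3-h grid, replicate statistics.

#' Specific growth rate between two OD readings
#'
#' `mu = (ln OD2 - ln OD1) / (t2 - t1)`, in h^-1: the fractional biomass
#' increase per hour assuming exponential growth over the interval.
#'
#' @param od1,od2 OD750 at the two times (must be positive).
#' @param t1,t2 times in hours (`t2 > t1`).
#' @return Specific growth rate(s), h^-1.
#' @export
#' @examples
#' specific_growth_rate(0.1, 0.2, 0, 1)  # ln 2
specific_growth_rate <- function(od1, od2, t1, t2) {
  if (any(od1 <= 0) || any(od2 <= 0)) {
    stop("OD values must be positive for log-scale rates")
  }
  if (any(t2 <= t1)) stop("need t2 > t1")
  (log(od2) - log(od1)) / (t2 - t1)
}

# mu series over consecutive points of a (fitted) OD grid, with a floor on
# non-positive ODs so one bad well does not abort a plate
mu_series_grid <- function(times_h, od, window_h = c(0, 48), floor_od = 1e-6) {
  if (any(od <= 0)) {
    warning("non-positive OD values floored at ", floor_od)
    od <- pmax(od, floor_od)
  }
  n <- length(times_h)
  keep <- which(times_h[-n] >= window_h[1] & times_h[-1L] <= window_h[2])
  if (!length(keep)) stop("window excludes every interval")
  mu <- (log(od[keep + 1L]) - log(od[keep])) / (times_h[keep + 1L] - times_h[keep])
  list(mu = mu, t1 = times_h[keep], t2 = times_h[keep + 1L])
}

#' Maximum specific growth rate from a fitted curve
#'
#' Applies the two-point rate to every pair of consecutive fitted values on
#' the sampling grid inside the analysis window (default the first 0-48 h,
#' which dodges late-run evaporation effects) and reports the maximum and
#' its interval. By default rates are computed on the sigmoid-fitted values;
#' `use_fitted = FALSE` uses the raw data (diagnostics only).
#'
#' @param fit a `growth_fit` (typically QC-passing).
#' @param window_h analysis window `(start, end)` in hours.
#' @param use_fitted use fitted (TRUE, default) or raw OD values.
#' @return Object of class `growth_rate`: `mu_max` (h^-1), `window` (the
#'   maximising interval), `mu_series`, `t1`, `t2`.
#' @export
#' @examples
#' tt <- seq(0, 72, by = 3)
#' fit <- fit_sigmoid(growth_curve(tt, sigmoid_od(tt, 0.1, 1, 30, 0.1)))
#' mu_max(fit)$mu_max
mu_max <- function(fit, window_h = c(0, 48), use_fitted = TRUE) {
  times_h <- fit$curve$times_h
  od <- if (use_fitted) fit$fitted_values else fit$curve$od750
  if (any(!is.finite(od))) stop("fit has no usable fitted values")
  ms <- mu_series_grid(times_h, od, window_h)
  i <- which.max(ms$mu)
  structure(list(mu_max = ms$mu[i], window = c(ms$t1[i], ms$t2[i]),
                 mu_series = ms$mu, t1 = ms$t1, t2 = ms$t2),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("mu_max = %.4f h^-1 over (%.0f, %.0f) h\n",
              x$mu_max, x$window[1], x$window[2]))
  invisible(x)
}

#' Aggregate replicate growth rates per condition
#'
#' Computes mean, SD and relative standard deviation (RSD, %) of `mu_max`
#' across replicate wells per condition (and species), omitting QC-excluded
#' wells and counting them. Conditions whose replicates are all excluded are
#' reported with `n_replicates = 0` and `NA` statistics.
#'
#' @param rates data frame with columns `condition_id`, `mu_max` and
#'   optionally `species_id`, `qc_pass` (wells with `qc_pass == FALSE` are
#'   dropped from the statistics but counted in `n_excluded`).
#' @return Data frame keyed by condition (and species) with `mu_mean`,
#'   `mu_sd`, `rsd_pct`, `n_replicates`, `n_excluded`.
#' @export
aggregate_replicates <- function(rates) {
  if (!all(c("condition_id", "mu_max") %in% names(rates))) {
    stop("rates must have condition_id and mu_max columns")
  }
  if (is.null(rates$species_id)) rates$species_id <- ""
  rates$species_id[is.na(rates$species_id)] <- ""
  if (is.null(rates$qc_pass)) rates$qc_pass <- TRUE
  key <- interaction(rates$condition_id, rates$species_id, drop = TRUE)
  rows <- lapply(split(rates, key), function(g) {
    ok <- g[g$qc_pass & is.finite(g$mu_max), ]
    n <- nrow(ok)
    mu_mean <- if (n >= 1L) mean(ok$mu_max) else NA_real_
    mu_sd <- if (n >= 2L) stats::sd(ok$mu_max) else NA_real_
    data.frame(
      condition_id = g$condition_id[1L], species_id = g$species_id[1L],
      mu_mean = mu_mean, mu_sd = mu_sd,
      rsd_pct = if (n >= 2L && mu_mean != 0) 100 * mu_sd / mu_mean else NA_real_,
      n_replicates = n, n_excluded = nrow(g) - n,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition_id, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha for replicate reliability
#'
#' Internal-consistency reliability of replicate measurement series:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(totals))`, with the
#' replicate series as items (columns) and conditions as observations
#' (rows).
#'
#' @param replicate_matrix numeric matrix, conditions x replicates.
#' @return Alpha (1 for identical replicate series, ~0 for unrelated noise).
#' @export
#' @examples
#' m <- cbind(a = 1:5, b = 1:5, c = 1:5)
#' cronbach_alpha(m)  # 1
cronbach_alpha <- function(replicate_matrix) {
  m <- as.matrix(replicate_matrix)
  k <- ncol(m)
  if (k < 2L || nrow(m) < 2L) {
    stop("need >= 2 replicate series over >= 2 conditions")
  }
  vt <- stats::var(rowSums(m))
  if (vt <= .Machine$double.eps) stop("zero total variance across conditions")
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / vt)
}
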