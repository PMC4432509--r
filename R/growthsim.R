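# Synthetic OD750 growth-curve generator. Emulates the morphologies seen in
# 96-well algal screens (robust, no growth, low plateau, death phase,
# circadian oscillation, long lag) and produces whole-plate datasets whose
# true maximum specific growth rates follow a known second-order response
# surface, so every downstream stage is testable without instruments.

# run code with a locally-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Growth-curve simulation parameters
#'
#' Parameters of one simulated well. The base signal is the variable-slope
#' sigmoid ([sigmoid_od()]) shifted right by `lag_h`, multiplied by an
#' exponential death decay beyond the post-midpoint peak (`t50 + 2/hill`)
#' when `death_rate > 0`, plus a circadian sine of amplitude `circ_amp` and
#' period `circ_period`.
#'
#' @param k0 baseline OD750 (inoculation density, default 0.1).
#' @param kn plateau OD750 (light/nutrient-limited ceiling, default 1.0).
#' @param t50 inflection time (h).
#' @param hill steepness (h^-1 scale).
#' @param lag_h extra lag before takeoff (h).
#' @param circ_amp circadian oscillation amplitude (OD units).
#' @param circ_period oscillation period (h, default 24).
#' @param death_rate post-peak exponential decline rate (h^-1).
#' @param morphology intended class label (bookkeeping only).
#' @return List of class `curve_params`.
#' @export
curve_params <- function(k0 = 0.1, kn = 1.0, t50 = 30, hill = 0.1, lag_h = 0,
                         circ_amp = 0, circ_period = 24, death_rate = 0,
                         morphology = "robust") {
  stopifnot(k0 > 0, circ_amp >= 0, death_rate >= 0, circ_period > 0)
  structure(list(k0 = k0, kn = kn, t50 = t50, hill = hill, lag_h = lag_h,
                 circ_amp = circ_amp, circ_period = circ_period,
                 death_rate = death_rate, morphology = morphology),
            class = "curve_params")
}

#' Simulation sampling configuration
#'
#' @param dt_h sampling interval in hours (default 3, the plate-reader cycle).
#' @param duration_h run length in hours (default 72; runs are kept at or
#'   below 75 h to limit evaporation).
#' @param noise_sd additive Gaussian OD noise SD (default 0.01, which
#'   reproduces sub-5% replicate RSD at plateau ~1.0).
#' @param seed RNG seed; a fixed seed makes output bit-for-bit reproducible
#'   and the caller's RNG stream is left untouched.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(dt_h = 3, duration_h = 72, noise_sd = 0.01, seed = NULL) {
  stopifnot(dt_h > 0, duration_h > 0)
  structure(list(dt_h = dt_h, duration_h = duration_h, noise_sd = noise_sd,
                 seed = seed), class = "sim_config")
}

# noiseless signal on an arbitrary time vector
curve_signal <- function(params, t) {
  p <- params
  base <- sigmoid_od(t - p$lag_h, p$k0, p$kn, p$t50, p$hill)
  if (p$death_rate > 0) {
    t_peak <- p$lag_h + p$t50 + 2 / p$hill
    base <- base * exp(-p$death_rate * pmax(0, t - t_peak))
  }
  pmax(base + p$circ_amp * sin(2 * pi * t / p$circ_period), 0)
}

#' Simulate one growth curve
#'
#' @param params a [curve_params()].
#' @param config a [sim_config()].
#' @param well,plate,condition_id,species_id,replicate provenance carried onto
#'   the returned curve.
#' @return A [growth_curve()] sampled on the regular grid
#'   `seq(0, duration_h, by = dt_h)`.
#' @export
#' @examples
#' gc <- simulate_curve(curve_params(), sim_config(noise_sd = 0, seed = 1))
#' range(gc$od750)
simulate_curve <- function(params, config = sim_config(), well = NA, plate = NA,
                           condition_id = NA, species_id = NA, replicate = NA) {
  t <- seq(0, config$duration_h, by = config$dt_h)
  y <- with_local_seed(config$seed, {
    sig <- curve_signal(params, t)
    if (config$noise_sd > 0) sig <- sig + stats::rnorm(length(t), 0, config$noise_sd)
    pmax(sig, 0)
  })
  growth_curve(t, y, well = well, plate = plate, condition_id = condition_id,
               species_id = species_id, replicate = replicate)
}

#' Morphology parameter presets
#'
#' Named [curve_params()] presets for the growth-curve shapes the triage
#' rules must recognise: robust growth, no growth, growth to a low plateau,
#' growth followed by death, weak/strong circadian oscillation, a long lag
#' phase, and rapid early growth ending in an early low plateau.
#'
#' @return Named list of `curve_params`.
#' @export
curve_presets <- function() {
  list(
    robust = curve_params(morphology = "robust"),
    no_growth = curve_params(kn = 0.1, morphology = "no_growth"),
    low_plateau = curve_params(kn = 0.6, t50 = 35, hill = 0.05,
                               morphology = "low_plateau"),
    death_phase = curve_params(t50 = 25, death_rate = 0.04,
                               morphology = "death_phase"),
    circadian_weak = curve_params(circ_amp = 0.012,
                                  morphology = "circadian_weak"),
    circadian_strong = curve_params(circ_amp = 0.06,
                                    morphology = "circadian_strong"),
    long_lag = curve_params(lag_h = 15, morphology = "long_lag"),
    early_plateau = curve_params(kn = 0.5, t50 = 15, hill = 0.15,
                                 morphology = "early_plateau")
  )
}

# pipeline mu_max of the noiseless curve on the sampling grid
grid_mu_max <- function(params, config = sim_config(noise_sd = 0),
                        window_h = c(0, 48)) {
  t <- seq(0, config$duration_h, by = config$dt_h)
  y <- pmax(curve_signal(params, t), 1e-9)
  ms <- mu_series_grid(t, y, window_h)
  max(ms$mu)
}

#' Calibrate the sigmoid steepness to a target growth rate
#'
#' Solves for the `hill` parameter such that the pipeline's own mu_max —
#' the maximum two-point log slope over consecutive noiseless samples on the
#' 3-h grid inside the analysis window — equals `mu_target`. Ground-truth
#' growth rates in [simulate_plate()] are defined operationally through this
#' root find, so a noiseless simulate -> fit -> mu_max round trip recovers
#' them by construction.
#'
#' @param mu_target target maximum specific growth rate (h^-1, > 0).
#' @param k0,kn,t50 remaining curve parameters.
#' @param config sampling grid.
#' @param window_h analysis window (must match the downstream [mu_max()] call).
#' @param tol relative tolerance of the calibration.
#' @return A calibrated [curve_params()].
#' @export
calibrate_curve <- function(mu_target, k0 = 0.1, kn = 1.0, t50 = 30,
                            config = sim_config(noise_sd = 0),
                            window_h = c(0, 48), tol = 1e-6) {
  if (mu_target <= 0) stop("mu_target must be positive")
  f <- function(h) {
    grid_mu_max(curve_params(k0 = k0, kn = kn, t50 = t50, hill = h),
                config, window_h) - mu_target
  }
  lo <- 1e-4
  hi <- 3
  if (f(hi) < 0) stop("mu_target ", mu_target, " exceeds the attainable range")
  if (f(lo) > 0) stop("mu_target ", mu_target, " below the attainable range")
  h <- stats::uniroot(f, c(lo, hi), tol = tol * 1e-2)$root
  curve_params(k0 = k0, kn = kn, t50 = t50, hill = h)
}

#' Define a true response surface for simulation
#'
#' Builds the full second-order coefficient vector for a design from sparse
#' named pieces. Coefficients are on the mu_max scale (h^-1 per coded unit).
#'
#' @param design a `bbd_design` (or coded matrix).
#' @param intercept centre-point mu_max (h^-1).
#' @param linear named vector of linear coefficients (names = factor names).
#' @param interactions named vector of cross-product coefficients (names like
#'   `"Ca:Mg"`, factors in design column order).
#' @param quadratic named vector of squared-term coefficients (names = factor
#'   names).
#' @param sigma residual SD of the true mu_max draw.
#' @return Object of class `true_surface`: `beta` (full named vector matching
#'   [build_model_matrix()] columns) and `sigma`.
#' @export
#' @examples
#' d <- generate_bbd(10, 20)
#' s <- true_surface(d, intercept = 0.1, linear = c(Ca = 0.02))
true_surface <- function(design, intercept = 0.1, linear = NULL,
                         interactions = NULL, quadratic = NULL, sigma = 0) {
  X <- build_model_matrix(design)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- intercept
  fill <- function(beta, v, suffix = "") {
    if (is.null(v)) return(beta)
    nm <- paste0(names(v), suffix)
    missing <- setdiff(nm, names(beta))
    if (length(missing)) stop("unknown surface term(s): ", paste(missing, collapse = ", "))
    beta[nm] <- v
    beta
  }
  beta <- fill(beta, linear)
  beta <- fill(beta, interactions)
  beta <- fill(beta, quadratic, "^2")
  structure(list(beta = beta, sigma = sigma), class = "true_surface")
}

#' Simulate a whole screening plate set
#'
#' Draws a true mu_max for every design condition from the response surface
#' (`x' beta + epsilon`), calibrates a sigmoid curve to each rate
#' ([calibrate_curve()]), lays the conditions out on 96-well plates and
#' simulates `replicates` noisy wells per condition. Conditions whose drawn
#' rate is non-positive are simulated as no-growth wells and flagged.
#'
#' @param design a `bbd_design` (or coded matrix).
#' @param surface a [true_surface()] (its `beta` must match the design).
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @param replicates wells per condition.
#' @param window_h analysis window used to define the ground-truth rates.
#' @return Object of class `plate_sim`: `curves` (list of [growth_curve()]),
#'   `data` (long data frame `plate`, `well`, `time_h`, `od750`), `truth`
#'   (`condition_id`, `mu_true`, `hill`, `no_growth`), `layout`, `config`.
#' @export
simulate_plate <- function(design, surface, config = sim_config(),
                           replicates = 3L, window_h = c(0, 48)) {
  X <- build_model_matrix(design)
  if (length(surface$beta) != ncol(X)) {
    stop("surface beta length ", length(surface$beta),
         " does not match design model matrix (", ncol(X), " columns)")
  }
  ids <- if (inherits(design, "bbd_design")) design$condition_id
         else sprintf("C%03d", seq_len(nrow(X)))
  n <- nrow(X)
  with_local_seed(config$seed, {
    mu_true <- as.numeric(X %*% surface$beta)
    if (surface$sigma > 0) mu_true <- mu_true + stats::rnorm(n, 0, surface$sigma)
    params <- vector("list", n)
    for (i in seq_len(n)) {
      params[[i]] <- if (mu_true[i] <= 0) {
        curve_params(kn = 0.1, morphology = "no_growth")
      } else {
        calibrate_curve(mu_true[i], config = sim_config(config$dt_h, config$duration_h, 0),
                        window_h = window_h)
      }
    }
    lay <- layout_run(ids, n_units = replicates,
                      n_plates = ceiling(n * replicates / 96),
                      species = rep("sim01", replicates))
    a <- lay$assignments
    curves <- vector("list", nrow(a))
    dat <- vector("list", nrow(a))
    for (w in seq_len(nrow(a))) {
      i <- match(a$condition_id[w], ids)
      cc <- simulate_curve(params[[i]],
                           sim_config(config$dt_h, config$duration_h,
                                      config$noise_sd, seed = NULL),
                           well = a$well[w], plate = a$plate[w],
                           condition_id = a$condition_id[w],
                           species_id = a$species_id[w],
                           replicate = a$replicate[w])
      curves[[w]] <- cc
      dat[[w]] <- data.frame(plate = a$plate[w], well = a$well[w],
                             time_h = cc$times_h, od750 = cc$od750,
                             stringsAsFactors = FALSE)
    }
    names(curves) <- paste0("p", a$plate, "_", a$well)
    truth <- data.frame(
      condition_id = ids, mu_true = mu_true,
      hill = vapply(params, function(p) p$hill, numeric(1)),
      no_growth = mu_true <= 0, stringsAsFactors = FALSE)
    structure(list(curves = curves, data = do.call(rbind, dat), truth = truth,
                   layout = lay, config = config, window_h = window_h),
              class = "plate_sim")
  })
}

#' @export
print.plate_sim <- function(x, ...) {
  cat(sprintf("plate_sim: %d wells (%d conditions), %d no-growth, noise_sd %g\n",
              length(x$curves), nrow(x$truth), sum(x$truth$no_growth),
              x$config$noise_sd))
  invisible(x)
}
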