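# Pipeline configuration, plate-reader I/O and orchestration.

#' Build and validate a run configuration
#'
#' A single structured configuration object drives a whole pipeline run and
#' is fully serialisable to YAML, so a saved config reproduces a run exactly
#' given the same inputs.
#'
#' @param screen `"screen1"` or `"screen2"`.
#' @param baseline nutrient-factor baseline (see [nutrient_factors()]).
#' @param n_center centre points for the Screen 2 design.
#' @param replicates wells per condition (simulate mode).
#' @param r2_min,abs_ss_max QC thresholds (see [qc_filter()]).
#' @param od_review_max low-plateau manual-review threshold.
#' @param window_h mu_max analysis window, hours.
#' @param method effects method, `"rsm_t"` or `"cluster_anova"`.
#' @param alpha significance level.
#' @param dt_h,duration_h,noise_sd simulator settings.
#' @param seed RNG seed.
#' @param out_dir output directory for the report bundle.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(screen = "screen2", baseline = "original",
                       n_center = 20L, replicates = 3L,
                       r2_min = 0.85, abs_ss_max = 0.1, od_review_max = 0.8,
                       window_h = c(0, 48), method = "rsm_t", alpha = 0.05,
                       dt_h = 3, duration_h = 72, noise_sd = 0.01,
                       seed = 1L, out_dir = "phycoscreen-run") {
  cfg <- list(screen = screen, baseline = baseline, n_center = n_center,
              replicates = replicates, r2_min = r2_min, abs_ss_max = abs_ss_max,
              od_review_max = od_review_max, window_h = window_h,
              method = method, alpha = alpha, dt_h = dt_h,
              duration_h = duration_h, noise_sd = noise_sd, seed = seed,
              out_dir = out_dir)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(cfg$screen %in% c("screen1", "screen2"), "screen must be screen1|screen2")
  chk(cfg$baseline %in% c("original", "refined"), "unknown baseline")
  chk(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min must be in [0, 1]")
  chk(cfg$abs_ss_max > 0, "abs_ss_max must be positive")
  chk(cfg$od_review_max > 0, "od_review_max must be positive")
  chk(length(cfg$window_h) == 2L && cfg$window_h[2] > cfg$window_h[1],
      "window_h must be an increasing pair")
  chk(cfg$method %in% c("rsm_t", "cluster_anova"), "unknown effects method")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$dt_h > 0 && cfg$duration_h > 0, "sampling settings must be positive")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$replicates >= 1, "replicates must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param file path to a YAML config file.
#' @param cfg a [run_config()].
#' @return `read_config` returns a validated `run_config`.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  defaults <- unclass(run_config())
  defaults[names(cfg)] <- cfg
  validate_config(defaults)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' Read a plate-reader time-series CSV
#'
#' Long format: columns `plate`, `well`, `time_h`, `od750`, one row per
#' reading. A wide layout (one `t<hours>` column per time point) is also
#' accepted. Negative ODs, malformed well addresses and duplicate
#' (well, time) readings are rejected with the offending row named.
#'
#' @param file CSV path (or a data frame already in long format).
#' @param layout optional [read_layout()] result used to attach condition,
#'   species and replicate to each curve.
#' @return Named list of [growth_curve()] objects keyed `"p<plate>_<well>"`,
#'   times sorted.
#' @export
read_plate_timeseries <- function(file, layout = NULL) {
  df <- if (is.data.frame(file)) file else utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("plate", "well", "time_h", "od750") %in% names(df))) {
    tcols <- grep("^t[0-9.]+$", names(df), value = TRUE)
    if (all(c("plate", "well") %in% names(df)) && length(tcols)) {
      long <- do.call(rbind, lapply(tcols, function(cn) {
        data.frame(plate = df$plate, well = df$well,
                   time_h = as.numeric(sub("^t", "", cn)), od750 = df[[cn]],
                   stringsAsFactors = FALSE)
      }))
      df <- long
    } else {
      stop("need columns plate, well, time_h, od750 (or wide t<hours> columns)")
    }
  }
  parse_well(df$well) # validates addresses
  if (any(df$od750 < 0)) {
    i <- which(df$od750 < 0)[1L]
    stop(sprintf("negative od750 at row %d (plate %s well %s, t = %g h)",
                 i, df$plate[i], df$well[i], df$time_h[i]))
  }
  key <- paste0("p", df$plate, "_", toupper(df$well))
  dupkey <- paste(key, df$time_h)
  if (anyDuplicated(dupkey)) {
    stop("duplicate reading for ", dupkey[duplicated(dupkey)][1L])
  }
  ann <- NULL
  if (!is.null(layout)) {
    a <- layout$assignments
    ann <- stats::setNames(seq_len(nrow(a)), paste0("p", a$plate, "_", a$well))
  }
  curves <- lapply(split(seq_len(nrow(df)), key), function(ii) {
    ii <- ii[order(df$time_h[ii])]
    k <- paste0("p", df$plate[ii[1L]], "_", toupper(df$well[ii[1L]]))
    meta <- list(condition_id = NA, species_id = NA, replicate = NA)
    if (!is.null(ann) && !is.na(ann[k])) {
      r <- layout$assignments[ann[[k]], ]
      meta <- list(condition_id = r$condition_id, species_id = r$species_id,
                   replicate = r$replicate)
    }
    growth_curve(df$time_h[ii], df$od750[ii],
                 well = toupper(df$well[ii[1L]]), plate = df$plate[ii[1L]],
                 condition_id = meta$condition_id, species_id = meta$species_id,
                 replicate = meta$replicate)
  })
  curves[order(names(curves))]
}

#' @rdname read_plate_timeseries
#' @param data long-format data frame (e.g. `plate_sim$data`).
#' @export
write_plate_timeseries <- function(data, file) {
  if (inherits(data, "plate_sim")) data <- data$data
  utils::write.csv(data[, c("plate", "well", "time_h", "od750")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Run the full screening pipeline
#'
#' Orchestrates design -> simulate (or ingest) -> fit -> QC/triage -> rates
#' -> effects -> ranking, writing a report bundle of CSVs plus a run log to
#' `cfg$out_dir`: `design.csv`, `layout.csv`, `timeseries.csv` (simulate
#' mode), `fits.csv`, `rates.csv`, `effects_main.csv`, `effects_pairs.csv`,
#' `ranking.csv`, `radial.csv`, `run_log.txt`, `config.yaml`. Runs are
#' deterministic given the config (including its seed).
#'
#' @param cfg a [run_config()].
#' @param data `"simulate"` to generate data from a known response surface,
#'   or a path to a plate-reader long-format CSV.
#' @param layout optional layout (required with file input to map wells to
#'   conditions).
#' @param surface optional [true_surface()] for simulate mode; default a
#'   mild Ca/Mg surface around 0.1 h^-1.
#' @return Invisibly, a list with the design, fit table, rates, effects
#'   report, ranking and per-stage counts.
#' @export
run_pipeline <- function(cfg, data = "simulate", layout = NULL, surface = NULL) {
  cfg <- validate_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  lg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  if (cfg$screen != "screen2") {
    stop("run_pipeline currently orchestrates the screen2 response-surface ",
         "analysis; use generate_screen1()/layout_run() for screen1 designs")
  }
  design <- generate_bbd(10L, cfg$n_center,
                         factors = {
                           f <- nutrient_factors(cfg$baseline)
                           f[f$role == "factor", ]
                         })
  write_design(design, file.path(cfg$out_dir, "design.csv"))
  lg("design: %d runs (%d centre points)", nrow(design$coded), cfg$n_center)
  if (identical(data, "simulate")) {
    if (is.null(surface)) {
      surface <- true_surface(design, intercept = 0.1,
                              linear = c(Ca = 0.01, Mg = 0.006),
                              interactions = c("Ca:Mg" = 0.004),
                              sigma = 0)
    }
    sim <- simulate_plate(design, surface,
                          sim_config(cfg$dt_h, cfg$duration_h, cfg$noise_sd,
                                     seed = cfg$seed),
                          replicates = cfg$replicates, window_h = cfg$window_h)
    curves <- sim$curves
    write_layout(sim$layout, file.path(cfg$out_dir, "layout.csv"))
    write_plate_timeseries(sim, file.path(cfg$out_dir, "timeseries.csv"))
    utils::write.csv(sim$truth, file.path(cfg$out_dir, "truth.csv"),
                     row.names = FALSE)
    lg("simulate: %d wells, noise_sd %g, seed %d", length(curves),
       cfg$noise_sd, cfg$seed)
  } else {
    curves <- read_plate_timeseries(data, layout = layout)
    known <- !is.na(vapply(curves, function(cc) cc$condition_id, NA_character_))
    if (any(!known)) {
      lg("warning: %d wells without layout conditions ignored", sum(!known))
      curves <- curves[known]
    }
    if (!is.null(layout)) {
      missing <- setdiff(paste0("p", layout$assignments$plate, "_",
                                layout$assignments$well), names(curves))
      if (length(missing)) {
        lg("warning: %d layout wells absent from data", length(missing))
      }
    }
  }
  fw <- fit_wells(curves, r2_min = cfg$r2_min, abs_ss_max = cfg$abs_ss_max,
                  thresholds = morphology_thresholds(od_review_max = cfg$od_review_max))
  tab <- fw$table
  utils::write.csv(tab, file.path(cfg$out_dir, "fits.csv"), row.names = FALSE)
  excl <- table(tab$class[!tab$qc_pass | tab$excluded])
  lg("fit: %d wells in = %d usable + %d excluded (%s)", nrow(tab),
     sum(tab$qc_pass & !tab$excluded), sum(!tab$qc_pass | tab$excluded),
     paste(names(excl), as.integer(excl), sep = ":", collapse = ", "))
  usable <- which(tab$qc_pass & !tab$excluded)
  rates <- tab[, c("plate", "well", "condition_id", "species_id", "replicate",
                   "qc_pass")]
  rates$mu_max <- NA_real_
  for (i in usable) {
    rates$mu_max[i] <- mu_max(fw$fits[[i]], window_h = cfg$window_h)$mu_max
  }
  rates$qc_pass <- rates$qc_pass & !tab$excluded
  agg <- aggregate_replicates(rates)
  agg$window_start <- cfg$window_h[1]
  agg$window_end <- cfg$window_h[2]
  utils::write.csv(agg, file.path(cfg$out_dir, "rates.csv"), row.names = FALSE)
  lg("rates: %d conditions, %d with no surviving replicate",
     nrow(agg), sum(agg$n_replicates == 0L))
  y <- agg$mu_mean[match(design$condition_id, agg$condition_id)]
  rep_eff <- effects_report(design, y, method = cfg$method, alpha = cfg$alpha)
  utils::write.csv(rep_eff$main, file.path(cfg$out_dir, "effects_main.csv"),
                   row.names = FALSE)
  utils::write.csv(rep_eff$interactions,
                   file.path(cfg$out_dir, "effects_pairs.csv"), row.names = FALSE)
  ranking <- rank_media(design, y)
  utils::write.csv(ranking$ranking, file.path(cfg$out_dir, "ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(radial_export(design, y), file.path(cfg$out_dir, "radial.csv"),
                   row.names = FALSE)
  write_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  lg("effects (%s): %d significant main, %d significant pairs; best %s (+%.1f%%)",
     cfg$method, sum(rep_eff$main$significant),
     sum(rep_eff$interactions$significant), ranking$best_condition,
     ranking$improvement_pct)
  invisible(list(design = design, fits = tab, rates = agg, effects = rep_eff,
                 ranking = ranking,
                 counts = list(wells_in = nrow(tab),
                               wells_usable = length(usable),
                               wells_excluded = nrow(tab) - length(usable))))
}
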