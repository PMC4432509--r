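#' Nutrient factor table for the two-step screen
#'
#' Returns the built-in nutrient formulation used by the screen: the ten
#' Screen 2 design factors (Ca, Mg, Fe, Mn, Cu, Zn, B, Se, V, Si) with their
#' mid-point concentrations, plus the constant background nutrients (Mo, Co,
#' EDTA, Tris buffer, vitamins B1/B12) that are carried on every condition but
#' never varied. Coded levels -1/0/+1 map to half/mid/twice the mid-point
#' concentration by default (the twofold rule); the mapping can be overridden
#' per factor by editing `low_mM`/`high_mM`.
#'
#' Two baselines are shipped: `"original"` uses the literature-average Ca and
#' Mg mid-points (0.213 and 0.375 mM); `"refined"` uses the fourfold-raised
#' concentrations adopted after a first optimisation cycle (0.85 and 1.50 mM).
#'
#' @param baseline `"original"` or `"refined"` Ca/Mg mid-points.
#' @param file optional path to a factor CSV (columns `name`, `salt`,
#'   `mid_mM`, `role`, optionally `low_mM`, `high_mM`); defaults to the
#'   versioned table shipped with the package.
#' @return A data frame with columns `name`, `salt`, `mid_mM`, `low_mM`,
#'   `high_mM` and `role` (`"factor"` or `"constant"`). Design factors come
#'   first, in the canonical Screen 2 order.
#' @export
#' @examples
#' nutrient_factors()[, c("name", "mid_mM")]
nutrient_factors <- function(baseline = c("original", "refined"), file = NULL) {
  baseline <- match.arg(baseline)
  if (is.null(file)) {
    file <- system.file("extdata", "nutrient_factors.csv",
                        package = "phycoscreen", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "salt", "mid_mM", "role", "baseline")
  if (!all(need %in% names(tab))) {
    stop("factor table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[tab$baseline %in% c("both", baseline), ]
  if (anyDuplicated(tab$name)) {
    stop("duplicate factor names in table: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  if (any(tab$mid_mM <= 0 & tab$role == "factor")) {
    stop("screened factors must have mid_mM > 0")
  }
  if (is.null(tab$low_mM)) tab$low_mM <- NA_real_
  if (is.null(tab$high_mM)) tab$high_mM <- NA_real_
  # twofold rule default for coded -1/+1
  tab$low_mM <- ifelse(is.na(tab$low_mM), tab$mid_mM / 2, tab$low_mM)
  tab$high_mM <- ifelse(is.na(tab$high_mM), tab$mid_mM * 2, tab$high_mM)
  bad <- tab$role == "factor" & !(tab$low_mM < tab$mid_mM & tab$mid_mM < tab$high_mM)
  if (any(bad)) {
    stop("need low_mM < mid_mM < high_mM for factors: ",
         paste(tab$name[bad], collapse = ", "))
  }
  ord <- c(screen2_factor_order(), setdiff(tab$name, screen2_factor_order()))
  tab <- tab[order(match(tab$name, ord)), ]
  rownames(tab) <- NULL
  tab[, c("name", "salt", "mid_mM", "low_mM", "high_mM", "role")]
}

#' Canonical Screen 2 factor order
#'
#' @return Character vector of the ten micronutrient factors in the fixed
#'   order used for coded design vectors.
#' @export
screen2_factor_order <- function() {
  c("Ca", "Mg", "Fe", "Mn", "Cu", "Zn", "B", "Se", "V", "Si")
}

#' Map a coded level to a concentration
#'
#' Resolves a coded Box-Behnken level (-1, 0, +1) to the factor's low, mid or
#' high concentration in mM. By default the low/high levels are a twofold
#' difference from the mid-point (`mid/2` and `2*mid`).
#'
#' @param factor a single-row data frame (one row of [nutrient_factors()]) or
#'   a list with `low_mM`, `mid_mM`, `high_mM`.
#' @param level coded level(s); each must be -1, 0 or +1.
#' @return Concentration(s) in mM.
#' @export
#' @examples
#' ca <- nutrient_factors()[1, ]
#' code_to_concentration(ca, c(-1, 0, 1))
code_to_concentration <- function(factor, level) {
  if (is.data.frame(factor)) {
    stopifnot(nrow(factor) == 1L)
    factor <- as.list(factor)
  }
  if (!all(level %in% c(-1, 0, 1))) {
    stop("coded level must be -1, 0 or +1")
  }
  lvl <- c(factor$low_mM, factor$mid_mM, factor$high_mM)
  lvl[match(level, c(-1, 0, 1))]
}
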