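# Second-order response-surface fitting, main/interaction effect tests and
# media ranking.

#' Fit the second-order response surface
#'
#' Ordinary least squares of the per-condition responses (maximum specific
#' growth rates, h^-1) on the quadratic model matrix of the coded design:
#' `y = X beta + epsilon` with intercept, linear, cross-product and squared
#' terms ([build_model_matrix()]). Rows with missing responses (QC-excluded
#' conditions) are dropped; estimability is re-checked after dropping, and a
#' rank-deficient fit reports which terms became inestimable.
#'
#' @param design a `bbd_design` or coded matrix.
#' @param responses numeric response vector aligned to design rows (`NA` for
#'   excluded runs).
#' @return Object of class `rsm_fit` with coefficients, standard errors,
#'   t statistics and p-values (on `n - p` residual degrees of freedom),
#'   `sigma`, `r.squared`, fitted values and residuals (on included rows).
#' @export
#' @examples
#' d <- generate_bbd(10, 20)
#' y <- as.numeric(build_model_matrix(d) %*%
#'                 true_surface(d, 0.1, c(Ca = 0.02))$beta)
#' fit <- fit_rsm(d, y)
#' coef(fit)[["Ca"]]
fit_rsm <- function(design, responses) {
  X <- build_model_matrix(design)
  y <- as.numeric(responses)
  if (length(y) != nrow(X)) stop("responses must align with design rows")
  keep <- is.finite(y)
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  n <- nrow(Xk)
  p <- ncol(Xk)
  qrX <- qr(Xk)
  if (qrX$rank < p) {
    drop_cols <- colnames(Xk)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("model is rank deficient after exclusions; inestimable terms: ",
         paste(drop_cols, collapse = ", "))
  }
  if (n <= p) stop("need more included runs (", n, ") than parameters (", p, ")")
  beta <- qr.coef(qrX, yk)
  fitted_values <- as.numeric(Xk %*% beta)
  res <- yk - fitted_values
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  scale <- max(abs(yk), 1e-12)
  if (sqrt(sigma2) < 1e-10 * scale) {
    # numerically exact fit: a (near-)zero coefficient is exactly null
    nz <- abs(beta) > 1e-8 * scale
    pval <- ifelse(nz, 0, 1)
    tval <- ifelse(nz, Inf, 0)
  }
  sst <- sum((yk - mean(yk))^2)
  m <- ncol(coded_matrix(design))
  structure(list(
    coefficients = beta, se = se, t = tval, p = pval, df.residual = df,
    sigma = sqrt(sigma2), r.squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
    fitted.values = fitted_values, residuals = res, included = keep,
    n = n, m = m, factor_names = colnames(coded_matrix(design)),
    design = design, vcov = XtXinv * sigma2),
    class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Second-order response-surface fit: %d runs, %d factors, %d terms\n",
              x$n, x$m, length(x$coefficients)))
  cat(sprintf("  residual SD %.4g on %d df; R2 = %.4f\n",
              x$sigma, x$df.residual, x$r.squared))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
vcov.rsm_fit <- function(object, ...) object$vcov

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
summary.rsm_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  structure(list(coefficients = tab, sigma = object$sigma,
                 df = object$df.residual, r.squared = object$r.squared),
            class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  cat("Second-order response-surface fit\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("residual SD %.4g on %d df; R2 = %.4f\n",
              x$sigma, x$df, x$r.squared))
  invisible(x)
}

#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- build_model_matrix(newdata)
  as.numeric(X %*% object$coefficients)
}

#' @export
plot.rsm_fit <- function(x, ...) {
  me <- main_effects(x$design, restore_responses(x), method = "rsm_t")
  mm <- as.matrix(me[, c("mean_m1", "mean_0", "mean_p1")])
  graphics::matplot(t(mm), type = "b", pch = 16, lty = 1, xaxt = "n",
                    xlab = "coded level", ylab = "mean response", ...)
  graphics::axis(1, at = 1:3, labels = c("-1", "0", "+1"))
  graphics::legend("topleft", legend = me$factor, col = seq_len(nrow(me)),
                   lty = 1, cex = 0.7, ncol = 2)
  invisible(x)
}

restore_responses <- function(fit) {
  y <- rep(NA_real_, length(fit$included))
  y[fit$included] <- fit$fitted.values + fit$residuals
  y
}

level_means <- function(D, y, j) {
  out <- numeric(6)
  for (l in c(-1, 0, 1)) {
    sel <- D[, j] == l & is.finite(y)
    i <- match(l, c(-1, 0, 1))
    out[i] <- mean(y[sel])
    out[i + 3L] <- stats::sd(y[sel])
  }
  out
}

#' Per-factor main-effect analysis
#'
#' Two methods are available. `"rsm_t"` (default) tests each factor's linear
#' coefficient in the second-order surface fit ([fit_rsm()]) with a t-test —
#' the response-surface software convention. `"cluster_anova"` follows the
#' cluster procedure: group all runs by the factor's coded level (-1/0/+1,
#' centre points falling in the 0 cluster), then one-way ANOVA across the
#' three clusters. Both report the per-level response means and SDs used for
#' main-effect plots.
#'
#' @param design a `bbd_design` or coded matrix.
#' @param responses response vector aligned to design rows (`NA` = excluded).
#' @param method `"rsm_t"` or `"cluster_anova"`.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return Data frame with one row per factor: `factor`, `p`, `significant`,
#'   and level means/SDs `mean_m1`, `mean_0`, `mean_p1`, `sd_m1`, `sd_0`,
#'   `sd_p1`.
#' @export
main_effects <- function(design, responses, method = c("rsm_t", "cluster_anova"),
                         alpha = 0.05) {
  method <- match.arg(method)
  D <- coded_matrix(design)
  y <- as.numeric(responses)
  m <- ncol(D)
  p <- numeric(m)
  if (method == "rsm_t") {
    fit <- fit_rsm(design, y)
    p <- unname(fit$p[colnames(D)])
  } else {
    for (j in seq_len(m)) {
      keep <- is.finite(y)
      lev <- factor(D[keep, j], levels = c(-1, 0, 1))
      if (any(table(lev) == 0L)) {
        stop("empty level cluster for factor ", colnames(D)[j], " after exclusions")
      }
      av <- stats::aov(y[keep] ~ lev)
      p[j] <- summary(av)[[1]][["Pr(>F)"]][1L]
    }
  }
  lm6 <- t(vapply(seq_len(m), function(j) level_means(D, y, j), numeric(6)))
  out <- data.frame(factor = colnames(D), p = p, significant = p <= alpha,
                    mean_m1 = lm6[, 1], mean_0 = lm6[, 2], mean_p1 = lm6[, 3],
                    sd_m1 = lm6[, 4], sd_0 = lm6[, 5], sd_p1 = lm6[, 6],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pairwise interaction-effect analysis
#'
#' Tests the synergistic/antagonistic joint effect of every unordered factor
#' pair. `"rsm_t"` uses the cross-product coefficient t-test from
#' [fit_rsm()]; `"cluster_anova"` restricts to the runs where both factors
#' sit at -1/+1 and tests the interaction contrast of the 2x2 cell means
#' (interaction term of `y ~ xi * xj` on those cells).
#'
#' @inheritParams main_effects
#' @return Data frame with one row per pair: `factor1`, `factor2`, `p`,
#'   `significant`.
#' @export
interaction_effects <- function(design, responses,
                                method = c("rsm_t", "cluster_anova"),
                                alpha = 0.05) {
  method <- match.arg(method)
  D <- coded_matrix(design)
  y <- as.numeric(responses)
  m <- ncol(D)
  nm <- colnames(D)
  pairs <- utils::combn(m, 2L)
  pv <- numeric(ncol(pairs))
  if (method == "rsm_t") {
    fit <- fit_rsm(design, y)
    for (q in seq_len(ncol(pairs))) {
      pv[q] <- fit$p[[paste0(nm[pairs[1L, q]], ":", nm[pairs[2L, q]])]]
    }
  } else {
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      sel <- D[, i] != 0 & D[, j] != 0 & is.finite(y)
      if (sum(sel) < 5L) stop("too few +/-1 cells for pair ", nm[i], ":", nm[j])
      xi <- D[sel, i]; xj <- D[sel, j]
      fit2 <- stats::lm(y[sel] ~ xi * xj)
      ct <- summary(fit2)$coefficients
      pv[q] <- ct["xi:xj", "Pr(>|t|)"]
    }
  }
  out <- data.frame(factor1 = nm[pairs[1L, ]], factor2 = nm[pairs[2L, ]],
                    p = pv, significant = pv <= alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full effects report
#'
#' Bundles the surface fit, main-effect and interaction-effect tables into
#' one object. No multiple-testing correction is applied by default across
#' the 10 factors / 45 pairs; set `adjust = "BH"` for Benjamini-Hochberg
#' adjusted significance calls.
#'
#' @inheritParams main_effects
#' @param adjust `"none"` (default) or a method accepted by
#'   [stats::p.adjust()] applied separately to main and interaction p-values.
#' @return Object of class `effects_report`: `fit` (the `rsm_fit`), `main`,
#'   `interactions`, `alpha`, `method`.
#' @export
effects_report <- function(design, responses, method = c("rsm_t", "cluster_anova"),
                           alpha = 0.05, adjust = "none") {
  method <- match.arg(method)
  main <- main_effects(design, responses, method, alpha)
  inter <- interaction_effects(design, responses, method, alpha)
  if (adjust != "none") {
    main$p_adj <- stats::p.adjust(main$p, adjust)
    main$significant <- main$p_adj <= alpha
    inter$p_adj <- stats::p.adjust(inter$p, adjust)
    inter$significant <- inter$p_adj <= alpha
  }
  structure(list(fit = fit_rsm(design, responses), main = main,
                 interactions = inter, alpha = alpha, method = method),
            class = "effects_report")
}

#' @export
print.effects_report <- function(x, ...) {
  cat(sprintf("Effects report (%s, alpha = %g)\n", x$method, x$alpha))
  sm <- x$main$factor[x$main$significant]
  si <- paste(x$interactions$factor1[x$interactions$significant],
              x$interactions$factor2[x$interactions$significant], sep = "-")
  cat("  significant main effects:",
      if (length(sm)) paste(sm, collapse = ", ") else "none", "\n")
  cat("  significant interactions:",
      if (length(si)) paste(si, collapse = ", ") else "none", "\n")
  invisible(x)
}

deviation_string <- function(coded_row, nm) {
  nz <- which(coded_row != 0)
  if (!length(nz)) return("")
  paste(sprintf("%s (%+d)", nm[nz], as.integer(coded_row[nz])), collapse = ", ")
}

#' Rank media formulations by response
#'
#' Sorts included conditions by response (descending; ties broken by design
#' row order), reports the best medium as its non-zero coded deviations from
#' the centre point (e.g. `"Ca (+1), Mn (+1), B (-1), V (-1)"`), and the
#' percentage improvement of the best response over a baseline. The baseline
#' defaults to the centre-point mean (the best previous-screen medium); it
#' must be supplied explicitly when the design has no centre points.
#'
#' @param design a `bbd_design` or coded matrix.
#' @param responses response vector aligned to design rows (`NA` = excluded).
#' @param baseline baseline response; default the mean over centre-point runs.
#' @return Object of class `media_ranking`: `ranking` (data frame `rank`,
#'   `condition_id`, `response`, `deviations`), `best_condition`,
#'   `centre_mean`, `baseline`, `improvement_pct`.
#' @export
#' @examples
#' # a 77% improvement of 0.108 over a 0.061 baseline
#' d3 <- generate_bbd(3, 3, factors = NULL)
#' y <- rep(0.061, nrow(d3$coded)); y[1] <- 0.108
#' rank_media(d3, y, baseline = 0.061)$improvement_pct
rank_media <- function(design, responses, baseline = NULL) {
  D <- coded_matrix(design)
  y <- as.numeric(responses)
  ids <- if (inherits(design, "bbd_design")) design$condition_id
         else sprintf("C%03d", seq_len(nrow(D)))
  centre <- rowSums(D != 0) == 0
  centre_mean <- if (any(centre & is.finite(y))) mean(y[centre & is.finite(y)]) else NA_real_
  if (is.null(baseline)) {
    if (!is.finite(centre_mean)) {
      stop("no centre points in design: supply a baseline explicitly")
    }
    baseline <- centre_mean
  }
  inc <- which(is.finite(y))
  if (!length(inc)) stop("no included conditions to rank")
  ord <- inc[order(-y[inc], inc)]
  ranking <- data.frame(
    rank = seq_along(ord), condition_id = ids[ord], response = y[ord],
    deviations = vapply(ord, function(i) deviation_string(D[i, ], colnames(D)), ""),
    stringsAsFactors = FALSE)
  best <- ord[1L]
  structure(list(ranking = ranking, best_condition = ids[best],
                 best_deviations = deviation_string(D[best, ], colnames(D)),
                 centre_mean = centre_mean, baseline = baseline,
                 improvement_pct = 100 * (y[best] - baseline) / baseline),
            class = "media_ranking")
}

#' @export
print.media_ranking <- function(x, ...) {
  cat(sprintf("Best medium: %s [%s]\n", x$best_condition,
              if (nzchar(x$best_deviations)) x$best_deviations else "centre point"))
  cat(sprintf("  response %.4g vs baseline %.4g: improvement %.1f%%\n",
              x$ranking$response[1L], x$baseline, x$improvement_pct))
  invisible(x)
}

#' Radial-plot data export
#'
#' Maps the per-condition responses to the polar layout used for whole-screen
#' radial summary plots: condition index as angle, response as radius.
#'
#' @param design a `bbd_design` or coded matrix.
#' @param responses response vector aligned to design rows.
#' @return Data frame `condition_id`, `index`, `angle_rad`, `response`.
#' @export
radial_export <- function(design, responses) {
  D <- coded_matrix(design)
  ids <- if (inherits(design, "bbd_design")) design$condition_id
         else sprintf("C%03d", seq_len(nrow(D)))
  n <- nrow(D)
  data.frame(condition_id = ids, index = seq_len(n),
             angle_rad = 2 * pi * (seq_len(n) - 1L) / n,
             response = as.numeric(responses), stringsAsFactors = FALSE)
}
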