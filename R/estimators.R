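# Causal-effect estimators on harmonized instruments: Wald ratio, IVW,
# MR-Egger, weighted median, and OR-scale reporting.

# Pull the kept (x, y, sx, sy) series from an instrument table.
instrument_series <- function(instruments) {
  k <- kept_instruments(instruments)
  if (any(k$beta_exp == 0)) {
    stop("instrument with zero exposure effect: Wald ratio undefined",
         call. = FALSE)
  }
  list(x = k$beta_exp, y = k$beta_out, sx = k$se_exp, sy = k$se_out,
       snp_id = k$snp_id, J = nrow(k))
}

new_mr_estimate <- function(method, beta, se, pvalue, n_snp,
                            model_detail = list()) {
  ci <- to_or_scale(beta, se)
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n_snp = n_snp, model_detail = model_detail),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta %.4g (se %.4g), OR %.4g [%.4g, %.4g], p %.4g, %d SNPs\n",
              x$method, x$beta, x$se, x$or, x$ci_low, x$ci_high,
              x$pvalue, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, pvalue = x$pvalue,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             n_snp = x$n_snp, stringsAsFactors = FALSE)
}

#' Convert a log odds-ratio estimate to the OR scale
#'
#' @param beta Estimate on the ln(OR) scale.
#' @param se Standard error of `beta`, positive.
#' @param z Normal multiplier for the confidence interval; 1.96 gives 95%.
#' @return List with `or = exp(beta)` and `ci_low`/`ci_high`
#'   `= exp(beta -/+ z * se)`.
#' @export
to_or_scale <- function(beta, se, z = 1.96) {
  stopifnot(all(se > 0))
  list(or = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Single-instrument Wald ratio
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' with the first-order standard error `se_out / |beta_exp|` and a
#' two-sided normal p-value.
#'
#' @param instruments An `mr_instruments` table with exactly one kept row,
#'   or a one-row subset.
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(instruments) {
  s <- instrument_series(instruments)
  if (s$J != 1L) {
    stop("wald_ratio expects exactly one kept instrument", call. = FALSE)
  }
  beta <- s$y / s$x
  se <- s$sy / abs(s$x)
  new_mr_estimate("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

# Wald ratios and IVW weights for a series.
ratio_series <- function(s) {
  list(theta = s$y / s$x, w = s$x^2 / s$sy^2)
}

#' Inverse-variance-weighted estimator
#'
#' Precision-weighted mean of the per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2` — numerically identical to weighted least
#' squares of `beta_out` on `beta_exp` through the origin with weights
#' `1 / se_out^2`. The fixed-effect standard error is `(sum w)^(-1/2)`;
#' the multiplicative random-effects model (the default) inflates it by
#' `sqrt(max(1, Q / (J - 1)))` where Q is Cochran's statistic, so the
#' standard error is never deflated below the fixed-effect value.
#'
#' @param instruments An `mr_instruments` table (kept rows are used).
#' @param model `"random"` (multiplicative random effects) or `"fixed"`.
#' @return An `mr_estimate` with `method = "ivw"`; `model_detail` records
#'   the effects model, Q, and the fixed-effect standard error.
#' @export
mr_ivw <- function(instruments, model = c("random", "fixed")) {
  model <- match.arg(model)
  s <- instrument_series(instruments)
  if (s$J < 1L) stop("IVW requires at least one instrument", call. = FALSE)
  r <- ratio_series(s)
  beta <- sum(r$w * r$theta) / sum(r$w)
  se_fixed <- sqrt(1 / sum(r$w))
  q <- sum(r$w * (r$theta - beta)^2)
  se <- se_fixed
  inflation <- 1
  if (model == "random" && s$J > 1L) {
    inflation <- sqrt(max(1, q / (s$J - 1)))
    se <- se_fixed * inflation
  }
  new_mr_estimate("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), s$J,
                  model_detail = list(effects_model = model, Q = q,
                                      se_fixed = se_fixed,
                                      inflation = inflation))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1 / se_out^2`, after orienting every
#' instrument so its exposure effect is non-negative. The slope is the
#' causal estimate; the intercept estimates the average directional
#' pleiotropy and a nonzero value signals violation of the exclusion
#' restriction. Standard errors use the residual scale floored at 1
#' (multiplicative random effects that never deflate below the
#' fixed-effect value); p-values use the t distribution with J - 2 df.
#'
#' @param instruments An `mr_instruments` table with at least 3 kept rows.
#' @return An `mr_estimate` with `method = "egger"`; `model_detail$intercept`
#'   holds the pleiotropy-test record (`estimate`, `se`, `pvalue`, `df`).
#' @export
mr_egger <- function(instruments) {
  s <- instrument_series(instruments)
  if (s$J < 3L) {
    stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  }
  flip <- s$x < 0
  x <- ifelse(flip, -s$x, s$x)
  y <- ifelse(flip, -s$y, s$y)
  w <- 1 / s$sy^2
  fit <- stats::lm(y ~ x, weights = w)
  # summary.lm warns on an exactly collinear (noiseless) fit; that case is
  # legitimate here and handled by flooring the residual scale below
  sm <- suppressWarnings(summary(fit))
  scale_up <- max(1, sm$sigma)          # floor residual sd at 1
  coefs <- sm$coefficients
  df <- s$J - 2L
  slope <- coefs["x", "Estimate"]
  slope_se <- coefs["x", "Std. Error"] / sm$sigma * scale_up
  int <- coefs["(Intercept)", "Estimate"]
  int_se <- coefs["(Intercept)", "Std. Error"] / sm$sigma * scale_up
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df)
  int_p <- 2 * stats::pt(-abs(int / int_se), df)
  new_mr_estimate("egger", slope, slope_se, slope_p, s$J,
                  model_detail = list(
                    intercept = list(estimate = int, se = int_se,
                                     pvalue = int_p, df = df),
                    sigma = sm$sigma, df = df))
}

# Percentile-interpolated weighted median of ratios.
weighted_median_point <- function(theta, w) {
  w <- w / sum(w)
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- cumsum(w) - w / 2
  if (length(theta) == 1L) return(theta)
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when at least half the total instrument weight comes from
#' valid instruments. Wald ratios are weighted by `beta_exp^2 / se_out^2`
#' (normalised to sum to one), sorted, assigned cumulative percentiles
#' `s_j = sum(w_1..w_j) - w_j/2`, and the estimate is the linear
#' interpolation of the ratios at the 50th percentile. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' redrawn from normal laws centred on their observed values with their
#' reported standard errors and the weighted median recomputed.
#'
#' @param instruments An `mr_instruments` table with at least 3 kept rows.
#' @param n_boot Bootstrap replicates; default 5000.
#' @param seed Mandatory integer seed for the bootstrap.
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 5000, seed) {
  s <- instrument_series(instruments)
  if (s$J < 3L) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  stopifnot(n_boot >= 1)
  r <- ratio_series(s)
  beta <- weighted_median_point(r$theta, r$w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- stats::rnorm(s$J, s$x, s$sx)
      yb <- stats::rnorm(s$J, s$y, s$sy)
      weighted_median_point(yb / xb, xb^2 / s$sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  pvalue <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else
    as.numeric(beta == 0)
  # degenerate zero-noise bootstrap: report the point estimate with a
  # vanishing se rather than divide by zero
  if (se == 0) se <- .Machine$double.eps
  new_mr_estimate("weighted_median", beta, se, pvalue, s$J,
                  model_detail = list(n_boot = n_boot, seed = seed))
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The package's central fitting function: runs the requested estimators
#' on one harmonized instrument set and returns a classed model object
#' with the usual accessors (`print`, `summary`, `coef`, `confint`,
#' `predict`, `residuals`, `plot`).
#'
#' @param instruments An `mr_instruments` table from [harmonize()],
#'   typically after [filter_weak()].
#' @param methods Estimators to run, a subset of `"ivw"`, `"egger"`,
#'   `"weighted_median"` (`"wald"` is used automatically when only one
#'   instrument is available and `"ivw"` is requested).
#' @param ivw_model Effects model for IVW: `"random"` or `"fixed"`.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Integer seed; mandatory when `"weighted_median"` is run.
#' @return An object of class `mr_fit`.
#' @export
#' @examples
#' pair <- simulate_pair(sim_scenario(n_snp = 8, beta_causal = log(0.8),
#'                                    seed = 7))
#' inst <- harmonize(pair$exposure, pair$outcome)
#' fit <- mr_fit(inst, seed = 1, n_boot = 200)
#' fit
mr_fit <- function(instruments,
                   methods = c("ivw", "egger", "weighted_median"),
                   ivw_model = c("random", "fixed"),
                   n_boot = 5000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  ivw_model <- match.arg(ivw_model)
  estimates <- list()
  J <- nrow(kept_instruments(instruments))
  if ("ivw" %in% methods) {
    estimates$ivw <- if (J == 1L) wald_ratio(instruments) else
      mr_ivw(instruments, model = ivw_model)
  }
  if ("egger" %in% methods && J >= 3L) {
    estimates$egger <- mr_egger(instruments)
  }
  if ("weighted_median" %in% methods && J >= 3L) {
    if (is.null(seed)) {
      stop("`seed` is mandatory when the weighted median is requested",
           call. = FALSE)
    }
    estimates$weighted_median <- mr_weighted_median(instruments,
                                                    n_boot = n_boot,
                                                    seed = seed)
  }
  if (length(estimates) == 0L) {
    stop("no requested estimator is applicable to ", J, " instrument(s)",
         call. = FALSE)
  }
  structure(list(estimates = estimates,
                 instruments = instruments,
                 n_snp = J,
                 exposure_id = attr(instruments, "exposure_id"),
                 outcome_id = attr(instruments, "outcome_id"),
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$exposure_id %||% "exposure", x$outcome_id %||% "outcome",
              x$n_snp))
  df <- as.data.frame(x)
  df[c("beta", "se", "pvalue", "or", "ci_low", "ci_high")] <-
    lapply(df[c("beta", "se", "pvalue", "or", "ci_low", "ci_high")],
           signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  J <- object$n_snp
  structure(list(fit = object,
                 q_ivw = if (J >= 2L) cochran_q(object$instruments, "ivw"),
                 egger_intercept = if (!is.null(object$estimates$egger))
                   object$estimates$egger$model_detail$intercept),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$q_ivw)) {
    cat(sprintf("Heterogeneity: Q = %.4g on %d df, p = %.4g\n",
                x$q_ivw$Q, x$q_ivw$df, x$q_ivw$pvalue))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4g (se %.4g), p = %.4g\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pvalue))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(x$estimates, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- t(vapply(object$estimates, function(e) {
    c(e$beta - z * e$se, e$beta + z * e$se)
  }, numeric(2)))
  colnames(m) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), " %")
  m
}

#' @export
predict.mr_fit <- function(object, newdata = NULL,
                           method = names(object$estimates)[1], ...) {
  x <- if (is.null(newdata)) kept_instruments(object$instruments)$beta_exp
  else newdata$beta_exp
  e <- object$estimates[[method]]
  if (is.null(e)) stop("method '", method, "' was not fitted", call. = FALSE)
  if (method == "egger") {
    # Egger instruments are oriented to non-negative exposure effects
    e$model_detail$intercept$estimate + e$beta * abs(x)
  } else {
    e$beta * x
  }
}

#' @export
residuals.mr_fit <- function(object, method = "ivw",
                             type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  k <- kept_instruments(object$instruments)
  e <- object$estimates[[method]]
  if (is.null(e)) stop("method '", method, "' was not fitted", call. = FALSE)
  if (method == "egger") {
    flip <- k$beta_exp < 0
    x <- abs(k$beta_exp)
    y <- ifelse(flip, -k$beta_out, k$beta_out)
    fitted <- e$model_detail$intercept$estimate + e$beta * x
  } else {
    y <- k$beta_out
    fitted <- e$beta * k$beta_exp
  }
  r <- y - fitted
  if (type == "pearson") r <- r / k$se_out
  stats::setNames(r, k$snp_id)
}

#' Scatter plot of per-SNP effects with fitted causal lines
#'
#' Draws the standard MR scatter plot — per-SNP exposure effects against
#' outcome effects with +/- 1.96 SE error bars — and overlays the fitted
#' IVW line through the origin and the Egger line with its intercept,
#' when those estimators were run.
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  k <- kept_instruments(x$instruments)
  flip <- k$beta_exp < 0
  bx <- ifelse(flip, -k$beta_exp, k$beta_exp)
  by <- ifelse(flip, -k$beta_out, k$beta_out)
  graphics::plot(bx, by,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(bx, by - 1.96 * k$se_out, bx, by + 1.96 * k$se_out,
                     col = "grey60")
  graphics::segments(bx - 1.96 * k$se_exp, by, bx + 1.96 * k$se_exp, by,
                     col = "grey60")
  legend_items <- character(0)
  legend_cols <- integer(0)
  if (!is.null(x$estimates$ivw)) {
    graphics::abline(0, x$estimates$ivw$beta, col = 2, lwd = 2)
    legend_items <- c(legend_items, "IVW")
    legend_cols <- c(legend_cols, 2L)
  }
  if (!is.null(x$estimates$egger)) {
    graphics::abline(x$estimates$egger$model_detail$intercept$estimate,
                     x$estimates$egger$beta, col = 4, lwd = 2, lty = 2)
    legend_items <- c(legend_items, "MR-Egger")
    legend_cols <- c(legend_cols, 4L)
  }
  if (length(legend_items)) {
    graphics::legend("topleft", legend = legend_items, col = legend_cols,
                     lty = c(1, 2)[seq_along(legend_items)], lwd = 2,
                     bty = "n")
  }
  invisible(x)
}
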