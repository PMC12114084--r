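# Pleiotropy, heterogeneity, outlier and influence diagnostics.

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept record from the Egger regression and applies
#' the decision rule: pleiotropy is flagged when the intercept's two-sided
#' p-value falls below `alpha`.
#'
#' @param instruments An `mr_instruments` table with at least 3 kept rows.
#' @param alpha Verdict level; default 0.05.
#' @return List with `estimate`, `se`, `pvalue`, `df` and logical
#'   `pleiotropy_detected`.
#' @export
egger_intercept_test <- function(instruments, alpha = 0.05) {
  fit <- mr_egger(instruments)
  rec <- fit$model_detail$intercept
  rec$pleiotropy_detected <- rec$pvalue < alpha
  rec
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted heterogeneity of the per-SNP Wald ratios about the fitted
#' model, `Q = sum w_j (theta_j - fitted_j)^2` with weights
#' `beta_exp^2 / se_out^2`. About the IVW fit the fitted value is the
#' constant IVW estimate (J - 1 df); about the Egger fit it is the fitted
#' line expressed on the ratio scale (J - 2 df). The p-value is the upper
#' chi-square tail; under instrument homogeneity Q has mean df.
#'
#' @param instruments An `mr_instruments` table.
#' @param about `"ivw"` (needs >= 2 instruments) or `"egger"` (>= 3).
#' @return List with `Q`, `df`, `pvalue`, `about`.
#' @export
cochran_q <- function(instruments, about = c("ivw", "egger")) {
  about <- match.arg(about)
  s <- instrument_series(instruments)
  min_j <- if (about == "ivw") 2L else 3L
  if (s$J < min_j) {
    stop("Cochran's Q about ", about, " requires at least ", min_j,
         " instruments", call. = FALSE)
  }
  r <- ratio_series(s)
  if (about == "ivw") {
    beta <- sum(r$w * r$theta) / sum(r$w)
    q <- sum(r$w * (r$theta - beta)^2)
    df <- s$J - 1L
  } else {
    fit <- mr_egger(instruments)
    int <- fit$model_detail$intercept$estimate
    # ratio-scale fitted value: (intercept + slope * |x|) / |x|; the Wald
    # ratio y/x is itself orientation-invariant
    theta_hat <- int / abs(s$x) + fit$beta
    q <- sum(r$w * (r$theta - theta_hat)^2)
    df <- s$J - 2L
  }
  list(Q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE),
       about = about)
}

# Leave-one-out IVW estimates from running sums (fixed-effect algebra,
# optionally re-inflated for the multiplicative random-effects model).
loo_ivw_estimates <- function(theta, w, model = "random") {
  J <- length(theta)
  S <- sum(w * theta)
  W <- sum(w)
  beta_loo <- (S - w * theta) / (W - w)
  se_fixed <- sqrt(1 / (W - w))
  if (model == "random" && J > 2L) {
    se <- vapply(seq_len(J), function(j) {
      q_j <- sum(w[-j] * (theta[-j] - beta_loo[j])^2)
      se_fixed[j] * sqrt(max(1, q_j / (J - 2L)))
    }, numeric(1))
  } else {
    se <- se_fixed
  }
  list(beta = beta_loo, se = se)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect with each instrument excluded in turn. The
#' influential verdict is true when any single exclusion flips the sign
#' of the estimate or moves its p-value across `alpha`.
#'
#' @param instruments An `mr_instruments` table with at least 2 kept rows.
#' @param model IVW effects model, `"random"` or `"fixed"`.
#' @param alpha Significance level for the verdict; default 0.05.
#' @return List with `table` (one row per excluded SNP: `snp_id`, `beta`,
#'   `se`, `pvalue`), `full` (the all-instrument estimate), logical
#'   `influential`, and `influential_snps`.
#' @export
leave_one_out <- function(instruments, model = c("random", "fixed"),
                          alpha = 0.05) {
  model <- match.arg(model)
  s <- instrument_series(instruments)
  if (s$J < 2L) {
    stop("leave-one-out requires at least 2 instruments", call. = FALSE)
  }
  r <- ratio_series(s)
  full <- mr_ivw(instruments, model = model)
  loo <- loo_ivw_estimates(r$theta, r$w, model = model)
  pvalue <- 2 * stats::pnorm(-abs(loo$beta / loo$se))
  tab <- data.frame(snp_id = s$snp_id, beta = loo$beta, se = loo$se,
                    pvalue = pvalue, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  flips_sign <- sign(tab$beta) != sign(full$beta)
  crosses_alpha <- (tab$pvalue < alpha) != (full$pvalue < alpha)
  influential <- flips_sign | crosses_alpha
  list(table = tab, full = full,
       influential = any(influential),
       influential_snps = s$snp_id[influential])
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy through the residual sum of squares.
#' For each SNP the residual is taken about the leave-one-out IVW fit,
#' `r_j = beta_out_j - beta_exp_j * theta_loo_j`; the observed global
#' statistic is `RSS = sum r_j^2 / se_out_j^2`. A parametric null
#' distribution is built by redrawing each outcome effect from a normal
#' law centred at its leave-one-out fitted value with its reported
#' standard error and recomputing RSS (including the leave-one-out fits).
#' Empirical p-values use the add-one rule `(1 + #exceedances)/(n_sim+1)`.
#' Per-SNP outlier p-values compare each observed squared standardised
#' residual with its simulated distribution, Bonferroni-adjusted across
#' instruments; the distortion test compares the IVW estimate with and
#' without the flagged outliers against random outlier sets of the same
#' size.
#'
#' @param instruments An `mr_instruments` table with at least 4 kept rows.
#' @param n_sim Number of parametric simulations; at least 1000.
#' @param seed Mandatory integer seed.
#' @param outlier_alpha Significance level applied to Bonferroni-adjusted
#'   per-SNP p-values; default 0.05.
#' @param distortion Run the distortion test when outliers are found.
#' @param n_distortion Random outlier-set draws for the distortion null.
#' @return An `mr_presso` list: `global_rss`, `global_pvalue`,
#'   `outlier_pvalues` (adjusted), `outlier_indices`, `outlier_snps`,
#'   `distortion` (list or `NA` when not applicable), `n_sim`, `seed`.
#' @export
mr_presso <- function(instruments, n_sim = 1000, seed,
                      outlier_alpha = 0.05, distortion = TRUE,
                      n_distortion = 500) {
  s <- instrument_series(instruments)
  if (s$J < 4L) {
    stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  }
  if (n_sim < 1000) {
    stop("MR-PRESSO requires n_sim >= 1000", call. = FALSE)
  }
  r <- ratio_series(s)
  J <- s$J
  loo <- loo_ivw_estimates(r$theta, r$w, model = "fixed")
  resid_obs <- s$y - s$x * loo$beta
  t_obs <- resid_obs^2 / s$sy^2
  rss_obs <- sum(t_obs)

  with_seed(seed, {
    # n_sim x J matrix of outcome draws about the leave-one-out fits
    mu <- s$x * loo$beta
    ystar <- matrix(stats::rnorm(n_sim * J, mean = rep(mu, each = n_sim),
                                 sd = rep(s$sy, each = n_sim)),
                    nrow = n_sim, ncol = J)
    wx_sy2 <- s$x / s$sy^2            # so that ystar %*% wx_sy2 = sum w theta*
    W <- sum(r$w)
    Sstar <- as.vector(ystar %*% wx_sy2)
    # leave-one-out IVW per simulated dataset, vectorised over sims
    beta_loo_star <- (matrix(Sstar, n_sim, J) -
                        sweep(ystar, 2, s$x / s$sy^2, `*`)) /
      matrix(W - r$w, n_sim, J, byrow = TRUE)
    resid_star <- ystar - sweep(beta_loo_star, 2, s$x, `*`)
    t_star <- sweep(resid_star^2, 2, s$sy^2, `/`)
    rss_star <- rowSums(t_star)
    global_pvalue <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    outlier_raw <- (1 + colSums(t_star >= matrix(t_obs, n_sim, J,
                                                 byrow = TRUE))) / (n_sim + 1)
    outlier_adj <- pmin(1, outlier_raw * J)
    outlier_idx <- which(outlier_adj < outlier_alpha)

    dist_res <- NA
    if (distortion && length(outlier_idx) > 0L && length(outlier_idx) < J) {
      beta_all <- sum(r$w * r$theta) / W
      keep_idx <- setdiff(seq_len(J), outlier_idx)
      beta_no_out <- sum(r$w[keep_idx] * r$theta[keep_idx]) /
        sum(r$w[keep_idx])
      d_obs <- (beta_no_out - beta_all) / abs(beta_no_out)
      d_null <- vapply(seq_len(n_distortion), function(b) {
        drop_idx <- sample.int(J, length(outlier_idx))
        ki <- setdiff(seq_len(J), drop_idx)
        beta_sub <- sum(r$w[ki] * r$theta[ki]) / sum(r$w[ki])
        (beta_sub - beta_all) / abs(beta_sub)
      }, numeric(1))
      dist_res <- list(
        beta_all = beta_all, beta_outlier_corrected = beta_no_out,
        distortion = d_obs,
        pvalue = (1 + sum(abs(d_null) >= abs(d_obs))) / (n_distortion + 1))
    }
    structure(list(global_rss = rss_obs, global_pvalue = global_pvalue,
                   outlier_pvalues = stats::setNames(outlier_adj, s$snp_id),
                   outlier_indices = outlier_idx,
                   outlier_snps = s$snp_id[outlier_idx],
                   distortion = dist_res,
                   n_sim = n_sim, seed = seed),
              class = "mr_presso")
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, p = %.4g (%d simulations)\n",
              x$global_rss, x$global_pvalue, x$n_sim))
  if (length(x$outlier_indices)) {
    cat("Outliers:", paste(x$outlier_snps, collapse = ", "), "\n")
    if (is.list(x$distortion)) {
      cat(sprintf("Distortion: %.3g%% (p = %.4g)\n",
                  100 * x$distortion$distortion, x$distortion$pvalue))
    }
  } else {
    cat("No outliers detected\n")
  }
  invisible(x)
}

#' Full sensitivity battery for one instrument set
#'
#' Bundles the Egger intercept test, Cochran's Q about the IVW and Egger
#' fits, MR-PRESSO, and the leave-one-out analysis, with pass/fail
#' verdicts at `alpha`. Components whose instrument-count preconditions
#' are not met are reported as `NULL` rather than raising.
#'
#' @param instruments An `mr_instruments` table.
#' @param alpha Verdict level; default 0.05.
#' @param presso Run MR-PRESSO (needs >= 4 instruments).
#' @param presso_n_sim Simulations for MR-PRESSO (>= 1000).
#' @param seed Mandatory when MR-PRESSO runs.
#' @param ivw_model Effects model used for the leave-one-out estimates.
#' @return An `mr_sensitivity` list with elements `egger_intercept`,
#'   `q_ivw`, `q_egger`, `presso`, `loo`, and `verdicts`
#'   (`pleiotropy_detected`, `heterogeneity_detected`, `influential_snps`).
#' @export
mr_sensitivity <- function(instruments, alpha = 0.05, presso = TRUE,
                           presso_n_sim = 1000, seed = NULL,
                           ivw_model = "random") {
  J <- nrow(kept_instruments(instruments))
  egger_rec <- if (J >= 3L) egger_intercept_test(instruments, alpha) else NULL
  q_ivw <- if (J >= 2L) cochran_q(instruments, "ivw") else NULL
  q_egger <- if (J >= 3L) cochran_q(instruments, "egger") else NULL
  presso_rec <- NULL
  if (presso && J >= 4L) {
    if (is.null(seed)) {
      stop("`seed` is mandatory when MR-PRESSO is requested", call. = FALSE)
    }
    presso_rec <- mr_presso(instruments, n_sim = presso_n_sim, seed = seed)
  }
  loo <- if (J >= 2L) leave_one_out(instruments, model = ivw_model,
                                    alpha = alpha) else NULL
  verdicts <- list(
    pleiotropy_detected = isTRUE(egger_rec$pleiotropy_detected) ||
      (is.list(presso_rec) && presso_rec$global_pvalue < alpha),
    heterogeneity_detected = isTRUE(!is.null(q_ivw) && q_ivw$pvalue < alpha),
    influential_snps = if (!is.null(loo)) loo$influential_snps else character(0)
  )
  structure(list(egger_intercept = egger_rec, q_ivw = q_ivw,
                 q_egger = q_egger, presso = presso_rec, loo = loo,
                 alpha = alpha, verdicts = verdicts),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report (alpha =", x$alpha, ")\n")
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept: %.4g (se %.4g), p = %.4g -> %s\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pvalue,
                if (x$egger_intercept$pleiotropy_detected)
                  "directional pleiotropy" else "no directional pleiotropy"))
  }
  for (qn in c("q_ivw", "q_egger")) {
    q <- x[[qn]]
    if (!is.null(q)) {
      cat(sprintf("  Cochran's Q (%s): %.4g on %d df, p = %.4g\n",
                  q$about, q$Q, q$df, q$pvalue))
    }
  }
  if (is.list(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.4g; %d outlier(s)\n",
                x$presso$global_pvalue, length(x$presso$outlier_indices)))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("  Leave-one-out: %s\n",
                if (x$loo$influential)
                  paste("influential:",
                        paste(x$loo$influential_snps, collapse = ", "))
                else "no single-SNP influence"))
  }
  invisible(x)
}
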