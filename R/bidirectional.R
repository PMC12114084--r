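# Orchestration of forward and reverse analyses across many traits.

#' Analysis configuration for a two-sample MR pipeline
#'
#' Collects every tunable of the pipeline stages with the defaults used
#' throughout: candidate threshold p < 5e-6 (strict), clumping at LD
#' r-squared < 0.001 within 10,000 kb, palindrome ambiguity limit 0.42,
#' weak-instrument removal at F < 10, multiplicative random-effects IVW,
#' and a 1000-simulation MR-PRESSO.
#'
#' @param p_threshold,clump_r2,clump_kb,ld_source See [clump_config()].
#' @param palindrome_eaf_limit See [harmonize()].
#' @param f_min Weak-instrument threshold; see [filter_weak()].
#' @param methods Estimators to run; see [mr_fit()].
#' @param ivw_model `"random"` or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso Run MR-PRESSO in the sensitivity battery.
#' @param presso_n_sim MR-PRESSO simulations (>= 1000).
#' @param alpha Reporting/verdict significance level.
#' @param seed Base integer seed; per-analysis seeds are derived from it
#'   deterministically.
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold = 5e-6, clump_r2 = 0.001,
                      clump_kb = 10000, ld_source = NULL,
                      palindrome_eaf_limit = 0.42, f_min = 10,
                      methods = c("ivw", "egger", "weighted_median"),
                      ivw_model = "random", n_boot = 5000,
                      presso = TRUE, presso_n_sim = 1000,
                      alpha = 0.05, seed = 1) {
  structure(list(
    clump = clump_config(p_threshold, clump_r2, clump_kb, ld_source),
    palindrome_eaf_limit = palindrome_eaf_limit, f_min = f_min,
    methods = methods, ivw_model = ivw_model, n_boot = n_boot,
    presso = presso, presso_n_sim = presso_n_sim,
    alpha = alpha, seed = as.integer(seed)), class = "mr_config")
}

not_analyzable <- function(exposure_id, outcome_id, reason, attrition) {
  structure(list(status = "not_analyzable",
                 exposure_id = exposure_id, outcome_id = outcome_id,
                 reason = reason, attrition = attrition),
            class = "mr_pair_result")
}

#' Run the full pipeline for one exposure/outcome pair
#'
#' Executes p-value selection, clumping, harmonization, weak-instrument
#' filtering, the requested estimators, and the sensitivity battery,
#' recording the SNP count after every stage. Statistical insufficiency
#' (no SNP below threshold, no overlap, everything weak) yields a
#' structured `"not_analyzable"` result rather than an error, so batch
#' runs never abort on one trait.
#'
#' @param exposure,outcome Validated `trait_table`s.
#' @param config An [mr_config()].
#' @param seed Integer seed for the stochastic components; defaults to
#'   `config$seed`.
#' @return An `mr_pair_result` list: `status` (`"ok"` or
#'   `"not_analyzable"`), `fit` (an `mr_fit`), `sensitivity`,
#'   `instruments`, and the stage-by-stage `attrition` log.
#' @export
run_pair <- function(exposure, outcome, config = mr_config(),
                     seed = config$seed) {
  stopifnot(inherits(config, "mr_config"))
  ex_id <- trait_id(exposure); ou_id <- trait_id(outcome)
  attrition <- c(input = nrow(exposure))

  selected <- select_by_pvalue(exposure, config$clump$p_threshold)
  attrition["p_selected"] <- nrow(selected)
  if (nrow(selected) == 0L) {
    return(not_analyzable(ex_id, ou_id, "no SNP below p threshold", attrition))
  }
  clumped <- clump(selected, config$clump)
  attrition["clumped"] <- nrow(clumped)

  inst <- tryCatch(
    harmonize(clumped, outcome,
              palindrome_eaf_limit = config$palindrome_eaf_limit),
    error = function(e) e)
  if (inherits(inst, "error")) {
    attrition["harmonized"] <- 0L
    return(not_analyzable(ex_id, ou_id, conditionMessage(inst), attrition))
  }
  attrition["harmonized"] <- nrow(kept_instruments(inst))
  if (attrition["harmonized"] == 0L) {
    return(not_analyzable(ex_id, ou_id, "no harmonizable instruments",
                          attrition))
  }
  inst <- tryCatch(suppressMessages(filter_weak(inst, config$f_min)),
                   error = function(e) e)
  if (inherits(inst, "error")) {
    attrition["strength_filtered"] <- 0L
    return(not_analyzable(ex_id, ou_id, conditionMessage(inst), attrition))
  }
  attrition["strength_filtered"] <- nrow(kept_instruments(inst))

  fit <- mr_fit(inst, methods = config$methods, ivw_model = config$ivw_model,
                n_boot = config$n_boot, seed = seed)
  J <- fit$n_snp
  sens <- if (J >= 2L) {
    mr_sensitivity(inst, alpha = config$alpha, presso = config$presso,
                   presso_n_sim = config$presso_n_sim, seed = seed + 1L,
                   ivw_model = config$ivw_model)
  } else NULL
  structure(list(status = "ok", exposure_id = ex_id, outcome_id = ou_id,
                 fit = fit, sensitivity = sens, instruments = inst,
                 attrition = attrition),
            class = "mr_pair_result")
}

#' @export
print.mr_pair_result <- function(x, ...) {
  cat(sprintf("MR pair %s -> %s: %s\n", x$exposure_id, x$outcome_id,
              x$status))
  if (x$status == "ok") print(x$fit) else cat("  reason:", x$reason, "\n")
  cat("  attrition:",
      paste(names(x$attrition), x$attrition, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Define a bidirectional analysis plan
#'
#' @param exposures,outcomes Lists of `trait_table`s (a single table is
#'   accepted). In the reverse direction the roles are swapped literally.
#' @param direction `"forward"`, `"reverse"`, or `"both"`.
#' @param config An [mr_config()].
#' @param alpha Significance flag level for the result table; defaults to
#'   `config$alpha`.
#' @return An `mr_plan` list.
#' @export
mr_plan <- function(exposures, outcomes, direction = c("both", "forward",
                                                       "reverse"),
                    config = mr_config(), alpha = config$alpha) {
  direction <- match.arg(direction)
  if (inherits(exposures, "trait_table")) exposures <- list(exposures)
  if (inherits(outcomes, "trait_table")) outcomes <- list(outcomes)
  if (length(exposures) == 0L || length(outcomes) == 0L) {
    stop("a plan needs at least one exposure and one outcome", call. = FALSE)
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 direction = direction, config = config, alpha = alpha),
            class = "mr_plan")
}

pair_rows <- function(res, direction, alpha) {
  if (res$status != "ok") {
    return(data.frame(
      id = res$exposure_id, outcome = res$outcome_id,
      direction = direction, method = NA_character_, n_snp = 0L,
      beta = NA_real_, se = NA_real_, pvalue = NA_real_, or = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, significant = FALSE,
      status = "not_analyzable", reason = res$reason,
      stringsAsFactors = FALSE))
  }
  df <- as.data.frame(res$fit)
  data.frame(id = res$exposure_id, outcome = res$outcome_id,
             direction = direction, method = df$method, n_snp = df$n_snp,
             beta = df$beta, se = df$se, pvalue = df$pvalue, or = df$or,
             ci_low = df$ci_low, ci_high = df$ci_high,
             significant = df$pvalue < alpha, status = "ok",
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Run a bidirectional analysis plan
#'
#' Runs [run_pair()] for every exposure/outcome combination in the
#' requested direction(s); the reverse direction literally swaps the
#' trait roles. Results are assembled into one row per (exposure,
#' outcome, direction, method), sorted by direction then p-value, with a
#' `significant` flag at `plan$alpha` and a Benjamini-Hochberg adjusted
#' column `p_bh` (computed per direction and method) for users who want
#' multiplicity control across taxa; the `significant` flag itself uses
#' raw p-values.
#'
#' @param plan An [mr_plan()].
#' @return An `mr_plan_result` list: `results` (the report table),
#'   `details` (every `mr_pair_result`), and `log` (one row per analysis
#'   attempted).
#' @export
run_plan <- function(plan) {
  stopifnot(inherits(plan, "mr_plan"))
  directions <- switch(plan$direction,
                       forward = "forward", reverse = "reverse",
                       both = c("forward", "reverse"))
  details <- list()
  rows <- list()
  log <- list()
  counter <- 0L
  for (direction in directions) {
    exps <- if (direction == "forward") plan$exposures else plan$outcomes
    outs <- if (direction == "forward") plan$outcomes else plan$exposures
    for (e in exps) {
      for (o in outs) {
        counter <- counter + 1L
        seed_i <- (plan$config$seed + 104729L * counter) %% 2147483647L
        res <- run_pair(e, o, plan$config, seed = seed_i)
        key <- sprintf("%03d|%s|%s|%s", counter, direction,
                       trait_id(e), trait_id(o))
        details[[key]] <- res
        rows[[key]] <- pair_rows(res, direction, plan$alpha)
        log[[key]] <- data.frame(direction = direction,
                                 exposure = trait_id(e),
                                 outcome = trait_id(o),
                                 status = res$status,
                                 seed = seed_i,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(match(results$direction, c("forward", "reverse")),
                           results$pvalue), , drop = FALSE]
  rownames(results) <- NULL
  results$p_bh <- NA_real_
  ok <- results$status == "ok"
  for (grp in split(which(ok), paste(results$direction[ok],
                                     results$method[ok]))) {
    results$p_bh[grp] <- stats::p.adjust(results$pvalue[grp], "BH")
  }
  structure(list(results = results, details = details,
                 log = do.call(rbind, c(log, list(make.row.names = FALSE)))),
            class = "mr_plan_result")
}

#' @export
print.mr_plan_result <- function(x, digits = 4, ...) {
  cat("MR plan:", nrow(x$log), "analyses\n")
  df <- x$results
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Shared-instrument report across traits
#'
#' For every pair of traits, counts and lists the instrument SNPs they
#' share after selection — the situation where two taxa are instrumented
#' by the same variants and their estimates are not independent.
#'
#' @param instrument_sets Named list: one character vector of SNP ids per
#'   trait.
#' @return `data.frame` with columns `trait_a`, `trait_b`, `n_shared`,
#'   `shared_ids` (comma-separated).
#' @export
shared_snp_report <- function(instrument_sets) {
  if (length(instrument_sets) < 2L) {
    stop("at least two traits are required", call. = FALSE)
  }
  ids <- names(instrument_sets)
  combos <- utils::combn(seq_along(ids), 2L)
  out <- apply(combos, 2L, function(idx) {
    shared <- intersect(instrument_sets[[idx[1]]], instrument_sets[[idx[2]]])
    data.frame(trait_a = ids[idx[1]], trait_b = ids[idx[2]],
               n_shared = length(shared),
               shared_ids = paste(shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
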