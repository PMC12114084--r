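# Instrument selection, allele harmonization, and instrument-strength
# screening.

#' Select candidate instruments by p-value threshold
#'
#' Keeps records with `pvalue` strictly below `threshold` (the comparison
#' is `<`, not `<=`), preserving input order.
#'
#' @param table A `trait_table`.
#' @param threshold Significance cutoff; default `5e-6`.
#' @return A `trait_table` of the selected records. When nothing passes,
#'   the (empty) result carries attribute `zero_instruments = TRUE`.
#' @export
select_by_pvalue <- function(table, threshold = 5e-6) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  out <- retable(table[table$pvalue < threshold, , drop = FALSE], table)
  rownames(out) <- NULL
  if (nrow(out) == 0L) attr(out, "zero_instruments") <- TRUE
  out
}

#' Clumping configuration
#'
#' Defaults mirror standard two-sample MR instrument selection for
#' microbiome exposures: candidate threshold p < 5e-6, LD pruning at
#' r-squared < 0.001 within a 10,000 kb window.
#'
#' @param p_threshold Significance cutoff for candidate instruments.
#' @param ld_r2_max Maximum tolerated pairwise LD r-squared.
#' @param window_kb Clumping window in kilobases.
#' @param ld_source Optional `data.frame` with columns `snp_id_a`,
#'   `snp_id_b`, `r2` giving pairwise LD. Pairs absent from the table are
#'   treated as uncorrelated. When `NULL`, any same-chromosome pair within
#'   the window is conservatively treated as correlated.
#' @return A `clump_config` list.
#' @export
clump_config <- function(p_threshold = 5e-6, ld_r2_max = 0.001,
                         window_kb = 10000, ld_source = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            ld_r2_max >= 0, ld_r2_max <= 1, window_kb > 0)
  if (!is.null(ld_source)) {
    stopifnot(all(c("snp_id_a", "snp_id_b", "r2") %in% names(ld_source)))
  }
  structure(list(p_threshold = p_threshold, ld_r2_max = ld_r2_max,
                 window_kb = window_kb, ld_source = ld_source),
            class = "clump_config")
}

# Pairwise LD lookup; unknown pairs are 0.
ld_lookup <- function(ld_source) {
  env <- new.env(parent = emptyenv(), size = max(29L, 2L * nrow(ld_source)))
  for (i in seq_len(nrow(ld_source))) {
    a <- ld_source$snp_id_a[i]; b <- ld_source$snp_id_b[i]
    assign(paste(a, b, sep = "\r"), ld_source$r2[i], envir = env)
    assign(paste(b, a, sep = "\r"), ld_source$r2[i], envir = env)
  }
  function(a, b) {
    key <- paste(a, b, sep = "\r")
    if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else 0
  }
}

#' Greedy LD clumping of candidate instruments
#'
#' Sorts records by ascending p-value (ties broken by chromosome then
#' position for determinism), repeatedly accepts the best remaining SNP and
#' removes every unaccepted SNP on the same chromosome within `window_kb`
#' whose LD r-squared with it is at least `ld_r2_max`. Without an LD
#' source every same-chromosome SNP inside the window is treated as
#' correlated and removed — a conservative reading of near-independence.
#'
#' @param table A `trait_table` with non-missing `chrom`/`pos`.
#' @param config A [clump_config()].
#' @return A `trait_table` of accepted SNPs in genomic order.
#' @export
clump <- function(table, config = clump_config()) {
  stopifnot(inherits(config, "clump_config"))
  if (nrow(table) == 0L) return(table)
  if (anyNA(table$chrom) || anyNA(table$pos)) {
    stop("clumping requires chrom and pos for every record", call. = FALSE)
  }
  df <- as.data.frame(table)
  ord <- order(df$pvalue, as.character(df$chrom), df$pos)
  alive <- rep(TRUE, nrow(df))
  accepted <- logical(nrow(df))
  ld <- if (!is.null(config$ld_source)) ld_lookup(config$ld_source) else NULL
  window_bp <- config$window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    near <- alive & !accepted & df$chrom == df$chrom[i] &
      abs(df$pos - df$pos[i]) <= window_bp
    if (!is.null(ld)) {
      idx <- which(near)
      r2 <- vapply(idx, function(j) ld(df$snp_id[i], df$snp_id[j]), numeric(1))
      near[idx] <- r2 >= config$ld_r2_max
    }
    alive[near] <- FALSE
  }
  out <- df[accepted, , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  retable(out, table)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic_pair <- function(a1, a2) .COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared SNP onto the exposure's
#' effect allele. Matching allele pairs are copied; swapped pairs have the
#' outcome beta negated and frequency reflected (`flipped`); strand
#' complements are complemented first (`strand_corrected`); palindromic
#' A/T and C/G pairs are kept only when both allele frequencies are
#' unambiguous — outside `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`
#' — and fall on the same side of 0.5 after label alignment, otherwise the
#' SNP is dropped with a reason; incompatible allele pairs are dropped.
#'
#' Per-SNP variance explained and F-statistics are filled in from the
#' exposure records where the effect-allele frequency is available.
#'
#' @param exposure,outcome Validated `trait_table`s sharing SNP ids.
#' @param palindrome_eaf_limit Ambiguity band half-width; default 0.42
#'   (drop when either frequency lies in \[0.42, 0.58\]).
#' @return An `mr_instruments` data frame with one row per shared SNP:
#'   exposure and outcome effects on the common orientation, flags
#'   (`flipped`, `strand_corrected`, `palindromic`), a `keep` mask with
#'   `dropped_reason`, and instrument-strength columns `r2`, `f_stat`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stop("no shared SNPs between exposure '", trait_id(exposure),
         "' and outcome '", trait_id(outcome), "'", call. = FALSE)
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp_id), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp_id), ]
  J <- length(shared)

  ea_e <- ex$effect_allele; oa_e <- ex$other_allele
  ea_o <- ou$effect_allele; oa_o <- ou$other_allele
  pal <- is_palindromic_pair(ea_e, oa_e)

  beta_out <- ou$beta
  eaf_out <- ou$eaf
  flipped <- rep(FALSE, J)
  strand <- rep(FALSE, J)
  keep <- rep(TRUE, J)
  reason <- rep(NA_character_, J)

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  c_same <- .COMPLEMENT[ea_o] == ea_e & .COMPLEMENT[oa_o] == oa_e
  c_swap <- .COMPLEMENT[ea_o] == oa_e & .COMPLEMENT[oa_o] == ea_e

  # For palindromic pairs strand complementation is indistinguishable from
  # label identity, so only label alignment applies before the EAF rule.
  do_flip <- (swap & !same) | (!pal & !same & !swap & c_swap)
  do_strand <- !pal & !same & !swap & (c_same | c_swap)
  incompatible <- !(same | swap | (!pal & (c_same | c_swap)))

  beta_out[do_flip] <- -beta_out[do_flip]
  eaf_out[do_flip] <- 1 - eaf_out[do_flip]
  flipped[do_flip] <- TRUE
  strand[do_strand] <- TRUE
  keep[incompatible] <- FALSE
  reason[incompatible] <- "incompatible alleles"

  # Palindrome resolution by allele frequency after label alignment.
  lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
  pal_check <- pal & keep
  missing_eaf <- pal_check & (is.na(ex$eaf) | is.na(eaf_out))
  keep[missing_eaf] <- FALSE
  reason[missing_eaf] <- "palindrome with missing EAF"
  pal_check <- pal_check & !missing_eaf
  ambiguous <- pal_check & (
    (ex$eaf >= lo & ex$eaf <= hi) | (eaf_out >= lo & eaf_out <= hi) |
      ((ex$eaf < 0.5) != (eaf_out < 0.5))
  )
  keep[ambiguous] <- FALSE
  reason[ambiguous] <- "ambiguous palindrome"

  out <- data.frame(
    snp_id = shared,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_e, other_allele = oa_e,
    beta_exp = ex$beta, se_exp = ex$se, pvalue_exp = ex$pvalue,
    n_exp = ex$n, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = ou$se, pvalue_out = ou$pvalue,
    n_out = ou$n, eaf_out = eaf_out,
    flipped = flipped, strand_corrected = strand, palindromic = pal,
    keep = keep, dropped_reason = reason,
    stringsAsFactors = FALSE
  )
  out$r2 <- ifelse(is.na(out$eaf_exp), NA_real_,
                   out$beta_exp^2 / (out$beta_exp^2 + out$se_exp^2 * out$n_exp))
  out$f_stat <- ifelse(is.na(out$r2), NA_real_,
                       out$r2 * (out$n_exp - 2) / (1 - out$r2))
  rownames(out) <- NULL
  structure(out,
            exposure_id = trait_id(exposure),
            outcome_id = trait_id(outcome),
            class = c("mr_instruments", "data.frame"))
}

#' Rows of an instrument table that survived harmonization and filtering
#' @param instruments An `mr_instruments` table.
#' @return The subset with `keep == TRUE`.
#' @export
kept_instruments <- function(instruments) {
  out <- instruments[instruments$keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained
#'
#' Proportion of trait variance explained by one SNP,
#' \deqn{R^2 = \frac{2\beta^2 \mathrm{EAF}(1-\mathrm{EAF})}
#'   {2\beta^2 \mathrm{EAF}(1-\mathrm{EAF}) +
#'    2\,\mathrm{SE}^2 N \,\mathrm{EAF}(1-\mathrm{EAF})},}
#' which reduces algebraically to \eqn{\beta^2/(\beta^2 + SE^2 N)}: the
#' frequency terms cancel, but EAF is still required so that a record
#' without it fails loudly instead of pretending to carry strength
#' information.
#'
#' @param beta Per-allele effect (ln(OR) for a binary trait).
#' @param eaf Effect-allele frequency in (0,1); mandatory.
#' @param se Standard error of `beta`, positive.
#' @param n GWAS sample size, at least 3.
#' @return Variance explained in `[0, 1)`. Vectorised.
#' @export
#' @examples
#' variance_explained(beta = 0.1, eaf = 0.5, se = 0.01, n = 1e4)
variance_explained <- function(beta, eaf, se, n) {
  if (anyNA(eaf)) {
    stop("effect-allele frequency (eaf) is required and missing", call. = FALSE)
  }
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0), all(n >= 3))
  pq <- eaf * (1 - eaf)
  num <- 2 * beta^2 * pq
  num / (num + 2 * se^2 * n * pq)
}

#' Instrument-strength F-statistic
#'
#' \deqn{F = \frac{R^2 (N - 2)}{1 - R^2}} for a single-SNP instrument.
#' Values below 10 conventionally mark a weak instrument.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n GWAS sample size, at least 3.
#' @return F-statistic, non-negative. Vectorised.
#' @export
#' @examples
#' f_statistic(0.01, 102) # 1.0101...
f_statistic <- function(r2, n) {
  if (any(r2 >= 1 | r2 < 0)) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(all(n >= 3))
  r2 * (n - 2) / (1 - r2)
}

#' Remove weak instruments by F-statistic
#'
#' Flags instruments with `f_stat < f_min` as dropped (`dropped_reason =
#' "weak"`). The conventional threshold is F < 10.
#'
#' @param instruments An `mr_instruments` table with `f_stat` computed for
#'   every kept row.
#' @param f_min Weak-instrument threshold; default 10.
#' @return The instrument table with weak rows unflagged from `keep`;
#'   attribute `n_weak` counts removals.
#' @export
filter_weak <- function(instruments, f_min = 10) {
  active <- instruments$keep
  if (any(active & is.na(instruments$f_stat))) {
    stop("f_stat missing for some instruments; supply EAF so strength can ",
         "be computed", call. = FALSE)
  }
  weak <- active & instruments$f_stat < f_min
  instruments$keep[weak] <- FALSE
  instruments$dropped_reason[weak] <- "weak"
  if (!any(instruments$keep)) {
    stop("all instruments are weak (F < ", f_min, ")", call. = FALSE)
  }
  if (any(weak)) {
    message("removed ", sum(weak), " weak instrument(s): ",
            paste(instruments$snp_id[weak], collapse = ", "))
  }
  attr(instruments, "n_weak") <- sum(weak)
  instruments
}
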