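# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A small well-formed summary-statistics data.frame.
make_sumstats_df <- function(n = 3, trait = "t") {
  data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = 1e6 * seq_len(n) * 30,
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    eaf = seq(0.15, 0.45, length.out = n),
    beta = seq(0.05, 0.2, length.out = n),
    se = rep(0.02, n),
    pvalue = rep(1e-7, n),
    n = rep(15000L, n),
    stringsAsFactors = FALSE
  )
}

make_trait_table <- function(n = 3, trait = "t", ...) {
  df <- make_sumstats_df(n, trait)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  trait_table(df, trait_id = trait)
}

# Hand-built harmonized instrument table (already aligned), bypassing
# harmonize(): useful for estimator-level tests with chosen numbers.
make_instruments <- function(beta_exp, beta_out, se_exp = NULL, se_out = NULL,
                             eaf = NULL, n_exp = 20000) {
  J <- length(beta_exp)
  se_exp <- se_exp %||% rep(0.01, J)
  se_out <- se_out %||% rep(0.01, J)
  eaf <- eaf %||% rep(0.3, J)
  structure(data.frame(
    snp_id = sprintf("rs%d", seq_len(J)),
    chrom = as.character(rep_len(1:22, J)),
    pos = 1e6 * seq_len(J),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, pvalue_exp = 1e-8,
    n_exp = n_exp, eaf_exp = eaf,
    beta_out = beta_out, se_out = se_out, pvalue_out = 0.01,
    n_out = 170000, eaf_out = eaf,
    flipped = FALSE, strand_corrected = FALSE, palindromic = FALSE,
    keep = TRUE, dropped_reason = NA_character_,
    r2 = beta_exp^2 / (beta_exp^2 + se_exp^2 * n_exp),
    f_stat = NA_real_,
    stringsAsFactors = FALSE
  ), exposure_id = "exp", outcome_id = "out",
  class = c("mr_instruments", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent generic WLS solve (X'WX)^-1 X'Wy used as the oracle for IVW
# (origin-constrained) and Egger (free intercept).
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)
}
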