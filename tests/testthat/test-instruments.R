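test_that("p-value selection is strict and order-preserving", {
  tt <- make_trait_table(3, pvalue = c(1e-7, 4.9e-6, 5e-6))
  sel <- select_by_pvalue(tt, 5e-6)
  expect_equal(sel$snp_id, c("rs1", "rs2"))   # 5e-6 itself excluded
  expect_equal(nrow(select_by_pvalue(tt, 1)), 3L)
  none <- select_by_pvalue(tt, 1e-9)
  expect_equal(nrow(none), 0L)
  expect_true(attr(none, "zero_instruments"))
})

test_that("distance clumping keeps the best SNP per window", {
  one <- make_trait_table(1)
  expect_equal(nrow(clump(one)), 1L)

  # two SNPs 5,000 kb apart on one chromosome: only the smaller p survives
  df <- make_sumstats_df(2)
  df$chrom <- "1"; df$pos <- c(1e6, 1e6 + 5e6)
  df$pvalue <- c(1e-8, 1e-7)
  tt <- trait_table(df, trait_id = "t")
  kept <- clump(tt)
  expect_equal(kept$snp_id, "rs1")

  # 20,000 kb apart: both survive
  df$pos <- c(1e6, 1e6 + 2e7)
  kept2 <- clump(trait_table(df, trait_id = "t"))
  expect_equal(sort(kept2$snp_id), c("rs1", "rs2"))
})

test_that("an LD table overrides the distance-only correlation rule", {
  df <- make_sumstats_df(3)
  df$chrom <- "2"; df$pos <- c(1e6, 2e6, 3e6)
  df$pvalue <- c(1e-9, 1e-8, 1e-7)
  tt <- trait_table(df, trait_id = "t")
  # rs1-rs2 correlated above threshold, rs1-rs3 and rs2-rs3 effectively
  # independent (below R^2 < 0.001)
  ld <- data.frame(snp_id_a = c("rs1", "rs1", "rs2"),
                   snp_id_b = c("rs2", "rs3", "rs3"),
                   r2 = c(0.5, 0.0005, 0.0009))
  kept <- clump(tt, clump_config(ld_source = ld))
  expect_equal(sort(kept$snp_id), c("rs1", "rs3"))
})

test_that("clump output is an independent set under the window/LD rule", {
  # brute-force pairwise check over random instances
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    df <- make_sumstats_df(n)
    df$chrom <- as.character(sample(1:3, n, replace = TRUE))
    df$pos <- sample.int(5e7, n)
    df$pvalue <- runif(n, 1e-10, 1e-5)
    tt <- trait_table(df, trait_id = "t")
    kept <- clump(tt)
    if (nrow(kept) > 1) {
      pairs <- combn(nrow(kept), 2)
      violations <- apply(pairs, 2, function(ij) {
        kept$chrom[ij[1]] == kept$chrom[ij[2]] &&
          abs(kept$pos[ij[1]] - kept$pos[ij[2]]) <= 1e7
      })
      expect_false(any(violations))
    }
    # every removed SNP must be within the window of some accepted SNP
    removed <- setdiff(df$snp_id, kept$snp_id)
    for (id in removed) {
      i <- match(id, df$snp_id)
      covered <- any(kept$chrom == df$chrom[i] &
                       abs(kept$pos - df$pos[i]) <= 1e7)
      expect_true(covered)
    }
  }
})

test_that("harmonization aligns swapped, strand-flipped and matching alleles", {
  exp_df <- make_sumstats_df(4)
  exp_df$effect_allele <- c("A", "A", "A", "A")
  exp_df$other_allele <- c("G", "G", "G", "G")
  exp_df$beta <- 0.1
  out_df <- exp_df
  # rs1 same orientation; rs2 swapped; rs3 strand complement (T/C);
  # rs4 strand complement swapped (C/T)
  out_df$effect_allele <- c("A", "G", "T", "C")
  out_df$other_allele <- c("G", "A", "C", "T")
  out_df$beta <- 0.05
  out_df$eaf <- 0.2
  ex <- trait_table(exp_df, trait_id = "e")
  ou <- trait_table(out_df, trait_id = "o")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, c(0.05, -0.05, 0.05, -0.05))
  expect_equal(h$flipped, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(h$strand_corrected, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(h$eaf_out, c(0.2, 0.8, 0.2, 0.8))
  expect_true(all(h$keep))

  # incompatible allele pair is dropped with a reason
  out_df$other_allele[1] <- "C"
  h2 <- harmonize(ex, trait_table(out_df, trait_id = "o"))
  expect_false(h2$keep[h2$snp_id == "rs1"])
  expect_match(h2$dropped_reason[h2$snp_id == "rs1"], "incompatible")
})

test_that("palindromic SNPs are resolved by allele frequency or dropped", {
  exp_df <- make_sumstats_df(3)
  exp_df$effect_allele <- c("A", "C", "A")
  exp_df$other_allele <- c("T", "G", "T")
  exp_df$eaf <- c(0.10, 0.30, 0.10)
  out_df <- exp_df
  out_df$eaf <- c(0.12, 0.50, 0.45)
  ex <- trait_table(exp_df, trait_id = "e")
  ou <- trait_table(out_df, trait_id = "o")
  h <- harmonize(ex, ou, palindrome_eaf_limit = 0.42)
  expect_true(all(h$palindromic))
  # rs1: both frequencies unambiguous, same side -> kept aligned
  expect_true(h$keep[1])
  expect_false(h$flipped[1])
  # rs2: outcome frequency exactly 0.5 -> ambiguous
  expect_false(h$keep[2])
  expect_match(h$dropped_reason[2], "ambiguous palindrome")
  # rs3: outcome frequency inside the [0.42, 0.58] band -> ambiguous
  expect_false(h$keep[3])

  # palindrome without EAF cannot be oriented and is dropped, not imputed
  out_df$eaf <- c(NA, 0.3, 0.1)
  h2 <- harmonize(ex, trait_table(out_df, trait_id = "o"))
  expect_false(h2$keep[1])
  expect_match(h2$dropped_reason[1], "missing EAF")
})

test_that("harmonization is idempotent and double-flip is the identity", {
  pair <- simulate_pair(sim_scenario(n_snp = 6, beta_causal = 0.3, seed = 4))
  h1 <- harmonize(pair$exposure, pair$outcome)
  # re-express the harmonized outcome as a trait table and re-harmonize
  out2 <- data.frame(
    snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out,
    pvalue = h1$pvalue_out, n = h1$n_out, stringsAsFactors = FALSE)
  h2 <- harmonize(pair$exposure, trait_table(out2, trait_id = "o2"))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))

  # double flip: swap outcome alleles and negate beta twice -> original
  out3 <- out2
  out3$effect_allele <- h1$other_allele
  out3$other_allele <- h1$effect_allele
  out3$beta <- -out3$beta
  out3$eaf <- 1 - out3$eaf
  h3 <- harmonize(pair$exposure, trait_table(out3, trait_id = "o3"))
  expect_true(all(h3$flipped[h3$keep]))
  expect_equal(h3$beta_out, h1$beta_out)
  expect_equal(h3$eaf_out, h1$eaf_out, tolerance = 1e-12)
})

test_that("harmonize errors when no SNPs are shared", {
  a <- make_trait_table(3)
  df <- make_sumstats_df(3)
  df$snp_id <- paste0("rs", 10:12)
  b <- trait_table(df, trait_id = "b")
  expect_error(harmonize(a, b), "no shared")
})

test_that("variance explained follows the printed formula and EAF cancels", {
  # beta 0.1, EAF 0.5, SE 0.01, N 10000: term-by-term evaluation
  beta <- 0.1; eaf <- 0.5; se <- 0.01; n <- 1e4
  pq <- eaf * (1 - eaf)
  expected <- (2 * beta^2 * pq) / (2 * beta^2 * pq + 2 * se^2 * n * pq)
  expect_equal(variance_explained(beta, eaf, se, n), expected)
  expect_equal(expected, 0.009901, tolerance = 1e-4)

  expect_equal(variance_explained(0, 0.3, 0.01, 1000), 0)
  # EAF terms cancel to machine precision
  expect_equal(variance_explained(0.1, 0.3, 0.02, 5e4),
               variance_explained(0.1, 0.7, 0.02, 5e4))
  expect_error(variance_explained(0.1, NA, 0.02, 5e4), "eaf")

  # always in [0, 1)
  set.seed(1)
  r2 <- variance_explained(rnorm(100), runif(100, 0.01, 0.99),
                           runif(100, 0.001, 0.5), 1000)
  expect_true(all(r2 >= 0 & r2 < 1))
})

test_that("F-statistic formula, monotonicity and large-F approximation", {
  expect_equal(f_statistic(0.01, 102), 0.01 * 100 / 0.99)
  expect_equal(f_statistic(0, 100), 0)
  expect_error(f_statistic(1, 100), "r2")

  r2 <- seq(0.001, 0.5, length.out = 50)
  f <- f_statistic(r2, 500)
  expect_true(all(diff(f) > 0))

  # for SE^2 N >> beta^2, F approximates the squared z-statistic within 1%
  set.seed(2)
  beta <- runif(50, 0.01, 0.05)
  se <- runif(50, 0.005, 0.02)
  n <- round(runif(50, 5e4, 2e5))
  r2 <- variance_explained(beta, 0.4, se, n)
  f <- f_statistic(r2, n)
  expect_true(all(abs(f / (beta / se)^2 - 1) < 0.01))
})

test_that("weak instruments are removed at the F < 10 rule", {
  inst <- make_instruments(c(0.004, 0.05, 0.36), c(0.01, 0.02, 0.1),
                           se_exp = rep(0.01, 3), n_exp = 20000)
  # choose exposure betas so F spans the published weak/strong range
  inst$f_stat <- c(2.153, 23.919, 1244.270)
  out <- suppressMessages(filter_weak(inst, f_min = 10))
  expect_equal(out$keep, c(FALSE, TRUE, TRUE))
  expect_equal(out$dropped_reason[1], "weak")
  expect_equal(attr(out, "n_weak"), 1L)

  # f_min = 0 is the identity
  out2 <- filter_weak(inst, f_min = 0)
  expect_true(all(out2$keep))

  # everything weak is a zero-instrument error
  inst$f_stat <- c(1, 2, 3)
  expect_error(suppressMessages(filter_weak(inst, 10)), "weak")
})
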