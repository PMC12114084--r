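test_that("Wald ratio divides effects and is orientation-invariant", {
  inst <- make_instruments(0.1, 0.05, se_out = 0.01)
  est <- wald_ratio(inst)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$or, exp(0.5))

  zero <- make_instruments(0.1, 0)
  est0 <- wald_ratio(zero)
  expect_equal(est0$beta, 0)
  expect_equal(est0$or, 1)

  # negating the exposure orientation (both betas) changes nothing
  flipped <- make_instruments(-0.1, -0.05, se_out = 0.01)
  estf <- wald_ratio(flipped)
  expect_equal(estf$beta, est$beta)
  expect_equal(estf$se, est$se)

  expect_error(wald_ratio(make_instruments(0, 0.05)), "zero exposure")
})

test_that("IVW equals the precision-weighted mean and the origin WLS slope", {
  set.seed(10)
  for (J in c(3, 8, 15)) {
    x <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
    y <- 0.4 * x + rnorm(J, 0, 0.02)
    sy <- runif(J, 0.005, 0.05)
    inst <- make_instruments(x, y, se_out = sy)
    est <- mr_ivw(inst, model = "fixed")
    # formulation 1: weighted mean of Wald ratios
    w <- x^2 / sy^2
    expect_equal(est$beta, sum(w * (y / x)) / sum(w), tolerance = 1e-12)
    # formulation 2: independent origin-constrained WLS matrix solve
    slope <- wls_oracle(matrix(x), y, 1 / sy^2)
    expect_equal(est$beta, as.numeric(slope), tolerance = 1e-10)
    expect_equal(est$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  }
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  inst <- make_instruments(0.12, 0.07, se_out = 0.02)
  expect_equal(mr_ivw(inst)$beta, wald_ratio(inst)$beta)
  expect_equal(mr_ivw(inst)$se, wald_ratio(inst)$se)
})

test_that("duplicating an instrument halves the fixed-effect variance", {
  one <- make_instruments(0.1, 0.05, se_out = 0.01)
  two <- make_instruments(c(0.1, 0.1), c(0.05, 0.05),
                          se_out = c(0.01, 0.01))
  e1 <- mr_ivw(one, model = "fixed")
  e2 <- mr_ivw(two, model = "fixed")
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$se, e1$se / sqrt(2))
})

test_that("random-effects IVW inflates but never deflates the se", {
  set.seed(11)
  x <- runif(10, 0.05, 0.3)
  y <- 0.2 * x + rnorm(10, 0, 0.1)   # heterogeneous
  inst <- make_instruments(x, y, se_out = rep(0.01, 10))
  fixed <- mr_ivw(inst, model = "fixed")
  random <- mr_ivw(inst, model = "random")
  expect_equal(random$beta, fixed$beta)
  expect_gte(random$se, fixed$se)
  q <- random$model_detail$Q
  expect_equal(random$se, fixed$se * sqrt(max(1, q / 9)))

  # homogeneous data: floor at the fixed-effect se
  y2 <- 0.2 * x
  inst2 <- make_instruments(x, y2, se_out = rep(0.01, 10))
  expect_equal(mr_ivw(inst2, "random")$se, mr_ivw(inst2, "fixed")$se)
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  x <- c(0.05, 0.1, 0.2, 0.3)
  y <- 0.02 + 0.5 * x
  inst <- make_instruments(x, y, se_out = rep(0.01, 4))
  est <- mr_egger(inst)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$model_detail$intercept$estimate, 0.02, tolerance = 1e-10)

  # collinear through the origin: intercept 0, slope equals IVW
  y0 <- 0.5 * x[1:3]
  inst0 <- make_instruments(x[1:3], y0, se_out = rep(0.01, 3))
  est0 <- mr_egger(inst0)
  expect_equal(est0$model_detail$intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(est0$beta, mr_ivw(inst0)$beta, tolerance = 1e-10)

  # random instruments against the generic WLS solve, with orientation
  set.seed(12)
  for (rep in 1:5) {
    J <- 10
    xr <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
    yr <- 0.01 + 0.3 * xr + rnorm(J, 0, 0.02)
    syr <- runif(J, 0.005, 0.05)
    inst_r <- make_instruments(xr, yr, se_out = syr)
    est_r <- mr_egger(inst_r)
    xo <- abs(xr); yo <- ifelse(xr < 0, -yr, yr)
    coefs <- wls_oracle(cbind(1, xo), yo, 1 / syr^2)
    expect_equal(est_r$model_detail$intercept$estimate, coefs[1],
                 tolerance = 1e-10)
    expect_equal(est_r$beta, coefs[2], tolerance = 1e-10)
  }

  expect_error(mr_egger(make_instruments(c(0.1, 0.2), c(0.1, 0.2))), "3")
})

test_that("weighted median interpolates the 50th weight percentile", {
  inst <- make_instruments(c(1, 1, 1), c(0.4, 0.5, 0.6),
                           se_out = rep(0.01, 3))
  est <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.5)

  # all ratios identical: that value, se shrinking with the noise
  inst2 <- make_instruments(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15),
                            se_exp = rep(1e-6, 3), se_out = rep(1e-6, 3))
  est2 <- mr_weighted_median(inst2, n_boot = 100, seed = 2)
  expect_equal(est2$beta, 0.5, tolerance = 1e-9)
  expect_lt(est2$se, 1e-4)

  # unequal weights against an independent re-computation of the
  # percentile interpolation
  set.seed(13)
  J <- 11
  x <- runif(J, 0.05, 0.3)
  y <- 0.25 * x + rnorm(J, 0, 0.02)
  sy <- runif(J, 0.005, 0.05)
  inst3 <- make_instruments(x, y, se_out = sy)
  est3 <- mr_weighted_median(inst3, n_boot = 50, seed = 3)
  theta <- y / x
  w <- (x^2 / sy^2); w <- w / sum(w)
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- cumsum(w) - w / 2
  k <- max(which(s < 0.5))
  expected <- theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) /
    (s[k + 1] - s[k])
  expect_equal(est3$beta, expected, tolerance = 1e-12)

  # same seed, same bootstrap se; different seed, different draw
  a <- mr_weighted_median(inst3, n_boot = 200, seed = 42)
  b <- mr_weighted_median(inst3, n_boot = 200, seed = 42)
  c <- mr_weighted_median(inst3, n_boot = 200, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(inst3, n_boot = 200),
               "seed")
})

test_that("OR-scale conversion multiplies CI bounds correctly", {
  conv <- to_or_scale(0, 0.1)
  expect_equal(conv$or, 1)
  expect_equal(conv$ci_low, exp(-1.96 * 0.1))
  expect_equal(conv$ci_high, exp(1.96 * 0.1))
  conv2 <- to_or_scale(log(1.541), 0.2)
  expect_equal(conv2$or, 1.541)
  expect_equal(conv2$ci_low, 1.541 * exp(-1.96 * 0.2))
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(14)
  J <- 9
  x <- runif(J, 0.05, 0.3)
  y <- 0.3 * x + rnorm(J, 0, 0.01)
  sy <- runif(J, 0.005, 0.02)
  inst <- make_instruments(x, y, se_out = sy)
  neg <- make_instruments(x, -y, se_out = sy)
  scaled <- make_instruments(3 * x, y, se_exp = rep(0.03, J), se_out = sy)

  for (f in list(function(i) mr_ivw(i)$beta,
                 function(i) mr_egger(i)$beta,
                 function(i) mr_weighted_median(i, 100, seed = 5)$beta)) {
    expect_equal(f(neg), -f(inst), tolerance = 1e-9)
    expect_equal(f(scaled), f(inst) / 3, tolerance = 1e-9)
  }
  expect_equal(mr_ivw(neg)$or, 1 / mr_ivw(inst)$or, tolerance = 1e-12)
})

test_that("mr_fit returns a model object with working accessors", {
  pair <- simulate_pair(sim_scenario(n_snp = 8, beta_causal = 0.2, seed = 21))
  inst <- harmonize(pair$exposure, pair$outcome)
  fit <- mr_fit(inst, seed = 9, n_boot = 100)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw", "egger", "weighted_median"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(3L, 2L))
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  df <- as.data.frame(fit)
  expect_equal(df$or, exp(df$beta))
  expect_true(all(df$ci_low < df$or & df$or < df$ci_high))
  r <- residuals(fit)
  expect_length(r, fit$n_snp)
  expect_equal(unname(predict(fit, data.frame(beta_exp = 1), "ivw")),
               coef(fit)[["ivw"]])
  expect_output(print(fit), "ivw")
  # seed is mandatory for the weighted median
  expect_error(mr_fit(inst), "seed")
  # plot executes silently on a null device
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
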