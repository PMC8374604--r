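# Log-log marker regressions and the genome-wide correlation screen.

test_that("a perfect power law is fit exactly", {
  x <- exp(seq(1, 3, length.out = 6))
  y <- exp(2 * log(x) - 1)
  m <- fit_loglog(x, y, "mu", "test")
  expect_equal(m$alpha, -1)
  expect_equal(m$beta, 2)
  expect_equal(m$r2, 1)
})

test_that("the fit reproduces the hand-worked normal-equations example", {
  # ln-pairs (1,1), (2,2), (3,2), (4,3): Sxx = 5, Sxy = 3, SSE = 0.2, SST = 2
  m <- fit_loglog(exp(1:4), exp(c(1, 2, 2, 3)))
  expect_equal(m$beta, 0.6)
  expect_equal(m$alpha, 0.5)
  expect_equal(m$r2, 0.9)
  expect_equal(m$residual_se, sqrt(0.2 / 2))
  expect_equal(m$f_stat, (0.9 / 0.1) * 2)
  expect_equal(m$df_den, 2L)
})

test_that("non-positive pairs are excluded with a warning; too few pairs fail", {
  x <- c(1, 2, 3, 4, 0)
  y <- c(1, 2, 3, -4, 5)
  expect_warning(m <- fit_loglog(x, y), "excluded")
  expect_equal(m$n_obs, 3L)
  expect_error(suppressWarnings(fit_loglog(c(1, 2, 0), c(1, 2, 3))),
               "fewer than 3")
  expect_error(fit_loglog(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("the fit matches the closed-form OLS oracle on random instances", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    lx <- rnorm(n, 5, 1)
    ly <- runif(1, -3, 3) + runif(1, -2, 2) * lx + rnorm(n, 0, 0.5)
    m <- fit_loglog(exp(lx), exp(ly))
    o <- ols_oracle(lx, ly)
    expect_equal(m$alpha, o$alpha, tolerance = 1e-10)
    expect_equal(m$beta, o$beta, tolerance = 1e-10)
    expect_equal(m$r2, o$r2, tolerance = 1e-10)
    expect_equal(m$residual_se, o$residual_se, tolerance = 1e-10)
    expect_equal(m$f_stat, o$f, tolerance = 1e-8)
    # R2 equals the squared Pearson correlation for simple regression
    expect_equal(m$r2, pearson_oracle(lx, ly)^2, tolerance = 1e-10)
  }
})

test_that("slope estimates are unbiased with spread matching the analytic SE", {
  set.seed(99)
  n <- 30
  lx <- rnorm(n, 6, 0.8)
  alpha <- -9.64; beta <- 1.4; sigma <- 0.45
  se_analytic <- sigma / sqrt(sum((lx - mean(lx))^2))
  betas <- replicate(200, {
    y <- exp(alpha + beta * lx + rnorm(n, 0, sigma))
    fit_loglog(exp(lx), y)$beta
  })
  expect_lt(abs(mean(betas) - beta), 2 * sd(betas) / sqrt(200))
  expect_lt(abs(sd(betas) - se_analytic) / se_analytic, 0.25)
})

test_that("prediction applies the back-transformed power law", {
  expect_equal(predict_rate(as_marker_model(0, 1), 5), 5)
  expect_equal(predict_rate(as_marker_model(-9.64, 1.4), exp(8)), exp(1.56))
  expect_equal(round(predict_rate(as_marker_model(-9.64, 1.4), exp(8)), 3),
               4.759)
  expect_equal(round(predict_rate(as_marker_model(-6.37, 0.98), exp(7)), 3),
               1.632)
  expect_error(predict_rate(as_marker_model(0, 1), -2), "expression")
})

test_that("the zero crossing is -alpha/beta", {
  expect_equal(zero_crossing(as_marker_model(0, 1)), 0)
  expect_equal(zero_crossing(as_marker_model(-6, 2)), 3)
  expect_error(zero_crossing(as_marker_model(1, 0)), "slope")
})

test_that("the correlation screen ranks by signed coefficient with deterministic ties", {
  rate <- c(s1 = 0.2, s2 = 0.5, s3 = 0.9, s4 = 1.4)
  em <- rbind(perfect = exp(log(rate)),               # r = +1
              inverse = exp(3 - 2 * log(rate)),       # r = -1
              noisy = c(30, 20, 45, 50))
  rownames(em) <- c("1.1.1.1", "2.2.2.2", "3.3.3.3")
  colnames(em) <- names(rate)
  rk <- correlation_screen(em, rate)
  expect_equal(rk$ec_id[1], "1.1.1.1")
  expect_equal(rk$pearson_r[1], 1)
  expect_equal(rk$ec_id[4 - 1], "2.2.2.2")  # decreasing affine: last defined
  expect_equal(rk$pearson_r[rk$ec_id == "2.2.2.2"], -1)
  # against the brute-force Pearson formula
  for (e in rownames(em)) {
    expect_equal(rk$pearson_r[rk$ec_id == e],
                 pearson_oracle(log(em[e, ]), log(rate)), tolerance = 1e-12)
  }
  # exact tie between duplicated rows: lexicographically smaller EC first
  em2 <- em[c(1, 1, 2), ]
  rownames(em2) <- c("5.5.5.5", "4.4.4.4", "2.2.2.2")
  rk2 <- correlation_screen(em2, rate)
  expect_equal(rk2$ec_id[1:2], c("4.4.4.4", "5.5.5.5"))
})

test_that("zero-variance classes are undefined and rank last", {
  rate <- c(s1 = 0.2, s2 = 0.5, s3 = 0.9)
  em <- rbind("1.2.3.4" = c(10, 20, 40), "9.9.9.9" = c(15, 15, 15))
  colnames(em) <- names(rate)
  rk <- correlation_screen(em, rate)
  expect_true(is.na(rk$pearson_r[rk$ec_id == "9.9.9.9"]))
  expect_equal(marker_rank(rk, "9.9.9.9"), 2)
  expect_error(marker_rank(rk, "0.0.0.0"), "not present")
})

test_that("the screen is invariant to per-class positive rescaling", {
  set.seed(5)
  rate <- setNames(runif(8, 0.1, 2), paste0("s", 1:8))
  em <- matrix(exp(rnorm(40, 4, 1)), 5, 8,
               dimnames = list(sprintf("1.1.1.%d", 1:5), names(rate)))
  rk1 <- correlation_screen(em, rate)
  em2 <- em * runif(5, 0.2, 50)  # per-class positive scale
  rk2 <- correlation_screen(em2, rate)
  expect_equal(rk1$ec_id, rk2$ec_id)
  expect_equal(rk1$pearson_r, rk2$pearson_r, tolerance = 1e-12)
})
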