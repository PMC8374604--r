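# Two-way ANOVA, Tukey HSD with letters, and stratified t-tests.

test_that("a balanced noiseless 2x2 design partitions exactly by hand", {
  # cell means (0, 0, 0, 4), two replicates, zero noise:
  # grand mean 1; A and B marginal effects each give SS 8; SST = 24
  a <- rep(c("a1", "a1", "a2", "a2"), each = 2)
  b <- rep(c("b1", "b2", "b1", "b2"), each = 2)
  y <- c(0, 0, 0, 0, 0, 0, 4, 4)
  tab <- two_way_anova(y, a, b, labels = c("A", "B"))
  expect_equal(tab$sum_sq, c(8, 8, 8, 0))
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(attr(tab, "model_r2"), 1)
  expect_equal(tab$f_value[1:3], c(0, 0, 0))  # zero residual MS: F as 0
  expect_false(is.null(attr(tab, "note")))
})

test_that("identical observations yield zero effect sums of squares", {
  a <- rep(c("x", "y"), each = 4)
  b <- rep(c("p", "q"), 4)
  tab <- two_way_anova(rep(2.5, 8), a, b)
  expect_equal(tab$sum_sq, rep(0, 4))
  expect_equal(tab$f_value[1:3], c(0, 0, 0))
})

test_that("sequential SS match the projection oracle on random unbalanced designs", {
  set.seed(17)
  for (i in 1:10) {
    na <- sample(2:4, 1)
    nb <- sample(2:3, 1)
    a <- character(0); b <- character(0)
    for (ai in seq_len(na)) for (bi in seq_len(nb)) {
      reps <- sample(2:5, 1)
      a <- c(a, rep(paste0("a", ai), reps))
      b <- c(b, rep(paste0("b", bi), reps))
    }
    y <- rnorm(length(a), as.integer(factor(a)) * 0.5, 1)
    tab <- two_way_anova(y, a, b)
    o <- seq_anova_oracle(y, a, b)
    expect_equal(tab$sum_sq, unname(o$ss), tolerance = 1e-8)
    expect_equal(tab$df, unname(o$df))
    expect_equal(attr(tab, "model_r2"), 1 - o$ss[["resid"]] / o$sst,
                 tolerance = 1e-10)
  }
})

test_that("balanced designs are order invariant; permutation never matters", {
  set.seed(23)
  a <- rep(c("a1", "a2", "a3"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 3)
  y <- rnorm(18, as.integer(factor(b)), 1)
  t_ab <- two_way_anova(y, a, b, order = "ab")
  t_ba <- two_way_anova(y, a, b, order = "ba")
  expect_equal(t_ab$sum_sq, t_ba$sum_sq, tolerance = 1e-10)
  perm <- sample(18)
  t_perm <- two_way_anova(y[perm], a[perm], b[perm])
  expect_equal(t_ab$sum_sq, t_perm$sum_sq, tolerance = 1e-10)
  expect_equal(t_ab$p_value, t_perm$p_value, tolerance = 1e-10)
})

test_that("empty cells are rejected with the offending cell named", {
  a <- c("a1", "a1", "a2", "a2")
  b <- c("b1", "b2", "b1", "b1")
  expect_error(two_way_anova(rnorm(4), a, b), "a2:b2")
})

test_that("Tukey HSD separates distant groups and unites identical ones", {
  same <- rep(c(1.2, 2.5, 3.1, 4.4, 5.0, 6.3), 2)  # identical groups
  g2 <- rep(c("g1", "g2"), each = 6)
  tk <- tukey_hsd(same, g2)
  expect_gt(tk$comparisons$adjusted_p, 0.99)
  set.seed(31)
  expect_equal(unname(tk$letters["g1"]), unname(tk$letters["g2"]))

  far <- c(rnorm(6, 0, 0.5), rnorm(6, 50, 0.5))
  tk2 <- tukey_hsd(far, g2)
  expect_lt(tk2$comparisons$adjusted_p, 1e-4)
  expect_false(tk2$letters["g1"] == tk2$letters["g2"])
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "singleton")
})

test_that("Tukey adjusted p-values match the studentized-range formula", {
  set.seed(37)
  g <- rep(c("w", "x", "y", "z"), times = c(4, 5, 4, 6))
  y <- rnorm(19, c(w = 0, x = 1, y = 3, z = 3.2)[g], 1)
  tk <- tukey_hsd(y, g)
  # direct oracle: q = |diff| / sqrt(MSE/2 * (1/ni + 1/nj)), p from ptukey
  means <- tapply(y, g, mean)
  ni <- table(g)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (19 - 4)
  for (k in seq_len(nrow(tk$comparisons))) {
    gi <- tk$comparisons$group_i[k]
    gj <- tk$comparisons$group_j[k]
    q <- abs(means[gj] - means[gi]) /
      sqrt(mse / 2 * (1 / ni[gi] + 1 / ni[gj]))
    p_oracle <- stats::ptukey(q, 4, 19 - 4, lower.tail = FALSE)
    expect_equal(tk$comparisons$adjusted_p[k], unname(p_oracle),
                 tolerance = 1e-3)
    expect_equal(tk$comparisons$mean_diff[k], unname(means[gj] - means[gi]),
                 tolerance = 1e-10)
  }
})

test_that("stratified Welch t-tests follow the hand formula", {
  # strata with identical groups: t = 0, p = 1
  v <- c(1, 2, 3, 1, 2, 3)
  tt <- per_group_ttests(v, rep(c("m1", "m2"), each = 3), rep("iso", 6))
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  # hand-computed Welch example: (0,1) vs (10,11)
  # s1^2 = s2^2 = 0.5, se = sqrt(0.25 + 0.25), t = -10/sqrt(0.5), df = 2
  tt2 <- per_group_ttests(c(0, 1, 10, 11), c("m1", "m1", "m2", "m2"),
                          rep("iso", 4))
  expect_equal(tt2$t, -10 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(tt2$df, 2, tolerance = 1e-10)
})

test_that("strata missing a treatment level are reported as missing", {
  v <- c(1, 2, 3, 4, 5, 6, 7)
  trt <- c("m1", "m1", "m2", "m2", "m1", "m1", "m1")
  st <- c("A", "A", "A", "A", "B", "B", "B")
  tt <- per_group_ttests(v, trt, st)
  expect_equal(tt$stratum, c("A", "B"))
  expect_false(is.na(tt$t[1]))
  expect_true(is.na(tt$t[2]))
  expect_equal(tt$n_2[2], 0)
})
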