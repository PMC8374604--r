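# The synthetic-study generator and its ground truth.

test_that("the same configuration reproduces the study exactly", {
  cfg <- study_config(seed = 123, n_genes = 300, n_ec_classes = 40,
                      n_replicates = 3, n_dropped = 2)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  s3 <- generate_study(study_config(seed = 124, n_genes = 300,
                                    n_ec_classes = 40, n_replicates = 3,
                                    n_dropped = 2))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("physiology inversion is the algebraic inverse of the flux equations", {
  expect_equal(invert_physiology(0, 0.5, B0 = 3, t = 7)$Bt_mg, 3)
  expect_equal(invert_physiology(0.2, 1, B0 = 2, t = 10)$Bt_mg, 2 * exp(2))
  expect_equal(round(invert_physiology(0.2, 1, B0 = 2, t = 10)$Bt_mg, 3),
               14.778)
  set.seed(8)
  mu <- runif(50, 0.01, 1)
  q <- runif(50, 0.01, 3)
  ph <- invert_physiology(mu, q, B0 = runif(50, 0.5, 8), t = runif(50, 2, 30))
  fx <- compute_fluxes(ph)
  expect_equal(fx$mu_per_day, mu, tolerance = 1e-9)
  expect_equal(fx$qco2_per_day, q, tolerance = 1e-9)
  expect_equal(fx$cue, mu / (mu + q), tolerance = 1e-9)
})

test_that("count generation inverts RPKM at the given library size", {
  tr <- matrix(20, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(generate_counts(tr, c(g1 = 500), 1e6, noise = "none")["g1", "s1"],
               10)
  tr0 <- matrix(c(0, 50), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  set.seed(4)
  cts <- generate_counts(tr0, c(g1 = 500, g2 = 1000), 1e6, noise = "poisson")
  expect_equal(cts["g1", "s1"], 0)  # zero expression never yields counts
  # doubling the library size doubles expected counts
  c1 <- generate_counts(tr, c(g1 = 500), 1e6, noise = "none")
  c2 <- generate_counts(tr, c(g1 = 500), 2e6, noise = "none")
  expect_equal(c2, 2 * c1)
})

test_that("a noiseless study is recovered exactly by the pipeline stages", {
  cfg <- study_config(seed = 5, sigma1 = 0, sigma2 = 0, count_noise = "none",
                      library_size_mean = 1e9, library_size_disp = 0,
                      n_dropped = 0, n_genes = 500, n_ec_classes = 60,
                      n_replicates = 3)
  st <- generate_study(cfg)
  fl <- compute_fluxes(st$phenotypes)
  expect_equal(fl$mu_per_day, st$truth$samples$mu, tolerance = 1e-9)
  expect_equal(fl$qco2_per_day, st$truth$samples$qco2, tolerance = 1e-9)
  expect_equal(fl$cue, st$truth$samples$cue, tolerance = 1e-9)
  ec <- aggregate_by_ec(rpkm_normalize(st$counts, st$gene_lengths),
                        st$annotation)
  m <- fit_loglog(ec["2.4.1.34", fl$sample_id], fl$mu_per_day, "mu")
  expect_equal(m$alpha, cfg$alpha1, tolerance = 1e-6)
  expect_equal(m$beta, cfg$beta1, tolerance = 1e-6)
  r <- fit_loglog(ec["1.2.4.2", fl$sample_id], fl$qco2_per_day, "qco2")
  expect_equal(r$beta, cfg$beta2, tolerance = 1e-6)
})

test_that("the default study matches the intended design", {
  st <- generate_study(study_config(seed = 2))
  expect_equal(nrow(st$metadata), 72)
  expect_equal(sum(st$metadata$sequenced), 62)
  expect_equal(ncol(st$counts), 62)
  expect_equal(nrow(st$counts), 2000)
  expect_true(all(st$counts >= 0) && all(st$counts == round(st$counts)))
  # truth ledger is internally consistent
  tr <- st$truth$samples
  expect_equal(tr$cue, tr$mu / (tr$mu + tr$qco2))
  # all six marker classes are annotated and present
  expect_true(all(marker_ec_numbers() %in%
                    unlist(strsplit(st$annotation$ec_numbers, ","))))
  expect_true(all(lengths(st$truth$marker_genes) >= 2))
  # glutamine synthetase is upregulated in the poor medium
  ec <- aggregate_by_ec(rpkm_normalize(st$counts, st$gene_lengths),
                        st$annotation)
  md <- st$metadata[st$metadata$sequenced, ]
  gs <- log(ec["6.3.1.2", md$sample_id])
  expect_gt(mean(gs[md$medium == "poor"]), mean(gs[md$medium == "rich"]))
})

test_that("fitted growth-model R2 falls in the pre-registered envelope", {
  # envelope [0.10, 0.92] frozen from a 100-study brute-force simulation at
  # the default configuration (observed range 0.15-0.88)
  for (s in c(5, 55, 155)) {
    r2 <- recover_growth_fit(seed = s)$fit$r2
    expect_gte(r2, 0.10)
    expect_lte(r2, 0.92)
  }
})

test_that("inconsistent configurations are rejected", {
  expect_error(study_config(n_dropped = 80), "n_dropped")
  expect_error(study_config(n_ec_classes = 3))
  expect_error(generate_study(study_config(n_genes = 5, n_ec_classes = 6)),
               "inconsistency")
})
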