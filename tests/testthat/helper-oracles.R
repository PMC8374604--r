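# Independent oracles used to cross-check the fitted models: closed-form
# normal equations for simple OLS, explicit sequential projections for the
# two-way ANOVA, and the textbook Pearson formula.

ols_oracle <- function(lx, ly) {
  sxx <- sum((lx - mean(lx))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  beta <- sxy / sxx
  alpha <- mean(ly) - beta * mean(lx)
  sse <- sum((ly - (alpha + beta * lx))^2)
  sst <- sum((ly - mean(ly))^2)
  n <- length(lx)
  list(alpha = alpha, beta = beta, r2 = 1 - sse / sst,
       residual_se = sqrt(sse / (n - 2)),
       f = (sst - sse) / (sse / (n - 2)))
}

# sequential (Type I) sums of squares by explicit nested least squares
seq_anova_oracle <- function(values, A, B) {
  A <- factor(A)
  B <- factor(B)
  n <- length(values)
  ind <- function(f) {
    m <- outer(f, levels(f), "==")
    storage.mode(m) <- "double"
    m
  }
  XA <- ind(A)
  XB <- ind(B)
  XAB <- matrix(0, n, 0)
  for (i in seq_len(ncol(XA)))
    for (j in seq_len(ncol(XB)))
      XAB <- cbind(XAB, XA[, i] * XB[, j])
  rss <- function(X) sum(qr.resid(qr(X), values)^2)
  r0 <- rss(matrix(1, n, 1))
  r1 <- rss(cbind(1, XA))
  r2 <- rss(cbind(1, XA, XB))
  r3 <- rss(cbind(1, XA, XB, XAB))
  list(ss = c(A = r0 - r1, B = r1 - r2, AB = r2 - r3, resid = r3),
       df = c(nlevels(A) - 1L, nlevels(B) - 1L,
              (nlevels(A) - 1L) * (nlevels(B) - 1L),
              n - nlevels(A) * nlevels(B)),
       sst = r0)
}

pearson_oracle <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# a compact study configuration for pipeline-level tests
small_config <- function(seed, ...) {
  study_config(n_genes = 400, n_ec_classes = 60, n_replicates = 4,
               n_dropped = 2, seed = seed, ...)
}

# generate a study and fit the growth marker the way the pipeline does,
# without the full orchestration overhead
recover_growth_fit <- function(seed) {
  st <- generate_study(study_config(seed = seed))
  fl <- compute_fluxes(st$phenotypes)
  usable <- intersect(usable_samples(fl), colnames(st$counts))
  mu <- stats::setNames(fl$mu_per_day[match(usable, fl$sample_id)], usable)
  ec <- aggregate_by_ec(rpkm_normalize(st$counts, st$gene_lengths),
                        st$annotation)
  filt <- filter_min_expression(ec[, usable, drop = FALSE])
  list(fit = fit_loglog(ec["2.4.1.34", usable], mu, "mu", "2.4.1.34"),
       rank = marker_rank(correlation_screen(filt, mu), "2.4.1.34"))
}
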