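# Synthetic culture studies with known ground truth: planted power-law
# marker-flux relationships, background enzyme classes, count sampling and
# algebraically inverted phenotype measurements.

#' Configuration for a synthetic culture study
#'
#' Defines the design (isolates x media x replicates), the transcriptome
#' size, the planted marker-flux relationships and the noise levels of a
#' simulated study. The defaults emulate the four-isolate / two-medium /
#' nine-replicate liquid-culture design with ten samples lost to failed
#' sequencing or quality exclusions, leaving 62 usable observations, and
#' plant growth and respiration power laws with coefficients and residual
#' spread at the scales observed in that experiment.
#'
#' @param n_isolates,n_media,n_replicates Design dimensions (4 x 2 x 9).
#' @param n_genes Number of genes in the transcriptome (2000).
#' @param n_ec_classes Number of enzyme classes, including the six marker
#'   classes (450).
#' @param n_dropped Samples removed to emulate failed sequencing and QC
#'   exclusions (10, leaving 62 usable).
#' @param library_size_mean,library_size_disp Mean counted reads per sample
#'   and the standard deviation of its natural log.
#' @param alpha1,beta1,sigma1 Intercept, slope and residual SD of the planted
#'   growth law `ln mu = alpha1 + beta1 ln GT48 + N(0, sigma1)`.
#' @param alpha2,beta2,sigma2 Same for the respiration law on ln KGD.
#' @param gt48_mean,kgd_mean Baseline marker expression, ln RPKM.
#' @param isolate_sd SD of isolate effects on ln marker expression.
#' @param medium_effect Additive rich-medium effect on ln GT48 and ln KGD.
#' @param interaction_sd SD of isolate-by-medium interaction effects.
#' @param replicate_sd Residual replicate SD of ln marker expression.
#' @param gs_poor_effect Upregulation of glutamine synthetase (ln scale) in
#'   the nitrogen-poor medium.
#' @param background_mean,background_sd Mean and SD (across classes) of
#'   background enzyme-class ln RPKM.
#' @param background_noise_sd Per-sample SD of background ln expression.
#' @param frac_correlated Fraction of background classes weakly coupled to
#'   the marker signals, making the correlation screen non-trivial.
#' @param corr_min,corr_max Range of the coupling coefficients (applied to
#'   the standardized marker signal).
#' @param count_noise `"poisson"` (default), `"nb"` (negative binomial) or
#'   `"none"` (deterministic rounding).
#' @param nb_size Negative-binomial size (inverse dispersion) for
#'   `count_noise = "nb"`.
#' @param b0_range Range of per-isolate inoculum dry mass, mg.
#' @param target_ln_ratio Targeted ln biomass ratio at harvest, used to set
#'   per-isolate culture durations.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#'
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(n_isolates = 4, n_media = 2, n_replicates = 9,
                         n_genes = 2000, n_ec_classes = 450, n_dropped = 10,
                         library_size_mean = 2e6, library_size_disp = 0.2,
                         alpha1 = -9.64, beta1 = 1.4, sigma1 = 0.45,
                         alpha2 = -6.37, beta2 = 0.98, sigma2 = 0.47,
                         gt48_mean = 6.5, kgd_mean = 6.5,
                         isolate_sd = 0.45, medium_effect = 0.25,
                         interaction_sd = 0.15, replicate_sd = 0.15,
                         gs_poor_effect = 1.0,
                         background_mean = 4.0, background_sd = 1.2,
                         background_noise_sd = 0.3,
                         frac_correlated = 0.3,
                         corr_min = 0.05, corr_max = 0.3,
                         count_noise = c("poisson", "nb", "none"),
                         nb_size = 20,
                         b0_range = c(1, 5), target_ln_ratio = 2.5,
                         seed = 1L) {
  cfg <- list(n_isolates = n_isolates, n_media = n_media,
              n_replicates = n_replicates, n_genes = n_genes,
              n_ec_classes = n_ec_classes, n_dropped = n_dropped,
              library_size_mean = library_size_mean,
              library_size_disp = library_size_disp,
              alpha1 = alpha1, beta1 = beta1, sigma1 = sigma1,
              alpha2 = alpha2, beta2 = beta2, sigma2 = sigma2,
              gt48_mean = gt48_mean, kgd_mean = kgd_mean,
              isolate_sd = isolate_sd, medium_effect = medium_effect,
              interaction_sd = interaction_sd, replicate_sd = replicate_sd,
              gs_poor_effect = gs_poor_effect,
              background_mean = background_mean,
              background_sd = background_sd,
              background_noise_sd = background_noise_sd,
              frac_correlated = frac_correlated,
              corr_min = corr_min, corr_max = corr_max,
              count_noise = match.arg(count_noise), nb_size = nb_size,
              b0_range = b0_range, target_ln_ratio = target_ln_ratio,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_isolates >= 1, n_media >= 2, n_replicates >= 1,
              n_genes >= 1, n_ec_classes >= 6,
              library_size_mean > 0, library_size_disp >= 0,
              sigma1 >= 0, sigma2 >= 0, isolate_sd >= 0, replicate_sd >= 0,
              frac_correlated >= 0, frac_correlated <= 1,
              corr_min >= 0, corr_max >= corr_min, nb_size > 0,
              length(b0_range) == 2, all(b0_range > 0), target_ln_ratio > 0)
  })
  n_samples <- cfg$n_isolates * cfg$n_media * cfg$n_replicates
  if (cfg$n_dropped < 0 || cfg$n_dropped >= n_samples) {
    stop("'n_dropped' must be in [0, n_samples)", call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

#' Invert the flux equations into phenotype measurements
#'
#' Given true relative growth rate and metabolic quotient, produces the raw
#' culture measurements that [compute_fluxes()] would convert back into
#' exactly those rates: harvest mass `Bt = B0 exp(mu t)` and the closed-loop
#' CO2 rise implied by `respiration = qco2 * biomass_carbon(Bt)`.
#'
#' @param mu Relative growth rate, day^-1 (may be negative).
#' @param qco2 Metabolic quotient, day^-1. Non-negative.
#' @param B0 Inoculum dry mass, mg.
#' @param t Culture duration, days.
#' @param constants A [physio_constants()] object.
#' @param sample_id Optional sample identifiers.
#'
#' @return Phenotype data frame with columns `sample_id`, `B0_mg`, `Bt_mg`,
#'   `t_days`, `delta_co2_ppm`.
#' @examples
#' ph <- invert_physiology(mu = 0.2, qco2 = 1.0, B0 = 2, t = 10)
#' compute_fluxes(ph)$mu_per_day # 0.2
#' @export
invert_physiology <- function(mu, qco2, B0, t,
                              constants = physio_constants(),
                              sample_id = NULL) {
  stopifnot(is.numeric(mu), all(is.finite(mu)))
  .check_nonnegative(qco2, "qco2")
  .check_positive(B0, "B0")
  .check_positive(t, "t")
  n <- max(length(mu), length(qco2), length(B0), length(t))
  mu <- rep_len(mu, n); qco2 <- rep_len(qco2, n)
  B0 <- rep_len(B0, n); t <- rep_len(t, n)
  if (is.null(sample_id)) sample_id <- sprintf("sample_%03d", seq_len(n))

  Bt <- B0 * exp(mu * t)
  respiration <- qco2 * biomass_carbon(Bt, constants)
  ppm_factor <- 1e-6 * .loop_moles(constants) *
    (1440 / constants$measurement_duration) * 1000
  delta_co2 <- respiration / ppm_factor
  if (any(delta_co2 < 0)) {
    stop("parameters imply a negative CO2 rise", call. = FALSE)
  }
  data.frame(sample_id = sample_id, B0_mg = B0, Bt_mg = Bt, t_days = t,
             delta_co2_ppm = delta_co2, stringsAsFactors = FALSE)
}

#' Sample an integer count matrix around true expression
#'
#' Inverts RPKM at the given library sizes: the expected count is
#' `true_rpkm[g, s] * length_kb[g] * library_size[s] / 1e6`. Counts are drawn
#' Poisson around the expectation (`"poisson"`), negative-binomial with size
#' `nb_size` (`"nb"`), or rounded deterministically (`"none"`).
#'
#' @param true_rpkm Gene x sample matrix of true RPKM values.
#' @param gene_lengths Gene lengths, bp; named or aligned with rows.
#' @param library_size Per-sample library sizes (counted reads); scalar or
#'   one per sample.
#' @param noise Count noise model.
#' @param nb_size Negative-binomial size parameter.
#'
#' @return Gene x sample count matrix with the dimnames of `true_rpkm`.
#' @export
generate_counts <- function(true_rpkm, gene_lengths, library_size,
                            noise = c("poisson", "nb", "none"),
                            nb_size = 20) {
  noise <- match.arg(noise)
  .check_expression_matrix(true_rpkm, "'true_rpkm'")
  if (!is.null(names(gene_lengths))) gene_lengths <- gene_lengths[rownames(true_rpkm)]
  .check_positive(gene_lengths, "gene_lengths")
  .check_positive(library_size, "library_size")
  library_size <- rep_len(library_size, ncol(true_rpkm))

  expected <- sweep(true_rpkm * (gene_lengths / 1000), 2L,
                    library_size / 1e6, "*")
  counts <- switch(noise,
    poisson = matrix(stats::rpois(length(expected), expected),
                     nrow = nrow(expected)),
    nb = matrix(stats::rnbinom(length(expected), mu = expected,
                               size = nb_size),
                nrow = nrow(expected)),
    none = round(expected))
  dimnames(counts) <- dimnames(true_rpkm)
  counts
}

# random syntactically valid EC codes, distinct from `exclude`
.random_ec_ids <- function(n, exclude) {
  out <- character(0)
  while (length(out) < n) {
    cand <- sprintf("%d.%d.%d.%d",
                    sample.int(6L, n, replace = TRUE),
                    sample.int(30L, n, replace = TRUE),
                    sample.int(40L, n, replace = TRUE),
                    sample.int(199L, n, replace = TRUE))
    out <- setdiff(unique(c(out, cand)), exclude)
  }
  out[seq_len(n)]
}

#' Generate a complete synthetic culture study
#'
#' Draws per-sample marker expression from additive isolate and medium
#' effects on the ln scale, derives true growth and respiration rates through
#' the planted power laws (`ln mu = alpha1 + beta1 ln GT48 + eps`, and
#' likewise for qCO2 on ln KGD), surrounds the markers with background enzyme
#' classes — a configurable fraction weakly coupled to the marker signals —
#' and converts everything into the raw inputs of the pipeline: phenotype
#' measurements (via [invert_physiology()]), an annotated integer count
#' matrix (via [generate_counts()]) and sample metadata. Because the rates
#' are derived from the final, depth-normalized expression values, running
#' the full pipeline on a noise-free study recovers the planted coefficients
#' exactly up to count rounding.
#'
#' @param config A [study_config()].
#'
#' @return A list of class `synthetic_study`:
#'   * `metadata`: `sample_id`, `isolate`, `medium`, `replicate`,
#'     `sequenced` (FALSE for the dropped samples);
#'   * `phenotypes`: input to [compute_fluxes()], all samples;
#'   * `counts`: gene x sample integer matrix, sequenced samples only;
#'   * `gene_lengths`: named vector, bp;
#'   * `annotation`: `gene_id`, `length_bp`, `ec_numbers`;
#'   * `truth`: per-sample true `mu`, `qco2`, `cue` and marker ln
#'     expression, the marker EC ids, per-marker gene ids, the true RPKM
#'     matrix and the configuration.
#' Identical configurations (including the seed) give identical studies.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)

  isolates <- paste0("isolate_", LETTERS[seq_len(config$n_isolates)])
  media <- if (config$n_media == 2) c("rich", "poor") else
    paste0("medium_", seq_len(config$n_media))
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        medium = media, isolate = isolates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("isolate", "medium", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%02d", design$isolate, design$medium,
                              design$replicate)
  n_s <- nrow(design)
  iso_idx <- match(design$isolate, isolates)
  rich <- as.numeric(design$medium == "rich")
  poor <- as.numeric(design$medium == "poor")
  cell_idx <- (iso_idx - 1L) * config$n_media +
    match(design$medium, media)

  markers <- marker_ec_numbers()

  # --- enzyme classes and gene assignment -------------------------------
  n_bg <- config$n_ec_classes - length(markers)
  bg_ecs <- .random_ec_ids(n_bg, markers)
  ec_ids <- c(unname(markers), bg_ecs)
  paralogs <- c(sample(2:3, length(markers), replace = TRUE),
                sample(1:3, n_bg, replace = TRUE))
  if (sum(paralogs) > config$n_genes) {
    stop("config inconsistency: ", sum(paralogs),
         " annotated genes required but n_genes = ", config$n_genes,
         call. = FALSE)
  }
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  gene_ec <- rep("", config$n_genes)
  gene_ec[seq_len(sum(paralogs))] <- rep(ec_ids, paralogs)
  gene_lengths <- stats::setNames(
    pmin(pmax(round(stats::rlnorm(config$n_genes, log(1500), 0.4)), 300), 10000),
    gene_ids)
  # fixed within-class expression shares of the paralogs
  weights <- stats::ave(stats::runif(config$n_genes, 0.5, 1.5), gene_ec,
                        FUN = function(w) w / sum(w))
  weights[gene_ec == ""] <- 1

  # --- ln expression of each enzyme class (EC x sample) -----------------
  marker_ln <- function(base, med_eff_rich, med_eff_poor = 0) {
    iso_eff <- stats::rnorm(config$n_isolates, 0, config$isolate_sd)
    inter <- stats::rnorm(config$n_isolates * config$n_media, 0,
                          config$interaction_sd)
    base + iso_eff[iso_idx] + med_eff_rich * rich + med_eff_poor * poor +
      inter[cell_idx] + stats::rnorm(n_s, 0, config$replicate_sd)
  }
  ln_gt48 <- marker_ln(config$gt48_mean, config$medium_effect)
  ln_kgd <- marker_ln(config$kgd_mean, config$medium_effect)
  z_gt48 <- as.vector(scale(ln_gt48))
  z_kgd <- as.vector(scale(ln_kgd))
  # weaker candidate markers: mildly coupled to the driving signals
  ln_gt2 <- config$gt48_mean - 0.8 + 0.25 * (ln_gt48 - config$gt48_mean) +
    stats::rnorm(n_s, 0, 0.4)
  ln_idh_nad <- marker_ln(config$kgd_mean - 0.5, 0)
  ln_idh_nadp <- marker_ln(config$kgd_mean - 0.4, 0)
  ln_gs <- marker_ln(config$kgd_mean - 0.3, 0, config$gs_poor_effect)

  ln_bg <- matrix(0, n_bg, n_s)
  bg_base <- stats::rnorm(n_bg, config$background_mean, config$background_sd)
  n_corr <- floor(config$frac_correlated * n_bg)
  corr_idx <- sample.int(n_bg, n_corr)
  gamma <- stats::runif(n_bg, config$corr_min, config$corr_max) *
    (seq_len(n_bg) %in% corr_idx)
  corr_target <- sample(c(TRUE, FALSE), n_bg, replace = TRUE) # TRUE: growth
  for (i in seq_len(n_bg)) {
    signal <- if (corr_target[i]) z_gt48 else z_kgd
    ln_bg[i, ] <- bg_base[i] + gamma[i] * signal +
      stats::rnorm(n_s, 0, config$background_noise_sd)
  }
  ec_ln <- rbind(ln_gt48, ln_gt2, ln_kgd, ln_idh_nad, ln_idh_nadp, ln_gs,
                 ln_bg)
  rownames(ec_ln) <- c(markers[["GT48"]], markers[["GT2"]], markers[["KGD"]],
                       markers[["IDH_NAD"]], markers[["IDH_NADP"]],
                       markers[["GS"]], bg_ecs)

  # --- gene-level RPKM, renormalized so totals match library sizes ------
  build_rpkm <- function(ec_ln, unannot_rpkm) {
    m <- matrix(0, config$n_genes, n_s,
                dimnames = list(gene_ids, design$sample_id))
    annotated <- which(gene_ec != "")
    m[annotated, ] <- exp(ec_ln[gene_ec[annotated], , drop = FALSE]) *
      weights[annotated]
    if (length(unannot_rpkm)) m[gene_ec == "", ] <- unannot_rpkm
    scale_s <- 1e6 / colSums(m * (gene_lengths / 1000))
    sweep(m, 2L, scale_s, "*")
  }
  unannot <- which(gene_ec == "")
  unannot_rpkm <- if (length(unannot)) {
    base_u <- stats::rnorm(length(unannot), config$background_mean - 0.5, 1.0)
    exp(base_u + matrix(stats::rnorm(length(unannot) * n_s, 0,
                                     config$background_noise_sd),
                        length(unannot), n_s))
  } else numeric(0)
  # Depth normalization fixes each sample's length-weighted RPKM total, so a
  # class's final level is set by its share of the transcriptome, which
  # depends on the configured transcriptome size. A first pass measures the
  # realized marker levels; the marker draws are then re-anchored so that,
  # after normalization, mean ln GT48 and ln KGD sit at their configured
  # baselines and the planted coefficients act at the intended scale.
  gt48_genes <- gene_ids[gene_ec == markers[["GT48"]]]
  kgd_genes <- gene_ids[gene_ec == markers[["KGD"]]]
  pass1 <- build_rpkm(ec_ln, unannot_rpkm)
  delta_g <- mean(log(colSums(pass1[gt48_genes, , drop = FALSE]))) -
    config$gt48_mean
  delta_k <- mean(log(colSums(pass1[kgd_genes, , drop = FALSE]))) -
    config$kgd_mean
  growth_side <- c(markers[["GT48"]], markers[["GT2"]])
  resp_side <- c(markers[["KGD"]], markers[["IDH_NAD"]],
                 markers[["IDH_NADP"]], markers[["GS"]])
  ec_ln[growth_side, ] <- ec_ln[growth_side, ] - delta_g
  ec_ln[resp_side, ] <- ec_ln[resp_side, ] - delta_k
  true_rpkm <- build_rpkm(ec_ln, unannot_rpkm)

  # --- true fluxes from the final marker expression ---------------------
  ln_gt48_final <- log(colSums(true_rpkm[gt48_genes, , drop = FALSE]))
  ln_kgd_final <- log(colSums(true_rpkm[kgd_genes, , drop = FALSE]))
  mu <- exp(config$alpha1 + config$beta1 * ln_gt48_final +
              stats::rnorm(n_s, 0, config$sigma1))
  qco2 <- exp(config$alpha2 + config$beta2 * ln_kgd_final +
                stats::rnorm(n_s, 0, config$sigma2))
  cue <- mu / (mu + qco2)

  # --- phenotypes: per-isolate inoculum and duration --------------------
  B0_iso <- stats::runif(config$n_isolates, config$b0_range[1L],
                         config$b0_range[2L])
  mu_iso <- tapply(mu, iso_idx, mean)
  t_iso <- pmin(pmax(config$target_ln_ratio / mu_iso, 2), 30)
  phenotypes <- invert_physiology(mu, qco2,
                                  B0 = B0_iso[iso_idx],
                                  t = as.numeric(t_iso[as.character(iso_idx)]),
                                  sample_id = design$sample_id)

  # --- counts and sequencing dropout ------------------------------------
  library_sizes <- stats::rlnorm(n_s, log(config$library_size_mean),
                                 config$library_size_disp)
  counts <- generate_counts(true_rpkm, gene_lengths, library_sizes,
                            noise = config$count_noise,
                            nb_size = config$nb_size)
  dropped <- if (config$n_dropped > 0) {
    sample(design$sample_id, config$n_dropped)
  } else character(0)
  metadata <- data.frame(design[, c("sample_id", "isolate", "medium",
                                    "replicate")],
                         sequenced = !design$sample_id %in% dropped,
                         stringsAsFactors = FALSE)
  counts <- counts[, metadata$sample_id[metadata$sequenced], drop = FALSE]

  annotation <- data.frame(gene_id = gene_ids,
                           length_bp = unname(gene_lengths),
                           ec_numbers = gene_ec,
                           stringsAsFactors = FALSE)
  marker_genes <- lapply(markers, function(e) gene_ids[gene_ec == e])
  truth <- list(samples = data.frame(sample_id = design$sample_id,
                                     mu = mu, qco2 = qco2, cue = cue,
                                     ln_gt48 = ln_gt48_final,
                                     ln_kgd = ln_kgd_final,
                                     stringsAsFactors = FALSE),
                marker_ecs = markers,
                marker_genes = marker_genes,
                true_rpkm = true_rpkm,
                library_sizes = stats::setNames(library_sizes,
                                                design$sample_id),
                config = config)
  structure(list(metadata = metadata, phenotypes = phenotypes,
                 counts = counts, gene_lengths = gene_lengths,
                 annotation = annotation, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic culture study: %d isolates x %d media x %d replicates\n",
              cfg$n_isolates, cfg$n_media, cfg$n_replicates))
  cat(sprintf("  %d genes, %d enzyme classes; %d of %d samples sequenced\n",
              cfg$n_genes, cfg$n_ec_classes, sum(x$metadata$sequenced),
              nrow(x$metadata)))
  cat(sprintf("  planted laws: ln mu = %.2f + %.2f ln GT48 (sd %.2f); ",
              cfg$alpha1, cfg$beta1, cfg$sigma1))
  cat(sprintf("ln qCO2 = %.2f + %.2f ln KGD (sd %.2f)\n",
              cfg$alpha2, cfg$beta2, cfg$sigma2))
  invisible(x)
}

#' A tiny fixed worked example
#'
#' A deterministic 3-gene, 4-sample study used in unit tests and
#' documentation: one 1,3-beta-glucan synthase gene, one 2-oxoglutarate
#' dehydrogenase gene and one unannotated gene, with hand-set counts and
#' phenotypes.
#'
#' @return A list with `phenotypes`, `counts`, `gene_lengths`, `annotation`
#'   and `metadata`, in the formats the pipeline consumes.
#' @export
toy_study <- function() {
  samples <- c("s1", "s2", "s3", "s4")
  counts <- matrix(c(6000, 2000, 92000,
                     9000, 2500, 88500,
                     12000, 3000, 85000,
                     18000, 3500, 78500),
                   nrow = 3, dimnames = list(c("gGT48", "gKGD", "gOther"),
                                             samples))
  gene_lengths <- c(gGT48 = 1500, gKGD = 2000, gOther = 1000)
  annotation <- data.frame(gene_id = names(gene_lengths),
                           length_bp = unname(gene_lengths),
                           ec_numbers = c("2.4.1.34", "1.2.4.2", ""),
                           stringsAsFactors = FALSE)
  phenotypes <- data.frame(sample_id = samples,
                           B0_mg = c(2, 2, 2, 2),
                           Bt_mg = c(6, 9, 14, 22),
                           t_days = c(8, 8, 8, 8),
                           delta_co2_ppm = c(60, 75, 110, 150),
                           stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = samples,
                         isolate = c("A", "A", "B", "B"),
                         medium = c("poor", "rich", "poor", "rich"),
                         replicate = c(1L, 1L, 1L, 1L),
                         sequenced = TRUE,
                         stringsAsFactors = FALSE)
  list(phenotypes = phenotypes, counts = counts, gene_lengths = gene_lengths,
       annotation = annotation, metadata = metadata)
}
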