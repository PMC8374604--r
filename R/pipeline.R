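# End-to-end orchestration: fluxes -> normalization -> aggregation -> filter
# -> candidate fits -> screen -> marker selection -> CUE index -> evaluation
# -> group statistics.

.log_msg <- function(quiet, ...) if (!quiet) message(...)

#' Select the best marker per role
#'
#' Picks, from a list of fitted candidate models, the one with the highest
#' coefficient of determination. Exact ties are broken by the
#' lexicographically smallest marker label.
#'
#' @param candidate_models Non-empty list of `marker_model` objects for one
#'   response.
#' @return List with `selected` (the winning model) and `runners_up` (data
#'   frame `marker`, `r2` for the rest, best first).
#' @export
select_markers <- function(candidate_models) {
  if (length(candidate_models) == 0L) {
    stop("empty candidate set", call. = FALSE)
  }
  stopifnot(all(vapply(candidate_models, inherits, TRUE, "marker_model")))
  r2 <- vapply(candidate_models, function(m) m$r2, numeric(1))
  marker <- vapply(candidate_models, function(m) m$marker, character(1))
  ord <- order(-r2, marker)
  list(selected = candidate_models[[ord[1L]]],
       runners_up = data.frame(marker = marker[ord[-1L]],
                               r2 = r2[ord[-1L]],
                               stringsAsFactors = FALSE))
}

.candidate_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(response = m$response, marker = m$marker,
               alpha = m$alpha, beta = m$beta, r2 = m$r2,
               residual_se = m$residual_se, f_stat = m$f_stat,
               df_den = m$df_den, n_obs = m$n_obs, p_value = m$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' Run the marker-derivation pipeline end to end
#'
#' Executes every stage on in-memory tables: carbon-flux calculation with QC
#' flagging, RPKM normalization, EC aggregation, the minimum-expression
#' filter, log-log fits of the a priori candidate markers, the genome-wide
#' correlation screens against growth rate and metabolic quotient, selection
#' of the best growth and respiration markers, construction and evaluation of
#' the CUE gene index, and (when metadata are supplied) the factorial group
#' statistics. The run is a pure function of its inputs; rerunning with the
#' same inputs gives identical results.
#'
#' @param phenotypes Phenotype data frame (see [compute_fluxes()]).
#' @param counts Gene x sample count matrix. Its samples must be a subset of
#'   the phenotype samples; ids in the counts but not the phenotypes are an
#'   error. Phenotype samples without counts are treated as unsequenced.
#' @param gene_lengths Gene lengths, bp (named by gene id).
#' @param annotation Data frame `gene_id`, `ec_numbers`.
#' @param metadata Optional data frame `sample_id`, `isolate`, `medium`;
#'   enables the ANOVA/Tukey/t-test stage.
#' @param constants A [physio_constants()] object.
#' @param min_rpkm Minimum-expression filter threshold (RPKM, default 10).
#' @param growth_candidates,resp_candidates EC ids of the a priori candidate
#'   markers for growth and respiration.
#' @param nitrogen_marker EC id of the nitrogen-limitation indicator tested
#'   in the group-statistics stage (glutamine synthetase by default).
#' @param pseudocount Pseudocount for the log-log fits (default 0; off).
#' @param output_dir Optional directory; when given, every stage artifact is
#'   written there (TSV tables, JSON models, JSON report).
#' @param quiet Suppress progress messages.
#'
#' @return An object of class `cue_pipeline` with elements `fluxes`, `rpkm`,
#'   `ecmat`, `filtered`, `candidate_models`, `screen_mu`, `screen_qco2`,
#'   `selection`, `index`, `samples` (per-sample index table),
#'   `index_evaluation`, `group_stats` and `report`.
#' @export
run_pipeline <- function(phenotypes, counts, gene_lengths, annotation,
                         metadata = NULL, constants = physio_constants(),
                         min_rpkm = 10,
                         growth_candidates = c("2.4.1.34", "2.4.1.16"),
                         resp_candidates = c("1.2.4.2", "1.1.1.41",
                                             "1.1.1.42"),
                         nitrogen_marker = "6.3.1.2",
                         pseudocount = 0, output_dir = NULL, quiet = FALSE) {
  extra <- setdiff(colnames(counts), phenotypes$sample_id)
  if (length(extra)) {
    stop("count samples missing from the phenotype table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  unsequenced <- setdiff(phenotypes$sample_id, colnames(counts))
  if (length(unsequenced)) {
    .log_msg(quiet, length(unsequenced),
             " sample(s) without expression data (treated as unsequenced)")
  }

  # stage 1: carbon fluxes with QC
  fluxes <- compute_fluxes(phenotypes, constants)
  flagged <- fluxes$sample_id[fluxes$qc_flags != ""]
  if (length(flagged)) {
    .log_msg(quiet, length(flagged), " sample(s) flagged by flux QC: ",
             paste(paste0(flagged, " [",
                          fluxes$qc_flags[fluxes$qc_flags != ""], "]"),
                   collapse = ", "))
  }
  usable <- intersect(usable_samples(fluxes), colnames(counts))
  if (length(usable) < 3L) {
    stop("fewer than 3 usable samples after QC", call. = FALSE)
  }
  .log_msg(quiet, length(usable), " usable samples enter the marker stages")
  fl <- fluxes[match(usable, fluxes$sample_id), ]
  mu <- stats::setNames(fl$mu_per_day, usable)
  qco2 <- stats::setNames(fl$qco2_per_day, usable)
  cue <- stats::setNames(fl$cue, usable)

  # stage 2: expression normalization, aggregation, filter
  rpkm <- rpkm_normalize(counts, gene_lengths)
  ecmat <- aggregate_by_ec(rpkm, annotation)
  ecmat_use <- ecmat[, usable, drop = FALSE]
  filtered <- filter_min_expression(ecmat_use, min_rpkm)
  .log_msg(quiet, nrow(filtered), " of ", nrow(ecmat),
           " enzyme classes pass the ", min_rpkm, "-RPKM filter")

  # stage 3: a priori candidate fits
  fit_candidates <- function(ecs, rates, response) {
    ecs <- intersect(ecs, rownames(ecmat_use))
    models <- lapply(ecs, function(e) {
      fit_loglog(ecmat_use[e, ], rates, response_label = response,
                 marker_label = e, pseudocount = pseudocount)
    })
    stats::setNames(models, ecs)
  }
  growth_models <- fit_candidates(growth_candidates, mu, "mu")
  resp_models <- fit_candidates(resp_candidates, qco2, "qco2")
  candidate_models <- c(growth_models, resp_models)

  # stage 4: genome-wide correlation screens
  screen_mu <- correlation_screen(filtered, mu, response_label = "mu")
  screen_qco2 <- correlation_screen(filtered, qco2, response_label = "qco2")

  # stage 5: marker selection and the CUE index
  index <- NULL
  samples_tab <- NULL
  index_eval <- NULL
  selection <- list()
  if (length(growth_models) == 0L || length(resp_models) == 0L) {
    .log_msg(quiet, "index stage skipped: need at least one candidate ",
             "marker per role (growth: ", length(growth_models),
             ", respiration: ", length(resp_models), ")")
  } else {
    sel_g <- select_markers(growth_models)
    sel_r <- select_markers(resp_models)
    selection <- list(growth = sel_g, resp = sel_r)
    .log_msg(quiet, "selected growth marker ", sel_g$selected$marker,
             " (R2 = ", round(sel_g$selected$r2, 3), "), respiration marker ",
             sel_r$selected$marker, " (R2 = ", round(sel_r$selected$r2, 3),
             ")")
    index <- build_index(sel_g$selected, sel_r$selected)
    gt48 <- ecmat_use[sel_g$selected$marker, ]
    kgd <- ecmat_use[sel_r$selected$marker, ]
    cg <- cue_gene(index, gt48, kgd)
    samples_tab <- data.frame(sample_id = usable,
                              gt48_rpkm = unname(gt48),
                              kgd_rpkm = unname(kgd),
                              cue_gene = unname(cg),
                              simple_ratio = unname(simple_ratio(gt48, kgd)),
                              measured_cue = unname(cue),
                              stringsAsFactors = FALSE)
    ok <- cue > 0 & cue < 1
    index_eval <- evaluate_index(cg[ok], cue[ok])
  }

  # stage 6: factorial group statistics
  group_stats <- NULL
  if (!is.null(metadata)) {
    md <- metadata[match(usable, metadata$sample_id), ]
    if (anyNA(md$sample_id)) {
      stop("metadata lacks sample(s): ",
           paste(setdiff(usable, metadata$sample_id), collapse = ", "),
           call. = FALSE)
    }
    responses <- list(log_mu = log(mu), log_qco2 = log(qco2),
                      log_cue = log(cue))
    if (!is.null(samples_tab)) {
      responses$log_gt48 <- log(samples_tab$gt48_rpkm)
      responses$log_kgd <- log(samples_tab$kgd_rpkm)
      responses$cue_gene <- samples_tab$cue_gene
    }
    if (nitrogen_marker %in% rownames(ecmat_use)) {
      responses$log_gs <- log(ecmat_use[nitrogen_marker, ])
    }
    group_stats <- lapply(responses, function(v) {
      list(anova = two_way_anova(v, md$isolate, md$medium),
           tukey = tukey_hsd(v, md$isolate),
           medium_ttests = per_group_ttests(v, md$medium, md$isolate))
    })
  }

  report <- list(
    n_samples = nrow(phenotypes),
    n_unsequenced = length(unsequenced),
    n_flagged = length(flagged),
    flagged = stats::setNames(fluxes$qc_flags[fluxes$qc_flags != ""],
                              flagged),
    n_usable = length(usable),
    n_classes_total = nrow(ecmat),
    n_classes_retained = nrow(filtered),
    min_rpkm = min_rpkm,
    candidate_table = .candidate_table(candidate_models),
    selected = if (length(selection)) {
      list(growth = selection$growth$selected$marker,
           resp = selection$resp$selected$marker)
    },
    marker_ranks = if (length(selection)) {
      list(growth = marker_rank(screen_mu, selection$growth$selected$marker),
           resp = marker_rank(screen_qco2, selection$resp$selected$marker))
    },
    compact_constant = if (!is.null(index)) index$compact_constant,
    index_evaluation = if (!is.null(index_eval)) .candidate_table(
      list(index_eval))
  )

  result <- structure(list(fluxes = fluxes, rpkm = rpkm, ecmat = ecmat,
                           filtered = filtered,
                           candidate_models = candidate_models,
                           screen_mu = screen_mu, screen_qco2 = screen_qco2,
                           selection = selection, index = index,
                           samples = samples_tab,
                           index_evaluation = index_eval,
                           group_stats = group_stats, report = report),
                      class = "cue_pipeline")
  if (!is.null(output_dir)) .write_pipeline_outputs(result, output_dir)
  result
}

.write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_fluxes(result$fluxes, p("fluxes.tsv"))
  write_matrix_tsv(result$rpkm, p("rpkm.tsv"))
  write_matrix_tsv(result$ecmat, p("ec_rpkm.tsv"), id_col = "ec_id")
  write_matrix_tsv(result$filtered, p("ec_rpkm_filtered.tsv"),
                   id_col = "ec_id")
  utils::write.table(result$screen_mu, p("screen_mu.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$screen_qco2, p("screen_qco2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$samples)) {
    utils::write.table(result$samples, p("cue_index_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$index)) write_model_json(result$index, p("cue_index.json"))
  report <- result$report
  report$candidate_table <- NULL
  jsonlite::write_json(
    c(report, list(candidate_table = result$report$candidate_table)),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  invisible(output_dir)
}

#' @export
print.cue_pipeline <- function(x, ...) {
  r <- x$report
  cat("CUE marker pipeline run\n")
  cat(sprintf("  samples: %d total, %d unsequenced, %d flagged, %d usable\n",
              r$n_samples, r$n_unsequenced, r$n_flagged, r$n_usable))
  cat(sprintf("  enzyme classes: %d aggregated, %d pass the %g-RPKM filter\n",
              r$n_classes_total, r$n_classes_retained, r$min_rpkm))
  cat("  candidate models:\n")
  print.data.frame(r$candidate_table[, c("response", "marker", "alpha",
                                         "beta", "r2")],
                   digits = 3, row.names = FALSE)
  if (!is.null(r$selected)) {
    cat(sprintf("  selected markers: growth %s (screen rank %d), respiration %s (rank %d)\n",
                r$selected$growth, r$marker_ranks$growth,
                r$selected$resp, r$marker_ranks$resp))
    cat(sprintf("  compact constant: %.4g\n", r$compact_constant))
  }
  if (!is.null(x$index_evaluation)) {
    m <- x$index_evaluation
    cat(sprintf("  index vs measured CUE: intercept %.3f, slope %.3f, R2 %.3f\n",
                m$alpha, m$beta, m$r2))
  }
  invisible(x)
}
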