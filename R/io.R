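# Reading and writing the pipeline's tab-separated tables and JSON models.

#' Read a phenotype table
#'
#' Tab-separated with header `sample_id`, `B0_mg`, `Bt_mg`, `t_days`,
#' `delta_co2_ppm`.
#'
#' @param path File path.
#' @return Data frame suitable for [compute_fluxes()].
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "B0_mg", "Bt_mg", "t_days", "delta_co2_ppm")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ph
}

#' Write a flux table
#'
#' @param fluxes A `flux_table` from [compute_fluxes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fluxes, path) {
  stopifnot(inherits(fluxes, "flux_table"))
  utils::write.table(fluxes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix
#'
#' Tab-separated; first column `gene_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @return Gene x sample numeric matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_id") {
    stop("count file must start with a 'gene_id' column", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `length_bp`, `ec_numbers`
#' (comma-separated EC codes, possibly empty).
#'
#' @param path File path.
#' @return Data frame with those columns; `ec_numbers` never `NA`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(ec_numbers = "character"))
  required <- c("gene_id", "length_bp", "ec_numbers")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$ec_numbers[is.na(df$ec_numbers)] <- ""
  df
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m Numeric matrix with rownames.
#' @param path Output file path.
#' @param id_col Name for the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a marker or index model as JSON
#'
#' @param model A `marker_model` or `cue_index_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  x <- if (inherits(model, "cue_index_model")) {
    list(growth_model = unclass(model$growth_model),
         resp_model = unclass(model$resp_model),
         compact_constant = model$compact_constant)
  } else if (inherits(model, "marker_model")) {
    unclass(model)
  } else {
    stop("not a marker_model or cue_index_model", call. = FALSE)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file whose entries correspond to arguments of
#' [run_pipeline()] (e.g. `min_rpkm`, `growth_candidates`) and, under a
#' `constants` block, overrides for [physio_constants()].
#'
#' @param path File path.
#' @return Named list of configuration values, with `constants` already
#'   converted to a `physio_constants` object when present.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$constants)) {
    cfg$constants <- do.call(physio_constants, cfg$constants)
  }
  cfg
}
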