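# RPKM normalization, EC-number aggregation and the minimum-expression filter.

.ec_pattern <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

.check_expression_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry rownames (features) and colnames (samples)",
         call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop(what, " must be non-negative and finite", call. = FALSE)
  }
  invisible(m)
}

#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of gene model per million counted reads:
#' `rpkm[g, s] = counts[g, s] / (length_kb[g] * total[s] / 1e6)`, where
#' `total[s]` is the per-sample sum of counts in the table. Normalizing by the
#' in-table total (reads assigned to genes) makes the result invariant to
#' uniform scaling of a sample's sequencing depth.
#'
#' @param counts Gene x sample numeric matrix of non-negative counts with
#'   gene rownames and sample colnames.
#' @param gene_lengths Gene lengths in bp; either named by gene id or
#'   positionally aligned with `rownames(counts)`.
#'
#' @return Numeric matrix of RPKM values, same dimensions and dimnames as
#'   `counts`.
#' @examples
#' cts <- matrix(c(10, 999990), 2, 1,
#'               dimnames = list(c("g1", "g2"), "s1"))
#' rpkm_normalize(cts, c(g1 = 500, g2 = 1000))["g1", "s1"] # 20
#' @export
rpkm_normalize <- function(counts, gene_lengths) {
  .check_expression_matrix(counts, "'counts'")
  if (!is.null(names(gene_lengths))) {
    missing_len <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing_len)) {
      stop("no gene length for: ",
           paste(utils::head(missing_len, 5), collapse = ", "), call. = FALSE)
    }
    gene_lengths <- gene_lengths[rownames(counts)]
  } else if (length(gene_lengths) != nrow(counts)) {
    stop("'gene_lengths' must match the rows of 'counts'", call. = FALSE)
  }
  .check_positive(gene_lengths, "gene_lengths")

  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  rpkm <- counts / (gene_lengths / 1000)
  sweep(rpkm, 2L, totals / 1e6, "/")
}

# annotation data frame -> named list gene_id -> character vector of ECs
.parse_annotation <- function(annotation) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "ec_numbers") %in% names(annotation))) {
    stop("'annotation' must be a data frame with columns gene_id, ec_numbers",
         call. = FALSE)
  }
  if (anyDuplicated(annotation$gene_id)) {
    stop("duplicated gene_id in annotation", call. = FALSE)
  }
  ecs <- strsplit(ifelse(is.na(annotation$ec_numbers), "",
                         annotation$ec_numbers), ",")
  ecs <- lapply(ecs, function(x) trimws(x[nzchar(trimws(x))]))
  bad <- unique(unlist(ecs))
  bad <- bad[!grepl(.ec_pattern, bad)]
  if (length(bad)) {
    stop("malformed EC number(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  names(ecs) <- annotation$gene_id
  ecs
}

#' Aggregate gene-level expression by Enzyme Commission number
#'
#' Sums RPKM over all genes annotated with each EC number, yielding an
#' enzyme-class x sample matrix that is comparable across species. A gene
#' listed under several EC numbers contributes its full expression to each
#' class; unannotated genes contribute to none. Partial codes (e.g.
#' `1.1.1.-`) are kept as distinct classes.
#'
#' @param expr Gene x sample RPKM matrix (see [rpkm_normalize()]).
#' @param annotation Data frame with columns `gene_id` and `ec_numbers`
#'   (comma-separated EC codes, possibly empty).
#'
#' @return EC x sample numeric matrix with EC ids as rownames, sorted
#'   lexicographically. Annotation rows for genes absent from `expr` are
#'   dropped with a warning.
#' @export
aggregate_by_ec <- function(expr, annotation) {
  .check_expression_matrix(expr, "'expr'")
  ecs <- .parse_annotation(annotation)
  absent <- setdiff(names(ecs), rownames(expr))
  if (length(absent)) {
    warning("annotation references ", length(absent),
            " gene id(s) absent from the expression matrix; ignored",
            call. = FALSE)
    ecs <- ecs[setdiff(names(ecs), absent)]
  }
  pairs <- data.frame(
    gene_id = rep(names(ecs), lengths(ecs)),
    ec = unlist(ecs, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    stop("no annotated gene present in the expression matrix", call. = FALSE)
  }
  out <- rowsum(expr[pairs$gene_id, , drop = FALSE], group = pairs$ec,
                reorder = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}

#' Minimum-expression filter for enzyme classes
#'
#' Retains the enzyme classes expressed at or above `threshold` RPKM in every
#' sample; classes falling below in any one sample are removed. Row order is
#' preserved and the operation is idempotent.
#'
#' @param ecmat EC x sample RPKM matrix (see [aggregate_by_ec()]).
#' @param threshold Minimum RPKM required in all samples (default 10).
#'
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_min_expression <- function(ecmat, threshold = 10) {
  .check_expression_matrix(ecmat, "'ecmat'")
  .check_nonnegative(threshold, "threshold")
  keep <- apply(ecmat, 1L, min) >= threshold
  ecmat[keep, , drop = FALSE]
}

#' EC numbers of the targeted marker enzymes
#'
#' The a priori growth, respiration and nitrogen-limitation marker classes:
#' 1,3-beta-glucan synthase (GT48), chitin synthase (GT2), 2-oxoglutarate
#' dehydrogenase (KGD), NAD- and NADP-dependent isocitrate dehydrogenase, and
#' glutamine synthetase (GS).
#'
#' @return Named character vector of EC codes.
#' @examples
#' marker_ec_numbers()["GT48"]
#' @export
marker_ec_numbers <- function() {
  c(GT48 = "2.4.1.34", GT2 = "2.4.1.16", KGD = "1.2.4.2",
    IDH_NAD = "1.1.1.41", IDH_NADP = "1.1.1.42", GS = "6.3.1.2")
}
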