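# Log-log marker regressions and the genome-wide correlation screen.

#' Construct a marker model from known coefficients
#'
#' Builds a `marker_model` object directly from intercept and slope on the
#' natural-log scale, without fitting. Useful for working with published
#' coefficients (see [reference_models()]) and for prediction utilities.
#'
#' @param alpha Intercept on the natural-log scale.
#' @param beta Slope of ln(rate) on ln(expression).
#' @param response_label Response identifier, e.g. `"mu"` or `"qco2"`.
#' @param marker_label Marker identifier, e.g. an EC number.
#' @param r2,residual_se,f_stat,df_den,n_obs,p_value Optional fit statistics.
#'
#' @return An object of class `marker_model`.
#' @export
as_marker_model <- function(alpha, beta, response_label = "rate",
                            marker_label = "marker", r2 = NA_real_,
                            residual_se = NA_real_, f_stat = NA_real_,
                            df_den = NA_integer_, n_obs = NA_integer_,
                            p_value = NA_real_) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L,
            is.finite(alpha), is.finite(beta))
  structure(list(response = response_label, marker = marker_label,
                 alpha = alpha, beta = beta, r2 = r2,
                 residual_se = residual_se, f_stat = f_stat,
                 df_num = 1L, df_den = df_den, n_obs = n_obs,
                 p_value = p_value),
            class = "marker_model")
}

#' Fit a log-log (power-law) marker model
#'
#' Ordinary least squares of `ln(y)` on `ln(x)`:
#' `ln(rate) = alpha + beta * ln(expression) + eps`. Back-transformed
#' (assuming zero residual) this is the power law
#' `rate = e^alpha * expression^beta` used by [predict_rate()]. All logs are
#' natural. Pairs where either value is non-positive (after the optional
#' pseudocount on `x`) are dropped with a warning; at least three usable
#' pairs are required.
#'
#' @param x Positive expression values (e.g. EC-aggregated RPKM).
#' @param y Positive rate values (e.g. mu or qCO2, day^-1).
#' @param response_label,marker_label Labels stored in the model.
#' @param pseudocount Added to `x` before log transform (default 0; off).
#'
#' @return A `marker_model` with fields `alpha`, `beta`, `r2`, `residual_se`,
#'   `f_stat` (1, n-2 df), `n_obs` and `p_value`.
#' @examples
#' x <- exp(c(1, 2, 3, 4)); y <- exp(c(1, 2, 2, 3))
#' fit_loglog(x, y) # beta 0.6, alpha 0.5, R2 0.9
#' @export
fit_loglog <- function(x, y, response_label = "rate", marker_label = "marker",
                       pseudocount = 0) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  xx <- x + pseudocount
  keep <- is.finite(xx) & is.finite(y) & xx > 0 & y > 0
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) with non-positive or missing values ",
            "excluded from the log-log fit", call. = FALSE)
  }
  lx <- log(xx[keep])
  ly <- log(y[keep])
  n <- length(lx)
  if (n < 3L) stop("fewer than 3 usable pairs for the log-log fit",
                   call. = FALSE)
  if (stats::var(lx) == 0) {
    stop("expression values are constant on the log scale; slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  s <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  f <- unname(s$fstatistic[1L])
  as_marker_model(alpha = unname(stats::coef(fit)[1L]),
                  beta = unname(stats::coef(fit)[2L]),
                  response_label = response_label,
                  marker_label = marker_label,
                  r2 = s$r.squared,
                  residual_se = s$sigma,
                  f_stat = f,
                  df_den = n - 2L,
                  n_obs = n,
                  p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("Log-log marker model: ln(%s) ~ ln(%s)\n", x$response, x$marker))
  cat(sprintf("  alpha = %.4f, beta = %.4f\n", x$alpha, x$beta))
  if (is.finite(x$r2)) {
    cat(sprintf("  R2 = %.3f, residual SE = %.3f, F(1, %d) = %.2f, p = %.3g, n = %d\n",
                x$r2, x$residual_se, x$df_den, x$f_stat, x$p_value, x$n_obs))
  }
  invisible(x)
}

#' Predict a rate from marker expression
#'
#' Evaluates the back-transformed power law `e^alpha * expression^beta`.
#'
#' @param model A `marker_model`.
#' @param expression Positive expression value(s).
#' @return Predicted rate(s), same units as the model response.
#' @export
predict_rate <- function(model, expression) {
  stopifnot(inherits(model, "marker_model"))
  .check_positive(expression, "expression")
  exp(model$alpha) * expression^model$beta
}

#' Zero crossing of a log-log marker model
#'
#' The ln-expression at which the predicted ln-rate is zero, `-alpha/beta`.
#' With a negative intercept and positive slope this is the basal expression
#' level below which the model predicts a rate under 1 (in the response's
#' units); on the expression axis of a log-log plot it is the x-intercept.
#'
#' @param model A `marker_model` with non-zero slope.
#' @return The ln-expression value `-alpha/beta`.
#' @export
zero_crossing <- function(model) {
  stopifnot(inherits(model, "marker_model"))
  if (model$beta == 0) stop("slope is zero; zero crossing undefined",
                            call. = FALSE)
  -model$alpha / model$beta
}

#' Genome-wide marker screen by Pearson correlation
#'
#' For every enzyme class, the Pearson correlation between log-transformed
#' expression and the log-transformed rate across samples, ranked in
#' descending order of the signed coefficient. Ties are broken by EC id
#' (lexicographic); classes with zero variance on the log scale get an
#' undefined coefficient and rank last.
#'
#' @param ecmat EC x sample RPKM matrix, pre-filtered with
#'   [filter_min_expression()] so all entries are positive.
#' @param rates Per-sample positive rates, named by sample id or aligned with
#'   `colnames(ecmat)`.
#' @param response_label Label recorded in the ranking.
#'
#' @return A data frame of class `correlation_ranking` with columns `ec_id`,
#'   `pearson_r`, `rank`, ordered by rank; the response label is stored in
#'   attribute `response_label`.
#' @export
correlation_screen <- function(ecmat, rates, response_label = "mu") {
  .check_expression_matrix(ecmat, "'ecmat'")
  if (!is.null(names(rates))) {
    missing_r <- setdiff(colnames(ecmat), names(rates))
    if (length(missing_r)) {
      stop("no rate for sample(s): ",
           paste(utils::head(missing_r, 5), collapse = ", "), call. = FALSE)
    }
    rates <- rates[colnames(ecmat)]
  } else if (length(rates) != ncol(ecmat)) {
    stop("'rates' must match the samples of 'ecmat'", call. = FALSE)
  }
  .check_positive(rates, "rates")
  if (any(ecmat <= 0)) {
    stop("'ecmat' must be strictly positive (apply filter_min_expression first)",
         call. = FALSE)
  }
  if (ncol(ecmat) < 3L) stop("need at least 3 samples", call. = FALSE)

  lx <- t(log(ecmat))
  ly <- log(rates)
  r <- suppressWarnings(as.vector(stats::cor(lx, ly)))
  r[!is.finite(r)] <- NA_real_
  ec <- rownames(ecmat)
  ord <- order(is.na(r), -ifelse(is.na(r), -Inf, r), ec)
  out <- data.frame(ec_id = ec[ord], pearson_r = r[ord],
                    rank = seq_along(ec), stringsAsFactors = FALSE)
  attr(out, "response_label") <- response_label
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' Rank of an enzyme class in a correlation screen
#'
#' @param ranking A `correlation_ranking` from [correlation_screen()].
#' @param ec_id EC identifier to look up.
#' @return The 1-based rank.
#' @export
marker_rank <- function(ranking, ec_id) {
  stopifnot(inherits(ranking, "correlation_ranking"))
  i <- match(ec_id, ranking$ec_id)
  if (is.na(i)) stop("EC '", ec_id, "' not present in the ranking",
                     call. = FALSE)
  ranking$rank[i]
}
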