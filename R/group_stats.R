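# Factorial comparisons: two-way ANOVA, Tukey HSD with compact letter
# display, and per-stratum Welch t-tests.

#' Two-way ANOVA with interaction
#'
#' Sequential (Type I) sums of squares for the model
#' `value ~ A + B + A:B`, each effect tested against the residual mean
#' square. The first factor is entered first; with mildly unbalanced designs
#' the order matters and can be swapped with `order`.
#'
#' @param values Numeric response vector.
#' @param factor_a First factor (e.g. isolate).
#' @param factor_b Second factor (e.g. growth medium).
#' @param order `"ab"` (A entered before B, default) or `"ba"`.
#' @param labels Length-2 character vector naming the factors in the output.
#'
#' @return A data frame of class `anova_table` with columns `term`, `sum_sq`,
#'   `df`, `f_value`, `p_value` (rows: A, B, A:B, Residuals) and attribute
#'   `model_r2`, the fraction of total variance explained by the full model.
#'   If the residual mean square is zero, F values are reported as 0 with
#'   missing p and a `note` attribute.
#' @export
two_way_anova <- function(values, factor_a, factor_b, order = c("ab", "ba"),
                          labels = c("isolate", "medium")) {
  order <- match.arg(order)
  stopifnot(is.numeric(values),
            length(values) == length(factor_a),
            length(values) == length(factor_b),
            length(labels) == 2L)
  A <- factor(factor_a)
  B <- factor(factor_b)
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(A, B)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("empty cell(s) make the interaction inestimable: ",
         paste(sprintf("%s:%s", rownames(cells)[empty[, 1L]],
                       colnames(cells)[empty[, 2L]]), collapse = ", "),
         call. = FALSE)
  }
  if (length(values) <= nlevels(A) * nlevels(B)) {
    stop("need more observations than cells to estimate the residual",
         call. = FALSE)
  }

  fit <- if (order == "ab") stats::lm(values ~ A * B) else stats::lm(values ~ B * A)
  tab <- suppressWarnings(stats::anova(fit))
  term_map <- if (order == "ab") {
    c(A = labels[1L], B = labels[2L])
  } else {
    c(B = labels[2L], A = labels[1L])
  }
  terms_out <- c(term_map[rownames(tab)[1:2]],
                 paste(labels, collapse = ":"), "Residuals")

  out <- data.frame(term = unname(terms_out),
                    sum_sq = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    f_value = tab[["F value"]],
                    p_value = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  # reorder so A always precedes B in the display
  effect_rows <- match(c(labels[1L], labels[2L], paste(labels, collapse = ":")),
                       out$term)
  out <- out[c(effect_rows, 4L), ]
  rownames(out) <- NULL

  ss_res <- out$sum_sq[out$term == "Residuals"]
  ss_tot <- sum(out$sum_sq)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  # a residual SS at rounding-error level makes F ratios meaningless
  if (ss_res <= 1e-12 * max(ss_tot, .Machine$double.eps) ||
      !all(is.finite(out$f_value[1:3]))) {
    out$f_value[1:3] <- 0
    out$p_value[1:3] <- NA_real_
    attr(out, "note") <- "residual mean square is (numerically) zero; F reported as 0"
  }
  attr(out, "model_r2") <- unname(r2)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat("Two-way ANOVA (sequential SS)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("Model R2 = %.3f\n", attr(x, "model_r2")))
  if (!is.null(attr(x, "note"))) cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}

# greedy compact letter display: cliques of the non-significance graph,
# groups visited in decreasing-mean order
.letter_display <- function(nonsig, group_order) {
  cliques <- list()
  for (g in group_order) {
    placed <- FALSE
    for (i in seq_along(cliques)) {
      if (all(nonsig[g, cliques[[i]]])) {
        cliques[[i]] <- c(cliques[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- g
  }
  letters_out <- stats::setNames(rep("", length(group_order)), group_order)
  for (i in seq_along(cliques)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) lab <- paste0(lab, (i - 1L) %/% 26L)
    for (g in cliques[[i]]) {
      letters_out[g] <- paste0(letters_out[g], lab)
    }
  }
  letters_out
}

#' Tukey honest significant difference comparisons
#'
#' All pairwise group comparisons with studentized-range adjusted p-values,
#' plus a compact letter display (groups sharing a letter do not differ at
#' level `alpha`). Letters are assigned greedily over the non-significance
#' graph, visiting groups in decreasing-mean order, which is deterministic.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor; every group needs at least 2 observations.
#' @param alpha Family-wise significance level for the letter display.
#'
#' @return An object of class `pairwise_comparisons`: a list with
#'   `comparisons` (data frame `group_i`, `group_j`, `mean_diff`,
#'   `adjusted_p`, `significant`), `letters` (named character vector) and
#'   `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g

  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  keys <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  tk <- tk[keys, , drop = FALSE]
  comparisons <- data.frame(group_i = pairs[1L, ],
                            group_j = pairs[2L, ],
                            mean_diff = unname(tk[, "diff"]),
                            adjusted_p = unname(tk[, "p adj"]),
                            stringsAsFactors = FALSE)
  comparisons$significant <- comparisons$adjusted_p < alpha

  nonsig <- matrix(TRUE, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  for (k in seq_len(nrow(comparisons))) {
    if (comparisons$significant[k]) {
      nonsig[comparisons$group_i[k], comparisons$group_j[k]] <- FALSE
      nonsig[comparisons$group_j[k], comparisons$group_i[k]] <- FALSE
    }
  }
  means <- tapply(values, g, mean)
  group_order <- names(sort(means, decreasing = TRUE))
  structure(list(comparisons = comparisons,
                 letters = .letter_display(nonsig, group_order)[lev],
                 alpha = alpha),
            class = "pairwise_comparisons")
}

#' @export
print.pairwise_comparisons <- function(x, ...) {
  cat(sprintf("Tukey HSD comparisons (alpha = %g)\n", x$alpha))
  print.data.frame(x$comparisons, digits = 4, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Per-stratum two-sample t-tests
#'
#' Compares the two levels of a treatment factor (e.g. growth medium) within
#' each stratum (e.g. isolate) separately, which is robust to large variance
#' differences between strata. Welch's unequal-variance t-test by default;
#' set `var_equal = TRUE` for the pooled-variance Student test. Strata
#' missing a treatment level, with fewer than 2 observations per level, or
#' with zero variance in both levels are reported with missing statistics.
#'
#' @param values Numeric response vector.
#' @param treatment Two-level factor compared within each stratum.
#' @param stratum Stratification factor.
#' @param var_equal Assume equal variances (default `FALSE`, Welch).
#'
#' @return Data frame with columns `stratum`, `n_1`, `n_2`, `t`, `df`,
#'   `p_value`; one row per stratum level.
#' @export
per_group_ttests <- function(values, treatment, stratum, var_equal = FALSE) {
  stopifnot(is.numeric(values),
            length(values) == length(treatment),
            length(values) == length(stratum))
  trt <- factor(treatment)
  if (nlevels(trt) != 2L) {
    stop("'treatment' must have exactly 2 levels", call. = FALSE)
  }
  st <- factor(stratum)
  rows <- lapply(levels(st), function(s) {
    sel <- st == s
    v1 <- values[sel & trt == levels(trt)[1L]]
    v2 <- values[sel & trt == levels(trt)[2L]]
    res <- data.frame(stratum = s, n_1 = length(v1), n_2 = length(v2),
                      t = NA_real_, df = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(v1) >= 2L && length(v2) >= 2L) {
      tt <- tryCatch(stats::t.test(v1, v2, var.equal = var_equal),
                     error = function(e) NULL)
      if (!is.null(tt)) {
        res$t <- unname(tt$statistic)
        res$df <- unname(tt$parameter)
        res$p_value <- tt$p.value
      }
    }
    res
  })
  do.call(rbind, rows)
}
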