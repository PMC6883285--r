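# Relative quantification of a target miRNA by 2^-ddCq against one or more
# reference genes, with one-way ANOVA and Tukey HSD across groups.

#' Relative expression by the 2^-ddCq method
#'
#' For each sample, `dCq = Cq_target - mean(Cq_references)` (the arithmetic
#' mean of reference Cq values corresponds to the geometric mean of reference
#' quantities), `ddCq = dCq - mean(dCq over calibrator-group samples)`, and
#' the fold change is `2^-ddCq`. By construction the calibrator group's
#' geometric-mean fold change is 1. A per-sample shift applied to target and
#' references alike (a loading difference) cancels exactly.
#'
#' @param ds A [cq_dataset()] with aggregated Cq values.
#' @param target Target gene identifier.
#' @param references Non-empty character vector of reference genes.
#' @param calibrator_group Group label used as calibrator (e.g. the untreated
#'   animals).
#' @return Object of class `relative_expression`: data frame `sample`,
#'   `group`, `dcq`, `ddcq`, `fold_change`, with `target`, `references`,
#'   `calibrator_group` attributes.
#' @export
relative_expression <- function(ds, target, references, calibrator_group) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (!length(references)) stop("`references` must be non-empty", call. = FALSE)
  need <- unique(c(target, references))
  miss <- setdiff(need, colnames(ds$cq))
  if (length(miss)) stop("gene(s) not in dataset: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!calibrator_group %in% ds$groups) {
    stop("calibrator group '", calibrator_group, "' has no samples", call. = FALSE)
  }
  cells <- ds$cq[, need, drop = FALSE]
  if (anyNA(cells)) {
    bad <- which(is.na(cells), arr.ind = TRUE)
    stop("missing Cq for: ",
         paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1L]],
                       colnames(cells)[bad[, 2L]]), collapse = ", "),
         call. = FALSE)
  }
  dcq <- ds$cq[, target] - rowMeans(ds$cq[, references, drop = FALSE])
  ddcq <- dcq - mean(dcq[ds$groups == calibrator_group])
  out <- data.frame(sample = rownames(ds$cq), group = unname(ds$groups),
                    dcq = unname(dcq), ddcq = unname(ddcq),
                    fold_change = 2^(-unname(ddcq)))
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "references") <- references
  attr(out, "calibrator_group") <- calibrator_group
  class(out) <- c("relative_expression", class(out))
  out
}

#' One-way ANOVA with Tukey post-hoc on relative expression
#'
#' Tests fold changes across experimental groups with a one-way ANOVA
#' followed by Tukey's multiple comparison test. The ANOVA runs on the linear
#' fold changes by default (the convention of 2^-ddCq reports);
#' `log_scale = TRUE` analyzes `-ddCq` (log2 fold changes) instead, which is
#' statistically preferable since fold changes are log-normal-like. Tukey
#' comparisons are always computed but flagged as not indicated when the
#' overall p exceeds `alpha`. Degrees of freedom follow the actual input
#' sizes: (G - 1, N - G) for N samples in G groups.
#'
#' @param expr A [relative_expression()] result.
#' @param alpha Significance level gating the post-hoc indication.
#' @param log_scale Analyze log2 fold changes instead of linear ones?
#' @return Object of class `group_test_report`: `F`, `df` (between, within),
#'   `p`, `tukey` (data frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`),
#'   `post_hoc_indicated`, `degenerate`.
#' @export
anova_tukey <- function(expr, alpha = 0.05, log_scale = FALSE) {
  stopifnot(inherits(expr, "relative_expression"))
  grp <- factor(expr$group)
  if (nlevels(grp) < 2L || any(table(grp) < 2L)) {
    stop("need at least 2 groups with at least 2 samples each", call. = FALSE)
  }
  y <- if (log_scale) -expr$ddcq else expr$fold_change
  fit <- stats::aov(y ~ grp)
  an <- summary(fit)[[1L]]  # row 1 = groups, row 2 = residuals
  degenerate <- an[2L, "Sum Sq"] < 1e-12 * max(1, an[1L, "Sum Sq"])
  Fval <- an[1L, "F value"]
  pval <- an[1L, "Pr(>F)"]
  tk <- stats::TukeyHSD(fit)$grp
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  rownames(tukey) <- NULL
  structure(
    list(F = unname(Fval), df = as.integer(an$Df), p = unname(pval), tukey = tukey,
         post_hoc_indicated = isTRUE(pval < alpha), degenerate = degenerate,
         scale = if (log_scale) "log2 fold change" else "fold change"),
    class = "group_test_report"
  )
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$scale, x$df[1L], x$df[2L], x$F, x$p,
              if (x$degenerate) " [degenerate: no residual variance]" else ""))
  cat(if (x$post_hoc_indicated) "Tukey HSD (indicated):\n" else
    "Tukey HSD (post-hoc not indicated at overall alpha):\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
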