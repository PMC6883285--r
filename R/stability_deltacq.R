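# Comparative delta-Cq stability: SD of pairwise Cq differences, averaged per
# gene. Per-sample loading shifts cancel exactly in every pairwise difference,
# which is the method's core robustness property.

#' Comparative delta-Cq stability
#'
#' For every ordered gene pair (g, h), forms the per-sample Cq differences
#' `dCq_s = Cq[s, g] - Cq[s, h]` and records their sample SD (denominator
#' n-1). A gene's stability measure is the mean of its pairwise SDs against
#' all other genes; low mean SD indicates stable expression. Groups are
#' pooled by default (the SD is taken across all samples); `by_group = TRUE`
#' computes the statistic within each group for exploration.
#'
#' @param ds A [cq_dataset()] with aggregated Cq values (no missing cells).
#' @param by_group Also return per-group mean SDs?
#' @return Object of class `delta_cq_result`: `pair_sd` (symmetric gene x
#'   gene matrix, zero diagonal), `table` (data frame `gene`, `mean_sd`,
#'   `rank`; ascending ranks, ties averaged; with exactly two genes both are
#'   tied at rank 1.5 by symmetry), and optionally `by_group`.
#' @export
delta_cq_stability <- function(ds, by_group = FALSE) {
  stopifnot(inherits(ds, "cq_dataset"))
  cq <- ds$cq
  if (anyNA(cq)) stop("missing Cq values; handle upstream", call. = FALSE)
  if (nrow(cq) < 3L || ncol(cq) < 2L) {
    stop("delta-Cq stability needs at least 3 samples and 2 genes", call. = FALSE)
  }
  genes <- colnames(cq); G <- length(genes)
  pair_sd <- matrix(0, G, G, dimnames = list(genes, genes))
  for (g in seq_len(G - 1L)) {
    for (h in (g + 1L):G) {
      s <- stats::sd(cq[, g] - cq[, h])
      pair_sd[g, h] <- s
      pair_sd[h, g] <- s
    }
  }
  mean_sd <- rowSums(pair_sd) / (G - 1L)
  res <- list(
    pair_sd = pair_sd,
    table = data.frame(gene = genes, mean_sd = unname(mean_sd),
                       rank = rank(mean_sd, ties.method = "average"))
  )
  if (by_group) {
    res$by_group <- lapply(split(rownames(cq), ds$groups), function(s) {
      if (length(s) < 3L) return(NULL)
      delta_cq_stability(cq_dataset(cq[s, , drop = FALSE], ds$groups[s],
                                    ds$tissue, ds$setting))$table
    })
  }
  structure(res, class = "delta_cq_result")
}

#' @export
print.delta_cq_result <- function(x, ...) {
  cat("Comparative delta-Cq stability (mean SD of pairwise Cq differences)\n")
  print(x$table[order(x$table$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}
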