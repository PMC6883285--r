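# BestKeeper stability: per-gene Cq SD, the BestKeeper index (per-sample
# geometric mean of Cq), Pearson correlation of each gene with the index, and
# the mean ranking score over the SD and correlation rankings.

#' BestKeeper stability evaluation
#'
#' For each candidate gene, computes the SD of its Cq values across all
#' samples (pooled over groups, denominator n-1) and the Pearson correlation
#' `r` (with p value) against the BestKeeper index, the per-sample geometric
#' mean of the Cq values of all evaluated genes. Stable candidates show low
#' SD and high correlation with the index. Genes are ranked ascending by SD
#' and descending by `r` (ties get average ranks) and the mean ranking score
#' is the average of the two ranks. Candidates with SD above `sd_cutoff`
#' (default 1 cycle) are flagged inappropriate for normalization and carry no
#' ranks; by default they still enter the index, since the SD cut is an
#' appropriateness rule, not an index-membership rule (`bki_genes =
#' "included"` restricts the index to unflagged genes).
#'
#' Non-significant correlation p values do not gate the ranking -- they are
#' reported alongside. Ranking uses the signed `r`; a message is emitted when
#' negative correlations appear, since signed and absolute ranking then
#' diverge.
#'
#' @param ds A [cq_dataset()] with aggregated Cq values (no missing cells).
#' @param sd_cutoff SD above which a gene is flagged inappropriate.
#' @param bki_genes `"all"` (default) or `"included"`, see above.
#' @return Object of class `bestkeeper_result`: `table` (data frame `gene`,
#'   `sd`, `r`, `p`, `sd_rank`, `r_rank`, `mean_rank_score`, `excluded`) and
#'   `bki` (named per-sample index vector).
#' @export
bestkeeper <- function(ds, sd_cutoff = 1, bki_genes = c("all", "included")) {
  stopifnot(inherits(ds, "cq_dataset"))
  bki_genes <- match.arg(bki_genes)
  cq <- ds$cq
  if (anyNA(cq)) {
    stop("missing Cq values; impute or drop the affected genes/samples upstream",
         call. = FALSE)
  }
  if (nrow(cq) < 3L || ncol(cq) < 2L) {
    stop("BestKeeper needs at least 3 samples and 2 genes", call. = FALSE)
  }
  sd_g <- apply(cq, 2L, stats::sd)
  excluded <- sd_g > sd_cutoff
  idx_genes <- if (bki_genes == "all") colnames(cq) else colnames(cq)[!excluded]
  if (length(idx_genes) < 2L) {
    stop("fewer than 2 genes available for the BestKeeper index", call. = FALSE)
  }
  bki <- exp(rowMeans(log(cq[, idx_genes, drop = FALSE])))
  if (stats::sd(bki) == 0) {
    r <- rep(NA_real_, ncol(cq)); p <- r
    warning("constant BestKeeper index: correlations undefined", call. = FALSE)
  } else {
    ct <- lapply(seq_len(ncol(cq)), function(j) {
      if (stats::sd(cq[, j]) == 0) return(list(estimate = NA_real_, p.value = NA_real_))
      stats::cor.test(cq[, j], bki, method = "pearson")
    })
    r <- vapply(ct, function(x) unname(x$estimate), numeric(1L))
    p <- vapply(ct, function(x) x$p.value, numeric(1L))
  }
  if (any(!is.na(r) & r < 0)) {
    message("negative correlation(s) with the BestKeeper index; ",
            "ranking uses signed r")
  }
  sd_rank <- r_rank <- rep(NA_real_, ncol(cq))
  inc <- !excluded
  sd_rank[inc] <- rank(sd_g[inc], ties.method = "average")
  r_rank[inc] <- rank(-r[inc], ties.method = "average")
  structure(
    list(table = data.frame(gene = colnames(cq), sd = unname(sd_g), r = r, p = p,
                            sd_rank = sd_rank, r_rank = r_rank,
                            mean_rank_score = (sd_rank + r_rank) / 2,
                            excluded = unname(excluded)),
         bki = bki, sd_cutoff = sd_cutoff),
    class = "bestkeeper_result"
  )
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper stability (SD cutoff", x$sd_cutoff, "cycles)\n")
  tab <- x$table[order(x$table$mean_rank_score), ]
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
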