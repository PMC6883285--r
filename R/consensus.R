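# Consensus stability ranking: combine the per-gene ranks of the four
# stability methods into one overall list per tissue and Cq setting.

#' Overall consensus ranking across the four stability methods
#'
#' Each method contributes a per-gene score: BestKeeper its (possibly
#' fractional) mean of SD-rank and correlation-rank, the delta-Cq method and
#' NormFinder their ordinal ranks, and geNorm its exclusion-order rank with
#' the tied 1.5 for both members of the final pair. The overall score is the
#' arithmetic mean of the four (geometric available as a variant; it dampens
#' extreme ranks and is therefore not the default), and the overall rank
#' orders genes by ascending overall score with average ties. All methods
#' must have been computed on the same gene set.
#'
#' @param bestkeeper A [bestkeeper()] result.
#' @param deltacq A [delta_cq_stability()] result.
#' @param genorm A [genorm_stepwise()] / [genorm()] result.
#' @param normfinder A [normfinder()] result.
#' @param aggregation `"arithmetic"` (default) or `"geometric"`.
#' @return Object of class `consensus_ranking`: a data frame `gene`,
#'   `bestkeeper`, `deltacq`, `genorm`, `normfinder`, `overall_score`,
#'   `overall_rank`, with the aggregation label as an attribute.
#' @export
overall_ranking <- function(bestkeeper, deltacq, genorm, normfinder,
                            aggregation = c("arithmetic", "geometric")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(bestkeeper, "bestkeeper_result"),
            inherits(deltacq, "delta_cq_result"),
            inherits(genorm, "genorm_result"),
            inherits(normfinder, "normfinder_result"))
  bk <- bestkeeper$table[!bestkeeper$table$excluded, ]
  sets <- list(bestkeeper = bk$gene, deltacq = deltacq$table$gene,
               genorm = names(genorm$ranks), normfinder = normfinder$table$gene)
  genes <- sets[[1L]]
  for (m in names(sets)[-1L]) {
    extra <- setdiff(sets[[m]], genes)
    missing <- setdiff(genes, sets[[m]])
    if (length(extra) || length(missing)) {
      stop(sprintf("gene sets differ across methods (%s): extra {%s}, missing {%s}",
                   m, paste(extra, collapse = ", "),
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  scores <- cbind(
    bestkeeper = bk$mean_rank_score[match(genes, bk$gene)],
    deltacq = deltacq$table$rank[match(genes, deltacq$table$gene)],
    genorm = unname(genorm$ranks[genes]),
    normfinder = normfinder$table$rank[match(genes, normfinder$table$gene)]
  )
  overall <- if (aggregation == "arithmetic") rowMeans(scores) else
    exp(rowMeans(log(scores)))
  out <- data.frame(gene = genes, scores,
                    overall_score = overall,
                    overall_rank = rank(overall, ties.method = "average"))
  rownames(out) <- NULL
  attr(out, "aggregation") <- aggregation
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Compare two consensus rankings
#'
#' Typically used to compare the ranking obtained under the common-threshold
#' Cq setting with the regression-corrected one. Reports the per-gene signed
#' rank difference and the Spearman correlation of the overall scores.
#'
#' @param ranking_a,ranking_b Two [overall_ranking()] results on the same
#'   gene set.
#' @return List with `table` (gene, rank_a, rank_b, delta) and
#'   `spearman_rho`.
#' @export
compare_settings <- function(ranking_a, ranking_b) {
  stopifnot(inherits(ranking_a, "consensus_ranking"),
            inherits(ranking_b, "consensus_ranking"))
  if (!setequal(ranking_a$gene, ranking_b$gene)) {
    stop("gene set mismatch: {",
         paste(setdiff(ranking_a$gene, ranking_b$gene), collapse = ", "),
         "} vs {",
         paste(setdiff(ranking_b$gene, ranking_a$gene), collapse = ", "), "}",
         call. = FALSE)
  }
  b <- ranking_b[match(ranking_a$gene, ranking_b$gene), ]
  list(
    table = data.frame(gene = ranking_a$gene,
                       rank_a = ranking_a$overall_rank,
                       rank_b = b$overall_rank,
                       delta = ranking_a$overall_rank - b$overall_rank),
    spearman_rho = stats::cor(ranking_a$overall_score, b$overall_score,
                              method = "spearman")
  )
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Consensus stability ranking (", attr(x, "aggregation"), " mean of method ranks)\n",
      sep = "")
  print(as.data.frame(x)[order(x$overall_rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}
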