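# One-call stability workflow: replicate QC, the four stability methods, and
# the consensus ranking, with the candidate-set conventions documented below.

#' Run the full reference-gene stability workflow
#'
#' Aggregates technical replicates, applies the duplicate-SD admissibility
#' rule, runs BestKeeper, the comparative delta-Cq method, geNorm and
#' NormFinder on the surviving candidates, and combines them into the
#' consensus ranking. Candidates flagged by BestKeeper as inappropriate
#' (Cq SD above `bk_sd_cutoff`) are removed from the candidate set and all
#' methods are recomputed on the reduced set, so every ranked gene carries
#' exactly four method scores.
#'
#' @param ds A [cq_dataset()] (with or without stored replicates).
#' @param sd_cutoff Duplicate-SD admissibility cut in cycles.
#' @param keep Genes retained despite a duplicate-SD flag.
#' @param bk_sd_cutoff BestKeeper appropriateness cut in cycles.
#' @param aggregation Consensus aggregation, see [overall_ranking()].
#' @return List with `qc` (the per-gene QC flags), `dropped_bestkeeper`,
#'   `bestkeeper`, `deltacq`, `genorm`, `normfinder`, `consensus`.
#' @export
evaluate_stability <- function(ds, sd_cutoff = 0.167, keep = character(),
                               bk_sd_cutoff = 1,
                               aggregation = c("arithmetic", "geometric")) {
  stopifnot(inherits(ds, "cq_dataset"))
  agg <- aggregate_technical_replicates(ds)
  qc <- if (nrow(agg$report)) {
    flag_high_variability_candidates(agg$report, sd_cutoff = sd_cutoff,
                                     keep = keep)
  } else {
    data.frame(gene = colnames(ds$cq), summary_sd = NA_real_,
               n_pairs = 0L, excluded = FALSE, reason = "")
  }
  work <- subset_genes(agg$dataset, qc$gene[!qc$excluded])
  bk <- bestkeeper(work, sd_cutoff = bk_sd_cutoff)
  dropped <- bk$table$gene[bk$table$excluded]
  if (length(dropped)) {
    work <- subset_genes(work, setdiff(colnames(work$cq), dropped))
    bk <- bestkeeper(work, sd_cutoff = bk_sd_cutoff)
  }
  dc <- delta_cq_stability(work)
  gn <- genorm(work)
  nf <- normfinder(work)
  cons <- overall_ranking(bk, dc, gn, nf, aggregation = aggregation)
  list(qc = qc, dropped_bestkeeper = dropped, bestkeeper = bk, deltacq = dc,
       genorm = gn, normfinder = nf, consensus = cons)
}
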