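# Technical-replicate aggregation, the duplicate-SD admissibility rule, and
# generic QC correlations.

#' Aggregate technical replicates
#'
#' Collapses the technical replicates of a [cq_dataset()] into per-(sample,
#' gene) arithmetic means and reports the per-pair duplicate SD (sample SD,
#' denominator n-1). For exactly two replicates the duplicate SD equals
#' |difference| / sqrt(2). A (sample, gene) cell with a single surviving
#' replicate keeps that value as its mean and is flagged; its SD is undefined
#' and excluded from downstream summaries rather than fabricated.
#'
#' @param ds A [cq_dataset()]. Datasets without stored replicates pass
#'   through unchanged with an empty report.
#' @return List with `dataset` (replicate means in `cq`) and `report`, a
#'   `replicate_qc_report` data frame: `sample`, `gene`, `n_replicates`,
#'   `mean_cq`, `sd`, `single_replicate`; the tissue is carried as an
#'   attribute.
#' @export
aggregate_technical_replicates <- function(ds) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (is.null(ds$replicate_cq)) {
    report <- data.frame(sample = character(), gene = character(),
                         n_replicates = integer(), mean_cq = numeric(),
                         sd = numeric(), single_replicate = logical())
    attr(report, "tissue") <- ds$tissue
    class(report) <- c("replicate_qc_report", class(report))
    return(list(dataset = ds, report = report))
  }
  samples <- rownames(ds$cq); genes <- colnames(ds$cq)
  grid <- expand.grid(sample = samples, gene = genes, stringsAsFactors = FALSE)
  stats_fun <- function(s, g) {
    reps <- ds$replicate_cq[s, g, ]
    reps <- reps[!is.na(reps)]
    n <- length(reps)
    c(n = n,
      mean = if (n) mean(reps) else NA_real_,
      sd = if (n >= 2L) stats::sd(reps) else NA_real_)
  }
  st <- mapply(stats_fun, grid$sample, grid$gene)
  report <- data.frame(sample = grid$sample, gene = grid$gene,
                       n_replicates = as.integer(st["n", ]),
                       mean_cq = st["mean", ], sd = st["sd", ],
                       single_replicate = st["n", ] == 1L)
  attr(report, "tissue") <- ds$tissue
  class(report) <- c("replicate_qc_report", class(report))
  cq <- matrix(st["mean", ], nrow = length(samples),
               dimnames = list(samples, genes))
  list(dataset = cq_dataset(cq, ds$groups, ds$tissue, ds$setting, ds$replicate_cq),
       report = report)
}

#' Flag genes with excessive technical-replicate variability
#'
#' Applies the duplicate-SD admissibility rule: a candidate gene whose
#' tissue-level summary of per-sample duplicate SDs exceeds `sd_cutoff`
#' (default 0.167 cycles, the SD required to resolve a 2-fold expression
#' change) is excluded from further analysis. The summary statistic is the
#' arithmetic mean of per-sample SDs by default (the quantity plotted in
#' per-tissue duplicate-variability figures); `stat = "median"` or `"max"`
#' are available. An override list can retain a flagged gene -- reference-gene
#' studies occasionally keep a candidate whose variability is acceptable
#' under one Cq setting -- in which case a warning is logged.
#'
#' @param report A `replicate_qc_report` from
#'   [aggregate_technical_replicates()].
#' @param sd_cutoff Duplicate-SD cut in cycles.
#' @param stat Tissue-level summary of per-sample SDs.
#' @param keep Character vector of genes retained despite the flag.
#' @return Data frame per gene: `gene`, `summary_sd`, `n_pairs`, `excluded`,
#'   `reason`.
#' @export
flag_high_variability_candidates <- function(report, sd_cutoff = 0.167,
                                             stat = c("mean", "median", "max"),
                                             keep = character()) {
  stopifnot(inherits(report, "replicate_qc_report"))
  stat <- match.arg(stat)
  fun <- switch(stat, mean = mean, median = stats::median, max = max)
  genes <- unique(report$gene)
  out <- lapply(genes, function(g) {
    sds <- report$sd[report$gene == g]
    sds <- sds[!is.na(sds)]
    summary_sd <- if (length(sds)) fun(sds) else NA_real_
    flagged <- !is.na(summary_sd) && summary_sd > sd_cutoff
    excluded <- flagged && !(g %in% keep)
    reason <- if (!flagged) "" else if (excluded) {
      sprintf("%s duplicate SD %.3f > %.3f", stat, summary_sd, sd_cutoff)
    } else "retained by override despite duplicate SD flag"
    data.frame(gene = g, summary_sd = summary_sd, n_pairs = length(sds),
               excluded = excluded, reason = reason)
  })
  out <- do.call(rbind, out)
  overridden <- out$gene[out$reason == "retained by override despite duplicate SD flag"]
  if (length(overridden)) {
    warning("retained despite duplicate SD > ", sd_cutoff, ": ",
            paste(overridden, collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Correlate two per-sample QC metrics
#'
#' Pearson correlation with a two-sided p value from the t transform, for QC
#' pairings such as RNA integrity number against per-amplicon efficiency.
#'
#' @param x,y Paired numeric metrics; pairs with missing values are dropped.
#' @return List with `r`, `p`, `n` and `note` (`"ok"`, or
#'   `"zero variance: correlation undefined"` with `r = NA`).
#' @export
correlate_qc_metrics <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired finite observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "zero variance: correlation undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), note = "ok")
}
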