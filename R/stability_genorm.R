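# geNorm stability: per-gene expression stability M (average SD of pairwise
# log2 expression ratios), iterative worst-candidate exclusion down to the
# most stable pair, and the pairwise-variation V series that determines how
# many reference genes are needed.

# Per-sample log2 relative quantities. With efficiency fixed at 2 (perfect
# doubling), log2 q[s, g] = meanCq_g - Cq[s, g]; with per-gene efficiencies,
# log2 q[s, g] = (meanCq_g - Cq[s, g]) * log2(E_g). The per-gene reference
# point (its mean Cq) is a constant and cancels in every ratio and in V.
log2_quantities <- function(cq, efficiencies = NULL) {
  genes <- colnames(cq)
  if (is.null(efficiencies)) {
    eff <- rep(2, length(genes))
  } else {
    if (is.null(names(efficiencies))) {
      stop("`efficiencies` must be named by gene", call. = FALSE)
    }
    miss <- setdiff(genes, names(efficiencies))
    if (length(miss)) stop("missing efficiencies for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    eff <- unname(efficiencies[genes])
  }
  sweep(sweep(-cq, 2L, -colMeans(cq)), 2L, log2(eff), `*`)
}

#' geNorm expression stability M
#'
#' The stability M of a gene is the arithmetic mean, over all other genes, of
#' the SD across samples of their pairwise log2 expression ratio. With the
#' default efficiency of 2 the log2 ratio of genes (g, h) in sample s is
#' `Cq[s, h] - Cq[s, g]`, so M coincides exactly with the comparative
#' delta-Cq mean SD. Lower M means more stable expression; the conventional
#' warning level is M > 1.5.
#'
#' @param ds A [cq_dataset()] with aggregated Cq values (no missing cells).
#' @param genes Optional subset of genes (at least 2).
#' @param efficiencies Optional named per-gene amplification factors; the
#'   default assumes E = 2 for every assay.
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(ds, genes = NULL, efficiencies = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  cq <- ds$cq
  if (anyNA(cq)) stop("missing Cq values; handle upstream", call. = FALSE)
  if (!is.null(genes)) cq <- cq[, genes, drop = FALSE]
  if (ncol(cq) < 2L || nrow(cq) < 3L) {
    stop("geNorm M needs at least 2 genes and 3 samples", call. = FALSE)
  }
  lq <- log2_quantities(cq, efficiencies)
  G <- ncol(lq)
  m <- vapply(seq_len(G), function(g) {
    mean(vapply(setdiff(seq_len(G), g),
                function(h) stats::sd(lq[, g] - lq[, h]), numeric(1L)))
  }, numeric(1L))
  names(m) <- colnames(cq)
  m
}

#' geNorm stepwise exclusion
#'
#' Repeatedly recomputes M on the remaining genes and removes the candidate
#' with the worst (largest) M until the most stable pair remains. The final
#' pair is unordered by construction, so both members receive the tied rank
#' 1.5 and the excluded genes receive ranks n, n-1, ..., 3 in exclusion
#' order. Ties at the worst M are broken by removing the gene with the larger
#' raw Cq SD, then lexicographically; tie events are recorded.
#'
#' @inheritParams genorm_m
#' @return Object of class `genorm_result`: `initial_m`, `exclusion_order`
#'   (worst first), `final_pair`, `m_trajectory` (mean M of the remaining
#'   genes at each step, named by remaining-set size), `ranks`,
#'   `high_m_genes` (genes whose initial M exceeds the 1.5 warning level) and
#'   `ties` (log of tie-break events).
#' @export
genorm_stepwise <- function(ds, efficiencies = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (ncol(ds$cq) < 3L) stop("stepwise exclusion needs at least 3 genes", call. = FALSE)
  initial_m <- genorm_m(ds, efficiencies = efficiencies)
  remaining <- colnames(ds$cq)
  cq_sd <- apply(ds$cq, 2L, stats::sd)
  exclusion_order <- character(0)
  m_traj <- numeric(0)
  ties <- character(0)
  repeat {
    m <- genorm_m(ds, genes = remaining, efficiencies = efficiencies)
    m_traj[as.character(length(remaining))] <- mean(m)
    if (length(remaining) == 2L) break
    worst <- names(m)[m >= max(m) - 1e-12]
    if (length(worst) > 1L) {
      ties <- c(ties, sprintf("M tie among {%s} at set size %d",
                              paste(worst, collapse = ", "), length(remaining)))
      sds <- cq_sd[worst]
      worst <- worst[sds >= max(sds) - 1e-12]
      worst <- sort(worst)[1L]
    }
    exclusion_order <- c(exclusion_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  n <- ncol(ds$cq)
  ranks <- stats::setNames(rep(1.5, 2L), remaining)
  if (length(exclusion_order)) {
    ranks <- c(ranks, stats::setNames(seq(n, 3L), exclusion_order))
  }
  ranks <- ranks[colnames(ds$cq)]
  structure(
    list(initial_m = initial_m, exclusion_order = exclusion_order,
         final_pair = remaining, m_trajectory = m_traj, ranks = ranks,
         high_m_genes = names(initial_m)[initial_m > 1.5], ties = ties),
    class = "genorm_result"
  )
}

#' geNorm pairwise variation V and optimal reference-gene count
#'
#' For the n best-ranked genes, the normalization factor `NF_n[s]` is the
#' geometric mean of their relative quantities in sample s. The pairwise
#' variation `V(n/n+1)` is the SD across samples of `log2(NF_n / NF_(n+1))`;
#' it measures how much adding the (n+1)-th gene changes normalization. The
#' optimal count is the smallest n with `V(n/n+1)` below `v_cutoff` (default
#' 0.15); when no V falls below the cutoff all candidates are needed and a
#' flag is set. V is invariant to the per-gene reference point used for the
#' relative quantities, since any per-gene constant cancels in the SD.
#'
#' @param ds A [cq_dataset()].
#' @param ranking A `genorm_result` from [genorm_stepwise()] (or a named rank
#'   vector); determines the best-first gene ordering.
#' @param v_cutoff Acceptability cut for V.
#' @inheritParams genorm_m
#' @return List with `v_series` (named `V2/3`, `V3/4`, ...), `optimal_n`, and
#'   `below_cutoff` (logical: did some V pass the cut?).
#' @export
genorm_pairwise_variation <- function(ds, ranking, v_cutoff = 0.15,
                                      efficiencies = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  ranks <- if (inherits(ranking, "genorm_result")) ranking$ranks else ranking
  genes <- names(sort(ranks))
  if (length(genes) < 3L) stop("pairwise variation needs at least 3 genes", call. = FALSE)
  lq <- log2_quantities(ds$cq[, genes, drop = FALSE], efficiencies)
  # log2 NF_n per sample = mean of log2 quantities of the n best genes
  v <- vapply(2:(length(genes) - 1L), function(n) {
    nf_n <- rowMeans(lq[, seq_len(n), drop = FALSE])
    nf_n1 <- rowMeans(lq[, seq_len(n + 1L), drop = FALSE])
    stats::sd(nf_n - nf_n1)
  }, numeric(1L))
  names(v) <- sprintf("V%d/%d", 2:(length(genes) - 1L), 3:length(genes))
  ok <- v < v_cutoff
  list(v_series = v,
       optimal_n = if (any(ok)) unname(which(ok)[1L] + 1L) else length(genes),
       below_cutoff = any(ok))
}

#' Full geNorm analysis
#'
#' Runs [genorm_stepwise()] and [genorm_pairwise_variation()] and returns the
#' combined result.
#'
#' @inheritParams genorm_pairwise_variation
#' @return A `genorm_result` extended with `v_series`, `optimal_n`,
#'   `below_cutoff`.
#' @export
genorm <- function(ds, v_cutoff = 0.15, efficiencies = NULL) {
  res <- genorm_stepwise(ds, efficiencies = efficiencies)
  pv <- genorm_pairwise_variation(ds, res, v_cutoff = v_cutoff,
                                  efficiencies = efficiencies)
  res[names(pv)] <- pv
  res
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability\n")
  cat("  most stable pair:", paste(x$final_pair, collapse = " / "), "\n")
  cat("  exclusion order (worst first):",
      paste(x$exclusion_order, collapse = ", "), "\n")
  if (length(x$high_m_genes)) {
    cat("  genes with initial M > 1.5:", paste(x$high_m_genes, collapse = ", "), "\n")
  }
  if (!is.null(x$v_series)) {
    cat("  V series:", paste(sprintf("%s = %.4f", names(x$v_series), x$v_series),
                             collapse = ", "), "\n")
    cat("  optimal number of reference genes:", x$optimal_n, "\n")
  }
  invisible(x)
}
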