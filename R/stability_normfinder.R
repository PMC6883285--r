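# NormFinder model-based stability: decompose each gene's log-scale variation
# into intra-group variance and inter-group expression shifts, shrink the
# group differences toward zero, and combine both into the stability value
# rho (lower = more stable). Cq values are already on a log2 quantity scale
# (sign-flipped); the decomposition is sign-invariant, so they are used
# directly.

normfinder_decompose <- function(cq, groups) {
  genes <- colnames(cq)
  G <- length(genes)
  grp <- factor(groups, levels = unique(groups))
  k <- nlevels(grp)
  n_a <- as.integer(table(grp))
  # remove per-sample effects (loading); rows then average to zero over genes
  xc <- cq - rowMeans(cq)
  # per-group gene averages and double-centered residuals
  gga <- matrix(0, k, G, dimnames = list(levels(grp), genes))
  u <- gga  # residual variance of the double-centered values, per (group, gene)
  for (a in seq_len(k)) {
    rows <- which(as.integer(grp) == a)
    gga[a, ] <- colMeans(xc[rows, , drop = FALSE])
    z <- sweep(xc[rows, , drop = FALSE], 2L, gga[a, ])
    u[a, ] <- colSums(z^2) / (n_a[a] - 1L)
  }
  # bias-corrected per-gene intra-group variances: removing sample effects
  # leaks a share of every gene's noise into every residual, and the G/(G-2)
  # correction undoes it
  sigma2 <- u
  for (a in seq_len(k)) {
    S <- sum(u[a, ])
    sigma2[a, ] <- pmax(0, G / (G - 2) * (u[a, ] - S / (G * (G - 1))))
  }
  # inter-group deviations; rows of xc are gene-centered so d rows sum to 0
  # and group-size-weighted column sums vanish
  d <- sweep(gga, 2L, colMeans(xc))
  vard <- sweep(sigma2, 1L, n_a, `/`)
  list(grp = grp, n_a = n_a, G = G, k = k, d = d, vard = vard, sigma2 = sigma2)
}

#' NormFinder stability evaluation
#'
#' Fits the two-way decomposition value = gene effect + sample effect +
#' (group x gene) effect + noise on the log scale, per group: per-gene
#' intra-group variances are estimated from double-centered residuals with a
#' small-sample bias correction (floored at zero), and the per-group
#' inter-group deviations d are shrunken toward zero by an empirical-Bayes
#' factor `gamma^2 / (gamma^2 + var(d_hat))`, where `gamma^2` is the
#' dispersion of the observed deviations in excess of their sampling
#' variance. The stability value of a gene is
#' `rho = mean over groups of ( |d_shrunk| + sqrt(var(d_shrunk)) )`,
#' combining systematic group shifts with intra-group uncertainty; lower rho
#' means more stable. Ranks are ascending in rho.
#'
#' With a single group (or `grouped = FALSE`), the inter-group term does not
#' exist and the analysis falls back to `rho = sqrt(intra-group variance)`,
#' flagged accordingly. If the observed inter-group dispersion does not
#' exceed its sampling variance (`gamma^2 <= 0`), shrinkage would null every
#' deviation; rho then falls back to the sampling SD of d alone and the
#' result is flagged.
#'
#' @param ds A [cq_dataset()] with aggregated Cq values (no missing cells).
#'   Grouped mode needs at least 2 groups with at least 2 samples each.
#' @param grouped Use the group labels? Default `TRUE` when 2+ groups exist.
#' @return Object of class `normfinder_result`: `table` (data frame `gene`,
#'   `rho`, `rank`), `intra_var` (groups x genes matrix of intra-group
#'   variance estimates), `inter_var` (groups x genes matrix of raw
#'   deviations d), `d_shrunk`, `var_d`, `var_d_shrunk`, `gamma2`, `mode`
#'   (`"grouped"`, `"single_group"`, or `"grouped_no_intergroup_dispersion"`).
#' @export
normfinder <- function(ds, grouped = TRUE) {
  stopifnot(inherits(ds, "cq_dataset"))
  cq <- ds$cq
  if (anyNA(cq)) stop("missing Cq values; handle upstream", call. = FALSE)
  if (ncol(cq) < 3L) stop("NormFinder needs at least 3 genes", call. = FALSE)
  groups <- ds$groups
  k <- length(unique(groups))
  if (grouped && k >= 2L) {
    if (any(table(groups) < 2L)) {
      stop("every group needs at least 2 samples in grouped mode", call. = FALSE)
    }
    dec <- normfinder_decompose(cq, groups)
    gamma2 <- sum(dec$d^2) / ((dec$k - 1L) * (dec$G - 1L)) - mean(dec$vard)
    if (gamma2 > 0) {
      shrink <- gamma2 / (gamma2 + dec$vard)
      d_shrunk <- dec$d * shrink
      var_shrunk <- dec$vard * shrink
      rho <- colMeans(abs(d_shrunk) + sqrt(var_shrunk))
      mode <- "grouped"
    } else {
      d_shrunk <- dec$d * 0
      var_shrunk <- dec$vard
      rho <- colMeans(sqrt(dec$vard))
      mode <- "grouped_no_intergroup_dispersion"
      gamma2 <- 0
    }
    res <- list(
      table = data.frame(gene = colnames(cq), rho = unname(rho),
                         rank = rank(rho, ties.method = "average")),
      intra_var = dec$sigma2, inter_var = dec$d, d_shrunk = d_shrunk,
      var_d = dec$vard, var_d_shrunk = var_shrunk, gamma2 = gamma2,
      groups = stats::setNames(dec$n_a, levels(dec$grp)), mode = mode
    )
  } else {
    # single-group fallback: stability = bias-corrected residual SD after
    # removing per-sample effects
    dec <- normfinder_decompose(cq, rep("all", nrow(cq)))
    rho <- sqrt(dec$sigma2[1L, ])
    res <- list(
      table = data.frame(gene = colnames(cq), rho = unname(rho),
                         rank = rank(rho, ties.method = "average")),
      intra_var = dec$sigma2, inter_var = NULL, d_shrunk = NULL,
      var_d = NULL, var_d_shrunk = NULL, gamma2 = NA_real_,
      groups = stats::setNames(nrow(cq), "all"), mode = "single_group"
    )
  }
  structure(res, class = "normfinder_result")
}

#' Best two-gene combination under the NormFinder model
#'
#' Averaging two genes averages their shrunken group deviations and
#' propagates a quarter of the sum of their deviation variances, so genes
#' with opposite group shifts cancel. The combined stability of a pair is
#' `mean over groups of ( |(d_g + d_h)/2| + sqrt((var_g + var_h)/4) )`; all
#' unordered pairs are enumerated and the minimizer returned.
#'
#' @param result A grouped-mode `normfinder_result`.
#' @return List with `pair` (the two gene names) and `value` (the pair
#'   stability).
#' @export
normfinder_best_pair <- function(result) {
  stopifnot(inherits(result, "normfinder_result"))
  if (result$mode == "single_group") {
    stop("best-pair search requires grouped mode", call. = FALSE)
  }
  genes <- result$table$gene
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  pairs <- utils::combn(genes, 2L)
  vals <- apply(pairs, 2L, function(p) {
    d <- (result$d_shrunk[, p[1L]] + result$d_shrunk[, p[2L]]) / 2
    v <- (result$var_d_shrunk[, p[1L]] + result$var_d_shrunk[, p[2L]]) / 4
    mean(abs(d) + sqrt(v))
  })
  best <- which.min(vals)
  list(pair = pairs[, best], value = vals[best])
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability (mode:", x$mode, ")\n")
  print(x$table[order(x$table$rank), ], row.names = FALSE, digits = 4)
  if (x$mode != "single_group") {
    bp <- normfinder_best_pair(x)
    cat(sprintf("  best pair: %s / %s (stability %.4f)\n",
                bp$pair[1L], bp$pair[2L], bp$value))
  }
  invisible(x)
}
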