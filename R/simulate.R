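# Synthetic Cq datasets and amplification curves with known ground truth:
# a per-gene noise ladder, a shared per-sample loading shift, planted group
# (injury) effects, technical-replicate noise, and exponential amplification
# curves with known per-amplicon efficiency. Every downstream stage of the
# pipeline is testable against the planted truth without any download.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default candidate reference-gene panel for simulation
#'
#' Eleven small nucleolar/nuclear RNA candidates emulating a neural-tissue
#' nerve-injury reference-gene study: baseline Cq means spanning roughly
#' 18--32 cycles (sno202 most abundant, sno412 least), a biological noise
#' ladder from 0.10 to 0.60 cycles in 0.05 steps, technical-replicate SD
#' 0.08 cycles except sno55 (0.35 cycles, placing its mean duplicate SD
#' clearly above the 0.167 admissibility rule, as for a candidate excluded
#' on technical grounds), and per-assay amplification efficiencies inside the range
#' typically estimated by regression analysis of hydrolysis-probe assays.
#'
#' @return Data frame with columns `gene`, `baseline_cq`, `noise_sd`,
#'   `replicate_sd`, `efficiency`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("sno202", "sno420", "sno429", "sno142", "U6", "sno234",
             "sno251", "sno412", "sno135", "sno292", "sno55"),
    baseline_cq = c(18.5, 22.0, 22.5, 23.5, 20.0, 24.5, 25.5, 31.5, 27.5,
                    26.5, 29.0),
    noise_sd = seq(0.10, 0.60, by = 0.05),
    replicate_sd = c(rep(0.08, 10L), 0.35),
    efficiency = c(1.82, 1.84, 1.86, 1.80, 1.88, 1.78, 1.83, 1.77, 1.85,
                   1.79, 1.81)
  )
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic Cq generator. The defaults
#' emulate a three-group nerve-injury design: non-treated (n = 5), sham
#' (n = 6) and SNI (n = 5) animals, eleven candidate genes measured in
#' technical duplicates, a shared per-sample loading shift with SD 0.3
#' cycles, and a planted +0.8-cycle SNI group effect on sno292 (a candidate
#' whose regulation by the injury makes it an unsuitable normalizer). All
#' noise terms are Gaussian on the Cq scale, i.e. multiplicative on the
#' quantity scale -- the units every stability method consumes.
#'
#' @param n_per_group Named integer vector of samples per group.
#' @param genes Gene panel as in [default_gene_panel()].
#' @param group_effects Named list: gene -> named numeric vector of per-group
#'   Cq shifts (cycles).
#' @param loading_sd SD of the shared per-sample loading shift (cycles).
#' @param n_replicates Technical replicates per (sample, gene).
#' @param seed Integer seed; a fixed seed reproduces the dataset bit for bit.
#' @param cycles Amplification-curve length (cycles).
#' @param baseline_fluor Constant fluorescence baseline of simulated curves.
#' @param plateau Fluorescence ceiling of simulated curves (`Inf` for a pure
#'   exponential).
#' @param fluor_noise_sd Additive Gaussian fluorescence noise SD.
#' @param threshold Fluorescence threshold used to anchor the curves so each
#'   gene's noiseless crossing sits at its baseline Cq.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c("non-treated" = 5L, "sham" = 6L, "SNI" = 5L),
                       genes = default_gene_panel(),
                       group_effects = list(sno292 = c(SNI = 0.8)),
                       loading_sd = 0.3, n_replicates = 2L, seed = 1L,
                       cycles = 40L, baseline_fluor = 0.05, plateau = 3,
                       fluor_noise_sd = 0.002, threshold = 0.1) {
  stopifnot(length(n_per_group) >= 1L, !is.null(names(n_per_group)),
            all(n_per_group >= 1L), loading_sd >= 0, n_replicates >= 1L,
            all(genes$noise_sd >= 0), all(genes$replicate_sd >= 0),
            all(genes$efficiency > 1 & genes$efficiency <= 2))
  bad <- setdiff(names(group_effects), genes$gene)
  if (length(bad)) stop("group_effects for unknown gene(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (g in names(group_effects)) {
    bad_grp <- setdiff(names(group_effects[[g]]), names(n_per_group))
    if (length(bad_grp)) stop("group_effects for unknown group(s): ",
                              paste(bad_grp, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, genes = genes,
         group_effects = group_effects, loading_sd = loading_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         cycles = as.integer(cycles), baseline_fluor = baseline_fluor,
         plateau = plateau, fluor_noise_sd = fluor_noise_sd,
         threshold = threshold),
    class = "sim_config"
  )
}

# genes x groups matrix of planted Cq shifts
effect_matrix <- function(config) {
  eff <- matrix(0, nrow(config$genes), length(config$n_per_group),
                dimnames = list(config$genes$gene, names(config$n_per_group)))
  for (g in names(config$group_effects)) {
    eff[g, names(config$group_effects[[g]])] <- config$group_effects[[g]]
  }
  eff
}

#' Simulate a Cq dataset with known ground truth
#'
#' Draws `Cq[s, g, rep] = baseline_cq_g + group_effect(g, group(s)) +
#' loading_s + gene_noise(s, g) + replicate_noise(s, g, rep)` with all terms
#' Gaussian at the configured SDs. The loading term is a shared per-sample
#' shift across all genes -- exactly the perturbation the delta-Cq, geNorm
#' and NormFinder statistics are invariant to.
#'
#' The ground truth records, per gene, the expected total perturbation
#' relevant to stability ranking: `sqrt(noise_sd^2 + between-group variance
#' of the planted shifts + replicate_sd^2 / n_replicates)`, and the implied
#' stability ordering (ascending).
#'
#' @param config A [sim_config()].
#' @param tissue,setting Labels stored on the returned dataset.
#' @return List with `dataset` (a [cq_dataset()] whose `cq` holds the
#'   replicate means) and `truth` (list: `loading`, `group_shift` per-sample
#'   matrix contribution, `expected_sd` per gene, `stability_order` genes
#'   ascending by expected perturbation).
#' @export
simulate_cq_dataset <- function(config, tissue = "DRG",
                                setting = "common_threshold") {
  stopifnot(inherits(config, "sim_config"))
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  samples <- sprintf("S%02d", seq_len(n))
  names(groups) <- samples
  genes <- config$genes$gene
  G <- length(genes)
  eff <- effect_matrix(config)
  with_seed(config$seed, {
    loading <- stats::rnorm(n, 0, config$loading_sd)
    gene_noise <- matrix(stats::rnorm(n * G, 0,
                                      rep(config$genes$noise_sd, each = n)),
                         n, G, dimnames = list(samples, genes))
    base <- matrix(config$genes$baseline_cq, n, G, byrow = TRUE) +
      t(eff[, groups, drop = FALSE]) + loading + gene_noise
    rep_cq <- array(NA_real_, c(n, G, config$n_replicates),
                    dimnames = list(samples, genes, NULL))
    for (r in seq_len(config$n_replicates)) {
      rep_cq[, , r] <- base +
        matrix(stats::rnorm(n * G, 0, rep(config$genes$replicate_sd, each = n)),
               n, G)
    }
  })
  cq <- apply(rep_cq, c(1, 2), mean)
  ds <- cq_dataset(cq, groups, tissue, setting, rep_cq)
  # expected per-gene perturbation: biological noise + planted between-group
  # variance (sample-weighted, n-1 denominator) + averaged technical noise
  shift_by_sample <- t(eff[, groups, drop = FALSE])
  group_var <- apply(shift_by_sample, 2L, stats::var)
  expected_sd <- sqrt(config$genes$noise_sd^2 + group_var +
                        config$genes$replicate_sd^2 / config$n_replicates)
  names(expected_sd) <- genes
  list(dataset = ds,
       truth = list(loading = stats::setNames(loading, samples),
                    group_shift = shift_by_sample,
                    expected_sd = expected_sd,
                    stability_order = genes[order(expected_sd)]))
}

#' Simulate amplification curves with known efficiency and Cq
#'
#' Builds per-well fluorescence series `F_c = baseline + sat(F0 * E^c) +
#' noise`, where `sat` saturates the exponential at the plateau ceiling
#' through a smooth hyperbolic knee (`sat(u) = plateau * u / (plateau + u)`),
#' enough to exercise plateau handling without kinetic realism. `F0` is
#' anchored so that the noiseless unsaturated curve crosses the configured
#' threshold exactly at the gene's baseline Cq, giving a closed-form true
#' fractional Cq `log(threshold / F0) / log(E)` per well.
#'
#' @param config A [sim_config()].
#' @param wells_per_gene Number of replicate wells per gene.
#' @param genes Optional subset of panel genes.
#' @return List with `curves` (list of [amplification_curve()]) and `truth`
#'   (data frame `well`, `target`, `efficiency`, `true_cq`).
#' @export
simulate_amplification_curves <- function(config, wells_per_gene = 2L,
                                          genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$genes
  if (!is.null(genes)) panel <- panel[panel$gene %in% genes, , drop = FALSE]
  sat <- function(u) {
    if (is.finite(config$plateau)) config$plateau * u / (config$plateau + u) else u
  }
  cyc <- seq_len(config$cycles)
  out <- list(); truth <- list()
  with_seed(config$seed + 1L, {
    for (i in seq_len(nrow(panel))) {
      E <- panel$efficiency[i]
      f0 <- config$threshold * E^(-panel$baseline_cq[i])
      for (w in seq_len(wells_per_gene)) {
        well <- sprintf("%s_w%d", panel$gene[i], w)
        f <- config$baseline_fluor + sat(f0 * E^cyc) +
          stats::rnorm(config$cycles, 0, config$fluor_noise_sd)
        out[[well]] <- amplification_curve(well, panel$gene[i],
                                           sprintf("sim%02d", w), f)
        truth[[well]] <- data.frame(well = well, target = panel$gene[i],
                                    efficiency = E,
                                    true_cq = log(config$threshold / f0) / log(E))
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(curves = out, truth = truth)
}
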