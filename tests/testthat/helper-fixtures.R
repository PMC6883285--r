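# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# wrap a bare matrix into a cq_dataset, inventing names/groups as needed
make_ds <- function(cq, groups = NULL, ...) {
  if (is.null(rownames(cq))) rownames(cq) <- sprintf("S%02d", seq_len(nrow(cq)))
  if (is.null(colnames(cq))) colnames(cq) <- sprintf("g%d", seq_len(ncol(cq)))
  if (is.null(groups)) {
    half <- ceiling(nrow(cq) / 2)
    groups <- rep(c("A", "B"), c(half, nrow(cq) - half))
  }
  cq_dataset(cq, groups, ...)
}

# random Cq matrix in a realistic range
random_cq <- function(n, G, lo = 20, hi = 30) {
  matrix(stats::runif(n * G, lo, hi), n, G,
         dimnames = list(sprintf("S%02d", seq_len(n)), sprintf("g%d", seq_len(G))))
}

# small hand matrix used by several oracle tests: 4 samples x 3 genes
hand_matrix_4x3 <- function() {
  matrix(c(20.0, 20.5, 21.0, 20.2,
           24.1, 24.9, 25.3, 24.0,
           28.3, 28.1, 29.0, 28.6),
         nrow = 4, dimnames = list(paste0("S", 1:4), c("gA", "gB", "gC")))
}

# noiseless exponential amplification curve
exp_curve <- function(E, f0, cycles = 40, well = "w1", target = "t",
                      sample = "s") {
  amplification_curve(well, target, sample, f0 * E^seq_len(cycles))
}
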