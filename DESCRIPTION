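Package: refstab
Title: Reference-Gene Stability Evaluation for RT-qPCR miRNA Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates candidate reference genes (small nucleolar and small
    nuclear RNAs) for normalizing miRNA RT-qPCR experiments. Implements
    per-reaction amplification efficiency and Cq estimation from raw
    fluorescence curves via window-of-linearity log-linear regression,
    technical-replicate quality control with the duplicate-SD admissibility
    rule, four reference-gene stability statistics (BestKeeper, the
    comparative delta-Cq method, geNorm M and pairwise variation V, and
    NormFinder's model-based variance decomposition), a consensus
    mean-of-ranks stability ranking, and multi-reference 2^-ddCq relative
    quantification with one-way ANOVA and Tukey post-hoc tests. A synthetic
    Cq-dataset and amplification-curve generator with known ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
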