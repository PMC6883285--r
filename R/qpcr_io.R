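# Shared data model and delimited-text IO for Cq tables and raw
# amplification-curve tables.

#' Construct a Cq dataset
#'
#' A `cq_dataset` holds the quantitation cycles of a single tissue under one
#' Cq-extraction setting: a samples x genes matrix of (replicate-averaged) Cq
#' values, per-sample experimental group labels, and optionally the raw
#' technical replicates before aggregation.
#'
#' @param cq Numeric matrix of Cq values, samples in rows, candidate genes in
#'   columns. Row and column names are required and serve as sample and gene
#'   identifiers.
#' @param groups Character vector of group labels, either named by sample or
#'   in row order of `cq`. Every sample must carry exactly one label.
#' @param tissue Tissue label (e.g. `"DRG"`, `"dhSC"`, `"mPFC"`).
#' @param setting Provenance of the Cq values: `"common_threshold"` for a
#'   fixed fluorescence threshold, `"regression_corrected"` for Cq values from
#'   per-reaction log-linear regression.
#' @param replicate_cq Optional 3-d array (samples x genes x replicates) of
#'   the raw technical-replicate Cq values. `NA` marks a missing replicate.
#'
#' @return An object of class `cq_dataset` with elements `cq`, `groups`,
#'   `tissue`, `setting`, `replicate_cq`.
#'
#' @details The constructor enforces structural validity only (shapes, names,
#'   one group per sample). Semantic invariants -- Cq within (0, 45), unique
#'   sample/gene identifiers, replicate means matching `cq` -- are checked by
#'   [validate_cq_dataset()], which reports violations instead of erroring so
#'   that defective instrument exports can be inspected.
#'
#' @seealso [read_cq_table()], [validate_cq_dataset()]
#' @export
cq_dataset <- function(cq, groups, tissue = "unspecified",
                       setting = c("common_threshold", "regression_corrected"),
                       replicate_cq = NULL) {
  setting <- match.arg(setting)
  if (!is.matrix(cq) || !is.numeric(cq)) {
    stop("`cq` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (is.null(rownames(cq)) || is.null(colnames(cq))) {
    stop("`cq` must carry sample row names and gene column names", call. = FALSE)
  }
  grp_names <- names(groups)
  groups <- as.character(groups)
  names(groups) <- grp_names
  if (is.null(names(groups))) {
    if (length(groups) != nrow(cq)) {
      stop("`groups` must be named by sample or have one label per row of `cq`",
           call. = FALSE)
    }
    names(groups) <- rownames(cq)
  }
  groups <- groups[rownames(cq)]
  if (anyNA(names(groups)) || anyNA(groups)) {
    stop("every sample must have exactly one group label", call. = FALSE)
  }
  if (!is.null(replicate_cq)) {
    d <- dim(replicate_cq)
    if (length(d) != 3L || d[1L] != nrow(cq) || d[2L] != ncol(cq)) {
      stop("`replicate_cq` must be a samples x genes x replicates array ",
           "conformable with `cq`", call. = FALSE)
    }
    dimnames(replicate_cq)[1:2] <- dimnames(cq)
  }
  structure(
    list(cq = cq, groups = groups, tissue = as.character(tissue)[1L],
         setting = setting, replicate_cq = replicate_cq),
    class = "cq_dataset"
  )
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf("<cq_dataset> %d samples x %d genes, tissue = %s, setting = %s\n",
              nrow(x$cq), ncol(x$cq), x$tissue, x$setting))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                 as.integer(table(x$groups))), collapse = ", "), "\n")
  if (!is.null(x$replicate_cq)) {
    cat(sprintf("  technical replicates: up to %d per (sample, gene)\n",
                dim(x$replicate_cq)[3L]))
  }
  invisible(x)
}

#' Restrict a Cq dataset to a subset of genes
#'
#' @param ds A [cq_dataset()].
#' @param genes Character vector of gene identifiers to retain (order kept).
#' @return A `cq_dataset` with only the requested genes.
#' @export
subset_genes <- function(ds, genes) {
  stopifnot(inherits(ds, "cq_dataset"))
  missing <- setdiff(genes, colnames(ds$cq))
  if (length(missing)) {
    stop("genes not present in dataset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rep_cq <- if (!is.null(ds$replicate_cq)) ds$replicate_cq[, genes, , drop = FALSE]
  cq_dataset(ds$cq[, genes, drop = FALSE], ds$groups, ds$tissue, ds$setting, rep_cq)
}

#' Report invariant violations of a Cq dataset
#'
#' Checks the semantic invariants of a [cq_dataset()] and reports each
#' violation with its location; an empty report means the dataset is valid.
#' Checked: every non-missing Cq lies in (0, 45); sample and gene identifiers
#' are unique; a non-empty group set; and, when replicates are present, `cq`
#' equals the arithmetic replicate mean.
#'
#' @param ds A [cq_dataset()].
#' @param tol Numeric tolerance for the replicate-mean identity.
#' @return A data frame with columns `check`, `location`, `message`; zero rows
#'   when all invariants hold.
#' @export
validate_cq_dataset <- function(ds, tol = 1e-8) {
  stopifnot(inherits(ds, "cq_dataset"))
  bad <- list()
  note <- function(check, location, message) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, location = location,
                                           message = message)
  }
  dup_s <- unique(rownames(ds$cq)[duplicated(rownames(ds$cq))])
  for (s in dup_s) note("unique_samples", s, "duplicated sample identifier")
  dup_g <- unique(colnames(ds$cq)[duplicated(colnames(ds$cq))])
  for (g in dup_g) note("unique_genes", g, "duplicated gene identifier")
  if (length(unique(ds$groups)) == 0L) {
    note("groups", "<dataset>", "group set is empty")
  }
  out <- which(!is.na(ds$cq) & (ds$cq <= 0 | ds$cq >= 45), arr.ind = TRUE)
  if (nrow(out)) {
    for (i in seq_len(nrow(out))) {
      note("cq_range",
           sprintf("(%s, %s)", rownames(ds$cq)[out[i, 1L]], colnames(ds$cq)[out[i, 2L]]),
           sprintf("Cq = %g outside (0, 45)", ds$cq[out[i, 1L], out[i, 2L]]))
    }
  }
  if (!is.null(ds$replicate_cq)) {
    means <- apply(ds$replicate_cq, c(1, 2), mean, na.rm = TRUE)
    means[is.nan(means)] <- NA_real_
    diff <- abs(means - ds$cq)
    off <- which(!is.na(diff) & diff > tol, arr.ind = TRUE)
    if (nrow(off)) {
      for (i in seq_len(nrow(off))) {
        note("replicate_mean",
             sprintf("(%s, %s)", rownames(ds$cq)[off[i, 1L]], colnames(ds$cq)[off[i, 2L]]),
             "cq does not equal the replicate arithmetic mean")
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(), location = character(), message = character())
}

# Delimiter auto-detection among comma / tab / semicolon, based on the header
# line. Vendor exports differ; decimal separator is fixed to ".".
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1L))
  if (all(counts == 0L)) stop("cannot detect delimiter in ", path, call. = FALSE)
  names(counts)[which.max(counts)]
}

.default_na <- c("", "NA", "Undetermined", "undetermined", "No Cq", "NoCq", "N/A")

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_delimiter(path)
  utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE, na.strings = .default_na,
                    check.names = FALSE, comment.char = "")
}

parse_cq_column <- function(raw, what = "cq") {
  if (is.numeric(raw)) return(as.numeric(raw))
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & !(raw %in% .default_na) & is.na(val))
  if (length(bad)) {
    stop(sprintf("non-numeric %s value '%s' at data row %d", what, raw[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  val
}

#' Read a Cq table from delimited text
#'
#' Reads a long (tidy) or wide Cq export, validates it, and returns a
#' [cq_dataset()]. In long format, one row per (sample, gene\[, replicate\])
#' observation; rows sharing a (sample, gene) key -- via an explicit replicate
#' column or simple repetition -- are collapsed into technical replicates and
#' `cq` becomes their arithmetic mean. In wide format, samples are rows and
#' genes are columns. The delimiter is auto-detected among comma, tab and
#' semicolon; the decimal separator is ".". `Undetermined`/no-Cq wells are
#' read as missing, never as the cycle count.
#'
#' @param path Path to the delimited file.
#' @param schema Named character vector mapping the roles
#'   `sample`, `group`, `gene`, `cq`, `replicate`, `tissue`, `setting` to the
#'   file's column names. Defaults to identically-named columns. For wide
#'   format only `sample` and `group` are used; every remaining column is a
#'   gene.
#' @param format `"long"` (default) or `"wide"`.
#' @param tissue,setting Optional overrides; otherwise taken from the file's
#'   columns when present.
#' @param sep Field delimiter; `NULL` (default) auto-detects.
#' @return A validated [cq_dataset()]; replicate rows are collapsed into the
#'   `replicate_cq` array. Row order of the input does not affect the result.
#' @export
read_cq_table <- function(path, schema = NULL, format = c("long", "wide"),
                          tissue = NULL, setting = NULL, sep = NULL) {
  format <- match.arg(format)
  sch <- c(sample = "sample", group = "group", gene = "gene", cq = "cq",
           replicate = "replicate", tissue = "tissue", setting = "setting")
  if (!is.null(schema)) sch[names(schema)] <- schema
  df <- read_delim_auto(path, sep)

  required <- if (format == "long") c("sample", "group", "gene", "cq") else c("sample", "group")
  for (role in required) {
    if (!sch[[role]] %in% names(df)) {
      stop(sprintf("schema error: required column '%s' (role '%s') not found",
                   sch[[role]], role), call. = FALSE)
    }
  }
  samp <- as.character(df[[sch[["sample"]]]])
  grp <- as.character(df[[sch[["group"]]]])
  # one group label per sample
  gmap <- tapply(grp, samp, function(x) unique(x))
  multi <- names(gmap)[lengths(gmap) > 1L]
  if (length(multi)) {
    stop("consistency error: sample(s) with conflicting group labels: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  groups <- vapply(gmap, `[[`, character(1L), 1L)

  meta <- function(role, override) {
    if (!is.null(override)) return(override)
    col <- sch[[role]]
    if (col %in% names(df)) {
      u <- unique(as.character(df[[col]]))
      if (length(u) > 1L) stop("multiple ", role, " labels in one file: ",
                               paste(u, collapse = ", "), call. = FALSE)
      return(u)
    }
    NULL
  }
  tissue <- meta("tissue", tissue) %||% "unspecified"
  setting <- meta("setting", setting) %||% "common_threshold"

  if (format == "long") {
    gene <- as.character(df[[sch[["gene"]]]])
    cqv <- parse_cq_column(df[[sch[["cq"]]]])
    oob <- which(!is.na(cqv) & (cqv <= 0 | cqv >= 45))
    if (length(oob)) {
      stop(sprintf("validation error: Cq = %g out of range (0, 45) at data row %d",
                   cqv[oob[1L]], oob[1L]), call. = FALSE)
    }
    samples <- unique(samp)
    genes <- unique(gene)
    if (sch[["replicate"]] %in% names(df)) {
      repid <- as.character(df[[sch[["replicate"]]]])
      key <- paste(samp, gene, repid, sep = "\r")
      if (anyDuplicated(key)) {
        d <- which(duplicated(key))[1L]
        stop(sprintf("duplicated (sample, gene, replicate) row: (%s, %s, %s)",
                     samp[d], gene[d], repid[d]), call. = FALSE)
      }
    } else {
      # rows repeating a (sample, gene) key are technical replicates in file order
      repid <- stats::ave(seq_along(samp), samp, gene, FUN = seq_along)
    }
    # deterministic replicate slots independent of row order
    ord <- order(match(samp, samples), match(gene, genes), repid)
    samp <- samp[ord]; gene <- gene[ord]; cqv <- cqv[ord]
    slot <- stats::ave(seq_along(samp), samp, gene, FUN = seq_along)
    n_rep <- max(slot)
    rep_cq <- array(NA_real_, dim = c(length(samples), length(genes), n_rep),
                    dimnames = list(samples, genes, NULL))
    rep_cq[cbind(match(samp, samples), match(gene, genes), slot)] <- cqv
    cq <- apply(rep_cq, c(1, 2), mean, na.rm = TRUE)
    cq[is.nan(cq)] <- NA_real_
    if (n_rep == 1L) rep_cq <- NULL
    cq_dataset(cq, groups[samples], tissue, setting, rep_cq)
  } else {
    keep <- setdiff(names(df), unname(sch[c("sample", "group", "tissue", "setting")]))
    if (!length(keep)) stop("wide format: no gene columns found", call. = FALSE)
    if (anyDuplicated(samp)) {
      stop("wide format: duplicated sample row: ",
           samp[duplicated(samp)][1L], call. = FALSE)
    }
    cq <- sapply(keep, function(g) parse_cq_column(df[[g]], what = g))
    cq <- matrix(as.numeric(cq), nrow = length(samp),
                 dimnames = list(samp, keep))
    oob <- which(!is.na(cq) & (cq <= 0 | cq >= 45), arr.ind = TRUE)
    if (nrow(oob)) {
      stop(sprintf("validation error: Cq out of range (0, 45) for sample %s, gene %s",
                   samp[oob[1L, 1L]], keep[oob[1L, 2L]]), call. = FALSE)
    }
    cq_dataset(cq, groups[samp], tissue, setting, NULL)
  }
}

#' Write a Cq dataset as a long delimited table
#'
#' Inverse of [read_cq_table()]: writes one row per (sample, gene, replicate)
#' when replicates are present, otherwise one row per (sample, gene), with
#' `tissue` and `setting` columns so the round trip is lossless.
#'
#' @param ds A [cq_dataset()].
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @export
write_cq_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "cq_dataset"))
  samples <- rownames(ds$cq); genes <- colnames(ds$cq)
  if (!is.null(ds$replicate_cq)) {
    n_rep <- dim(ds$replicate_cq)[3L]
    df <- expand.grid(replicate = seq_len(n_rep), gene = genes, sample = samples,
                      stringsAsFactors = FALSE)[, c("sample", "gene", "replicate")]
    df$cq <- ds$replicate_cq[cbind(match(df$sample, samples),
                                   match(df$gene, genes), df$replicate)]
    df <- df[!is.na(df$cq), , drop = FALSE]
  } else {
    df <- expand.grid(gene = genes, sample = samples,
                      stringsAsFactors = FALSE)[, c("sample", "gene")]
    df$cq <- ds$cq[cbind(match(df$sample, samples), match(df$gene, genes))]
  }
  df$group <- ds$groups[df$sample]
  df$tissue <- ds$tissue
  df$setting <- ds$setting
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an amplification curve
#'
#' One raw fluorescence reading per PCR cycle for a single well, with target
#' and sample annotation. Cycles are implicitly 1..C.
#'
#' @param well_id Well identifier.
#' @param target Gene (assay) identifier.
#' @param sample Sample identifier.
#' @param fluorescence Numeric vector of fluorescence readings for cycles
#'   `1..length(fluorescence)`; all values must be finite and at least 10
#'   cycles are required.
#' @return An object of class `amplification_curve`.
#' @export
amplification_curve <- function(well_id, target, sample, fluorescence) {
  fluorescence <- as.numeric(fluorescence)
  if (length(fluorescence) < 10L) {
    stop("an amplification curve needs at least 10 cycles", call. = FALSE)
  }
  if (!all(is.finite(fluorescence))) {
    stop("fluorescence values must all be finite", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), target = as.character(target),
         sample = as.character(sample), fluorescence = fluorescence,
         cycles = length(fluorescence)),
    class = "amplification_curve"
  )
}

#' @export
print.amplification_curve <- function(x, ...) {
  cat(sprintf("<amplification_curve> well %s (%s / %s), %d cycles, F in [%.4g, %.4g]\n",
              x$well_id, x$target, x$sample, x$cycles,
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' Read raw amplification curves from delimited text
#'
#' Expects columns `well`, `target`, `sample`, `cycle`, `fluorescence`; one
#' reading per (well, cycle). Returns one [amplification_curve()] per well
#' with cycles sorted ascending. Duplicated (well, cycle) readings and gaps in
#' the cycle index are rejected, so any row permutation of the input yields
#' identical curves.
#'
#' @param path Path to the delimited file.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return Named list of `amplification_curve` objects (by well).
#' @export
read_amplification_table <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  needed <- c("well", "target", "sample", "cycle", "fluorescence")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("schema error: required column(s) not found: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$well <- as.character(df$well)
  df$cycle <- parse_cq_column(df$cycle, "cycle")
  df$fluorescence <- parse_cq_column(df$fluorescence, "fluorescence")
  wells <- unique(df$well)
  curves <- lapply(wells, function(w) {
    sub <- df[df$well == w, , drop = FALSE]
    if (anyDuplicated(sub$cycle)) {
      stop(sprintf("duplicated (well, cycle) reading: well %s, cycle %g",
                   w, sub$cycle[duplicated(sub$cycle)][1L]), call. = FALSE)
    }
    sub <- sub[order(sub$cycle), , drop = FALSE]
    if (!identical(as.integer(sub$cycle), seq_len(nrow(sub)))) {
      stop(sprintf("non-contiguous cycle index for well %s: cycles must be 1..C", w),
           call. = FALSE)
    }
    amplification_curve(w, sub$target[1L], sub$sample[1L], sub$fluorescence)
  })
  names(curves) <- wells
  curves
}

#' Write amplification curves as a long delimited table
#'
#' @param curves List of [amplification_curve()] objects.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @export
write_amplification_table <- function(curves, path, sep = ",") {
  rows <- lapply(curves, function(cu) {
    data.frame(well = cu$well_id, target = cu$target, sample = cu$sample,
               cycle = seq_len(cu$cycles), fluorescence = cu$fluorescence)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
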