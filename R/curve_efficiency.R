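# Per-reaction amplification efficiency and Cq from raw fluorescence curves:
# constant-baseline correction, window-of-linearity search, log-linear
# regression (regression Cq) and the fixed-threshold Cq alternative.

#' Baseline-correct an amplification curve
#'
#' Subtracts a constant baseline estimated as the mean fluorescence over a
#' configurable early-cycle window (default cycles 3--15, the conventional
#' automatic-baseline window of plate instruments). A curve whose corrected
#' amplitude never rises above the baseline noise band is flagged
#' non-amplifying and should be excluded downstream.
#'
#' @param curve An [amplification_curve()].
#' @param baseline_cycles Integer cycles used for the baseline estimate;
#'   cycles beyond the curve length are ignored.
#' @param noise_mult A curve is non-amplifying when its maximal corrected
#'   fluorescence does not exceed `noise_mult` times the baseline-window SD.
#' @return The curve with corrected `fluorescence`, plus elements `baseline`
#'   (the subtracted constant), `non_amplifying` (logical) and
#'   `baseline_corrected = TRUE`.
#' @export
correct_baseline <- function(curve, baseline_cycles = 3:15, noise_mult = 10) {
  stopifnot(inherits(curve, "amplification_curve"))
  idx <- intersect(baseline_cycles, seq_len(curve$cycles))
  if (length(idx) < 2L) {
    stop("curve shorter than the baseline window", call. = FALSE)
  }
  base <- mean(curve$fluorescence[idx])
  noise <- stats::sd(curve$fluorescence[idx])
  corrected <- curve$fluorescence - base
  curve$fluorescence <- corrected
  curve$baseline <- base
  curve$non_amplifying <- max(corrected) <= max(noise_mult * noise, 1e-12)
  curve$baseline_corrected <- TRUE
  curve
}

# R^2 of log10(F) on cycle over an index window; NA when degenerate.
window_r2 <- function(logf, cycles) {
  r <- suppressWarnings(stats::cor(cycles, logf))
  if (is.na(r)) NA_real_ else r * r
}

#' Find the window of linearity
#'
#' Scans all contiguous `points`-cycle windows of a baseline-corrected curve
#' and returns the one maximizing the R-squared of log10(fluorescence) against
#' cycle. Windows must lie in the log-linear phase: all fluorescence values
#' positive, strictly increasing within the window (the strictly continuous
#' log-linear criterion), and below the plateau (at most `plateau_frac` of the
#' maximal corrected fluorescence). Ties are broken toward earlier cycles, so
#' a noiseless exponential returns the earliest admissible window.
#'
#' @param curve A baseline-corrected [amplification_curve()].
#' @param points Window length in cycles (default 4).
#' @param plateau_frac Fraction of the maximal fluorescence above which cycles
#'   are treated as plateau and excluded from the window.
#' @param floor Positivity floor for the log transform.
#' @return Integer vector `c(start, end)` of the selected window.
#' @export
window_of_linearity <- function(curve, points = 4L, plateau_frac = 0.9,
                                floor = 1e-12) {
  stopifnot(inherits(curve, "amplification_curve"), points >= 3L)
  f <- curve$fluorescence
  if (isTRUE(curve$non_amplifying)) {
    stop("curve is flagged non-amplifying; no window of linearity", call. = FALSE)
  }
  if (sum(f > floor) < points) {
    stop("fewer than `points` cycles with positive corrected fluorescence",
         call. = FALSE)
  }
  cap <- plateau_frac * max(f)
  best <- NULL; best_r2 <- -Inf
  for (s in seq_len(curve$cycles - points + 1L)) {
    idx <- s:(s + points - 1L)
    fi <- f[idx]
    if (any(fi <= floor) || any(diff(fi) <= 0) || any(fi > cap)) next
    r2 <- window_r2(log10(fi), idx)
    if (!is.na(r2) && r2 > best_r2 + 1e-12) {
      best_r2 <- r2; best <- c(s, s + points - 1L)
    }
  }
  if (is.null(best)) {
    stop("no admissible window of linearity found", call. = FALSE)
  }
  best
}

#' Per-reaction efficiency and Cq by log-linear regression
#'
#' Regresses log10(fluorescence) on cycle inside the window of linearity. The
#' amplification efficiency is `E = 10^slope` (per-cycle fold change); the
#' regression Cq is the fractional cycle where the fitted line crosses
#' `log10(threshold)`. The fixed-threshold Cq -- the single-threshold value a
#' plate instrument reports -- is also computed, by linear interpolation of
#' log10(fluorescence) between the two cycles bracketing the threshold.
#'
#' @param curve A baseline-corrected [amplification_curve()].
#' @param window Integer `c(start, end)`; computed by [window_of_linearity()]
#'   when `NULL`.
#' @param threshold Fluorescence threshold (default 0.1).
#' @param points Window length passed to [window_of_linearity()].
#' @param plateau_cycles,plateau_increase Plateau check: a reaction has no
#'   plateau when the mean relative fluorescence increase per cycle over the
#'   last `plateau_cycles` cycles exceeds `plateau_increase`. A reaction
#'   still in exponential growth gains `E - 1` (70--100 percent) per cycle,
#'   so the default 0.2 separates saturated tails from still-amplifying
#'   ones.
#' @param r2_min Windows fitting worse than this R-squared are flagged
#'   `below_r2`.
#' @return An object of class `efficiency_estimate`: `well_id`, `target`,
#'   `sample`, `efficiency`, `r_squared`, `cq_regression`, `cq_threshold`,
#'   `window`, and a named logical `flags` vector
#'   (`failed`, `no_plateau`, `below_r2`, `no_threshold_cross`,
#'   `non_amplifying`).
#' @export
reaction_efficiency_and_cq <- function(curve, window = NULL, threshold = 0.1,
                                       points = 4L, plateau_cycles = 5L,
                                       plateau_increase = 0.2, r2_min = 0.99) {
  stopifnot(inherits(curve, "amplification_curve"), threshold > 0)
  flags <- c(failed = FALSE, no_plateau = FALSE, below_r2 = FALSE,
             no_threshold_cross = FALSE,
             non_amplifying = isTRUE(curve$non_amplifying))
  out <- structure(
    list(well_id = curve$well_id, target = curve$target, sample = curve$sample,
         efficiency = NA_real_, r_squared = NA_real_, cq_regression = NA_real_,
         cq_threshold = NA_real_, window = c(NA_integer_, NA_integer_),
         flags = flags),
    class = "efficiency_estimate"
  )
  if (flags[["non_amplifying"]]) {
    out$flags[["failed"]] <- TRUE
    return(out)
  }
  if (is.null(window)) window <- window_of_linearity(curve, points = points)
  f <- curve$fluorescence
  idx <- window[1L]:window[2L]
  fit <- stats::lm.fit(cbind(1, idx), log10(f[idx]))
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  out$window <- window
  out$r_squared <- window_r2(log10(f[idx]), idx)
  if (!is.finite(slope) || slope <= 0) {
    out$flags[["failed"]] <- TRUE
    return(out)
  }
  out$efficiency <- 10^slope
  out$cq_regression <- (log10(threshold) - intercept) / slope
  # fixed-threshold Cq: interpolate in log-fluorescence across the crossing
  above <- which(f >= threshold)
  if (!length(above) || above[1L] == 1L || f[above[1L] - 1L] <= 0) {
    out$flags[["no_threshold_cross"]] <- TRUE
  } else {
    i <- above[1L]
    out$cq_threshold <- (i - 1L) +
      (log10(threshold) - log10(f[i - 1L])) / (log10(f[i]) - log10(f[i - 1L]))
  }
  # plateau check on the raw tail: still growing -> no plateau reached
  last <- (curve$cycles - plateau_cycles + 1L):curve$cycles
  rel <- diff(f[last]) / pmax(abs(f[last][-plateau_cycles]), 1e-12)
  out$flags[["no_plateau"]] <- mean(rel) > plateau_increase
  out$flags[["below_r2"]] <- !is.na(out$r_squared) && out$r_squared < r2_min
  out
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> well %s (%s / %s): E = %.4f, R2 = %.5f, Cq(reg) = %.3f, Cq(thr) = %.3f\n",
              x$well_id, x$target, x$sample, x$efficiency, x$r_squared,
              x$cq_regression, x$cq_threshold))
  on <- names(x$flags)[x$flags]
  if (length(on)) cat("  flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate efficiency and Cq for a set of curves
#'
#' Convenience pipeline: baseline-correct each curve, locate its window of
#' linearity and estimate per-reaction efficiency and Cq values.
#'
#' @param curves List of [amplification_curve()] objects.
#' @param baseline_cycles Baseline window, see [correct_baseline()].
#' @param points Window-of-linearity length.
#' @param threshold Fluorescence threshold for the fixed-threshold Cq.
#' @param ... Further arguments passed to [reaction_efficiency_and_cq()].
#' @return Data frame with one row per well: `well`, `target`, `sample`,
#'   `efficiency`, `r_squared`, `cq_regression`, `cq_threshold`,
#'   `window_start`, `window_end`, one logical column per flag.
#' @export
estimate_efficiencies <- function(curves, baseline_cycles = 3:15, points = 4L,
                                  threshold = 0.1, ...) {
  rows <- lapply(curves, function(cu) {
    cc <- correct_baseline(cu, baseline_cycles = baseline_cycles)
    est <- if (cc$non_amplifying) {
      reaction_efficiency_and_cq(cc, window = c(NA, NA), threshold = threshold, ...)
    } else {
      reaction_efficiency_and_cq(cc, threshold = threshold, points = points, ...)
    }
    cbind(
      data.frame(well = est$well_id, target = est$target, sample = est$sample,
                 efficiency = est$efficiency, r_squared = est$r_squared,
                 cq_regression = est$cq_regression, cq_threshold = est$cq_threshold,
                 window_start = est$window[1L], window_end = est$window[2L]),
      as.data.frame(as.list(est$flags))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-amplicon efficiency summary
#'
#' Averages per-reaction efficiencies for each target. Reactions flagged
#' failed, non-amplifying or no-plateau are excluded; efficiency outliers
#' (deviating from the per-target median by more than `mad_mult` median
#' absolute deviations) are included by default, mirroring common regression
#' software policy, or excluded when `include_outliers = FALSE`.
#'
#' @param estimates Data frame from [estimate_efficiencies()].
#' @param include_outliers Keep MAD-flagged efficiency outliers in the mean?
#' @param mad_mult Outlier cut in MAD units.
#' @return Data frame with one row per target: `target`, `mean_efficiency`,
#'   `n_reactions`, `n_excluded`, `n_outliers`, `mean_r_squared`. A target
#'   whose reactions are all excluded (e.g. none reached plateau) is reported
#'   with `NA` and a warning; only a call excluding everything is an error.
#' @export
amplicon_efficiency_summary <- function(estimates, include_outliers = TRUE,
                                        mad_mult = 3) {
  stopifnot(is.data.frame(estimates), nrow(estimates) > 0L)
  out <- lapply(split(estimates, estimates$target), function(sub) {
    ok <- !sub$failed & !sub$no_plateau & !sub$non_amplifying & is.finite(sub$efficiency)
    e <- sub$efficiency[ok]
    n_out <- 0L
    if (length(e) >= 3L) {
      dev <- abs(e - stats::median(e))
      mad_e <- stats::mad(e)
      is_out <- mad_e > 0 & dev > mad_mult * mad_e
      n_out <- sum(is_out)
      if (!include_outliers) {
        e <- e[!is_out]
        ok[ok][is_out] <- FALSE
      }
    }
    if (!length(e)) {
      warning("all reactions excluded for target ", sub$target[1L],
              call. = FALSE)
      return(data.frame(target = sub$target[1L], mean_efficiency = NA_real_,
                        n_reactions = 0L, n_excluded = nrow(sub),
                        n_outliers = n_out, mean_r_squared = NA_real_))
    }
    data.frame(target = sub$target[1L], mean_efficiency = mean(e),
               n_reactions = length(e), n_excluded = nrow(sub) - length(e),
               n_outliers = n_out, mean_r_squared = mean(sub$r_squared[ok], na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (all(is.na(out$mean_efficiency))) {
    stop("all reactions excluded", call. = FALSE)
  }
  out
}

#' Compare efficiencies across the levels of a design factor
#'
#' One-way ANOVA of per-reaction efficiencies across factor levels
#' (experimental day, group, tissue, ...), per amplicon. Used to check that
#' assay performance does not differ between runs or conditions.
#'
#' @param estimates Data frame from [estimate_efficiencies()] with an extra
#'   factor column.
#' @param factor_col Name of the factor column.
#' @return Data frame per target: `target`, `F`, `df1`, `df2`, `p`,
#'   `degenerate` (TRUE with `p = 1` convention when the efficiencies carry no
#'   variance at all).
#' @export
compare_efficiency_by_factor <- function(estimates, factor_col) {
  stopifnot(is.data.frame(estimates), factor_col %in% names(estimates))
  out <- lapply(split(estimates, estimates$target), function(sub) {
    keep <- is.finite(sub$efficiency)
    e <- sub$efficiency[keep]
    fac <- factor(sub[[factor_col]][keep])
    if (nlevels(fac) < 2L || any(table(fac) < 2L)) {
      stop("need at least 2 levels with at least 2 observations each (target ",
           sub$target[1L], ")", call. = FALSE)
    }
    if (stats::sd(e) == 0) {
      return(data.frame(target = sub$target[1L], F = 0, df1 = nlevels(fac) - 1L,
                        df2 = length(e) - nlevels(fac), p = 1, degenerate = TRUE))
    }
    an <- stats::anova(stats::lm(e ~ fac))
    data.frame(target = sub$target[1L], F = an[["F value"]][1L],
               df1 = an$Df[1L], df2 = an$Df[2L], p = an[["Pr(>F)"]][1L],
               degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
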