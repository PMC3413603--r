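#' Efficiency-corrected relative qPCR quantification
#'
#' Standard-curve estimation of per-assay amplification efficiency from a
#' 2x serial dilution, and efficiency-corrected relative expression between
#' a case and a control sample with one target and one or more reference
#' assays (Pfaffl-style ratio; multiple references combined by the
#' geometric mean of their efficiency-corrected ratios).
#'
#' @name qpcrx
NULL

#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Least-squares fit of Ct on log2(relative quantity). With slope `m` (Ct
#' per twofold dilution step) the amplification efficiency is
#' `E = 2^(-1/m) - 1`, so a perfect doubling per cycle gives m = -1 and
#' E = 1 (100%). A helper converts the common log10 slope convention
#' (m10 ~ -3.32 at 100%).
#'
#' @param points data frame with columns `log2_quantity` and `ct`
#'   (>= 3 points, at least two distinct quantities).
#' @return object of class `standard_curve`: slope, intercept, r_squared,
#'   efficiency.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(all(c("log2_quantity", "ct") %in% names(points)))
  if (nrow(points) < 3L) stopf("standard curve needs at least 3 points")
  if (length(unique(points$log2_quantity)) < 2L)
    stopf("degenerate dilution series: all quantities identical")
  fit <- stats::lm(ct ~ log2_quantity, data = points)
  slope <- unname(stats::coef(fit)[2L])
  # a noise-free series fits perfectly; the summary warning is immaterial
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, efficiency = 2^(-1 / slope) - 1,
                 n_points = nrow(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f Ct/log2, efficiency %.1f%%, r^2 %.4f (%d points)\n",
              x$slope, 100 * x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param slope_log10 slope of Ct on log10(quantity).
#' @export
efficiency_from_log10_slope <- function(slope_log10) {
  10^(-1 / slope_log10) - 1
}

#' Efficiency-corrected case/control expression ratio
#'
#' Replicate Cts are averaged per (sample, assay) cell. With per-assay
#' efficiency E and `dCt = Ct(control) - Ct(case)`, the target ratio is
#' `(1 + E_target)^dCt_target` divided by the combined reference ratio —
#' the geometric mean over references of `(1 + E_ref)^dCt_ref` (the
#' conventional multi-reference rule; `combine = "mean_dct"` instead
#' exponentiates each reference's mean dCt arithmetically averaged). A
#' ratio below 1 is reported as an N-fold reduction with N = 1/ratio.
#'
#' @param plate data frame with columns `sample` (values `case` and
#'   `control`), `assay`, `ct` (one row per replicate).
#' @param target target assay name.
#' @param references character vector of reference assay names (>= 1).
#' @param efficiencies named numeric vector of per-assay efficiencies,
#'   each in (0, 1.2].
#' @param combine reference combination rule.
#' @return object of class `fold_change_result`: ratio, fold, direction,
#'   description, per-assay dCt.
#' @export
fold_change <- function(plate, target, references, efficiencies,
                        combine = c("geometric", "mean_dct")) {
  combine <- match.arg(combine)
  assays <- c(target, references)
  if (any(!assays %in% names(efficiencies)))
    stopf("missing efficiency for assay %s",
          setdiff(assays, names(efficiencies))[1L])
  if (any(efficiencies[assays] <= 0 | efficiencies[assays] > 1.2))
    stopf("efficiency outside (0, 1.2] for assay %s",
          assays[which(efficiencies[assays] <= 0 |
                         efficiencies[assays] > 1.2)[1L]])
  cell_mean <- function(s, a) {
    ct <- plate$ct[plate$sample == s & plate$assay == a]
    if (!length(ct)) stopf("missing plate cell: sample %s, assay %s", s, a)
    mean(ct)
  }
  dct <- vapply(assays, function(a)
    cell_mean("control", a) - cell_mean("case", a), 1.0)
  ratio_t <- (1 + efficiencies[target])^dct[target]
  ref_ratios <- (1 + efficiencies[references])^dct[references]
  ratio_r <- switch(combine,
                    geometric = exp(mean(log(ref_ratios))),
                    mean_dct = {
      # arithmetic mean of reference dCts, at the mean reference efficiency
      (1 + mean(efficiencies[references]))^mean(dct[references])
    })
  ratio <- unname(ratio_t / ratio_r)
  fold <- if (ratio < 1) 1 / ratio else ratio
  direction <- if (ratio < 1) "reduction" else "increase"
  structure(list(ratio = ratio, fold = unname(fold), direction = direction,
                 dct = dct,
                 description = sprintf("%.3g-fold %s in case relative to control",
                                       fold, direction)),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("expression ratio (case/control): %.4g -> %s\n",
              x$ratio, x$description))
  invisible(x)
}
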