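#' Background-corrected FM4-64 signal
#'
#' `F = (F1 - B1) / (F0 - B0)`: the styryl-dye fluorescence at a time
#' point, background-subtracted and normalized to the background-subtracted
#' baseline intensity. Units cancel, so any common rescaling of the raw
#' intensities leaves `F` unchanged.
#'
#' @param F1 signal intensity at the time point.
#' @param B1 paired background at the time point.
#' @param F0 baseline signal intensity.
#' @param B0 baseline background.
#' @return numeric signal (vectorized over time points).
#' @export
fm464_signal <- function(F1, B1, F0, B0) {
  if (any(F0 - B0 == 0)) stop("degenerate baseline: F0 equals B0")
  (F1 - B1) / (F0 - B0)
}

#' FM4-64 destaining series
#'
#' Per-time-point background-corrected signal normalized to the mean
#' corrected intensity over the pre-stimulus baseline window. Destaining
#' upon depolarization shows as values falling below 1; monotone decrease
#' is expected of a real trace but is reported, not enforced.
#'
#' @param time numeric time points (ordered).
#' @param signal measured intensity per time point.
#' @param background paired background intensity per time point
#'   (nonnegative).
#' @param baseline_index indices of the pre-stimulus baseline window.
#' @return data.frame `time`, `depletion`.
#' @export
fm464_depletion_series <- function(time, signal, background, baseline_index) {
  stopifnot(length(time) == length(signal),
            length(signal) == length(background),
            length(baseline_index) >= 1,
            all(baseline_index %in% seq_along(time)))
  if (any(background < 0)) stop("negative background intensity")
  corrected <- signal - background
  base <- mean(corrected[baseline_index])
  if (base == 0) stop("degenerate baseline: zero mean corrected intensity")
  data.frame(time = time, depletion = corrected / base)
}

#' FRAP recovery normalized to unbleached cells
#'
#' Corrects the bleached-cell trace for acquisition decay using the
#' unbleached reference as a multiplicative decay standard anchored at its
#' first point - `corrected(t) = bleached(t) / unbleached(t) *
#' unbleached(1)` - converts to the recovered proportion
#' `corrected(t) / prebleach`, and expresses each time point as fold change
#' over the first post-bleach point.
#'
#' @param bleached intensity trace of the photobleached cell (first element
#'   = first post-bleach point).
#' @param unbleached aligned trace of an unbleached reference cell
#'   (positive).
#' @param prebleach_value pre-bleach intensity of the bleached cell.
#' @return numeric fold-recovery per time point (first element 1).
#' @export
frap_recovery <- function(bleached, unbleached, prebleach_value) {
  stopifnot(length(bleached) == length(unbleached), length(bleached) >= 1,
            length(prebleach_value) == 1)
  if (any(unbleached <= 0)) stop("nonpositive unbleached reference intensity")
  if (prebleach_value <= 0) stop("nonpositive pre-bleach intensity")
  corrected <- bleached / unbleached * unbleached[1]
  proportion <- corrected / prebleach_value
  if (proportion[1] == 0) stop("zero signal at the first post-bleach point")
  proportion / proportion[1]
}

#' Dual-luciferase knockdown relative to a scrambled control
#'
#' Each condition's reporter signal is normalized to its internal control;
#' knockdown is the fractional decrease of the treatment ratio relative to
#' the scramble ratio, `1 - ratio_treatment / ratio_scramble`. The
#' `meets_criterion` flag applies the strict `> 40%`-decrease criterion
#' (a decrease of exactly 0.40 does not meet it).
#'
#' @param treatment,scramble numeric length-2 vectors or lists with
#'   elements `reporter` and `control` (control > 0).
#' @param criterion fractional-decrease criterion (default 0.40, strict).
#' @return list `knockdown` (fractional decrease), `meets_criterion`.
#' @export
luciferase_knockdown <- function(treatment, scramble, criterion = 0.40) {
  get <- function(x, what, i) {
    v <- if (!is.null(names(x)) && what %in% names(x)) x[[what]] else x[[i]]
    as.numeric(v)
  }
  rt_ctrl <- get(treatment, "control", 2)
  rs_ctrl <- get(scramble, "control", 2)
  if (rt_ctrl <= 0 || rs_ctrl <= 0) stop("nonpositive internal-control signal")
  ratio_t <- get(treatment, "reporter", 1) / rt_ctrl
  ratio_s <- get(scramble, "reporter", 1) / rs_ctrl
  if (ratio_s == 0) stop("zero scramble reporter ratio")
  kd <- 1 - ratio_t / ratio_s
  list(knockdown = kd, meets_criterion = kd > criterion)
}
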