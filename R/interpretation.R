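# interpretation: class-activation maps, LOESS smoothing, CAM peak calling

#' Per-base class activation scores
#'
#' The raw CAM score of base `i` is the class-weighted sum over channels of
#' the final convolutional feature maps at position `i`. Class weights are
#' the gradient of the head logit with respect to the pooled convolutional
#' features at this sample, which is exact for the piecewise-linear dense
#' head and reduces to the classic class-weight vector when the head is a
#' single linear layer. Because the convolutions are stride-1 with
#' same-padding, the feature maps are already at base resolution and the
#' profile length equals the input length.
#'
#' @param model trained `insuloop_model` of kind `cnn_anchor` or `anchor`.
#' @param sequence a window sequence (character scalar).
#' @return numeric vector of per-base scores, one per input base.
#' @export
compute_cam <- function(model, sequence) {
  if (!model$kind %in% c("cnn_anchor", "anchor"))
    stop("CAM requires a model with a convolutional branch (cnn_anchor or anchor)")
  uses <- model_uses(model)
  opts <- cpp_opts(model$config, use_cnn = TRUE, use_rnn = uses[["rnn"]])
  fm <- cpp_cnn_featmaps(model$params, as.integer(encode_codes(sequence)), opts)
  feat <- trunk_features(model, sequence)
  w <- cpp_head_grad(model$params$head, as.numeric(feat[1, ]),
                     model$config$leaky_slope)
  ncnn <- ncol(fm$featmaps)
  as.numeric(fm$featmaps %*% w[seq_len(ncnn)])
}

#' LOESS-smooth a per-base score profile
#'
#' Locally weighted linear regression evaluated at every base with span
#' fraction `alpha`: the fit at each position is weighted toward the
#' nearest surrounding scores. Constant profiles are reproduced exactly and
#' linear profiles to numerical precision.
#'
#' @param raw numeric score vector (at least 10 points).
#' @param alpha span fraction in (0, 1]; default 0.4.
#' @return numeric vector of the same length.
#' @export
loess_smooth <- function(raw, alpha = 0.4) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (length(raw) < 10L) stop("loess_smooth needs at least 10 points")
  stats::lowess(seq_along(raw), raw, f = alpha, iter = 0L)$y
}

#' Call peaks on a smoothed CAM profile
#'
#' A base is a peak when it is the maximum of its centered `window`-base
#' span and its height strictly exceeds the `min_height_quantile` quantile
#' of the profile; adjacent qualifying bases collapse to the single highest
#' (leftmost on exact ties). A flat profile yields no peaks.
#'
#' @param smoothed numeric profile from [loess_smooth()].
#' @param window sliding-window width in bases (default 40).
#' @param min_height_quantile height threshold quantile (default 0.75).
#' @return `data.table` with `position` (1-based) and `height`.
#' @export
call_cam_peaks <- function(smoothed, window = 40L, min_height_quantile = 0.75) {
  n <- length(smoothed)
  if (window > n) stop("peak-calling window exceeds the profile length")
  half <- as.integer(window) %/% 2L
  thr <- stats::quantile(smoothed, min_height_quantile, names = FALSE)
  cand <- which(smoothed > thr)
  is_peak <- logical(n)
  for (i in cand) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half - 1L)
    if (smoothed[i] >= max(smoothed[lo:hi])) is_peak[i] <- TRUE
  }
  idx <- which(is_peak)
  if (length(idx) == 0L)
    return(data.table(position = integer(), height = numeric()))
  # collapse runs of adjacent qualifying bases to their highest base
  runs <- cumsum(c(1L, diff(idx) > 1L))
  keep <- vapply(split(idx, runs), function(ii) ii[which.max(smoothed[ii])],
                 integer(1))
  keep <- unname(sort(keep))
  data.table(position = keep, height = smoothed[keep])
}

#' Full CAM profile for one anchor window
#'
#' @param model trained model with a convolutional branch.
#' @param sequence anchor window sequence.
#' @param alpha LOESS span fraction.
#' @param window peak-calling window in bases.
#' @param min_height_quantile peak height threshold quantile.
#' @return list of class `cam_profile` with `raw`, `smoothed`, `peaks`,
#'   `alpha`, `window`.
#' @export
cam_profile <- function(model, sequence, alpha = 0.4, window = 40L,
                        min_height_quantile = 0.75) {
  raw <- compute_cam(model, sequence)
  smoothed <- loess_smooth(raw, alpha)
  peaks <- call_cam_peaks(smoothed, window, min_height_quantile)
  structure(list(raw = raw, smoothed = smoothed, peaks = peaks,
                 alpha = alpha, window = as.integer(window)),
            class = "cam_profile")
}

#' Aggregate CAM peak positions across anchors
#'
#' Positions are expressed relative to the window center (0-based offset in
#' `[-L/2, L/2)`), histogrammed into `bins` equal-width bins. The histogram
#' counts conserve the total peak number.
#'
#' @param profiles list of `cam_profile` objects over equal-length windows.
#' @param bins number of histogram bins.
#' @return list with `histogram` (`data.table`: `bin_start`, `bin_end`,
#'   `count`), `positions` (all relative positions), and
#'   `mean_peaks_per_anchor`.
#' @export
aggregate_peak_positions <- function(profiles, bins = 40L) {
  L <- length(profiles[[1]]$raw)
  rel <- unlist(lapply(profiles, function(p) p$peaks$position - 1L - L %/% 2L))
  breaks <- seq(-L %/% 2L, L - L %/% 2L, length.out = bins + 1L)
  counts <- if (length(rel)) {
    as.integer(table(cut(rel, breaks = breaks, right = FALSE,
                         include.lowest = TRUE)))
  } else rep(0L, bins)
  list(histogram = data.table(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1L], count = counts),
       positions = rel,
       mean_peaks_per_anchor = length(rel) / length(profiles))
}
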