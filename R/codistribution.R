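#' Fraction of mask A covered by mask B (percent)
#'
#' Area-based codistribution fraction `100 * |A intersect B| / |A|`,
#' deliberately asymmetric (e.g. the fraction of total SNX1 signal that
#' codistributes with EEA1). Computed on binary mask areas; pass `weights`
#' (an intensity image) for the intensity-weighted variant.
#'
#' @param maskA,maskB logical arrays of identical shape.
#' @param weights optional non-negative intensity array of the same shape;
#'   if given, sums of intensity replace pixel counts.
#' @return percentage in `[0, 100]`; 0 with a warning when `|A| = 0`.
#' @export
overlap_fraction <- function(maskA, maskB, weights = NULL) {
  if (!identical(dim(maskA), dim(maskB))) stopf("mask shapes differ")
  w <- if (is.null(weights)) 1 else { stopifnot(identical(dim(weights), dim(maskA))); weights }
  tot <- sum(maskA * w)
  if (tot == 0) {
    warnf("overlap_fraction: empty reference mask; returning 0")
    return(0)
  }
  100 * sum((maskA & maskB) * w) / tot
}

#' Merged-signal percentage of two masks (percent)
#'
#' Fraction of merged (codistributing) signal over the total signal of both
#' channels. The default denominator is the union `|A or B|`; the
#' alternative reading `|A| + |B|` is available via `denominator = "sum"`.
#' Symmetric in its arguments. The denominator convention used is attached
#' as attribute `denominator`.
#'
#' @param maskA,maskB logical arrays of identical shape.
#' @param denominator `"union"` (default) or `"sum"`.
#' @return percentage; 0 with a warning on an empty union.
#' @export
merge_percentage <- function(maskA, maskB, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(maskA), dim(maskB))) stopf("mask shapes differ")
  inter <- sum(maskA & maskB)
  den <- if (denominator == "union") sum(maskA | maskB) else sum(maskA) + sum(maskB)
  if (den == 0) {
    warnf("merge_percentage: both masks empty; returning 0")
    return(structure(0, denominator = denominator))
  }
  structure(100 * inter / den, denominator = denominator)
}

#' Detect puncta (spots) in one channel
#'
#' Single-scale blob detection in the spirit of spot-detector plugins: a
#' band-pass (difference of Gaussians at `scale_um` and `1.6 * scale_um`)
#' response is computed, local maxima are extracted, and maxima are kept if
#' they exceed a robust background threshold (median + k * MAD of the
#' response, floored at a fraction of the peak response so that noiseless
#' images behave). Deterministic given its inputs.
#'
#' @param image a 2D [calibrated_image].
#' @param channel channel name or index.
#' @param scale_um spot scale (Gaussian sigma) in micrometers.
#' @param k robust threshold multiplier (default 5).
#' @param rel_floor minimum response as a fraction of the maximum response
#'   (default 0.1).
#' @return a `data.frame` of class `spot_set`: `x_um`, `y_um`, `x_px`,
#'   `y_px`, `radius_um`, `peak`; attribute `channel`.
#' @export
detect_puncta <- function(image, channel, scale_um = 0.15, k = 5,
                          rel_floor = 0.1) {
  x <- get_channel(image, channel)
  if (length(dim(x)) != 2L) stopf("detect_puncta expects a 2D channel")
  px <- image$pixel_size_xy
  s1 <- scale_um / px
  g1 <- EBImage::gblur(x, sigma = s1)
  g2 <- EBImage::gblur(x, sigma = 1.6 * s1)
  resp <- g1 - g2
  thr <- stats::median(resp) + k * stats::mad(resp)
  mx <- max(resp)
  if (mx <= 0) return(empty_spots(channel))
  thr <- max(thr, rel_floor * mx)
  # 3x3 neighborhood maxima
  d <- dim(resp)
  pad <- matrix(-Inf, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- resp
  nbmax <- matrix(-Inf, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbmax <- pmax(nbmax, pad[2:(d[1] + 1L) + dr, 2:(d[2] + 1L) + dc])
  }
  peaks <- which(resp >= nbmax & resp > thr)
  if (!length(peaks)) return(empty_spots(channel))
  rc <- arrayInd(peaks, d)
  # collapse plateau/adjacent maxima into single spots
  sel <- matrix(FALSE, d[1], d[2]); sel[peaks] <- TRUE
  lab <- label(sel, connectivity = 8L)
  nsp <- attr(lab, "n")
  out <- data.frame(x_px = numeric(nsp), y_px = numeric(nsp),
                    x_um = numeric(nsp), y_um = numeric(nsp),
                    radius_um = scale_um * sqrt(2), peak = numeric(nsp))
  labv <- lab[peaks]
  for (i in seq_len(nsp)) {
    sub <- rc[labv == i, , drop = FALSE]
    wts <- resp[sub]
    cy <- sum(sub[, 1] * wts) / sum(wts)
    cx <- sum(sub[, 2] * wts) / sum(wts)
    out$y_px[i] <- cy - 0.5
    out$x_px[i] <- cx - 0.5
    out$y_um[i] <- (cy - 0.5) * px
    out$x_um[i] <- (cx - 0.5) * px
    out$peak[i] <- max(x[sub])
  }
  attr(out, "channel") <- channel
  class(out) <- c("spot_set", "data.frame")
  out
}

empty_spots <- function(channel) {
  out <- data.frame(x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
                    y_um = numeric(0), radius_um = numeric(0), peak = numeric(0))
  attr(out, "channel") <- channel
  class(out) <- c("spot_set", "data.frame")
  out
}

#' Percentage of spots associated with a reference signal
#'
#' A spot is associated when its centroid lies within `radius_um` of
#' reference foreground (for a mask reference; `radius_um = 0` means the
#' centroid's pixel must itself be foreground) or of any reference spot
#' centroid (for a spot-set reference, where the default radius is the
#' reference spot radius).
#'
#' @param spots a `spot_set` from [detect_puncta()].
#' @param reference logical mask or another `spot_set`.
#' @param radius_um association radius in micrometers (>= 0).
#' @param pixel_size micrometers per pixel (required for mask reference).
#' @return percentage of associated spots; `NA` with attribute
#'   `undefined = TRUE` when there are no spots.
#' @export
puncta_association <- function(spots, reference, radius_um = NULL,
                               pixel_size = NULL) {
  ntot <- nrow(spots)
  if (ntot == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    warnf("puncta_association: no spots; association undefined")
    return(out)
  }
  if (is.matrix(reference) && is.logical(reference)) {
    if (is.null(pixel_size)) stopf("mask reference requires pixel_size")
    if (is.null(radius_um)) radius_um <- 0
    if (!any(reference)) return(0)
    dist <- edt_distance(reference, spacing = c(pixel_size, pixel_size))
    rr <- pmin(pmax(round(spots$y_px + 0.5), 1), nrow(reference))
    cc <- pmin(pmax(round(spots$x_px + 0.5), 1), ncol(reference))
    dv <- dist[cbind(rr, cc)]
    assoc <- dv <= radius_um + 1e-9
  } else if (inherits(reference, "spot_set") || is.data.frame(reference)) {
    if (nrow(reference) == 0L) return(0)
    if (is.null(radius_um)) radius_um <- stats::median(reference$radius_um)
    assoc <- vapply(seq_len(ntot), function(i) {
      min(sqrt((reference$x_um - spots$x_um[i])^2 +
                 (reference$y_um - spots$y_um[i])^2)) <= radius_um + 1e-9
    }, logical(1))
  } else stopf("reference must be a logical mask or a spot_set")
  100 * sum(assoc) / ntot
}
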