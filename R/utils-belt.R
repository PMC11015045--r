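#' @title Circular-belt arithmetic helpers
#' @description Positions on the treadmill belt live on a circle of
#'   circumference `beltLength` (360 cm by default). All zone membership,
#'   distance and bin arithmetic must respect the wrap-around, with
#'   half-open intervals `[start, end)` in cm and 0-based half-open bins
#'   `[i*w, (i+1)*w)`.
#' @name belt-arithmetic
NULL

#' Wrap positions onto the belt
#'
#' @param x numeric positions in cm (any real value).
#' @param beltLength belt circumference in cm.
#' @return positions in `[0, beltLength)`.
#' @export
beltWrap <- function(x, beltLength) {
  ((x %% beltLength) + beltLength) %% beltLength
}

#' Unsigned circular distance between belt positions
#'
#' @param a,b positions in cm.
#' @param beltLength belt circumference in cm.
#' @return shortest arc distance, in `[0, beltLength/2]`.
#' @export
beltDistance <- function(a, b, beltLength) {
  d <- abs(beltWrap(a, beltLength) - beltWrap(b, beltLength))
  pmin(d, beltLength - d)
}

#' Half-open, wrap-aware zone membership
#'
#' @param position positions in cm.
#' @param zone numeric length-2, `c(start, end)`; interpreted as the
#'   half-open interval `[start, end)` walked forward from start, so a zone
#'   crossing 0 (start > end after wrapping) is handled.
#' @param beltLength belt circumference in cm.
#' @return logical vector.
#' @export
inZone <- function(position, zone, beltLength) {
  p <- beltWrap(position, beltLength)
  s <- beltWrap(zone[1], beltLength)
  e <- beltWrap(zone[2], beltLength)
  if (s < e) p >= s & p < e else p >= s | p < e
}

#' Spatial bin index of belt positions
#'
#' Bins are 0-based half-open intervals of width `beltLength / nBins`
#' (8 cm for the default 45 bins on a 360 cm belt). The returned index is
#' 1-based for R indexing; bin i covers `[(i-1)*w, i*w)` cm.
#'
#' @param position positions in cm.
#' @param beltLength belt circumference in cm.
#' @param nBins number of spatial bins.
#' @return integer bin indices in `1..nBins`.
#' @export
positionBin <- function(position, beltLength, nBins) {
  w <- beltLength / nBins
  idx <- floor(beltWrap(position, beltLength) / w) + 1L
  # guard against idx == nBins + 1 from floating point at the wrap point
  pmin(as.integer(idx), nBins)
}

#' Centers of the spatial bins in cm
#' @param beltLength belt circumference in cm.
#' @param nBins number of spatial bins.
#' @return numeric vector of bin-center positions.
#' @export
binCenters <- function(beltLength, nBins) {
  w <- beltLength / nBins
  (seq_len(nBins) - 0.5) * w
}

# internal: derive a 32-bit-safe child seed from a session seed
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}
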