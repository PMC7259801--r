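#' Speed, velocity and wandering index of a cell track
#'
#' Implements the track statistics used for cardiomyocytes migrating from
#' the anterior lateral plate mesoderm to the heart cone, exactly as
#' defined for manual Fiji tracks:
#' * mean speed `S` = sum of consecutive Euclidean step distances divided
#'   by total time (`t_last - t_first`);
#' * mean velocity `V` = straight-line distance from first to last point
#'   divided by total time;
#' * wandering index `W = S / V` (>= 1; equals 1 for a straight
#'   constant-direction path).
#'
#' Note `W` here is speed over velocity as printed in the source protocol;
#' the conventional meandering index is its reciprocal, available as
#' `1 / W`. When the net displacement is zero `W` is undefined: `S` is
#' still returned, `V = 0`, `W = NA` and the flag is set.
#'
#' @param track data.frame with columns `t` (minutes, strictly
#'   increasing), `x`, `y` (micrometres); at least two rows.
#' @return List with `S`, `V`, `W` and `undefined_wander` flag.
#' @export
#' @examples
#' compute_track_metrics(data.frame(t = 0:2, x = c(0, 3, 6), y = c(0, 4, 0)))
compute_track_metrics <- function(track) {
  stopifnot(all(c("t", "x", "y") %in% names(track)))
  if (nrow(track) < 2)
    .stop_cls("invalid_track", "track needs at least 2 samples")
  if (any(diff(track$t) <= 0))
    .stop_cls("invalid_track", "timestamps must be strictly increasing")
  total_time <- track$t[nrow(track)] - track$t[1]
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  S <- sum(steps) / total_time
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  V <- net / total_time
  if (V == 0) {
    list(S = S, V = 0, W = NA_real_, undefined_wander = TRUE)
  } else {
    list(S = S, V = V, W = S / V, undefined_wander = FALSE)
  }
}

#' Track metrics for a table of tracks
#'
#' @param tracks data.frame `track_id`, `t`, `x`, `y`.
#' @return data.frame with one row per track: `track_id`, `S`, `V`, `W`,
#'   `undefined_wander`.
#' @export
track_metrics_table <- function(tracks) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    m <- compute_track_metrics(tr[order(tr$t), ])
    data.frame(track_id = tr$track_id[1], S = m$S, V = m$V, W = m$W,
               undefined_wander = m$undefined_wander,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chamber-resolved cardiomyocyte counts from labelled nuclei
#'
#' Mef2 labels every cardiomyocyte nucleus; S46 co-labelling marks atrial
#' cardiomyocytes. A nucleus positive for both is atrial, never
#' ventricular; S46-only points (non-cardiomyocyte signal) are ignored.
#'
#' @param field data.frame with logical columns `mef2`, `s46` (and
#'   optionally coordinates and extra marker columns).
#' @return List `ventricular`, `atrial`, `total` with
#'   `ventricular + atrial == total`.
#' @export
count_chambers <- function(field) {
  stopifnot(all(c("mef2", "s46") %in% names(field)))
  mef2 <- as.logical(field$mef2)
  s46 <- as.logical(field$s46)
  list(ventricular = sum(mef2 & !s46),
       atrial = sum(mef2 & s46),
       total = sum(mef2))
}

#' Fraction of cardiomyocytes positive for an extra marker
#'
#' Used for BrdU proliferation and TUNEL cell-death indices: the number of
#' Mef2-positive nuclei that also carry the marker, over all Mef2-positive
#' nuclei.
#'
#' @param field data.frame with logical `mef2` column and the marker
#'   column.
#' @param marker Name of the logical marker column.
#' @return Fraction in `[0, 1]`.
#' @export
labeled_fraction <- function(field, marker) {
  stopifnot(marker %in% names(field), "mef2" %in% names(field))
  mef2 <- as.logical(field$mef2)
  if (sum(mef2) == 0)
    .stop_cls("undefined_denominator", "no mef2-positive nuclei in field")
  sum(mef2 & as.logical(field[[marker]])) / sum(mef2)
}

#' M-mode reslice of an image stack along a line
#'
#' Builds the kymograph ("M-mode") representation of a movie: for every
#' frame, intensities are sampled at unit spacing along a fixed line
#' segment using bilinear interpolation, and the sampled profiles are laid
#' out as columns ordered by frame.
#'
#' @param stack 3-D numeric array `[frame, row, col]`, at least 2 frames.
#' @param from,to Numeric `(row, col)` endpoints of the segment, 1-based,
#'   inside the image.
#' @return Matrix `[position_along_line, frame]` with
#'   `floor(segment_length) + 1` rows.
#' @export
reslice_mmode <- function(stack, from, to) {
  stopifnot(length(dim(stack)) == 3, length(from) == 2, length(to) == 2)
  nf <- dim(stack)[1]; nr <- dim(stack)[2]; nc <- dim(stack)[3]
  if (nf < 2) .stop_cls("insufficient_frames", "need at least 2 frames")
  pts <- rbind(from, to)
  if (any(pts[, 1] < 1 | pts[, 1] > nr | pts[, 2] < 1 | pts[, 2] > nc))
    .stop_cls("bounds_error", "line endpoints outside image bounds")
  len <- sqrt(sum((to - from)^2))
  n_pos <- floor(len) + 1
  frac <- if (len > 0) (seq_len(n_pos) - 1) / len else 0
  r <- from[1] + frac * (to[1] - from[1])
  c_ <- from[2] + frac * (to[2] - from[2])
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c_), nc - 1)
  wr <- r - r0; wc <- c_ - c0
  kymo <- matrix(0, nrow = n_pos, ncol = nf)
  for (f in seq_len(nf)) {
    img <- stack[f, , ]
    kymo[, f] <-
      img[cbind(r0, c0)] * (1 - wr) * (1 - wc) +
      img[cbind(r0 + 1, c0)] * wr * (1 - wc) +
      img[cbind(r0, c0 + 1)] * (1 - wr) * wc +
      img[cbind(r0 + 1, c0 + 1)] * wr * wc
  }
  kymo
}

#' Prominence-filtered local maxima
#'
#' Minimal peak picker used for beat detection: local maxima are filtered
#' by topographic prominence and then by a minimum separation (keeping the
#' higher peak of any too-close pair).
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence (same units as `x`).
#' @param min_separation Minimum index distance between kept peaks.
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prominence = 0, min_separation = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    hl <- which(x[seq_len(i - 1)] > x[i])
    left_min <- min(x[(if (length(hl)) max(hl) else 1):i])
    hr <- which(x[(i + 1):n] > x[i]) + i
    right_min <- min(x[i:(if (length(hr)) min(hr) else n)])
    x[i] - max(left_min, right_min)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (min_separation > 0 && length(cand) > 1) {
    keep <- integer(0)
    for (i in cand[order(x[cand], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - i) >= min_separation))
        keep <- c(keep, i)
    }
    cand <- sort(keep)
  }
  cand
}

#' Fractional shortening and heart rate from a diameter trace
#'
#' Detects diastolic peaks in a uniformly sampled ventricular diameter
#' trace (local maxima with prominence at least `prominence_frac` of the
#' trace range and separation at least `separation_frac` of the median
#' beat period), then computes:
#' * fractional shortening `FS = (Dd - Ds) / Dd` with `Dd` the mean of the
#'   cycle maxima and `Ds` the mean of the minima between consecutive
#'   peaks;
#' * heart rate as `(n_peaks - 1)` intervals over the elapsed time between
#'   first and last peak, in beats per minute.
#'
#' @param t Time in seconds (uniform sampling).
#' @param diameter Ventricular diameter per frame (micrometres, > 0).
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   trace range (default 0.10).
#' @param separation_frac Minimum peak separation as a fraction of the
#'   median inter-peak period (default 0.25).
#' @return List with `fractional_shortening`, `heart_rate_bpm`,
#'   `n_beats` (number of detected diastolic peaks).
#' @export
contraction_metrics <- function(t, diameter, prominence_frac = 0.10,
                                separation_frac = 0.25) {
  stopifnot(length(t) == length(diameter), all(diameter > 0))
  rng <- diff(range(diameter))
  if (rng == 0) .stop_cls("insufficient_cycles", "constant trace: no beats")
  peaks <- find_peaks(diameter, min_prominence = prominence_frac * rng)
  if (length(peaks) >= 3) {
    med_period <- median(diff(peaks))
    peaks <- find_peaks(diameter, min_prominence = prominence_frac * rng,
                        min_separation = separation_frac * med_period)
  }
  if (length(peaks) < 2)
    .stop_cls("insufficient_cycles", "fewer than 2 diastolic peaks detected")
  dd <- mean(diameter[peaks])
  troughs <- vapply(seq_len(length(peaks) - 1), function(i)
    min(diameter[peaks[i]:peaks[i + 1]]), numeric(1))
  ds <- mean(troughs)
  elapsed <- t[peaks[length(peaks)]] - t[peaks[1]]
  list(fractional_shortening = (dd - ds) / dd,
       heart_rate_bpm = (length(peaks) - 1) / elapsed * 60,
       n_beats = length(peaks))
}

#' Area of a gene expression field from a binary mask
#'
#' @param mask Logical (or strictly 0/1 numeric) matrix.
#' @param pixel_size Pixel edge length in micrometres (default 1, giving
#'   area in pixels squared).
#' @return Area: number of true pixels times `pixel_size^2`.
#' @export
#' @examples
#' expression_area(matrix(1, 10, 10), pixel_size = 2)  # 400
expression_area <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  v <- as.vector(mask)
  if (is.numeric(v) && !all(v %in% c(0, 1)))
    .stop_cls("invalid_mask", "mask must be binary (0/1 or logical)")
  sum(as.logical(v)) * pixel_size^2
}
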