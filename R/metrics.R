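# Acquisition-throughput normalization and signal/background measurement.
#
# Throughput is expressed as seconds per acquisition sequence per
# nanoliter of imaged volume, with 1 nL = 100^3 µm^3 = 1e6 µm^3:
#
#   normalized = acquisition_time_s / (n_sequences * volume_nL)
#
# The package ships a reference acquisition log (inst/extdata/
# acquisition_log.csv) of published benchmark recordings across light
# sheet, widefield and confocal instruments; rows whose printed normalized
# value is reproducible from their own time/sequence/extent columns are
# flagged self_consistent.

#' Parse an "HH:MM:SS.ms" duration into seconds
#'
#' Tolerates stray whitespace around the separators (as found in
#' hand-edited logs).
#'
#' @param text duration string, e.g. `"01:25:35.556"`.
#' @return seconds as a double.
#' @export
parse_duration <- function(text) {
  vapply(as.character(text), function(s) {
    s <- gsub("[[:space:]]", "", s)
    m <- regmatches(s, regexec("^(\\d+):(\\d{1,2}):(\\d{1,2}(\\.\\d+)?)$", s))[[1L]]
    if (length(m) < 4L) stopf("malformed duration '%s' (expected HH:MM:SS.ms)", s)
    as.numeric(m[2L]) * 3600 + as.numeric(m[3L]) * 60 + as.numeric(m[4L])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build an acquisition record
#'
#' @param acquisition_time duration string (`"HH:MM:SS.ms"`) or seconds.
#' @param n_sequences number of acquisition sequences (>= 1).
#' @param extent_um physical imaged extent `c(x, y, z)` in µm.
#' @param modality free-text tag.
#' @return an object of class `acquisition_record`.
#' @export
acquisition_record <- function(acquisition_time, n_sequences, extent_um,
                               modality = "unknown") {
  t <- if (is.character(acquisition_time)) parse_duration(acquisition_time)
       else as.numeric(acquisition_time)
  extent_um <- as.numeric(extent_um)
  if (!is.finite(t) || t <= 0) stopf("acquisition time must be > 0")
  if (n_sequences < 1) stopf("n_sequences must be a positive integer")
  if (length(extent_um) != 3L || any(extent_um <= 0)) {
    stopf("extent_um must be three positive numbers (x, y, z)")
  }
  structure(
    list(acquisition_time_s = t, n_sequences = as.integer(n_sequences),
         extent_um = extent_um, modality = modality),
    class = "acquisition_record"
  )
}

#' Normalized acquisition time (s per sequence per nL)
#'
#' `time_s / (n_sequences * volume_nL)` with
#' `volume_nL = x * y * z / 1e6` (extents in µm, 1 nL = 100^3 µm^3).
#'
#' @param record an [acquisition_record()].
#' @return seconds per sequence per nanoliter (full precision; see
#'   [table_round()] for printed-table rounding).
#' @export
normalized_time <- function(record) {
  stopifnot(inherits(record, "acquisition_record"))
  vol_nl <- prod(record$extent_um) / 1e6
  record$acquisition_time_s / (record$n_sequences * vol_nl)
}

#' Round like a published summary table
#'
#' Round-half-even to a fixed number of decimals, the convention the
#' reference acquisition log is printed with. The full-precision value
#' should always be retained alongside.
#'
#' @param x numeric vector.
#' @param decimals decimals to keep.
#' @return rounded numeric vector.
#' @export
table_round <- function(x, decimals) {
  round(x, decimals)
}

#' Reference acquisition log
#'
#' The bundled benchmark acquisition records (time, channels/sequences,
#' extents, printed normalized throughput and its printed decimals), with
#' the recomputed full-precision and table-rounded normalized values.
#' Rows with `self_consistent = FALSE` do not reproduce their printed
#' value from their own columns and are kept for the record only.
#'
#' @return a `data.table` with one row per recorded acquisition.
#' @export
acquisition_log <- function() {
  path <- system.file("extdata", "acquisition_log.csv", package = "voxcyto")
  dt <- data.table::fread(path)
  dt[, time_s := parse_duration(acquisition_time)]
  dt[, normalized_s_per_seq_nl := time_s /
       (n_sequences * (x_um * y_um * z_um / 1e6))]
  dt[, normalized_rounded := mapply(table_round, normalized_s_per_seq_nl,
                                    printed_decimals)]
  dt[]
}

#' Signal / background intensity measurement
#'
#' Emulates manual ROI measurement: samples `n_positions` square regions
#' of side `position_size_px` fully inside the signal mask and the
#' background mask (seeded, uniform over admissible positions), averages
#' the mean grey value per region, then across regions; the ratio of the
#' two averages is the signal-to-background estimate.
#'
#' @param image 2-D matrix or 3-D array (a single plane is sampled per
#'   region; 3-D inputs sample regions within random z-slices).
#' @param signal_mask,background_mask logical masks of the same shape;
#'   must be non-empty and disjoint.
#' @param n_positions regions per mask.
#' @param position_size_px square side length in pixels.
#' @param seed RNG seed.
#' @return list: `mean_signal`, `mean_background`, `ratio`.
#' @export
signal_background <- function(image, signal_mask, background_mask,
                              n_positions = 10L, position_size_px = 5L,
                              seed = 1L) {
  if (length(dim(image)) == 2L) {
    image <- array(image, dim = c(1L, dim(image)))
    signal_mask <- array(signal_mask, dim = dim(image))
    background_mask <- array(background_mask, dim = dim(image))
  }
  if (!identical(dim(image), dim(signal_mask)) ||
      !identical(dim(image), dim(background_mask))) {
    stopf("image and masks must share dimensions")
  }
  if (!any(signal_mask) || !any(background_mask)) stopf("masks must be non-empty")
  if (any(signal_mask & background_mask)) stopf("masks must be disjoint")
  k <- as.integer(position_size_px)
  # admissible top-left corners: k x k square fully inside the mask,
  # found with a 2-D integral image per slice
  corners <- function(mask) {
    d <- dim(mask)
    out <- NULL
    for (z in seq_len(d[1L])) {
      sl <- mask[z, , ]
      dim(sl) <- d[2:3]
      ny <- d[2L]; nx <- d[3L]
      if (ny < k || nx < k) next
      cs <- matrix(0, ny + 1L, nx + 1L)
      cs[-1L, -1L] <- t(apply(apply(sl * 1, 2L, cumsum), 1L, cumsum))
      ys <- seq_len(ny - k + 1L)
      xs <- seq_len(nx - k + 1L)
      tot <- cs[ys + k, xs + k, drop = FALSE] - cs[ys, xs + k, drop = FALSE] -
        cs[ys + k, xs, drop = FALSE] + cs[ys, xs, drop = FALSE]
      hit <- which(tot == k * k, arr.ind = TRUE)
      if (nrow(hit)) out <- rbind(out, cbind(z = z, hit))
    }
    out
  }
  region_means <- function(mask) {
    cand <- corners(mask)
    if (is.null(cand) || nrow(cand) < 1L) {
      stopf("cannot place a %dx%d region inside the mask", k, k)
    }
    pick <- cand[sample.int(nrow(cand), n_positions, replace = nrow(cand) < n_positions), ,
                 drop = FALSE]
    vapply(seq_len(nrow(pick)), function(i) {
      z <- pick[i, 1L]; y <- pick[i, 2L]; x <- pick[i, 3L]
      mean(image[z, y:(y + k - 1L), x:(x + k - 1L)])
    }, numeric(1))
  }
  with_seed(seed, {
    ms <- mean(region_means(signal_mask))
    mb <- mean(region_means(background_mask))
    list(mean_signal = ms, mean_background = mb, ratio = ms / mb)
  })
}
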