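# Channel segmentation: anisotropy-aware smoothing, global threshold,
# per-slice hole filling, connected components, optional distance-transform
# watershed splitting of touching objects, size filtering, and deterministic
# relabeling. Plus the shape-based split of one structural channel into
# glomeruli vs vessels.

#' Segmentation parameters
#'
#' @param smoothing_sigma_um Gaussian sigma in µm (>= 0); converted to a
#'   per-axis sigma in voxels, so smoothing is physically isotropic on
#'   anisotropic grids.
#' @param threshold list: `method` `"otsu"` or `"fixed"`; `value` required
#'   for `"fixed"`.
#' @param min_volume_um3 components smaller than this are removed (>= 0).
#' @param split_touching split touching blobs by distance-transform
#'   watershed.
#' @param connectivity 6, 18 or 26 (voxel neighborhood).
#' @param seed_separation_um minimum physical separation between watershed
#'   seeds (roughly one cell radius).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_um = 0.5,
                                threshold = list(method = "otsu", value = NULL),
                                min_volume_um3 = 0,
                                split_touching = FALSE,
                                connectivity = 26L,
                                seed_separation_um = 3) {
  if (!is.list(threshold) || is.null(threshold$method) ||
      !threshold$method %in% c("otsu", "fixed")) {
    stopf("threshold$method must be 'otsu' or 'fixed'")
  }
  if (threshold$method == "fixed" && is.null(threshold$value)) {
    stopf("fixed threshold requires a value")
  }
  if (!is.finite(min_volume_um3) || min_volume_um3 < 0) {
    stopf("min_volume_um3 must be finite and >= 0")
  }
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  if (smoothing_sigma_um < 0) stopf("smoothing_sigma_um must be >= 0")
  structure(
    list(smoothing_sigma_um = smoothing_sigma_um, threshold = threshold,
         min_volume_um3 = min_volume_um3, split_touching = isTRUE(split_touching),
         connectivity = as.integer(connectivity),
         seed_separation_um = seed_separation_um),
    class = "segmentation_params"
  )
}

#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximization on a 256-bin histogram.
#' @param values numeric vector.
#' @param n_bins histogram bins.
#' @return threshold on the intensity scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stopf("degenerate histogram: channel is constant")
  }
  h <- tabulate(pmin(n_bins, 1L + floor((values - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1L] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  # an empty valley between modes gives a plateau of maxima; take its middle
  top <- which(sigma_b >= max(sigma_b, na.rm = TRUE) * (1 - 1e-9))
  k <- top[ceiling(length(top) / 2)]
  rng[1L] + k / n_bins * diff(rng)
}

#' Segment one channel of a VoxelGrid into labeled 3D objects
#'
#' Pipeline: anisotropy-aware Gaussian smoothing, global threshold (Otsu or
#' fixed), per-z-slice hole filling (recovers solid masks from hollow
#' structures such as glomerular shells), connected components at the
#' configured connectivity, optional watershed split of touching blobs
#' (seeded at distance-map maxima), removal of components below
#' `min_volume_um3`, and relabeling 1..N by decreasing volume (ties broken
#' by ascending pre-relabel id).
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name or index.
#' @param params a [segmentation_params()].
#' @return a [label_map()] with attribute `threshold` (the value used).
#' @export
segment_channel <- function(grid, channel, params = segmentation_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "segmentation_params"))
  dims <- grid_dim(grid)
  vs <- grid$voxel_size_um
  vol_vox <- prod(vs)
  arr <- get_channel(grid, channel)
  x <- as.vector(arr)
  if (params$smoothing_sigma_um > 0) {
    x <- cpp_gaussian3d(x, dims, params$smoothing_sigma_um / vs)
  }
  thr <- if (params$threshold$method == "otsu") {
    otsu_threshold(x)
  } else {
    params$threshold$value
  }
  mask <- x > thr
  mask <- cpp_fill_holes_slices(mask, dims)
  lab <- cpp_label_components(mask, dims, params$connectivity)

  if (params$split_touching && any(mask)) {
    interior <- cpp_edt(!mask, dims, vs)$dist   # distance of fg to background
    maxima <- cpp_local_maxima(interior, mask, dims)
    seeds <- select_seeds(which(maxima), interior[maxima], dims, vs,
                          params$seed_separation_um)
    markers <- integer(length(mask))
    markers[seeds] <- seq_along(seeds)
    split_lab <- cpp_watershed(interior, mask, markers, dims)
    # voxels unreachable from any seed keep their component label (offset)
    orphan <- mask & split_lab == 0L
    if (any(orphan)) split_lab[orphan] <- max(split_lab) + lab[orphan]
    lab <- normalize_labels(split_lab)
  }

  # size filter (the only stage allowed to delete foreground voxels)
  if (params$min_volume_um3 > 0 && max(lab) > 0L) {
    sizes <- tabulate(lab)
    small <- sizes * vol_vox < params$min_volume_um3
    if (any(small)) {
      kill <- c(FALSE, small)   # position 1 = label 0
      lab[kill[lab + 1L]] <- 0L
    }
  }
  lab <- relabel_by_volume(lab)
  out <- label_map(array(lab, dim = dims), vs,
                   class_name = if (is.character(channel)) channel else
                     grid$channel_names[channel])
  attr(out, "threshold") <- thr
  out
}

# greedy seed thinning: keep maxima in decreasing depth order, suppressing
# any candidate within `sep_um` of an accepted seed
select_seeds <- function(idx, depth, dims, vs, sep_um) {
  if (!length(idx)) return(integer())
  ord <- order(depth, idx, decreasing = c(TRUE, FALSE), method = "radix")
  idx <- idx[ord]
  pos <- decode_index(idx, dims)
  pz <- (pos$z + 0.5) * vs[1L]
  py <- (pos$y + 0.5) * vs[2L]
  px <- (pos$x + 0.5) * vs[3L]
  keep <- integer()
  kz <- ky <- kx <- numeric()
  for (i in seq_along(idx)) {
    if (length(keep)) {
      d2 <- (kz - pz[i])^2 + (ky - py[i])^2 + (kx - px[i])^2
      if (min(d2) < sep_um^2) next
    }
    keep <- c(keep, idx[i])
    kz <- c(kz, pz[i]); ky <- c(ky, py[i]); kx <- c(kx, px[i])
  }
  keep
}

# renumber labels to contiguous 1..N in ascending original-id order
normalize_labels <- function(lab) {
  m <- max(lab)
  if (m == 0L) return(lab)
  sizes <- tabulate(lab, nbins = m)
  u <- which(sizes > 0L)
  if (length(u) == m && all(u == seq_len(m))) return(lab)
  map <- integer(m)
  map[u] <- seq_along(u)
  fg <- lab > 0L
  lab[fg] <- map[lab[fg]]
  lab
}

# relabel 1..N by decreasing voxel count, ties by ascending original label
relabel_by_volume <- function(lab) {
  lab <- normalize_labels(lab)
  m <- max(lab)
  if (m == 0L) return(lab)
  sizes <- tabulate(lab, nbins = m)
  ord <- order(-sizes, seq_len(m))
  map <- integer(m)
  map[ord] <- seq_len(m)
  fg <- lab > 0L
  lab[fg] <- map[lab[fg]]
  lab
}

#' Split a structural label map into glomeruli and vessels by shape
#'
#' Objects whose sphericity is at least `sphericity_min` and whose volume
#' lies inside `volume_range_um3` become glomeruli; every other object
#' becomes a vessel. The two outputs partition the input foreground
#' exactly; original label ids are preserved in attribute `source_labels`.
#'
#' @param labelmap a [label_map()] from the structural channel.
#' @param stats an [compute_object_stats()] table covering all its labels.
#' @param rules list: `sphericity_min`, `volume_range_um3 = c(lo, hi)`.
#' @return list with [label_map()]s `glomeruli` and `vessels`.
#' @export
split_structure_channel <- function(labelmap, stats,
                                    rules = list(sphericity_min = 0.7,
                                                 volume_range_um3 = c(1e4, 1e5))) {
  stopifnot(inherits(labelmap, "label_map"))
  ids <- sort(unique(labelmap$labels[labelmap$labels > 0L]))
  if (!all(ids %in% stats$object_id)) {
    stopf("stats table does not cover all labels")
  }
  st <- stats[match(ids, stats$object_id), ]
  is_glom <- st$sphericity >= rules$sphericity_min &
    st$volume_um3 >= rules$volume_range_um3[1L] &
    st$volume_um3 <= rules$volume_range_um3[2L]
  take <- function(sel_ids, name) {
    lab <- labelmap$labels
    lab[!(lab %in% sel_ids)] <- 0L
    lab <- normalize_labels(lab)
    out <- label_map(lab, labelmap$voxel_size_um, class_name = name)
    attr(out, "source_labels") <- sel_ids
    out
  }
  list(
    glomeruli = take(ids[is_glom], "glomeruli"),
    vessels = take(ids[!is_glom], "vessels")
  )
}
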