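# Per-object "surface" statistics: centroid, volume, mesh surface area,
# sphericity, per-channel median intensities, bounding box. One row per
# labeled object, mirroring what commercial surface-creation tools export.

#' Sphericity of a 3D object
#'
#' The standard dimensionless shape index: the surface area of a sphere of
#' the object's volume divided by the object's surface area,
#' `pi^(1/3) * (6 V)^(2/3) / A`. 1 for a perfect sphere, smaller for
#' elongated shapes. Mesh smoothing can push tiny digitized objects
#' slightly above 1; values are clipped at 1.05 with a warning rather than
#' silently snapped to 1.
#'
#' @param volume_um3 object volume (> 0).
#' @param surface_area_um2 object surface area (> 0).
#' @return sphericity in (0, 1.05].
#' @export
sphericity <- function(volume_um3, surface_area_um2) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0) ||
      any(!is.finite(surface_area_um2)) || any(surface_area_um2 <= 0)) {
    stopf("volume and surface area must be positive")
  }
  s <- pi^(1 / 3) * (6 * volume_um3)^(2 / 3) / surface_area_um2
  if (any(s > 1.05)) {
    warning(sprintf("%d sphericity value(s) above 1.05 clipped (mesh artifact)",
                    sum(s > 1.05)))
    s <- pmin(s, 1.05)
  }
  s
}

# mesh surface area of one object's binary mask (cropped block), honoring
# physical voxel spacing. The mask is padded with background and lightly
# smoothed (0.8 voxel Gaussian, validated against analytic sphere and
# spheroid areas) before isosurface extraction at 0.5, which
# removes voxelization faceting; objects too thin to survive smoothing fall
# back to the raw binary surface.
mask_mesh_area_um2 <- function(mask, voxel_size_um, smooth_vox = 0.8) {
  d <- dim(mask)
  pad <- 3L
  field <- array(0, dim = d + 2L * pad)
  field[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <-
    as.numeric(mask)
  dims <- dim(field)
  if (smooth_vox > 0) {
    sm <- cpp_gaussian3d(as.vector(field), dims, rep(smooth_vox, 3L))
    if (max(sm) >= 0.55) {
      field <- sm
    }  # else: object thinner than the kernel; keep the binary surface
  }
  cpp_mesh_area(as.vector(field), dims, voxel_size_um, 0.5)
}

#' Compute per-object statistics for a label map
#'
#' One record per label: physical centroid (`x_um`, `y_um`, `z_um`; centre
#' of mass of member voxel centres), exact voxel-count volume, mesh surface
#' area, sphericity, per-channel median intensity over member voxels
#' (even counts: mean of the two central values), and bounding-box extents.
#'
#' @param labelmap a [label_map()].
#' @param grid optional [voxel_grid()] sharing the geometry; when given,
#'   `median_<channel>` columns are added.
#' @return a `data.table` of class `object_table`, keyed by `object_id`,
#'   with attribute `provenance`.
#' @export
compute_object_stats <- function(labelmap, grid = NULL) {
  stopifnot(inherits(labelmap, "label_map"))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "voxel_grid"))
    if (!same_geometry(labelmap, grid)) {
      stopf("labelmap and grid geometry differ")
    }
  }
  dims <- grid_dim(labelmap)
  vs <- labelmap$voxel_size_um
  vox_vol <- prod(vs)
  idx <- which(labelmap$labels > 0L)
  if (!length(idx)) {
    out <- data.table::data.table(
      object_id = integer(), class_name = character(),
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      volume_um3 = numeric(), surface_area_um2 = numeric(),
      sphericity = numeric(),
      bbox_x_um = numeric(), bbox_y_um = numeric(), bbox_z_um = numeric()
    )
    data.table::setattr(out, "class", c("object_table", class(out)))
    return(out)
  }
  lab <- labelmap$labels[idx]
  pos <- decode_index(idx, dims)
  dt <- data.table::data.table(
    object_id = lab,
    z = (pos$z + 0.5) * vs[1L],
    y = (pos$y + 0.5) * vs[2L],
    x = (pos$x + 0.5) * vs[3L],
    iz = pos$z, iy = pos$y, ix = pos$x
  )
  if (!is.null(grid)) {
    nc <- dim(grid$intensities)[1L]
    for (ci in seq_along(grid$channel_names)) {
      # direct strided lookup into the (channel, z, y, x) array
      dt[, paste0("..int_", ci) := grid$intensities[ci + nc * (idx - 1)]]
    }
  }
  stats <- dt[, {
    base <- list(
      x_um = mean(x), y_um = mean(y), z_um = mean(z),
      volume_um3 = .N * vox_vol,
      iz0 = min(iz), iz1 = max(iz), iy0 = min(iy), iy1 = max(iy),
      ix0 = min(ix), ix1 = max(ix)
    )
    if (!is.null(grid)) {
      for (ci in seq_along(grid$channel_names)) {
        base[[paste0("median_", grid$channel_names[ci])]] <-
          median(.SD[[paste0("..int_", ci)]])
      }
    }
    base
  }, by = object_id]
  data.table::setorder(stats, object_id)

  # surface area per object from its cropped mask
  areas <- numeric(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    zr <- (stats$iz0[i]:stats$iz1[i]) + 1L
    yr <- (stats$iy0[i]:stats$iy1[i]) + 1L
    xr <- (stats$ix0[i]:stats$ix1[i]) + 1L
    block <- labelmap$labels[zr, yr, xr, drop = FALSE]
    dim(block) <- c(length(zr), length(yr), length(xr))
    areas[i] <- mask_mesh_area_um2(block == stats$object_id[i], vs)
  }
  stats[, surface_area_um2 := areas]
  stats[, sphericity := sphericity(volume_um3, surface_area_um2)]
  stats[, `:=`(
    class_name = labelmap$class_name,
    bbox_z_um = (iz1 - iz0 + 1L) * vs[1L],
    bbox_y_um = (iy1 - iy0 + 1L) * vs[2L],
    bbox_x_um = (ix1 - ix0 + 1L) * vs[3L]
  )]
  stats[, c("iz0", "iz1", "iy0", "iy1", "ix0", "ix1") := NULL]
  front <- c("object_id", "class_name", "x_um", "y_um", "z_um",
             "volume_um3", "surface_area_um2", "sphericity")
  data.table::setcolorder(stats, c(front, setdiff(names(stats), front)))
  data.table::setattr(stats, "provenance", list(
    class_name = labelmap$class_name,
    voxel_size_um = vs,
    dims = dims
  ))
  data.table::setattr(stats, "class", c("object_table", class(stats)))
  stats[]
}

#' Roundness (inverse aspect ratio) of a 2D region
#'
#' Minor/major axis-length ratio of the best-fit (second-moment) ellipse,
#' in (0, 1]. A single-pixel region is 1 by convention; each pixel
#' contributes its own 1/12-pixel moment so degenerate one-pixel-wide
#' regions stay finite.
#'
#' @param mask logical matrix.
#' @return roundness in (0, 1].
#' @export
roundness_2d <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) stopf("empty region")
  if (nrow(w) == 1L) return(1.0)
  cc <- scale(w, scale = FALSE)
  cov <- crossprod(cc) / nrow(w) + diag(1 / 12, 2L)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[2L] / ev[1L])
}

#' Convert an object table into long-format statistics tables
#'
#' One [statistics_long()] table per parameter, the per-parameter CSV
#' layout that [concat_statistics()] consumes. Intensity medians carry
#' their channel name.
#'
#' @param stats an [compute_object_stats()] table.
#' @return named list of `statistics_long` tables.
#' @export
object_stats_long <- function(stats) {
  geom <- c("x_um", "y_um", "z_um", "volume_um3", "surface_area_um2",
            "sphericity", "bbox_x_um", "bbox_y_um", "bbox_z_um")
  out <- list()
  for (p in intersect(geom, names(stats))) {
    out[[p]] <- statistics_long(stats$object_id, p, stats[[p]])
  }
  med <- grep("^median_", names(stats), value = TRUE)
  if (length(med)) {
    tabs <- lapply(med, function(m) {
      statistics_long(stats$object_id, "median_intensity", stats[[m]],
                      channel = sub("^median_", "", m))
    })
    out$median_intensity <- data.table::rbindlist(tabs)
    data.table::setattr(out$median_intensity, "class",
                        c("statistics_long", class(data.table::data.table())))
  }
  out
}
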