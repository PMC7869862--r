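# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures on disk.

# -- digitized shapes -------------------------------------------------------

# binary sphere mask: voxel centres (i + 0.5) * vs inside radius r around the
# volume centre (or an explicit centre in µm)
mk_sphere_mask <- function(dims, vs = c(1, 1, 1), r, center_um = dims * vs / 2) {
  zc <- ((seq_len(dims[1]) - 0.5) * vs[1]) - center_um[1]
  yc <- ((seq_len(dims[2]) - 0.5) * vs[2]) - center_um[2]
  xc <- ((seq_len(dims[3]) - 0.5) * vs[3]) - center_um[3]
  d2 <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`)
  array(d2 <= r^2, dim = dims)
}

# axis-aligned prolate spheroid mask, semi-axes (az, ay, ax) in µm
mk_spheroid_mask <- function(dims, vs = c(1, 1, 1), axes_um,
                             center_um = dims * vs / 2) {
  zc <- (((seq_len(dims[1]) - 0.5) * vs[1]) - center_um[1]) / axes_um[1]
  yc <- (((seq_len(dims[2]) - 0.5) * vs[2]) - center_um[2]) / axes_um[2]
  xc <- (((seq_len(dims[3]) - 0.5) * vs[3]) - center_um[3]) / axes_um[3]
  d2 <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`)
  array(d2 <= 1, dim = dims)
}

# closed-form prolate spheroid surface area, semi-axes a = b < c
spheroid_area_analytic <- function(a, c) {
  e <- sqrt(1 - a^2 / c^2)
  2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
}

# -- independent signed-distance oracle -------------------------------------

# brute-force signed distance at every voxel centre: min over foreground
# centres outside, -min over background centres inside (chunked so 32^3
# cases stay within memory)
oracle_signed_edt <- function(mask, vs) {
  dims <- dim(mask)
  n <- prod(dims)
  idx_all <- seq_len(n)
  pos <- voxcyto:::decode_index(idx_all, dims)
  P <- cbind((pos$z + 0.5) * vs[1], (pos$y + 0.5) * vs[2], (pos$x + 0.5) * vs[3])
  fg <- which(as.vector(mask))
  bg <- which(!as.vector(mask))
  out <- numeric(n)
  min_dist_to <- function(queries, sites) {
    if (!length(sites)) return(rep(Inf, length(queries)))
    S <- P[sites, , drop = FALSE]
    res <- numeric(length(queries))
    step <- 2048L
    for (s in seq(1, length(queries), by = step)) {
      q <- queries[s:min(length(queries), s + step - 1L)]
      Q <- P[q, , drop = FALSE]
      d2 <- outer(Q[, 1], S[, 1], `-`)^2 + outer(Q[, 2], S[, 2], `-`)^2 +
        outer(Q[, 3], S[, 3], `-`)^2
      res[(s:min(length(queries), s + step - 1L)) - s + 1L +
            (s - 1L)] <- sqrt(apply(d2, 1L, min))
    }
    res
  }
  out[bg] <- min_dist_to(bg, fg)
  out[fg] <- -min_dist_to(fg, bg)
  array(out, dim = dims)
}

# -- small phantoms ---------------------------------------------------------

# a fast, fully featured phantom: one field with glomeruli, vessel, cells of
# all three populations, deposits
tiny_phantom_spec <- function(seed = 1L, n_cells = 30L,
                              fractions = c(within = 0.2, surrounding = 0.4,
                                            peripheral = 0.4)) {
  phantom_spec(
    shape_voxels = c(48L, 128L, 128L),
    voxel_size_um = c(1.0, 0.6, 0.6),
    glomeruli = list(count = 2L, radius_um = c(10, 0.5), shell_thickness_um = 2.5,
                     min_gap_um = 6),
    vessels = list(count = 1L, radius_um = 3, waypoints = 2L),
    cells = list(count = n_cells, radius_um = c(2.5, 0.2),
                 population_fractions = fractions, min_gap_um = 2),
    deposits = list(fraction_of_glomeruli_with_deposits = 0.5,
                    per_glomerulus_count = 3L, radius_um = 1.2),
    seed = seed
  )
}

# segmentation parameters matched to the phantom intensity model
# (mid-amplitude thresholds)
tiny_seg_params <- function(channel = "mhc2", min_volume_um3 = 10) {
  value <- c(mhc2 = 95, cd31 = 100, igg = 120)[[channel]]
  segmentation_params(
    smoothing_sigma_um = 0.4,
    threshold = list(method = "fixed", value = value),
    min_volume_um3 = min_volume_um3
  )
}

# greedy 1:1 centroid matching between measured objects and ground truth;
# returns counts for recall/precision
match_objects <- function(stats, gt_cells, tol_um) {
  used <- rep(FALSE, nrow(gt_cells))
  hits <- 0L
  for (i in seq_len(nrow(stats))) {
    d2 <- (gt_cells$x_um - stats$x_um[i])^2 + (gt_cells$y_um - stats$y_um[i])^2 +
      (gt_cells$z_um - stats$z_um[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol_um^2) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(hits = hits, recall = hits / nrow(gt_cells), precision = hits / nrow(stats))
}
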