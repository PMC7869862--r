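# Channel segmentation and the glomeruli/vessel shape split.

sphere_grid <- function(centers_um, r_um, dims = c(24L, 48L, 48L),
                        vs = c(1, 0.5, 0.5), fg = 200, bg = 0) {
  ch <- array(bg, dim = dims)
  for (i in seq_len(nrow(centers_um))) {
    m <- mk_sphere_mask(dims, vs, r_um, centers_um[i, ])
    ch[m] <- fg
  }
  arr <- array(0, dim = c(1, dims))
  arr[1, , , ] <- ch
  voxel_grid(arr, vs, "ch")
}

test_that("disjoint bright spheres yield exactly one label each", {
  centers <- rbind(c(8, 6, 6), c(8, 18, 6), c(16, 12, 18))
  grid <- sphere_grid(centers, 3)
  lm <- segment_channel(grid, "ch", segmentation_params(
    smoothing_sigma_um = 0, threshold = list(method = "fixed", value = 100)))
  expect_identical(n_labels(lm), 3L)
  # labels are contiguous and ordered by decreasing volume
  st <- suppressWarnings(compute_object_stats(lm))
  expect_identical(st$object_id, 1:3)
  expect_true(all(diff(st$volume_um3) <= 0))
})

test_that("noise below threshold yields zero labels; Otsu rejects flat input", {
  set.seed(3)
  arr <- array(runif(16 * 16 * 16) * 10, dim = c(1, 16, 16, 16))
  grid <- voxel_grid(arr, c(1, 1, 1), "ch")
  lm <- segment_channel(grid, "ch", segmentation_params(
    0, list(method = "fixed", value = 50)))
  expect_identical(n_labels(lm), 0L)
  flat <- voxel_grid(array(7, dim = c(1, 8, 8, 8)), c(1, 1, 1), "ch")
  expect_error(segment_channel(flat, "ch", segmentation_params(0)),
               "degenerate histogram")
})

test_that("Otsu separates a bimodal channel near the midpoint", {
  set.seed(11)
  vals <- c(rnorm(5000, 20, 4), rnorm(800, 180, 10))
  thr <- otsu_threshold(vals)
  expect_gt(thr, 40)
  expect_lt(thr, 160)
})

test_that("per-slice hole filling recovers solid masks from hollow shells", {
  dims <- c(24L, 32L, 32L); vs <- c(1, 1, 1)
  shell <- mk_sphere_mask(dims, vs, 10) & !mk_sphere_mask(dims, vs, 7)
  arr <- array(0, dim = c(1, dims)); arr[1, , , ][shell] <- 100
  grid <- voxel_grid(arr, vs, "ch")
  lm <- segment_channel(grid, "ch", segmentation_params(
    0, list(method = "fixed", value = 50)))
  # the filled object covers the solid sphere, not just the shell
  st <- suppressWarnings(compute_object_stats(lm))
  expect_equal(st$volume_um3, 4 / 3 * pi * 10^3, tolerance = 0.06)
})

test_that("foreground is conserved up to the size filter (property)", {
  spec <- tiny_phantom_spec(seed = 21L, n_cells = 20L)
  ph <- generate_phantom(spec)
  params0 <- segmentation_params(0.4, list(method = "fixed", value = 95), 0)
  lm <- segment_channel(ph$grid, "mhc2", params0)
  # recompute the mask independently from the smoothed channel
  x <- voxcyto:::cpp_gaussian3d(as.vector(get_channel(ph$grid, "mhc2")),
                                grid_dim(ph$grid),
                                0.4 / ph$grid$voxel_size_um)
  mask <- voxcyto:::cpp_fill_holes_slices(x > 95, grid_dim(ph$grid))
  expect_identical(sum(lm$labels > 0L), sum(mask))
})

test_that("raising min_volume_um3 never increases the object count", {
  spec <- tiny_phantom_spec(seed = 22L, n_cells = 25L)
  ph <- generate_phantom(spec)
  counts <- vapply(c(0, 10, 40, 80, 200), function(mv) {
    n_labels(segment_channel(ph$grid, "mhc2", segmentation_params(
      0.4, list(method = "fixed", value = 95), mv)))
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("watershed splits touching blobs and never merges", {
  # two spheres touching at a neck
  dims <- c(20L, 40L, 24L); vs <- c(1, 1, 1)
  ch <- array(0, dim = dims)
  ch[mk_sphere_mask(dims, vs, 6, c(10, 14, 12))] <- 100
  ch[mk_sphere_mask(dims, vs, 6, c(10, 25, 12))] <- 100
  arr <- array(0, dim = c(1, dims)); arr[1, , , ] <- ch
  grid <- voxel_grid(arr, vs, "ch")
  merged <- segment_channel(grid, "ch", segmentation_params(
    0, list(method = "fixed", value = 50), split_touching = FALSE))
  split <- segment_channel(grid, "ch", segmentation_params(
    0, list(method = "fixed", value = 50), split_touching = TRUE,
    seed_separation_um = 6))
  expect_identical(n_labels(merged), 1L)
  expect_identical(n_labels(split), 2L)
  expect_gte(n_labels(split), n_labels(merged))
  # voxel conservation through the split
  expect_identical(sum(split$labels > 0L), sum(merged$labels > 0L))
})

test_that("cell recovery on phantoms reaches the 1:1 matching bar", {
  hits <- 0L; total <- 0L; found <- 0L
  for (s in c(31L, 32L)) {
    ph <- generate_phantom(tiny_phantom_spec(seed = s, n_cells = 50L))
    lm <- segment_channel(ph$grid, "mhc2", tiny_seg_params("mhc2"))
    st <- suppressWarnings(compute_object_stats(lm))
    gt <- ph$ground_truth[ph$ground_truth$class == "mhc2_cells"]
    tol <- sqrt(sum(ph$grid$voxel_size_um^2))   # one voxel diagonal
    m <- match_objects(st, gt, tol)
    hits <- hits + m$hits; total <- total + nrow(gt); found <- found + nrow(st)
  }
  expect_gte(hits / total, 0.98)   # recall
  expect_gte(hits / found, 0.98)   # precision
})

test_that("split_structure_channel separates spheres from tubes by shape", {
  dims <- c(30L, 60L, 60L); vs <- c(1, 1, 1)
  ch <- array(0, dim = dims)
  ch[mk_sphere_mask(dims, vs, 12, c(15, 20, 20))] <- 100
  # a 1:10 tube along y
  for (y in 5:55) ch[14:18, y, 44:48] <- 100
  arr <- array(0, dim = c(1, dims)); arr[1, , , ] <- ch
  grid <- voxel_grid(arr, vs, "ch")
  lm <- segment_channel(grid, "ch", segmentation_params(
    0, list(method = "fixed", value = 50)))
  st <- suppressWarnings(compute_object_stats(lm))
  parts <- split_structure_channel(lm, st, rules = list(
    sphericity_min = 0.7, volume_range_um3 = c(1e3, 5e4)))
  expect_identical(n_labels(parts$glomeruli), 1L)
  expect_identical(n_labels(parts$vessels), 1L)
  # exact foreground partition
  expect_identical(sum(parts$glomeruli$labels > 0L) + sum(parts$vessels$labels > 0L),
                   sum(lm$labels > 0L))
  expect_false(any(parts$glomeruli$labels > 0L & parts$vessels$labels > 0L))
  # all-spherical input -> empty vessels
  lm2 <- label_map(ifelse(mk_sphere_mask(dims, vs, 10, c(15, 30, 30)), 1L, 0L) |>
                     array(dim = dims), vs)
  st2 <- suppressWarnings(compute_object_stats(lm2))
  parts2 <- split_structure_channel(lm2, st2, rules = list(
    sphericity_min = 0.7, volume_range_um3 = c(1e3, 5e4)))
  expect_identical(n_labels(parts2$vessels), 0L)
  # empty input -> two empty outputs
  empty <- label_map(array(0L, dim = c(4, 4, 4)), c(1, 1, 1))
  parts3 <- split_structure_channel(empty, suppressWarnings(compute_object_stats(empty)))
  expect_identical(n_labels(parts3$glomeruli), 0L)
  expect_identical(n_labels(parts3$vessels), 0L)
  # stats/label mismatch errors
  expect_error(split_structure_channel(lm, st2), "cover")
})
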