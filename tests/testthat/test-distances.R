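# Signed distance transform, shortest distances, population classification.

half_diag <- function(vs) sqrt(sum(vs^2)) / 2

test_that("signed distance map has radial geometry on a solid sphere", {
  dims <- c(32L, 32L, 32L); vs <- c(1, 1, 1)
  center <- dims * vs / 2
  mask <- mk_sphere_mask(dims, vs, 10)
  lm <- label_map(array(as.integer(mask), dim = dims), vs)
  dm <- signed_distance_map(lm)
  probe <- function(offset_um) {
    # voxel whose centre is closest to center + (0, 0, offset)
    ix <- round(c(center[1], center[2], center[3] + offset_um) / vs - 0.5) + 1
    dm$dist[ix[1], ix[2], ix[3]]
  }
  expect_equal(probe(15), 5, tolerance = half_diag(vs))
  expect_equal(probe(4), -6, tolerance = half_diag(vs))
  # the zero level brackets the analytic boundary within one voxel step
  expect_lte(abs(probe(10)), 1 + 1e-9)
  expect_lt(probe(9), 0)
  expect_gt(probe(11), 0)
})

test_that("empty target gives an all-Inf map with a warning", {
  empty <- label_map(array(0L, dim = c(6, 6, 6)), c(1, 1, 1))
  expect_warning(dm <- signed_distance_map(empty), "empty target")
  expect_true(all(is.infinite(dm$dist)))
  obj <- label_map(array(rep(c(0L, 1L), 108), dim = c(6, 6, 6)), c(1, 1, 1))
  res <- shortest_distance(obj, dm)
  expect_true(all(is.infinite(res$shortest_distance_um)))
  expect_true(all(is.na(res$nearest_target_id)))
})

test_that("distance map equals the brute-force oracle on random anisotropic masks", {
  set.seed(77)
  for (rep in 1:12) {
    dims <- sample(6:16, 3, replace = TRUE)
    vs <- c(runif(1, 0.8, 2.5), runif(1, 0.2, 0.8), runif(1, 0.2, 0.8))
    mask <- array(runif(prod(dims)) < runif(1, 0.03, 0.3), dim = dims)
    if (!any(mask) || all(mask)) next
    lm <- label_map(array(as.integer(mask), dim = dims), vs)
    dm <- signed_distance_map(lm, fill_holes = FALSE)
    oracle <- oracle_signed_edt(mask, vs)
    expect_lt(max(abs(dm$dist - oracle)), 1e-9)       # exact, voxel-centre sense
    expect_lt(max(abs(dm$dist - oracle)), half_diag(vs))
  }
})

test_that("shortest distance has surface-to-surface semantics", {
  dims <- c(24L, 64L, 24L); vs <- c(1, 1, 1)
  glom <- mk_sphere_mask(dims, vs, 10, c(12, 14, 12))
  tl <- label_map(array(as.integer(glom), dim = dims), vs, "glomeruli")
  dm <- signed_distance_map(tl)
  # analytic gap 15: cell r=5 centred 30 from glom centre r=10
  cell <- mk_sphere_mask(dims, vs, 5, c(12, 44, 12))
  ol <- label_map(array(as.integer(cell), dim = dims), vs, "cells")
  res <- shortest_distance(ol, dm, tl)
  expect_equal(res$shortest_distance_um, 15, tolerance = half_diag(vs))
  expect_identical(res$nearest_target_id, 1L)
  # containment -> negative
  inside <- mk_sphere_mask(dims, vs, 3, c(12, 14, 12))
  il <- label_map(array(as.integer(inside), dim = dims), vs)
  expect_lt(shortest_distance(il, dm, tl)$shortest_distance_um, 0)
})

test_that("local supersampling refinement tightens small gaps, never below zero", {
  dims <- c(20L, 48L, 20L); vs <- c(1, 0.6, 0.6)
  glom <- mk_sphere_mask(dims, vs, 8, c(10, 9, 6))
  tl <- label_map(array(as.integer(glom), dim = dims), vs, "glomeruli")
  cell <- mk_sphere_mask(dims, vs, 3, c(10, 9 + 8 + 3 + 1.0, 6))  # gap 1 µm
  ol <- label_map(array(as.integer(cell), dim = dims), vs, "cells")
  dm <- signed_distance_map(tl)
  raw <- shortest_distance(ol, dm, tl)$shortest_distance_um
  ref <- shortest_distance(ol, dm, tl, refine_below_um = 2.5,
                           refine_factor = 2)$shortest_distance_um
  expect_lte(ref, raw)
  expect_gt(ref, 0)
  expect_equal(ref, 1.0, tolerance = half_diag(vs))
})

test_that("population classification follows the gate conventions", {
  expect_identical(classify_population(-2), "within")
  expect_identical(classify_population(10), "surrounding")
  expect_identical(classify_population(25), "peripheral")
  # boundary conventions: 0.5 and 20 belong to 'surrounding'
  expect_identical(classify_population(c(0.4999, 0.5, 20, 20.0001, Inf)),
                   c("within", "surrounding", "surrounding", "peripheral",
                     "peripheral"))
  expect_error(classify_population(1, c(2, 1)), "t_in < t_out|need")
})

test_that("within_fraction gates at <= 20 and guards the empty gate", {
  res <- data.table::data.table(shortest_distance_um = c(-1, 10, 10, 30))
  wf <- within_fraction(res)
  expect_identical(wf$n_gated, 3L)
  expect_equal(wf$fraction_within, 1 / 3)
  # d = 20 is inside the gate (within + surrounding compose it)
  wf20 <- within_fraction(data.table::data.table(shortest_distance_um = c(20, 21)))
  expect_identical(wf20$n_gated, 1L)
  # all peripheral -> undefined, not zero
  wfall <- within_fraction(data.table::data.table(shortest_distance_um = c(30, 40)))
  expect_identical(wfall$n_gated, 0L)
  expect_true(is.na(wfall$fraction_within))
  expect_error(within_fraction(data.table::data.table(shortest_distance_um = numeric())),
               "non-empty")
})

test_that("populations always partition the objects (property)", {
  set.seed(99)
  for (rep in 1:20) {
    d <- c(runif(sample(5:50, 1), -5, 50), if (runif(1) < 0.3) Inf)
    pop <- classify_population(d)
    expect_identical(length(d),
                     sum(pop == "within") + sum(pop == "surrounding") +
                       sum(pop == "peripheral"))
  }
})

test_that("whole-voxel rigid translation leaves distances unchanged", {
  dims <- c(18L, 30L, 30L); vs <- c(1.2, 0.5, 0.5)
  set.seed(5)
  glom <- mk_sphere_mask(dims, vs, 5, c(8, 6, 6))
  cell <- mk_sphere_mask(dims, vs, 2, c(10, 11, 9))
  shift <- function(m, dz, dy, dx) {
    out <- array(FALSE, dim = dim(m))
    out[(1 + dz):dim(m)[1], (1 + dy):dim(m)[2], (1 + dx):dim(m)[3]] <-
      m[1:(dim(m)[1] - dz), 1:(dim(m)[2] - dy), 1:(dim(m)[3] - dx)]
    out
  }
  d0 <- shortest_distance(
    label_map(array(as.integer(cell), dim = dims), vs),
    signed_distance_map(label_map(array(as.integer(glom), dim = dims), vs))
  )$shortest_distance_um
  d1 <- shortest_distance(
    label_map(array(as.integer(shift(cell, 3, 5, 2)), dim = dims), vs),
    signed_distance_map(label_map(array(as.integer(shift(glom, 3, 5, 2)), dim = dims), vs))
  )$shortest_distance_um
  expect_equal(d0, d1)
})

test_that("dilating the target never increases any shortest distance", {
  set.seed(55)
  dims <- c(16L, 24L, 24L); vs <- c(1, 0.7, 0.7)
  glom <- mk_sphere_mask(dims, vs, 4, c(8, 8, 8))
  tl <- label_map(array(as.integer(glom), dim = dims), vs)
  cells <- array(0L, dim = dims)
  cells[2, 20, 20] <- 1L; cells[14, 4, 18] <- 2L; cells[8, 16, 5] <- 3L
  ol <- label_map(cells, vs)
  d0 <- shortest_distance(ol, signed_distance_map(tl))$shortest_distance_um
  dil <- dilate_mask(tl, 2)
  d1 <- shortest_distance(ol, signed_distance_map(dil))$shortest_distance_um
  expect_true(all(d1 <= d0 + 1e-9))
})

test_that("geometry mismatches are rejected", {
  a <- label_map(array(0L, dim = c(4, 4, 4)), c(1, 1, 1))
  b <- label_map(array(0L, dim = c(4, 4, 5)), c(1, 1, 1))
  suppressWarnings(dm <- signed_distance_map(a))
  expect_error(shortest_distance(b, dm), "geometry")
})
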