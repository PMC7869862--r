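# Phantom generator: determinism, planted-label consistency, rasterization
# accuracy, scenario presets, noise model.

test_that("same spec and seed give bit-identical phantom and ground truth", {
  spec <- tiny_phantom_spec(seed = 5L, n_cells = 12L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$grid$intensities, b$grid$intensities)
  expect_identical(as.data.frame(a$ground_truth), as.data.frame(b$ground_truth))
})

test_that("zero cells means a background-only cell channel", {
  spec <- phantom_spec(
    shape_voxels = c(16L, 24L, 24L), voxel_size_um = c(1, 1, 1),
    glomeruli = list(count = 1L, radius_um = c(6, 0.1)),
    vessels = list(count = 0L),
    cells = list(count = 0L),
    deposits = list(fraction_of_glomeruli_with_deposits = 0),
    noise = list(background_level = 10, gaussian_sd = 0, poisson = FALSE),
    seed = 2L
  )
  ph <- generate_phantom(spec)
  expect_false(any(ph$ground_truth$class == "mhc2_cells"))
  mhc2 <- get_channel(ph$grid, "mhc2")
  expect_true(all(mhc2 == 10))   # exactly background: no noise, no objects
})

test_that("population fractions are honored exactly and planted distances verify", {
  spec <- tiny_phantom_spec(seed = 9L, n_cells = 100L,
                            fractions = c(within = 0.2, surrounding = 0.3,
                                          peripheral = 0.5))
  ph <- generate_phantom(spec)
  gt <- ph$ground_truth
  cells <- gt[gt$class == "mhc2_cells"]
  expect_identical(unname(table(cells$true_population)[c("within", "surrounding", "peripheral")]),
                   table(factor(c(rep("within", 20), rep("surrounding", 30),
                                  rep("peripheral", 50)),
                                levels = c("within", "surrounding", "peripheral"))) |>
                     unname())
  # analytic sphere-to-sphere re-derivation: |c_cell - c_glom| - r_glom - r_cell
  glom <- gt[gt$class == "glomeruli"]
  d_re <- vapply(seq_len(nrow(cells)), function(i) {
    min(sqrt((glom$x_um - cells$x_um[i])^2 + (glom$y_um - cells$y_um[i])^2 +
               (glom$z_um - cells$z_um[i])^2) - glom$radius_um - cells$radius_um[i])
  }, numeric(1))
  expect_equal(d_re, cells$planted_distance_um, tolerance = 1e-12)
  # recomputed labels reproduce the planted labels exactly
  expect_identical(classify_population(d_re), cells$true_population)
  # population intervals hold
  expect_true(all(d_re[cells$true_population == "within"] < 0.5))
  expect_true(all(d_re[cells$true_population == "surrounding"] >= 0.5 &
                    d_re[cells$true_population == "surrounding"] <= 20))
  expect_true(all(d_re[cells$true_population == "peripheral"] > 20))
})

test_that("rasterized sphere voxel coverage matches the analytic volume", {
  gt <- data.table::data.table(z_um = 20, y_um = 20, x_um = 20, radius_um = 10)
  out <- rasterize_objects(gt, c(40L, 40L, 40L), c(1, 1, 1), intensity = 100)
  count <- sum(out$channel > 0)
  expect_equal(count, 4 / 3 * pi * 10^3, tolerance = 0.05)
  expect_false(out$truncated[1])
  # zero-intensity model -> all-background channel
  out0 <- rasterize_objects(gt, c(40L, 40L, 40L), c(1, 1, 1), intensity = 0)
  expect_true(all(out0$channel == 0))
})

test_that("sphere centred on a volume face is half-rendered and flagged", {
  gt <- data.table::data.table(z_um = 0, y_um = 20, x_um = 20, radius_um = 10)
  out <- rasterize_objects(gt, c(40L, 40L, 40L), c(1, 1, 1), intensity = 50)
  full <- 4 / 3 * pi * 10^3
  expect_equal(sum(out$channel > 0), full / 2, tolerance = 0.06)
  expect_true(out$truncated[1])
  # entirely outside -> warning + skip
  gt2 <- data.table::data.table(z_um = -30, y_um = 20, x_um = 20, radius_um = 5)
  expect_warning(out2 <- rasterize_objects(gt2, c(40L, 40L, 40L), c(1, 1, 1), 50),
                 "outside")
  expect_true(out2$skipped[1])
  expect_true(all(out2$channel == 0))
})

test_that("scenario presets carry the published composition", {
  wt <- scenario("WT")
  ko <- scenario("KO")
  p_wt <- attr(wt, "planted")
  p_ko <- attr(ko, "planted")
  expect_equal(p_wt$within_fraction, 38 / 229)   # targets 16.8%
  expect_equal(p_ko$within_fraction, 97 / 278)   # targets 35%
  expect_equal(p_wt$within_fraction, 0.168, tolerance = 0.015)
  expect_equal(p_ko$within_fraction, 0.350, tolerance = 0.005)
  expect_true(p_wt$gated >= 229 && p_ko$gated <= 278)
  # peripheral shares follow the published 73.7% / 26.1%
  expect_equal(unname(p_wt$counts["peripheral"] / sum(p_wt$counts)), 0.737,
               tolerance = 0.005)
  expect_equal(unname(p_ko$counts["peripheral"] / sum(p_ko$counts)), 0.261,
               tolerance = 0.005)
  expect_error(scenario("XX"), "unknown scenario")
})

test_that("planted summaries of generated scenarios match the presets", {
  spec <- scenario("KO", seed = 3L)
  ph <- generate_phantom(spec)
  ps <- planted_summary(ph$ground_truth)
  expect_identical(ps$n_gated, 278L)
  expect_equal(ps$within_fraction, 97 / 278)
})

test_that("Poisson noise is unbiased: seed-ensemble mean within 3 SE", {
  base <- phantom_spec(
    shape_voxels = c(16L, 16L, 16L), voxel_size_um = c(1, 1, 1),
    glomeruli = list(count = 0L), vessels = list(count = 0L),
    cells = list(count = 0L),
    deposits = list(fraction_of_glomeruli_with_deposits = 0),
    noise = list(background_level = 30, gaussian_sd = 0, poisson = TRUE)
  )
  n_seeds <- 150L
  acc <- array(0, dim = c(16, 16, 16))
  for (s in seq_len(n_seeds)) {
    sp <- base; sp$seed <- s
    acc <- acc + get_channel(generate_phantom(sp)$grid, "mhc2")
  }
  means <- acc / n_seeds
  se <- sqrt(30 / n_seeds)
  # per-voxel: ~99.7% inside 3 SE; allow the binomial wiggle
  expect_gte(mean(abs(means - 30) <= 3 * se), 0.985)
  # patch average much tighter
  expect_lt(abs(mean(means) - 30), 4 * se / sqrt(length(means)))
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(cells = list(population_fractions = c(0.5, 0.4, 0.2))),
               "sum to 1")
  expect_error(phantom_spec(glomeruli = list(count = -1L)), ">= 0")
  expect_error(phantom_spec(vessels = list(radius_um = -2)), "positive")
  expect_error(phantom_spec(cells = list(bogus = 1)), "unknown field")
  # impossible geometry errors with a placement report
  small <- phantom_spec(shape_voxels = c(8L, 8L, 8L), voxel_size_um = c(1, 1, 1),
                        glomeruli = list(count = 1L, radius_um = c(20, 0.1)))
  expect_error(generate_phantom(small), "too small|placement failed")
})
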