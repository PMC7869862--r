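# Gating, frequency reports, positional export, and the two group tests.

wide_fixture <- function() {
  data.table::data.table(
    object_id = 1:3,
    x_um = c(10, 20, 30), y_um = c(5, 6, 7),
    shortest_distance_um = c(-1, 10, 30),
    population = c("within", "surrounding", "peripheral"),
    volume_um3 = c(100, 110, 120)
  )
}

test_that("apply_gate filters by conjunction of conditions", {
  w <- wide_fixture()
  g <- gate("within", list(list(column = "population", equals = "within")))
  expect_identical(nrow(apply_gate(w, g)), 1L)
  # tautological gate = identity, stable order
  t_ <- gate("all", list(list(column = "shortest_distance_um", min = -Inf)))
  expect_identical(apply_gate(w, t_)$object_id, w$object_id)
  # contradictory gate -> empty, no error
  cg <- gate("none", list(list(column = "volume_um3", min = 1000)))
  expect_identical(nrow(apply_gate(w, cg)), 0L)
  expect_error(apply_gate(w, gate("bad", list(list(column = "nope", min = 0)))),
               "unknown column")
})

test_that("population_frequencies uses parent-gate (flow) semantics", {
  set.seed(2)
  w <- data.table::data.table(object_id = 1:100, v = c(rep(1, 35), rep(0, 65)))
  gates <- list(
    gate("parent", list(list(column = "object_id", min = 1))),
    gate("hit", list(list(column = "v", equals = 1)), parent = "parent")
  )
  fr <- population_frequencies(w, gates)
  expect_equal(fr[fr$gate == "hit"]$frequency_pct, 35)
  expect_equal(fr[fr$gate == "hit"]$count, 35L)
  # empty parent -> undefined marker, not 0
  gates2 <- list(
    gate("empty", list(list(column = "v", equals = 99))),
    gate("child", list(list(column = "v", min = 0)), parent = "empty")
  )
  fr2 <- population_frequencies(w, gates2)
  expect_true(is.na(fr2[fr2$gate == "child"]$frequency_pct))
  # cyclic tree is an error
  gates3 <- list(
    gate("a", list(), parent = "b"),
    gate("b", list(), parent = "a")
  )
  expect_error(population_frequencies(w, gates3), "cyclic")
})

test_that("exhaustive sibling gates conserve the parent count (property)", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    w <- data.table::data.table(object_id = seq_len(n),
                                d = runif(n, -5, 40))
    gates <- list(
      gate("gated", list(list(column = "d", max = 20))),
      gate("lo", list(list(column = "d", max = 0.5 - 1e-12)), parent = "gated"),
      gate("hi", list(list(column = "d", min = 0.5)), parent = "gated")
    )
    fr <- population_frequencies(w, gates)
    expect_identical(fr$count[fr$gate == "lo"] + fr$count[fr$gate == "hi"],
                     fr$count[fr$gate == "gated"])
    # invariance under row permutation
    fr2 <- population_frequencies(w[sample(n)], gates)
    expect_identical(fr2$count, fr$count)
  }
})

test_that("positional_export emits one row per object per matched gate", {
  w <- wide_fixture()
  g1 <- gate("all", list(list(column = "volume_um3", min = 0)))
  pos <- positional_export(w, list(g1))
  expect_identical(nrow(pos), 3L)
  expect_identical(names(pos), c("object_id", "x_um", "y_um", "gate"))
  # an object matching two sibling gates appears once per gate
  g2 <- gate("big", list(list(column = "volume_um3", min = 105)))
  pos2 <- positional_export(w, list(g1, g2))
  expect_identical(nrow(pos2), 5L)
  expect_identical(sum(pos2$object_id == 3L), 2L)
})

test_that("Mann-Whitney exact path matches enumeration and known cases", {
  res <- compare_volumes_mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_tailed, 0.100)
  expect_identical(res$method, "exact")
  # identical tied groups: no effect
  expect_gte(compare_volumes_mwu(c(5, 5, 5), c(5, 5, 5))$p_two_tailed, 0.99)
  expect_error(compare_volumes_mwu(numeric(), 1), "non-empty")

  # property: exact path equals an independent enumeration oracle and the
  # reference implementation, for random no-tie inputs with combined n <= 10
  set.seed(19)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1 + n2)  # distinct -> no ties
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    got <- compare_volumes_mwu(a, b)
    # oracle 1: direct enumeration of all group assignments, computing U
    # from scratch by pair counting
    pool <- c(a, b)
    combos <- utils::combn(length(pool), n1)
    u_of <- function(av, bv) sum(outer(av, bv, `>`))
    u_null <- apply(combos, 2, function(ix) u_of(pool[ix], pool[-ix]))
    u_obs <- u_of(a, b)
    p_oracle <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
    expect_equal(got$U, u_obs)
    expect_equal(got$p_two_tailed, p_oracle)
    # oracle 2: stats::wilcox.test exact two-sided p
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(got$p_two_tailed, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney has power against a planted shift (simulation)", {
  set.seed(23)
  hits <- 0L
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50) + 1.2
    p <- compare_volumes_mwu(a, b)$p_two_tailed
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of seeds
})

test_that("Welch's t follows the closed form", {
  res <- compare_means_welch(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p_two_tailed, 1)
  res2 <- compare_means_welch(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_lt(res2$p_two_tailed, 0.01)
  # minimal n = 2 vs 2 returns finite df
  res3 <- compare_means_welch(c(1, 2), c(5, 9))
  expect_true(is.finite(res3$df))
  expect_error(compare_means_welch(c(1, 1), c(2, 2)), "degenerate")
  expect_error(compare_means_welch(1, c(1, 2)), ">= 2")
  # oracle: stats::t.test on random inputs
  set.seed(29)
  for (rep in 1:10) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = 2)
    got <- compare_means_welch(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(got$t, unname(ref$statistic))
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p_two_tailed, ref$p.value)
  }
})
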