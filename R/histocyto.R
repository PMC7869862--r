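# Flow-style analysis of the wide object table: gate definitions,
# hierarchical frequency reports, positional exports for XY scatter
# visualization, and the two group-comparison tests used downstream
# (Mann-Whitney U, Welch's t).

#' Define a gate on the wide object table
#'
#' A gate is a named conjunction of per-column conditions: closed numeric
#' intervals (`min` / `max`, either open-ended) and/or categorical equality
#' (`equals`). Gates serialize to plain lists, so they round-trip through
#' the JSON pipeline config.
#'
#' @param name gate name.
#' @param conditions list of conditions, each a list with `column` and any
#'   of `min`, `max`, `equals`.
#' @param parent name of the parent gate (`NULL` = root population).
#' @return an object of class `vc_gate`.
#' @export
gate <- function(name, conditions = list(), parent = NULL) {
  for (cond in conditions) {
    if (is.null(cond$column)) stopf("every gate condition needs a column")
    if (is.null(cond$min) && is.null(cond$max) && is.null(cond$equals)) {
      stopf("condition on '%s' needs min, max or equals", cond$column)
    }
  }
  structure(list(name = name, conditions = conditions, parent = parent),
            class = "vc_gate")
}

#' Apply a gate to a wide table
#'
#' Returns the rows satisfying all of the gate's conditions, in their
#' original order. Interval bounds are inclusive; `NA` cells never match.
#'
#' @param wide wide `data.table`/data.frame.
#' @param g a [gate()].
#' @return the matching subset (same column layout).
#' @export
apply_gate <- function(wide, g) {
  stopifnot(inherits(g, "vc_gate"))
  wide <- data.table::as.data.table(wide)
  keep <- rep(TRUE, nrow(wide))
  for (cond in g$conditions) {
    if (!cond$column %in% names(wide)) {
      stopf("gate '%s' references unknown column '%s'", g$name, cond$column)
    }
    v <- wide[[cond$column]]
    ok <- !is.na(v)
    if (!is.null(cond$equals)) ok <- ok & v == cond$equals
    if (!is.null(cond$min)) ok <- ok & v >= cond$min
    if (!is.null(cond$max)) ok <- ok & v <= cond$max
    keep <- keep & ok
  }
  wide[keep]
}

#' Hierarchical gate frequencies
#'
#' Applies a gating tree to the wide table and reports, per gate, its
#' count and its frequency as a percentage of its parent gate (the root
#' parent is the full table) — flow-software semantics, which is what
#' turns a within-glomerulus count into "% of the <=20 µm gate".
#'
#' @param wide wide table.
#' @param gates list of [gate()]s; parents must precede children or at
#'   least form an acyclic tree rooted at `NULL`.
#' @return data.table: `gate`, `parent`, `count`, `frequency_pct`
#'   (`NA` when the parent gate is empty — undefined, not 0).
#' @export
population_frequencies <- function(wide, gates) {
  wide <- data.table::as.data.table(wide)
  names(gates) <- vapply(gates, function(g) g$name, "")
  # detect cycles / unknown parents while resolving memberships
  resolved <- list()
  resolving <- character()
  resolve <- function(name) {
    if (name %in% names(resolved)) return(resolved[[name]])
    if (name %in% resolving) stopf("cyclic gating tree at '%s'", name)
    resolving <<- c(resolving, name)
    g <- gates[[name]]
    if (is.null(g)) stopf("unknown gate '%s'", name)
    base <- if (is.null(g$parent)) wide else resolve(g$parent)
    out <- apply_gate(base, g)
    resolving <<- setdiff(resolving, name)
    resolved[[name]] <<- out
    out
  }
  rows <- lapply(gates, function(g) {
    sub <- resolve(g$name)
    parent_n <- if (is.null(g$parent)) nrow(wide) else nrow(resolve(g$parent))
    data.table::data.table(
      gate = g$name,
      parent = g$parent %||% NA_character_,
      count = nrow(sub),
      frequency_pct = if (parent_n > 0) 100 * nrow(sub) / parent_n else NA_real_
    )
  })
  data.table::rbindlist(rows)
}

#' Positional export of gated populations
#'
#' One row per object per matched gate (an object matching two sibling
#' gates appears once per gate), with physical XY centroid coordinates —
#' the table behind positioning scatter plots.
#'
#' @param wide wide table with `x_um` and `y_um` columns.
#' @param gates list of [gate()]s (flat; parents resolved as in
#'   [population_frequencies()]).
#' @return data.table: `object_id`, `x_um`, `y_um`, `gate`.
#' @export
positional_export <- function(wide, gates) {
  wide <- data.table::as.data.table(wide)
  if (!all(c("x_um", "y_um") %in% names(wide))) {
    stopf("wide table needs centroid columns x_um and y_um")
  }
  names(gates) <- vapply(gates, function(g) g$name, "")
  out <- lapply(gates, function(g) {
    base <- wide
    p <- g$parent
    seen <- character()
    while (!is.null(p)) {
      if (p %in% seen) stopf("cyclic gating tree at '%s'", p)
      seen <- c(seen, p)
      if (is.null(gates[[p]])) stopf("unknown gate '%s'", p)
      base <- apply_gate(base, gates[[p]])
      p <- gates[[p]]$parent
    }
    sub <- apply_gate(base, g)
    if (!nrow(sub)) return(NULL)
    data.table::data.table(object_id = sub$object_id, x_um = sub$x_um,
                           y_um = sub$y_um, gate = g$name)
  })
  data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p by enumeration of rank assignments for combined n <= 12 without
#' ties (two-tailed p doubles the smaller tail probability, capped at 1);
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list: `U` (statistic of group `a`), `p_two_tailed`, `method`.
#' @export
compare_volumes_mwu <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (N <= 12 && !ties) {
    # exact null distribution of U by enumeration of C(N, n1) assignments
    combos <- utils::combn(N, n1)
    ranks_all <- rank(pooled)  # no ties: a permutation of 1..N
    u_null <- colSums(matrix(sort(ranks_all)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_low <- mean(u_null <= U)
    p_high <- mean(u_null >= U)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(U = U, p_two_tailed = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab)
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U, p_two_tailed = 1, method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p_two_tailed = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Two-tailed Welch's t test
#'
#' Unpaired, unequal-variance t with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @return list: `t`, `df`, `p_two_tailed`.
#' @export
compare_means_welch <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  v1 <- var(a); v2 <- var(b)
  if (v1 == 0 && v2 == 0) stopf("degenerate: zero variance in both groups")
  se2 <- v1 / length(a) + v2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(a)^2 * (length(a) - 1)) +
                   v2^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p_two_tailed = 2 * pt(-abs(t), df))
}
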