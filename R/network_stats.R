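# Network-based statistics: edgewise two-sample t-scores, suprathreshold
# components, permutation null of the largest-component extent, and
# threshold sweeps.
#
# Internally a cohort contrast is held as an edges x subjects matrix so
# the permutation null is computed with two matrix products per block of
# permutations (group sums and sums of squares), not per-edge loops.

# Stack a list of conn_matrix into an edges x subjects matrix over the
# shared scaffold (upper-triangle order).
edge_value_matrix <- function(matrices, scaffold) {
  sel <- which(ut_values(scaffold))
  W <- vapply(matrices, function(m) ut_values(unclass(m))[sel],
              numeric(length(sel)))
  # vapply drops to a vector when the scaffold has a single edge
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  W
}

contrast_data <- function(groupA, groupB) {
  groupA <- unname(groupA); groupB <- unname(groupB)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least 2 subjects")
  scaffold <- check_shared_scaffold(c(groupA, groupB))
  W <- edge_value_matrix(c(groupA, groupB), scaffold)
  list(W = W, nA = length(groupA), nB = length(groupB),
       scaffold = scaffold, n_nodes = nrow(scaffold))
}

# Pooled-variance two-sample t for every edge (rows of W), for one or
# many group-A membership indicators (columns of P).  Degenerate edges
# (zero pooled variance) score 0.
pooled_t <- function(W, W2, P, nA, nB) {
  SA <- W %*% P
  QA <- W2 %*% P
  S <- rowSums(W); Q <- rowSums(W2)
  SB <- S - SA; QB <- Q - QA
  mA <- SA / nA; mB <- SB / nB
  ssA <- pmax(QA - SA^2 / nA, 0)
  ssB <- pmax(QB - SB^2 / nB, 0)
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0] <- 0
  t
}

orient_sign <- function(tail = c("A_less_B", "A_greater_B")) {
  tail <- match.arg(tail)
  if (tail == "A_less_B") -1 else 1
}

#' Edgewise two-sample t-scores
#'
#' Pooled-variance (Student) t statistics comparing each scaffold edge
#' between two groups, oriented so that positive values indicate
#' alteration in the stated tail direction: with `tail = "A_less_B"`
#' (e.g. FA reduction in patients relative to controls with group A the
#' patients) an edge where group A is lower scores positive.  Edges with
#' zero pooled variance score 0 with a warning.
#'
#' @param groupA,groupB Lists of `conn_matrix` sharing one scaffold.
#' @param tail `"A_less_B"` or `"A_greater_B"`.
#' @return An `edge_stats` object: list with `t` (symmetric matrix,
#'   zero off scaffold), `scaffold`, `nA`, `nB`, `tail`.
#' @export
edge_t_scores <- function(groupA, groupB, tail = c("A_less_B", "A_greater_B")) {
  tail <- match.arg(tail)
  cd <- contrast_data(groupA, groupB)
  P <- matrix(c(rep(1, cd$nA), rep(0, cd$nB)), ncol = 1L)
  t_raw <- pooled_t(cd$W, cd$W^2, P, cd$nA, cd$nB)[, 1L]
  WA <- cd$W[, seq_len(cd$nA), drop = FALSE]
  WB <- cd$W[, cd$nA + seq_len(cd$nB), drop = FALSE]
  ss <- rowSums((WA - rowMeans(WA))^2) + rowSums((WB - rowMeans(WB))^2)
  if (any(ss == 0))
    warning(sum(ss == 0),
            " degenerate edge(s) with zero pooled variance scored t = 0")
  t_or <- orient_sign(tail) * t_raw
  tm <- matrix(0, cd$n_nodes, cd$n_nodes)
  tm[upper_tri_idx(cd$n_nodes)[which(ut_values(cd$scaffold))]] <- t_or
  structure(list(t = tm + t(tm), scaffold = cd$scaffold,
                 nA = cd$nA, nB = cd$nB, tail = tail),
            class = "edge_stats")
}

#' Suprathreshold edges
#'
#' Scaffold edges whose oriented t-score strictly exceeds the threshold.
#'
#' @param stats An `edge_stats` object.
#' @param t_threshold Positive threshold on the oriented t-score.
#' @return Two-column integer matrix of node pairs (i < j), with the
#'   surviving t-scores as attribute `"t"`.
#' @export
suprathreshold_edges <- function(stats, t_threshold) {
  if (t_threshold <= 0) stop("t_threshold must be positive")
  n <- nrow(stats$t)
  ut <- upper_tri_idx(n)
  keep <- ut[ut_values(stats$scaffold) & ut_values(stats$t) > t_threshold]
  pairs <- idx_to_pairs(keep, n)
  attr(pairs, "t") <- stats$t[keep]
  pairs
}

# Union-find largest component over an edge list; returns maximum edge
# count per connected component (ties resolved later).  `ei`, `ej` are
# integer endpoint vectors.
component_edge_counts <- function(ei, ej, n_nodes) {
  parent <- seq_len(n_nodes)
  m <- length(ei)
  for (k in seq_len(m)) {
    a <- ei[k]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- ej[k]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[a] <- b
  }
  root <- parent
  repeat {
    r2 <- root[root]
    if (identical(r2, root)) break
    root <- r2
  }
  list(edge_comp = root[ei], counts = tabulate(root[ei], n_nodes))
}

#' Largest connected component of an edge set
#'
#' Components are formed through shared nodes; the component maximizing
#' the number of edges is returned, and its edge count is the "extent of
#' alteration".  Equal-sized components are tie-broken by the smallest
#' member node index.  An empty edge set has extent 0.
#'
#' @param edges Two-column integer matrix of node pairs.
#' @param n_nodes Number of nodes in the graph.
#' @return List with `edges` (the component's edge rows) and `extent`.
#' @export
largest_component_extent <- function(edges, n_nodes = 90L) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L)
    return(list(edges = edges, extent = 0L))
  cc <- component_edge_counts(edges[, 1L], edges[, 2L], n_nodes)
  best <- max(cc$counts)
  cand <- which(cc$counts == best)
  if (length(cand) > 1L) {
    minnode <- vapply(cand, function(co)
      min(edges[cc$edge_comp == co, ]), numeric(1))
    cand <- cand[which.min(minnode)]
  }
  sel <- cc$edge_comp == cand[1L]
  list(edges = edges[sel, , drop = FALSE], extent = sum(sel))
}

# Max-component extent straight from suprathreshold entries of an
# oriented t vector (scaffold edge order); used in the permutation loop.
extent_from_t <- function(t_vec, pair_i, pair_j, thr, n_nodes) {
  keep <- t_vec > thr
  if (!any(keep)) return(0L)
  max(component_edge_counts(pair_i[keep], pair_j[keep], n_nodes)$counts)
}

# Permutation group-A indicator matrix: columns are 0/1 vectors with nA
# ones.  `exact = TRUE` enumerates all choose(n, nA) assignments.
permutation_indicators <- function(n, nA, n_permutations, seed, exact = FALSE) {
  if (exact) {
    sets <- combn(n, nA)
    P <- matrix(0, n, ncol(sets))
    P[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = nA))] <- 1
    return(P)
  }
  with_seed(derive_seed(seed, 6L), {
    P <- matrix(0, n, n_permutations)
    for (b in seq_len(n_permutations))
      P[sample.int(n, nA), b] <- 1
    P
  })
}

#' Network-based statistics permutation test
#'
#' Computes the observed suprathreshold largest-component extent, then
#' permutes the group labels (group sizes preserved) and records the
#' maximal component extent of each permutation as the null
#' distribution.  The p-value uses the add-the-observed convention
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`, so it is
#' never exactly 0.  With `exact = TRUE` all label assignments are
#' enumerated instead and `p` is the exact proportion of assignments
#' with extent at least the observed one.
#'
#' @inheritParams edge_t_scores
#' @param t_threshold Positive t-score threshold.
#' @param n_permutations Number of random permutations (>= 1).
#' @param seed Integer seed making the permutation stream reproducible.
#' @param exact Enumerate all label assignments (feasible for small
#'   groups only).
#' @param block Permutations processed per matrix-product block.
#' @return An `nbs_result`: list with `t_threshold`, `component_edges`,
#'   `extent`, `p_value`, `null_extents`, `tail`, `seed`.
#' @export
nbs_test <- function(groupA, groupB, tail = c("A_less_B", "A_greater_B"),
                     t_threshold = 3, n_permutations = 5000L, seed = 1L,
                     exact = FALSE, block = 1000L) {
  tail <- match.arg(tail)
  if (!exact && n_permutations < 1L) stop("n_permutations must be >= 1")
  if (t_threshold <= 0) stop("t_threshold must be positive")
  cd <- contrast_data(groupA, groupB)
  W2 <- cd$W^2
  n <- cd$nA + cd$nB
  sgn <- orient_sign(tail)
  pairs <- idx_to_pairs(upper_tri_idx(cd$n_nodes), cd$n_nodes)
  pairs <- pairs[ut_values(cd$scaffold), , drop = FALSE]

  obs_t <- sgn * pooled_t(cd$W, W2, matrix(c(rep(1, cd$nA), rep(0, cd$nB))),
                          cd$nA, cd$nB)[, 1L]
  obs_keep <- obs_t > t_threshold
  obs <- largest_component_extent(pairs[obs_keep, , drop = FALSE], cd$n_nodes)

  P <- permutation_indicators(n, cd$nA, n_permutations, seed, exact)
  nb <- ncol(P)
  null_extents <- integer(nb)
  for (start in seq(1L, nb, by = block)) {
    cols <- start:min(start + block - 1L, nb)
    Tb <- sgn * pooled_t(cd$W, W2, P[, cols, drop = FALSE], cd$nA, cd$nB)
    for (k in seq_along(cols))
      null_extents[cols[k]] <- extent_from_t(Tb[, k], pairs[, 1L], pairs[, 2L],
                                             t_threshold, cd$n_nodes)
  }
  p <- if (exact) mean(null_extents >= obs$extent)
       else (1 + sum(null_extents >= obs$extent)) / (nb + 1)
  if (obs$extent == 0L) p <- 1
  structure(list(t_threshold = t_threshold, component_edges = obs$edges,
                 extent = obs$extent, p_value = p,
                 null_extents = null_extents, tail = tail,
                 nA = cd$nA, nB = cd$nB, seed = seed, exact = exact),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf(paste0("<nbs_result> t > %.2f: extent %d edges, p = %.4g ",
                     "(%d %s permutations, tail %s)\n"),
              x$t_threshold, x$extent, x$p_value, length(x$null_extents),
              if (x$exact) "exhaustive" else "random", x$tail))
  invisible(x)
}

#' Threshold sweep of the NBS analysis
#'
#' Repeats the suprathreshold-component analysis over a grid of
#' t-thresholds (default 0.05 to 5 in steps of 0.05), sharing one set of
#' permutations across the grid.  The observed extent is a non-
#' increasing step function of the threshold.  `n_permutations = 0`
#' skips the permutation null (extents only, `p = NA`), which is useful
#' for extent-ordering comparisons.
#'
#' @inheritParams nbs_test
#' @param grid Ascending grid of positive t-thresholds.
#' @return A `sweep_curve` data frame with columns `threshold`, `extent`,
#'   `p_value`.
#' @export
threshold_sweep <- function(groupA, groupB, tail = c("A_less_B", "A_greater_B"),
                            grid = seq(0.05, 5, by = 0.05),
                            n_permutations = 5000L, seed = 1L,
                            block = 500L) {
  tail <- match.arg(tail)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE) || any(grid <= 0))
    stop("grid must be a nonempty ascending grid of positive thresholds")
  cd <- contrast_data(groupA, groupB)
  W2 <- cd$W^2
  sgn <- orient_sign(tail)
  pairs <- idx_to_pairs(upper_tri_idx(cd$n_nodes), cd$n_nodes)
  pairs <- pairs[ut_values(cd$scaffold), , drop = FALSE]
  obs_t <- sgn * pooled_t(cd$W, W2, matrix(c(rep(1, cd$nA), rep(0, cd$nB))),
                          cd$nA, cd$nB)[, 1L]
  extents <- vapply(grid, function(thr)
    extent_from_t(obs_t, pairs[, 1L], pairs[, 2L], thr, cd$n_nodes), 0L)
  if (n_permutations >= 1L) {
    P <- permutation_indicators(cd$nA + cd$nB, cd$nA, n_permutations, seed)
    exceed <- matrix(0L, length(grid), n_permutations)
    for (start in seq(1L, n_permutations, by = block)) {
      cols <- start:min(start + block - 1L, n_permutations)
      Tb <- sgn * pooled_t(cd$W, W2, P[, cols, drop = FALSE], cd$nA, cd$nB)
      for (k in seq_along(cols))
        exceed[, cols[k]] <- vapply(grid, function(thr)
          extent_from_t(Tb[, k], pairs[, 1L], pairs[, 2L], thr, cd$n_nodes), 0L)
    }
    p <- vapply(seq_along(grid), function(g)
      (1 + sum(exceed[g, ] >= extents[g])) / (n_permutations + 1), numeric(1))
    p[extents == 0L] <- 1
  } else {
    p <- rep(NA_real_, length(grid))
  }
  structure(data.frame(threshold = grid, extent = extents, p_value = p),
            class = c("sweep_curve", "data.frame"), tail = tail, seed = seed)
}
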