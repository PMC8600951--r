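# Per-subject normative z-scoring of connections against control
# distributions, abnormal-edge and abnormal-node identification,
# abnormality load at whole-brain / lobe / region resolution, and
# selection of the most discriminatory threshold pair.

#' Fit per-edge control distributions
#'
#' For every scaffold edge the sample mean and sample standard deviation
#' (n - 1 denominator) of the control weights.  Edges with zero SD are
#' flagged degenerate; downstream z-scores there are set to 0 with a
#' warning.
#'
#' @param controls List of `conn_matrix` (>= 3) sharing one scaffold.
#' @return A `control_dists` object: list with `mean` and `sd`
#'   (symmetric matrices, zero off scaffold), `scaffold`, `n_controls`,
#'   `degenerate` (logical matrix).
#' @export
fit_control_distributions <- function(controls) {
  if (length(controls) < 3L) stop("need at least 3 controls")
  scaffold <- check_shared_scaffold(controls)
  W <- edge_value_matrix(controls, scaffold)
  n <- length(controls)
  mu <- rowMeans(W)
  sdv <- sqrt(rowSums((W - mu)^2) / (n - 1))
  degenerate <- sdv == 0
  if (any(degenerate))
    warning(sum(degenerate), " scaffold edge(s) have zero control SD")
  n_nodes <- nrow(scaffold)
  sel <- upper_tri_idx(n_nodes)[which(ut_values(scaffold))]
  mk <- function(v) { m <- matrix(0, n_nodes, n_nodes); m[sel] <- v; m + t(m) }
  dg <- matrix(FALSE, n_nodes, n_nodes); dg[sel] <- degenerate
  structure(list(mean = mk(mu), sd = mk(sdv), scaffold = scaffold,
                 n_controls = n, degenerate = dg | t(dg)),
            class = "control_dists")
}

zscore_from_parts <- function(w_ut, mu_ut, sd_ut, degen_ut, scaffold,
                              subject_id, loo) {
  z <- (w_ut - mu_ut) / sd_ut
  z[degen_ut] <- 0
  n_nodes <- nrow(scaffold)
  sel <- upper_tri_idx(n_nodes)[which(ut_values(scaffold))]
  zm <- matrix(0, n_nodes, n_nodes)
  zm[sel] <- z
  structure(zm + t(zm), subject_id = subject_id, loo = loo,
            scaffold = scaffold, class = c("zscore_matrix", "matrix", "array"))
}

#' z-score a subject against control distributions
#'
#' `z_ij = (w_ij - mean_ij) / sd_ij` on every scaffold edge, i.e. the
#' number of control standard deviations the subject's connection lies
#' from the control mean.
#'
#' @param m A `conn_matrix` on the same scaffold as `dists`.
#' @param dists A `control_dists` from [fit_control_distributions()].
#' @return A `zscore_matrix` (symmetric, zero diagonal and off
#'   scaffold).
#' @export
zscore_subject <- function(m, dists) {
  if (!identical(scaffold_of(m), dists$scaffold))
    stop("subject ", attr(m, "subject_id"),
         ": scaffold differs from control scaffold")
  sel <- which(ut_values(dists$scaffold))
  if (any(ut_values(dists$degenerate)[sel]))
    warning("z set to 0 on degenerate edges for subject ",
            attr(m, "subject_id"))
  zscore_from_parts(ut_values(unclass(m))[sel], ut_values(dists$mean)[sel],
                    ut_values(dists$sd)[sel],
                    ut_values(dists$degenerate)[sel], dists$scaffold,
                    attr(m, "subject_id"), loo = FALSE)
}

#' Leave-one-out z-scores for controls
#'
#' Each control is z-scored against distributions fitted on the
#' remaining n - 1 controls, so controls are never compared to
#' themselves.
#'
#' @param controls List of `conn_matrix` (>= 4) sharing one scaffold.
#' @return List of `zscore_matrix`, one per control.
#' @export
zscore_controls_loo <- function(controls) {
  if (length(controls) < 4L) stop("need at least 4 controls for leave-one-out")
  scaffold <- check_shared_scaffold(controls)
  W <- edge_value_matrix(controls, scaffold)
  n <- ncol(W)
  S <- rowSums(W); Q <- rowSums(W^2)
  lapply(seq_len(n), function(s) {
    w <- W[, s]
    mu <- (S - w) / (n - 1)
    ss <- pmax(Q - w^2 - (S - w)^2 / (n - 1), 0)
    sdv <- sqrt(ss / (n - 2))
    degen <- sdv == 0
    if (any(degen))
      warning("z set to 0 on ", sum(degen), " degenerate edge(s) for control ",
              attr(controls[[s]], "subject_id"))
    zscore_from_parts(w, mu, sdv, degen, scaffold,
                      attr(controls[[s]], "subject_id"), loo = TRUE)
  })
}

#' Abnormal-edge mask
#'
#' Scaffold edges whose z-score exceeds the threshold: `|z| >
#' z_threshold` for `two_sided` (default), signed comparisons for
#' `decrease_only` (`z < -z_threshold`) and `increase_only`.
#' Inequalities are strict.
#'
#' @param z A `zscore_matrix`.
#' @param z_threshold Positive threshold (the study grid is 1.5 to 3.5
#'   in steps of 0.1).
#' @param direction `"two_sided"`, `"decrease_only"`, or
#'   `"increase_only"`.
#' @return Symmetric logical matrix of abnormal edges.
#' @export
abnormal_edge_mask <- function(z, z_threshold,
                               direction = c("two_sided", "decrease_only",
                                             "increase_only")) {
  direction <- match.arg(direction)
  if (z_threshold <= 0) stop("z_threshold must be positive")
  zm <- unclass(z)
  mask <- switch(direction,
                 two_sided = abs(zm) > z_threshold,
                 decrease_only = zm < -z_threshold,
                 increase_only = zm > z_threshold)
  mask & attr(z, "scaffold")
}

#' Node abnormality profile
#'
#' Per node, the ratio of abnormal connections to the node's total
#' number of scaffold connections (the degree of the non-binarized
#' z-score network, identical across subjects under the constant-density
#' scaffold).  Isolated nodes (scaffold degree 0) get ratio 0 with a
#' warning.
#'
#' @param mask Logical abnormal-edge matrix from [abnormal_edge_mask()]
#'   (must be a subset of the scaffold).
#' @param z The `zscore_matrix` the mask was derived from.
#' @param z_threshold Threshold recorded in the profile.
#' @param direction Exceedance rule recorded in the profile.
#' @return A `node_profile`: list with `subject_id`, `z_threshold`,
#'   `direction`, `ratio` (length-n, in `[0, 1]`), `degree`
#'   (scaffold degree).
#' @export
node_abnormality <- function(mask, z, z_threshold = NA_real_,
                             direction = "two_sided") {
  scaffold <- attr(z, "scaffold")
  if (any(mask & !scaffold)) stop("mask contains edges off the scaffold")
  degree <- rowSums(scaffold)
  abnormal <- rowSums(mask)
  if (any(degree == 0))
    warning("isolated node(s) assigned node abnormality 0")
  ratio <- ifelse(degree > 0, abnormal / degree, 0)
  structure(list(subject_id = attr(z, "subject_id"),
                 z_threshold = z_threshold, direction = direction,
                 ratio = ratio, degree = degree),
            class = "node_profile")
}

# One-call profile for a subject's z matrix at a given threshold.
profile_at <- function(z, z_threshold, direction = "two_sided") {
  node_abnormality(abnormal_edge_mask(z, z_threshold, direction), z,
                   z_threshold, direction)
}

#' Abnormality load
#'
#' Number of nodes in a region set whose node abnormality strictly
#' exceeds the node-abnormality threshold (the study grid is 0.01 to
#' 0.20 in steps of 0.01).  Region sets are `"whole_brain"`, a lobe
#' (`"temporal"`, ...), or a hemisphere-tagged lobe
#' (`"temporal_left"`, ...); lobewise loads over the six lobes sum to
#' the whole-brain load.
#'
#' @param profile A `node_profile`.
#' @param node_abnormality_threshold Required proportion of abnormal
#'   connections, in (0, 1).
#' @param region_set Region-set name (see [region_sets()]).
#' @param atlas Atlas defining the region sets.
#' @return Integer load with attributes recording the thresholds and
#'   region set.
#' @export
abnormality_load <- function(profile, node_abnormality_threshold,
                             region_set = "whole_brain",
                             atlas = aal90_atlas()) {
  if (node_abnormality_threshold <= 0 || node_abnormality_threshold >= 1)
    stop("node_abnormality_threshold must lie in (0, 1)")
  idx <- region_set_indices(region_set, atlas)
  load <- sum(profile$ratio[idx] > node_abnormality_threshold)
  structure(as.integer(load), z_threshold = profile$z_threshold,
            node_abnormality_threshold = node_abnormality_threshold,
            region_set = region_set)
}

#' Whole-brain abnormality-load grid
#'
#' Evaluates the abnormality load of every subject at every pair of
#' z-score and node-abnormality thresholds.
#'
#' @param zscores List of `zscore_matrix` (one per subject).
#' @param z_grid Ascending grid of z-score thresholds.
#' @param ratio_grid Ascending grid of node-abnormality thresholds.
#' @param atlas Atlas.
#' @param region_set Region set to count within.
#' @param direction Exceedance rule passed to [abnormal_edge_mask()].
#' @return Long data frame: `subject_id`, `z_threshold`,
#'   `ratio_threshold`, `load`.
#' @export
abnormality_load_grid <- function(zscores, z_grid = seq(1.5, 3.5, by = 0.1),
                                  ratio_grid = seq(0.01, 0.20, by = 0.01),
                                  atlas = aal90_atlas(),
                                  region_set = "whole_brain",
                                  direction = "two_sided") {
  idx <- region_set_indices(region_set, atlas)
  out <- lapply(zscores, function(z) {
    scaffold <- attr(z, "scaffold")
    degree <- rowSums(scaffold)
    sel <- which(ut_values(scaffold))
    zv <- abs(ut_values(unclass(z))[sel])
    if (direction == "decrease_only") zv <- -ut_values(unclass(z))[sel]
    if (direction == "increase_only") zv <- ut_values(unclass(z))[sel]
    pairs <- idx_to_pairs(upper_tri_idx(nrow(scaffold))[sel], nrow(scaffold))
    # node x z-threshold abnormal-edge counts via incidence accumulation
    counts <- vapply(z_grid, function(thr) {
      keep <- zv > thr
      tabulate(c(pairs[keep, 1L], pairs[keep, 2L]), nrow(scaffold))
    }, numeric(nrow(scaffold)))
    ratio <- counts / ifelse(degree > 0, degree, 1)
    loads <- vapply(ratio_grid, function(a)
      colSums(ratio[idx, , drop = FALSE] > a), numeric(length(z_grid)))
    data.frame(subject_id = attr(z, "subject_id"),
               z_threshold = rep(z_grid, times = length(ratio_grid)),
               ratio_threshold = rep(ratio_grid, each = length(z_grid)),
               load = as.integer(loads))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select the most discriminatory threshold pair
#'
#' Over the full grid of z-score and node-abnormality thresholds, finds
#' the pair maximizing the absolute Cohen's d between the two groups'
#' whole-brain abnormality loads.  Ties are broken towards the smaller
#' z threshold, then the smaller node-abnormality threshold.
#'
#' @param zscoresA,zscoresB Lists of `zscore_matrix` for the two groups
#'   (e.g. FBTCS+ and FBTCS- patients).
#' @inheritParams abnormality_load_grid
#' @return List with `z_threshold`, `ratio_threshold`, `cohen_d`
#'   (signed, A minus B at the selected pair), and the full `grid` data
#'   frame of d values.
#' @export
select_threshold_pair <- function(zscoresA, zscoresB,
                                  z_grid = seq(1.5, 3.5, by = 0.1),
                                  ratio_grid = seq(0.01, 0.20, by = 0.01),
                                  atlas = aal90_atlas(),
                                  direction = "two_sided") {
  gA <- abnormality_load_grid(zscoresA, z_grid, ratio_grid, atlas,
                              direction = direction)
  gB <- abnormality_load_grid(zscoresB, z_grid, ratio_grid, atlas,
                              direction = direction)
  if (all(gA$load == 0L) && all(gB$load == 0L))
    stop("abnormality loads are zero over the whole grid; nothing to select")
  pairs <- unique(gA[, c("z_threshold", "ratio_threshold")])
  d <- mapply(function(zt, at) {
    a <- gA$load[gA$z_threshold == zt & gA$ratio_threshold == at]
    b <- gB$load[gB$z_threshold == zt & gB$ratio_threshold == at]
    if (var(a) + var(b) == 0) {
      # constant loads: no spread, effect is 0 or infinite separation
      if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    } else cohen_d(a, b)
  }, pairs$z_threshold, pairs$ratio_threshold)
  grid <- cbind(pairs, cohen_d = d)
  ord <- order(-abs(grid$cohen_d), grid$z_threshold, grid$ratio_threshold)
  best <- grid[ord[1L], ]
  list(z_threshold = best$z_threshold, ratio_threshold = best$ratio_threshold,
       cohen_d = best$cohen_d, grid = grid)
}

#' Region-wise group comparison of node abnormality
#'
#' Compares the per-node abnormality ratio between two groups of
#' profiles (already expressed in a common ipsilateral/contralateral
#' frame), one rank-sum test per region with Benjamini-Hochberg false
#' discovery rate correction applied jointly across all regions.
#'
#' @param profilesA,profilesB Lists of `node_profile` (>= 3 subjects per
#'   group), computed at a common z-threshold (the study uses 2.5).
#' @param atlas Atlas for region names and lobes.
#' @param direction Tail of the rank-sum test: `"greater"` tests A > B.
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data frame with one row per region: `roi`, `lobe`,
#'   `mean_A`, `mean_B`, `mean_diff`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
roiwise_comparison <- function(profilesA, profilesB, atlas = aal90_atlas(),
                               direction = c("greater", "less"),
                               alpha = 0.05) {
  direction <- match.arg(direction)
  if (length(profilesA) < 3L || length(profilesB) < 3L)
    stop("need at least 3 subjects per group")
  RA <- vapply(profilesA, `[[`, numeric(nrow(atlas)), "ratio")
  RB <- vapply(profilesB, `[[`, numeric(nrow(atlas)), "ratio")
  p <- vapply(seq_len(nrow(atlas)), function(i)
    rank_sum_one_tailed(RA[i, ], RB[i, ], direction)$p_value, numeric(1))
  adj <- bh_fdr(p)
  data.frame(roi = atlas$roi, lobe = atlas$lobe,
             mean_A = rowMeans(RA), mean_B = rowMeans(RB),
             mean_diff = rowMeans(RA) - rowMeans(RB),
             p_value = p, p_adjusted = adj,
             significant = adj < alpha)
}
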