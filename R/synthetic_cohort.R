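# Synthetic connectome-cohort generator: a shared binary scaffold,
# per-edge Gaussian control distributions, and patient groups whose
# edge weights are reduced (FA) or increased (MD) on a targeted edge
# set, with ground truth returned for recovery tests.

#' Generator configuration
#'
#' Defaults mirror the cohort structure of a single-centre temporal lobe
#' epilepsy study: 29 controls, 23 patients with localized alterations
#' (FBTCS- analogue) and 60 with widespread alterations (FBTCS+
#' analogue), a shared scaffold at 25% density, and per-edge FA control
#' distributions with means drawn once per edge from `edge_mean_range`
#' and common standard deviation `edge_sd`.
#'
#' @param n_controls,n_patients_localized,n_patients_widespread Group
#'   sizes (each at least 2).
#' @param scaffold_density Fraction of the 4005 possible edges present,
#'   in (0, 1]; must allow a connected graph on 90 nodes.
#' @param edge_mean_range Interval within `[0, 1]` from which per-edge
#'   FA means are drawn.
#' @param edge_sd Per-edge standard deviation of control weights (> 0).
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the configuration including the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_controls = 29L,
                             n_patients_localized = 23L,
                             n_patients_widespread = 60L,
                             scaffold_density = 0.25,
                             edge_mean_range = c(0.2, 0.6),
                             edge_sd = 0.04,
                             seed = 1L) {
  cfg <- list(n_controls = as.integer(n_controls),
              n_patients_localized = as.integer(n_patients_localized),
              n_patients_widespread = as.integer(n_patients_widespread),
              scaffold_density = scaffold_density,
              edge_mean_range = edge_mean_range,
              edge_sd = edge_sd,
              seed = as.integer(seed))
  if (any(c(cfg$n_controls, cfg$n_patients_localized,
            cfg$n_patients_widespread) < 2L))
    stop("group sizes must be at least 2")
  if (scaffold_density <= 0 || scaffold_density > 1)
    stop("scaffold_density must lie in (0, 1]")
  if (round(scaffold_density * 4005) < 89)
    stop("scaffold_density too low to connect 90 nodes")
  if (edge_sd <= 0) stop("edge_sd must be positive")
  if (length(edge_mean_range) != 2L || edge_mean_range[1] > edge_mean_range[2] ||
      edge_mean_range[1] < 0 || edge_mean_range[2] > 1)
    stop("edge_mean_range must be an ordered interval within [0, 1]")
  class(cfg) <- "generator_config"
  cfg
}

#' Alteration specification for a synthetic patient group
#'
#' @param target_nodes ROI indices in which alterations are seeded.
#' @param affected_edge_fraction Fraction (0, 1] of scaffold edges
#'   incident to `target_nodes` that are altered; edges with both
#'   endpoints in the target set are altered first.
#' @param effect_size_sd Mean shift of altered edges in units of the
#'   control SD; positive values reduce FA (and increase MD).
#' @param bilateral Flag recording whether the target set spans both
#'   hemispheres (informational).
#' @return An `alteration_spec` list.
#' @export
alteration_spec <- function(target_nodes, affected_edge_fraction = 0.5,
                            effect_size_sd = 1.5, bilateral = FALSE) {
  target_nodes <- sort(unique(as.integer(target_nodes)))
  if (length(target_nodes) == 0L) stop("target_nodes must be nonempty")
  if (affected_edge_fraction <= 0 || affected_edge_fraction > 1)
    stop("affected_edge_fraction must lie in (0, 1]")
  if (effect_size_sd < 0) stop("effect_size_sd must be nonnegative")
  structure(list(target_nodes = target_nodes,
                 affected_edge_fraction = affected_edge_fraction,
                 effect_size_sd = effect_size_sd,
                 bilateral = isTRUE(bilateral)),
            class = "alteration_spec")
}

#' Localized-alteration preset (FBTCS- analogue)
#'
#' Targets the left temporal lobe plus a small left inferior-frontal /
#' opercular set, mimicking alterations confined to the neighbourhood of
#' a left temporal seizure focus.
#'
#' @param atlas Atlas (default [aal90_atlas()]).
#' @param effect_size_sd Injected effect size in control-SD units.
#' @return An `alteration_spec`.
#' @export
preset_localized <- function(atlas = aal90_atlas(), effect_size_sd = 1.5) {
  temporal_left <- which(atlas$lobe == "temporal" & atlas$hemisphere == "left")
  frontal_sub <- which(atlas$roi %in% c("Frontal_Inf_Oper_L",
                                        "Frontal_Inf_Tri_L",
                                        "Frontal_Inf_Orb_L",
                                        "Rolandic_Oper_L"))
  alteration_spec(c(temporal_left, frontal_sub),
                  affected_edge_fraction = 0.5,
                  effect_size_sd = effect_size_sd, bilateral = FALSE)
}

#' Widespread-alteration preset (FBTCS+ analogue)
#'
#' Targets temporal, subcortical and parietal regions in both
#' hemispheres, mimicking the bilateral widespread alterations seen with
#' secondarily generalizing seizures.
#'
#' @inheritParams preset_localized
#' @return An `alteration_spec`.
#' @export
preset_widespread <- function(atlas = aal90_atlas(), effect_size_sd = 1.5) {
  target <- which(atlas$lobe %in% c("temporal", "subcortical", "parietal"))
  alteration_spec(target, affected_edge_fraction = 0.5,
                  effect_size_sd = effect_size_sd, bilateral = TRUE)
}

#' Generate a shared binary scaffold
#'
#' A connected random graph on the atlas nodes with edge count
#' `round(density * n(n-1)/2)`: a random spanning tree plus uniformly
#' sampled extra edges.  Deterministic given the config seed.
#'
#' @param config A `generator_config`.
#' @param atlas Atlas giving the node count.
#' @return Symmetric logical matrix (the scaffold).
#' @export
make_scaffold <- function(config, atlas = aal90_atlas()) {
  n <- nrow(atlas)
  n_target <- round(config$scaffold_density * n * (n - 1) / 2)
  if (n_target < n - 1) stop("density too low to connect ", n, " nodes")
  with_seed(derive_seed(config$seed, 1L), {
    order <- sample.int(n)
    # random recursive tree over a shuffled node order
    parents <- vapply(2:n, function(k) order[sample.int(k - 1L, 1L)], 1L)
    tree <- cbind(pmin(order[2:n], parents), pmax(order[2:n], parents))
    tree_idx <- pairs_to_idx(tree, n)
    all_idx <- upper_tri_idx(n)
    rest <- setdiff(all_idx, tree_idx)
    extra <- if (n_target - length(tree_idx) > 0)
      sample(rest, n_target - length(tree_idx)) else integer(0)
    keep <- c(tree_idx, extra)
  })
  sc <- matrix(FALSE, n, n)
  sc[keep] <- TRUE
  sc | t(sc)
}

# Per-edge control distribution parameters on a scaffold.
control_params <- function(config, scaffold) {
  ut <- ut_values(scaffold)
  n_edges <- sum(ut)
  mu <- with_seed(derive_seed(config$seed, 2L),
                  runif(n_edges, config$edge_mean_range[1],
                        config$edge_mean_range[2]))
  list(mu = mu, sigma = rep(config$edge_sd, n_edges),
       edge_mask = ut, n_nodes = nrow(scaffold))
}

# Draw edge weights ~ Normal(mu, sigma) truncated to (0, 1] by
# resampling; vectorized over edges x subjects.
draw_truncated <- function(mu, sigma, n_subj) {
  n_edges <- length(mu)
  w <- matrix(rnorm(n_edges * n_subj, mu, sigma), n_edges, n_subj)
  bad <- which(w <= 0 | w > 1)
  while (length(bad)) {
    w[bad] <- rnorm(length(bad), mu[(bad - 1L) %% n_edges + 1L],
                    sigma[(bad - 1L) %% n_edges + 1L])
    bad <- bad[w[bad] <= 0 | w[bad] > 1]
  }
  w
}

edge_matrix_to_conn <- function(w, scaffold, ids, modality) {
  n <- nrow(scaffold)
  ut <- upper_tri_idx(n)
  sel <- ut[ut_values(scaffold)]
  lapply(seq_along(ids), function(s) {
    m <- matrix(0, n, n)
    m[sel] <- w[, s]
    conn_matrix(m + t(m), ids[s], modality)
  })
}

#' Generate control subjects
#'
#' Each scaffold edge `e` carries weight `Normal(mu_e, sigma_e)`
#' truncated to `(0, 1]`; all subjects share the scaffold.
#'
#' @param config A `generator_config`.
#' @param scaffold Logical scaffold matrix from [make_scaffold()].
#' @param params Per-edge parameters; defaults to
#'   `control_params(config, scaffold)` (exposed via the returned
#'   attribute `"params"`).
#' @param ids Subject identifiers (default `ctrl_01` ...).
#' @return List of `conn_matrix` with attribute `"params"`.
#' @export
generate_controls <- function(config, scaffold, params = NULL, ids = NULL) {
  params <- params %||% control_params(config, scaffold)
  ids <- ids %||% sprintf("ctrl_%02d", seq_len(config$n_controls))
  w <- with_seed(derive_seed(config$seed, 3L),
                 draw_truncated(params$mu, params$sigma, length(ids)))
  out <- edge_matrix_to_conn(w, scaffold, ids, "FA")
  attr(out, "params") <- params
  out
}

# Deterministic selection of altered edges: scaffold edges incident to
# the target set, both-endpoint edges first, then single-endpoint,
# shuffled within class by the seed, truncated to the stated fraction.
select_altered_edges <- function(scaffold, spec, seed) {
  n <- nrow(scaffold)
  pairs <- idx_to_pairs(upper_tri_idx(n), n)
  on_scaffold <- ut_values(scaffold)
  in_target <- matrix(pairs %in% spec$target_nodes, ncol = 2L)
  n_in <- rowSums(in_target)
  both <- which(on_scaffold & n_in == 2L)
  single <- which(on_scaffold & n_in == 1L)
  if (length(both) + length(single) == 0L)
    stop("target_nodes have no scaffold edges")
  with_seed(derive_seed(seed, 4L), {
    both <- both[sample.int(length(both))]
    single <- single[sample.int(length(single))]
  })
  ordered <- c(both, single)
  k <- round(spec$affected_edge_fraction * length(ordered))
  ordered[seq_len(max(k, 1L))]
}

#' Generate a patient group with injected alterations
#'
#' Altered edges are the stated fraction of scaffold edges incident to
#' the target nodes (both-endpoint edges first); their control means are
#' shifted by `effect_size_sd * sigma_e` -- downwards for FA, upwards
#' for MD.  All other edges follow the control distribution.
#'
#' @inheritParams generate_controls
#' @param spec An [alteration_spec()].
#' @param n Number of patients.
#' @param modality `"FA"` (reductions) or `"MD"` (increases).
#' @param seed_offset Offset added to the config seed so distinct groups
#'   draw independent noise.
#' @return List with `matrices` (list of `conn_matrix`) and
#'   `ground_truth`: `altered_edges` (2-column ROI index matrix),
#'   `altered_nodes`, and `effect_sd` per altered edge.
#' @export
generate_patients <- function(config, scaffold, params, spec, n,
                              ids = NULL, modality = c("FA", "MD"),
                              seed_offset = 10L) {
  modality <- match.arg(modality)
  ids <- ids %||% sprintf("pat_%02d", seq_len(n))
  if (any(spec$target_nodes < 1L | spec$target_nodes > nrow(scaffold)))
    stop("target_nodes outside atlas range")
  altered_row <- select_altered_edges(scaffold, spec,
                                      config$seed + seed_offset)
  # altered_row indexes rows of the full upper-triangle pair list;
  # map to positions within the scaffold edge vector
  n_nodes <- nrow(scaffold)
  on_scaffold <- which(ut_values(scaffold))
  edge_pos <- match(altered_row, on_scaffold)
  mu <- params$mu
  sign <- if (modality == "FA") -1 else 1
  mu[edge_pos] <- mu[edge_pos] + sign * spec$effect_size_sd * params$sigma[edge_pos]
  if (modality == "FA") mu <- pmax(mu, 1e-3)
  w <- with_seed(derive_seed(config$seed, 100L + seed_offset),
                 draw_truncated(mu, params$sigma, n))
  pairs <- idx_to_pairs(upper_tri_idx(n_nodes), n_nodes)[altered_row, , drop = FALSE]
  gt <- list(altered_edges = pairs,
             altered_nodes = sort(unique(as.vector(pairs))),
             effect_sd = rep(spec$effect_size_sd, nrow(pairs)))
  list(matrices = edge_matrix_to_conn(w, scaffold, ids, modality),
       ground_truth = gt)
}

#' Simulate a full three-group cohort
#'
#' Controls plus a localized-alteration patient group (FBTCS-
#' analogue) and a widespread-alteration group (FBTCS+ analogue), with a
#' manifest carrying plausible demographics and the per-group ground
#' truth.  All patients are simulated as left-sided (alterations seeded
#' in left-hemisphere targets for the localized group), so downstream
#' ipsi/contra reorientation flips every patient.
#'
#' @param config A `generator_config`.
#' @param atlas Atlas.
#' @param spec_localized,spec_widespread Alteration specs; default
#'   presets at 1.5 SD.
#' @param modality `"FA"` or `"MD"`.
#' @return A `conn_cohort` with extra elements `ground_truth` (per
#'   patient group) and `params`.
#' @export
simulate_cohort <- function(config = generator_config(),
                            atlas = aal90_atlas(),
                            spec_localized = preset_localized(atlas),
                            spec_widespread = preset_widespread(atlas),
                            modality = c("FA", "MD")) {
  modality <- match.arg(modality)
  scaffold <- make_scaffold(config, atlas)
  params <- control_params(config, scaffold)
  controls <- generate_controls(config, scaffold, params)
  loc <- generate_patients(config, scaffold, params, spec_localized,
                           config$n_patients_localized,
                           ids = sprintf("fbtcsneg_%02d",
                                         seq_len(config$n_patients_localized)),
                           modality = modality, seed_offset = 10L)
  wide <- generate_patients(config, scaffold, params, spec_widespread,
                            config$n_patients_widespread,
                            ids = sprintf("fbtcspos_%02d",
                                          seq_len(config$n_patients_widespread)),
                            modality = modality, seed_offset = 20L)
  mats <- c(controls, loc$matrices, wide$matrices)
  names(mats) <- vapply(mats, attr, "", "subject_id")
  manifest <- with_seed(derive_seed(config$seed, 5L), data.frame(
    subject_id = names(mats),
    group = rep(c("control", "FBTCS-", "FBTCS+"),
                c(length(controls), length(loc$matrices), length(wide$matrices))),
    side = rep(c("none", "left", "left"),
               c(length(controls), length(loc$matrices), length(wide$matrices))),
    sex = sample(c("M", "F"), length(mats), replace = TRUE, prob = c(0.42, 0.58)),
    age = round(rnorm(length(mats), 38, 11), 1),
    stringsAsFactors = FALSE
  ))
  cohort <- as_conn_cohort(manifest, mats, modality, atlas)
  cohort$ground_truth <- list(`FBTCS-` = loc$ground_truth,
                              `FBTCS+` = wide$ground_truth)
  cohort$params <- params
  cohort$config <- config
  cohort
}
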