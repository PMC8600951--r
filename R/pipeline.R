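# End-to-end orchestration: simulate or load a cohort, run both NBS
# contrasts, the abnormality-load analysis with threshold-pair
# selection, the three-group and pairwise estimation statistics, and
# the region-wise ipsi/contra comparison, under one config and seed.

.paper_defaults <- list(
  t_grid = seq(0.05, 5, by = 0.05),
  z_grid = seq(1.5, 3.5, by = 0.1),
  ratio_grid = seq(0.01, 0.20, by = 0.01),
  n_permutations = 5000L,
  n_bootstrap = 5000L,
  roi_z = 2.5,
  t_threshold = 3
)

#' Pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: t-threshold grid
#' 0.05--5 in steps of 0.05 with a headline threshold of 3, z-score grid
#' 1.5--3.5 in steps of 0.1, node-abnormality grid 0.01--0.20 in steps
#' of 0.01, 5000 permutations, 5000 bootstrap resamples, region-wise
#' comparison at z > 2.5, and ipsi/contra reference side "right".
#'
#' @param manifest,matrix_dir Paths to an on-disk cohort; leave `NULL`
#'   to simulate.
#' @param simulate A [generator_config()] used when no paths are given.
#' @param modality `"FA"` or `"MD"`.
#' @param tail NBS tail; `"A_less_B"` tests weight reductions in
#'   patients (FA convention).
#' @param direction Abnormal-edge rule for z exceedance.
#' @param t_threshold Headline NBS threshold.
#' @param t_grid,z_grid,ratio_grid Analysis grids (ascending).
#' @param n_permutations,n_bootstrap Resampling sizes.
#' @param roi_z z-threshold of the region-wise comparison.
#' @param run_sweep Also run the full NBS threshold sweep (slower).
#' @param sweep_permutations Permutations per sweep (0 = extents only).
#' @param reference_side Ipsi/contra reference side.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, matrix_dir = NULL,
                            simulate = generator_config(),
                            modality = "FA", tail = "A_less_B",
                            direction = "two_sided",
                            t_threshold = 3,
                            t_grid = .paper_defaults$t_grid,
                            z_grid = .paper_defaults$z_grid,
                            ratio_grid = .paper_defaults$ratio_grid,
                            n_permutations = 5000L, n_bootstrap = 5000L,
                            roi_z = 2.5, run_sweep = FALSE,
                            sweep_permutations = 0L,
                            reference_side = "right", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  for (g in c("t_grid", "z_grid", "ratio_grid"))
    if (length(cfg[[g]]) == 0L || is.unsorted(cfg[[g]], strictly = TRUE))
      stop(g, " must be a nonempty ascending grid")
  if (cfg$n_permutations < 1L || cfg$n_bootstrap < 100L)
    stop("resampling counts too small")
  cfg
}

#' Report configuration deviations from the reference defaults
#'
#' Compares a configuration against the reference analysis parameters so
#' reproductions are auditable; returns one finding per deviation (empty
#' for the defaults).
#'
#' @param config A `pipeline_config`.
#' @return Character vector of findings.
#' @export
validate_config <- function(config) {
  findings <- character(0)
  note <- function(msg) findings <<- c(findings, msg)
  cmp <- function(name, label) {
    if (!isTRUE(all.equal(config[[name]], .paper_defaults[[name]])))
      note(sprintf("%s differs from reference default", label))
  }
  cmp("t_grid", "t-threshold grid (0.05-5 step 0.05)")
  cmp("z_grid", "z-score grid (1.5-3.5 step 0.1)")
  cmp("ratio_grid", "node-abnormality grid (0.01-0.20 step 0.01)")
  cmp("roi_z", "region-wise z-threshold (2.5)")
  cmp("t_threshold", "headline t-threshold (3)")
  if (config$n_permutations != .paper_defaults$n_permutations)
    note(sprintf("n_permutations = %d differs from reference default 5000",
                 config$n_permutations))
  if (config$n_bootstrap != .paper_defaults$n_bootstrap)
    note(sprintf("n_bootstrap = %d differs from reference default 5000",
                 config$n_bootstrap))
  findings
}

#' Run the full analysis
#'
#' Executes, deterministically under the config seed: (1) NBS contrasts
#' FBTCS+ vs control and FBTCS- vs control at the headline t-threshold
#' (and optionally the full sweep); (2) leave-one-out z-scoring of
#' controls and z-scoring of patients, the whole-brain abnormality-load
#' grid, and selection of the most discriminatory threshold pair between
#' the patient groups; (3) the three-group Kruskal-Wallis test and the
#' three pairwise estimation contrasts of whole-brain load at the
#' selected pair; (4) the region-wise FBTCS+ vs FBTCS- comparison of
#' node abnormality at `roi_z` in the ipsi/contra frame.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `conn_cohort` (overrides paths and
#'   simulation).
#' @return An `analysis_report` list; see the vignette for the layout.
#' @export
run_full <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$manifest) && !is.null(config$matrix_dir)) {
      read_cohort(config$manifest, config$matrix_dir, config$modality)
    } else {
      sim_cfg <- config$simulate
      sim_cfg$seed <- derive_seed(config$seed, 11L)
      simulate_cohort(sim_cfg, modality = config$modality)
    }
  }
  atlas <- cohort$atlas
  controls <- cohort_group(cohort, "control")
  fbtcs_neg <- cohort_group(cohort, "FBTCS-")
  fbtcs_pos <- cohort_group(cohort, "FBTCS+")

  nbs <- list(
    fbtcs_pos_vs_control = nbs_test(fbtcs_pos, controls, config$tail,
                                    config$t_threshold, config$n_permutations,
                                    seed = derive_seed(config$seed, 21L)),
    fbtcs_neg_vs_control = nbs_test(fbtcs_neg, controls, config$tail,
                                    config$t_threshold, config$n_permutations,
                                    seed = derive_seed(config$seed, 22L))
  )
  sweep <- NULL
  if (isTRUE(config$run_sweep)) {
    sweep <- list(
      fbtcs_pos_vs_control = threshold_sweep(fbtcs_pos, controls, config$tail,
                                             config$t_grid,
                                             config$sweep_permutations,
                                             seed = derive_seed(config$seed, 23L)),
      fbtcs_neg_vs_control = threshold_sweep(fbtcs_neg, controls, config$tail,
                                             config$t_grid,
                                             config$sweep_permutations,
                                             seed = derive_seed(config$seed, 24L))
    )
  }

  z_controls <- zscore_controls_loo(controls)
  dists <- fit_control_distributions(controls)
  z_neg <- lapply(fbtcs_neg, zscore_subject, dists = dists)
  z_pos <- lapply(fbtcs_pos, zscore_subject, dists = dists)

  selection <- select_threshold_pair(z_pos, z_neg, config$z_grid,
                                     config$ratio_grid, atlas,
                                     config$direction)
  load_at <- function(zs) vapply(zs, function(z)
    as.integer(abnormality_load(profile_at(z, selection$z_threshold,
                                           config$direction),
                                selection$ratio_threshold, "whole_brain",
                                atlas)), integer(1))
  loads <- list(control = load_at(z_controls),
                fbtcs_neg = load_at(z_neg), fbtcs_pos = load_at(z_pos))

  kw <- kruskal_wallis(unname(loads))
  contrasts <- list(
    fbtcs_neg_vs_control = estimate_contrast(loads$fbtcs_neg, loads$control,
                                             "greater", config$n_bootstrap,
                                             derive_seed(config$seed, 31L)),
    fbtcs_pos_vs_control = estimate_contrast(loads$fbtcs_pos, loads$control,
                                             "greater", config$n_bootstrap,
                                             derive_seed(config$seed, 32L)),
    fbtcs_pos_vs_fbtcs_neg = estimate_contrast(loads$fbtcs_pos, loads$fbtcs_neg,
                                               "greater", config$n_bootstrap,
                                               derive_seed(config$seed, 33L))
  )

  # region-wise comparison in the common ipsi/contra frame: per-node
  # abnormality of subjects whose side differs from the reference is
  # flipped through the homologue pairs
  flip_profiles <- function(zs, ids) {
    sides <- cohort$manifest$side[match(ids, cohort$manifest$subject_id)]
    profs <- lapply(zs, profile_at, z_threshold = config$roi_z,
                    direction = config$direction)
    Map(function(p, side) {
      if (side %in% c("left", "right") && side != config$reference_side)
        p$ratio <- flip_node_values(p$ratio, atlas)
      p
    }, profs, sides)
  }
  roiwise <- roiwise_comparison(
    flip_profiles(z_pos, names(fbtcs_pos)),
    flip_profiles(z_neg, names(fbtcs_neg)),
    atlas
  )

  structure(list(
    nbs = nbs, sweep = sweep, selection = selection, loads = loads,
    kruskal_wallis = kw, contrasts = contrasts, roiwise = roiwise,
    provenance = list(config = config, seed = config$seed,
                      package_version = as.character(utils::packageVersion("netabnorm")),
                      r_version = R.version.string,
                      deviations = validate_config(config))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  NBS (t > %.2f): FBTCS+ vs control extent %d (p = %.4g); ",
              x$nbs$fbtcs_pos_vs_control$t_threshold,
              x$nbs$fbtcs_pos_vs_control$extent,
              x$nbs$fbtcs_pos_vs_control$p_value))
  cat(sprintf("FBTCS- vs control extent %d (p = %.4g)\n",
              x$nbs$fbtcs_neg_vs_control$extent,
              x$nbs$fbtcs_neg_vs_control$p_value))
  cat(sprintf("  selected thresholds: z = %.2f, ratio = %.2f (d = %.3f)\n",
              x$selection$z_threshold, x$selection$ratio_threshold,
              x$selection$cohen_d))
  cat(sprintf("  Kruskal-Wallis chi-square = %.3f (p = %.4g)\n",
              x$kruskal_wallis$statistic, x$kruskal_wallis$p_value))
  cat(sprintf("  significant ROIs (BH < .05): %d / %d\n",
              sum(x$roiwise$significant), nrow(x$roiwise)))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' TSV tables (NBS component edge list, load table, region-wise table,
#' sweep curves when present) plus one JSON report with every scalar
#' result and the provenance block.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  for (nm in names(report$nbs)) {
    r <- report$nbs[[nm]]
    tsv(as.data.frame(r$component_edges), paste0("nbs_component_", nm, ".tsv"))
  }
  loads <- do.call(rbind, lapply(names(report$loads), function(g)
    data.frame(group = g, subject = seq_along(report$loads[[g]]),
               load = report$loads[[g]])))
  tsv(loads, "abnormality_load.tsv")
  tsv(report$roiwise, "roiwise_comparison.tsv")
  if (!is.null(report$sweep))
    for (nm in names(report$sweep))
      tsv(report$sweep[[nm]], paste0("sweep_", nm, ".tsv"))
  scalars <- list(
    nbs = lapply(report$nbs, function(r)
      list(t_threshold = r$t_threshold, extent = r$extent, p_value = r$p_value)),
    selection = report$selection[c("z_threshold", "ratio_threshold", "cohen_d")],
    kruskal_wallis = report$kruskal_wallis,
    contrasts = lapply(report$contrasts, function(cst)
      list(cohen_d = cst$cohen_d, cohen_d_ci = as.numeric(cst$cohen_d_ci),
           auroc = cst$auroc, auroc_ci = as.numeric(cst$auroc_ci),
           p_value = cst$p_value)),
    n_significant_rois = sum(report$roiwise$significant),
    provenance = report$provenance[c("seed", "package_version", "r_version",
                                     "deviations")]
  )
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
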