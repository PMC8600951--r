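# Normative z-scoring, abnormal edges/nodes, abnormality load,
# threshold-pair selection, region-wise comparison.

test_that("control distributions: hand values and degeneracy flags", {
  ctrl <- lapply(c(0.4, 0.5, 0.6), function(w)
    full_matrix(c(w, 0.5 + (w - 0.5) / 2, w / 2), 3, paste0("c", w)))
  d <- fit_control_distributions(ctrl)
  expect_equal(d$mean[1, 2], 0.5)
  expect_equal(d$sd[1, 2], 0.1)
  expect_equal(d$sd[1, 3], 0.05)
  expect_equal(d$mean[2, 3], 0.25)
  expect_equal(d$n_controls, 3L)

  same <- rep(list(full_matrix(c(0.4, 0.5, 0.6), 3, "c")), 3)
  expect_warning(dz <- fit_control_distributions(same), "zero control SD")
  expect_true(all(dz$degenerate[unclass(dz$scaffold)]))
  probe <- full_matrix(c(0.9, 0.5, 0.6), 3, "p")
  expect_warning(z <- zscore_subject(probe, dz), "degenerate")
  expect_true(all(unclass(z) == 0))    # z forced to 0, not Inf

  expect_error(fit_control_distributions(same[1:2]), "at least 3")
})

test_that("control-distribution estimates converge (Monte-Carlo, n = 500)", {
  cfg <- generator_config(n_controls = 500, seed = 29)
  sc <- make_scaffold(cfg)
  params <- netabnorm:::control_params(cfg, sc)
  d <- fit_control_distributions(generate_controls(cfg, sc, params))
  sel <- which(sc & upper.tri(sc))
  se_mean <- cfg$edge_sd / sqrt(500)
  # compare in matched edge order
  mu_mat <- netabnorm:::sym_from_ut(
    replace(rep(0, 4005), which(sc[upper.tri(sc)]), params$mu), 90)
  sd_mat <- netabnorm:::sym_from_ut(
    replace(rep(0, 4005), which(sc[upper.tri(sc)]), params$sigma), 90)
  expect_gte(mean(abs(d$mean[sel] - mu_mat[sel]) <= 3 * se_mean), 0.99)
  se_sd <- params$sigma[1] / sqrt(2 * 499)
  expect_gte(mean(abs(d$sd[sel] - sd_mat[sel]) <= 3 * se_sd), 0.99)
})

test_that("z-scores: arithmetic, zero at the mean, exact linearity", {
  ctrl <- lapply(c(0.45, 0.50, 0.55), function(w)
    full_matrix(c(w, 0.6 + (w - 0.5), 0.4 - (w - 0.5)), 3, paste0("c", w)))
  d <- fit_control_distributions(ctrl)
  expect_equal(d$mean[1, 2], 0.5)
  expect_equal(d$mean[1, 3], 0.6)
  expect_equal(d$mean[2, 3], 0.4)

  subj <- full_matrix(c(0.35, 0.6, 0.4), 3, "s")
  z <- zscore_subject(subj, d)
  expect_equal(z[1, 2], (0.35 - 0.5) / d$sd[1, 2])
  expect_equal(z[1, 3], 0)
  expect_equal(z[2, 3], 0)

  # subject at the control mean scores zero everywhere
  mean_subj <- conn_matrix(d$mean, "mean")
  expect_true(all(unclass(zscore_subject(mean_subj, d)) == 0))

  # shifting one edge by +k*SD shifts its z by exactly +k
  k <- 1.75
  w <- unclass(subj)
  w[1, 2] <- w[2, 1] <- w[1, 2] + k * d$sd[1, 2]
  z2 <- zscore_subject(conn_matrix(w, "s2"), d)
  expect_equal(z2[1, 2] - z[1, 2], k, tolerance = 1e-12)

  # scaffold mismatch errors
  other <- full_matrix(c(0, 0.6, 0.4), 3, "o")
  expect_error(zscore_subject(other, d), "scaffold")
})

test_that("leave-one-out z-scoring isolates the perturbed control", {
  ne <- 15
  base <- seq(0.3, 0.7, length.out = ne)
  withr::with_seed(5, {
    mats <- lapply(1:6, function(k)
      full_matrix(base + rnorm(ne, 0, 0.005), 6, paste0("c", k)))
  })
  # large perturbation of edge (1,2) in control 1 only
  w <- unclass(mats[[1]])
  w[1, 2] <- w[2, 1] <- w[1, 2] + 0.3
  mats[[1]] <- conn_matrix(w, "c1")
  zs <- zscore_controls_loo(mats)
  z_at_edge <- vapply(zs, function(z) abs(z[1, 2]), 0)
  expect_equal(which.max(z_at_edge), 1L)
  expect_gt(z_at_edge[1], 20)
  expect_true(all(z_at_edge[-1] < 5))
  expect_true(all(vapply(zs, attr, TRUE, "loo")))
  # recomputation is deterministic
  expect_identical(lapply(zscore_controls_loo(mats), unclass),
                   lapply(zs, unclass))
  expect_error(zscore_controls_loo(mats[1:3]), "at least 4")
})

test_that("LOO z-scores of exchangeable controls are centred near 0", {
  # 50 replicate cohorts of 8 controls; per-edge grand mean of z
  sums <- NULL; count <- 0
  for (r in 1:50) {
    world <- small_world(seed = 3000 + r, n_controls = 8)
    ctrl <- generate_controls(world$cfg, world$scaffold, world$params)
    zs <- zscore_controls_loo(ctrl)
    sel <- which(world$scaffold & upper.tri(world$scaffold))
    zm <- rowMeans(vapply(zs, function(z) unclass(z)[sel], numeric(length(sel))))
    sums <- if (is.null(sums)) zm else sums + zm
    count <- count + 1
  }
  grand <- sums / count
  expect_lt(quantile(abs(grand), 0.99), 0.2)
})

test_that("abnormal-edge masks: direction, strictness, monotonicity", {
  sc <- matrix(TRUE, 4, 4); diag(sc) <- FALSE
  zm <- matrix(0, 4, 4)
  zm[1, 2] <- zm[2, 1] <- -3
  zm[1, 3] <- zm[3, 1] <- -2
  zm[1, 4] <- zm[4, 1] <- 2.6
  z <- structure(zm, subject_id = "s", loo = FALSE, scaffold = sc,
                 class = c("zscore_matrix", "matrix", "array"))
  expect_equal(sum(abnormal_edge_mask(z, 2.5)) / 2, 2)       # -3 and 2.6
  expect_equal(sum(abnormal_edge_mask(z, 2.5, "decrease_only")) / 2, 1)
  expect_equal(sum(abnormal_edge_mask(z, 2.5, "increase_only")) / 2, 1)
  expect_equal(sum(abnormal_edge_mask(z, 2.6, "increase_only")), 0)  # strict
  expect_equal(sum(abnormal_edge_mask(z, 3.5)), 0)
  sizes <- vapply(seq(0.5, 3.5, by = 0.5),
                  function(thr) sum(abnormal_edge_mask(z, thr)), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("node abnormality is the abnormal-to-total connection ratio", {
  # six-node toy in the illustration style: node 2 has 3 connections,
  # one abnormal -> ratio 1/3
  sc <- matrix(FALSE, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(2, 6), c(3, 4), c(4, 5), c(5, 6))
  sc[edges] <- TRUE; sc <- sc | t(sc)
  zm <- matrix(0, 6, 6)
  zm[1, 2] <- zm[2, 1] <- 4   # the single abnormal connection
  zm[sc & zm == 0] <- 0.5
  z <- structure(zm, subject_id = "toy", loo = FALSE, scaffold = sc,
                 class = c("zscore_matrix", "matrix", "array"))
  prof <- node_abnormality(abnormal_edge_mask(z, 2.5), z, 2.5)
  expect_equal(prof$ratio[2], 1 / 3)
  expect_equal(prof$ratio[1], 1)      # degree-1 node, its edge abnormal
  expect_equal(prof$ratio[4], 0)
  expect_equal(prof$degree[2], 3)

  # node of degree 4 with one abnormal edge -> 0.25
  sc4 <- matrix(FALSE, 5, 5); sc4[1, 2:5] <- TRUE; sc4 <- sc4 | t(sc4)
  zm4 <- matrix(0, 5, 5); zm4[1, 2] <- zm4[2, 1] <- 3; zm4[1, 3:5] <- 1
  zm4 <- pmax(zm4, t(zm4))
  z4 <- structure(zm4, subject_id = "t4", loo = FALSE, scaffold = sc4,
                  class = c("zscore_matrix", "matrix", "array"))
  p4 <- node_abnormality(abnormal_edge_mask(z4, 2.5), z4, 2.5)
  expect_equal(p4$ratio[1], 0.25)

  # empty mask -> all zeros; mask off scaffold -> error
  p0 <- node_abnormality(abnormal_edge_mask(z, 10), z, 10)
  expect_true(all(p0$ratio == 0))
  bad <- matrix(TRUE, 6, 6)
  expect_error(node_abnormality(bad, z), "off the scaffold")
})

test_that("abnormality load: strict threshold, region sets, partition", {
  atlas <- aal90_atlas()
  prof <- structure(list(subject_id = "s", z_threshold = 2.5,
                         direction = "two_sided",
                         ratio = rep(0, 90), degree = rep(10, 90)),
                    class = "node_profile")
  prof$ratio[c(1, 5, 9, 20)] <- c(0.25, 0.5, 0.1, 0.2)
  expect_equal(as.integer(abnormality_load(prof, 0.2, "whole_brain", atlas)), 2L)
  expect_equal(as.integer(abnormality_load(prof, 0.6, "whole_brain", atlas)), 0L)
  expect_error(abnormality_load(prof, 0.2, "brainstem", atlas), "unknown")
  expect_error(abnormality_load(prof, 0, "whole_brain", atlas), "\\(0, 1\\)")

  # lobewise loads partition the whole-brain load; hemisphere-tagged
  # lobes partition each lobe
  withr::with_seed(41, {
    for (r in 1:5) {
      prof$ratio <- runif(90, 0, 0.3)
      thr <- runif(1, 0.01, 0.25)
      whole <- as.integer(abnormality_load(prof, thr, "whole_brain", atlas))
      lobes <- vapply(c("temporal", "subcortical", "frontal", "parietal",
                        "occipital", "cingulate"), function(l)
        as.integer(abnormality_load(prof, thr, l, atlas)), 0L)
      expect_equal(sum(lobes), whole)
      lr <- as.integer(abnormality_load(prof, thr, "temporal_left", atlas)) +
        as.integer(abnormality_load(prof, thr, "temporal_right", atlas))
      expect_equal(lr, lobes[["temporal"]])
    }
  })
})

test_that("load grid is monotone in both thresholds and matches the
           one-shot path", {
  world <- small_world(seed = 71, n_controls = 8)
  ctrl <- generate_controls(world$cfg, world$scaffold, world$params)
  zs <- zscore_controls_loo(ctrl)
  z_grid <- seq(1.5, 3.5, by = 0.5)
  ratio_grid <- c(0.02, 0.05, 0.1, 0.2)
  grid <- abnormality_load_grid(zs, z_grid, ratio_grid, world$atlas)
  # cross-check a few cells against profile_at + abnormality_load
  for (k in c(1, 7, 20)) {
    row <- grid[k, ]
    z <- zs[[which(vapply(zs, attr, "", "subject_id") == row$subject_id)]]
    direct <- abnormality_load(
      netabnorm:::profile_at(z, row$z_threshold), row$ratio_threshold,
      "whole_brain", world$atlas)
    expect_equal(row$load, as.integer(direct))
  }
  # monotone: load non-increasing as either threshold grows
  for (id in unique(grid$subject_id)[1:3]) {
    g <- grid[grid$subject_id == id, ]
    m <- matrix(g$load[order(g$z_threshold, g$ratio_threshold)],
                nrow = length(z_grid), byrow = TRUE)
    expect_true(all(apply(m, 1, diff) <= 0))
    expect_true(all(apply(m, 2, diff) <= 0))
  }
})

test_that("threshold-pair selection maximizes |d| with deterministic ties", {
  # construct z-matrices where group A has huge |z| on many edges and
  # group B none: loads are constant over the whole grid, so every pair
  # ties and the smallest (z, ratio) pair must be returned
  sc <- matrix(TRUE, 6, 6); diag(sc) <- FALSE
  mk <- function(vals, id) {
    zm <- matrix(0, 6, 6); zm[upper.tri(zm)] <- vals
    structure(zm + t(zm), subject_id = id, loo = FALSE, scaffold = sc,
              class = c("zscore_matrix", "matrix", "array"))
  }
  withr::with_seed(6, {
    za <- lapply(1:5, function(k) mk(ifelse(runif(15) < 0.6, 9, 8), paste0("a", k)))
    zb <- lapply(1:5, function(k) mk(rep(0.1, 15), paste0("b", k)))
  })
  atlas6 <- as_conn_atlas(data.frame(
    roi = c("A_L", "A_R", "B_L", "B_R", "C_L", "C_R"),
    hemisphere = rep(c("left", "right"), 3),
    homologue = c("A_R", "A_L", "B_R", "B_L", "C_R", "C_L"),
    lobe = rep("temporal", 6)), strict = FALSE)
  sel <- select_threshold_pair(za, zb, z_grid = c(2, 3), ratio_grid = c(0.1, 0.2),
                               atlas = atlas6)
  expect_equal(sel$z_threshold, 2)
  expect_equal(sel$ratio_threshold, 0.1)
  expect_gt(sel$cohen_d, 0)

  # all-zero grid errors
  expect_error(select_threshold_pair(zb, zb, z_grid = c(2, 3),
                                     ratio_grid = c(0.1, 0.2), atlas = atlas6),
               "zero over the whole grid")
})

test_that("region-wise comparison: null case and single separated ROI
           survive BH exactly as the hand oracle says", {
  atlas <- aal90_atlas()
  mkprof <- function(ratio, id)
    structure(list(subject_id = id, z_threshold = 2.5,
                   direction = "two_sided", ratio = ratio,
                   degree = rep(10, 90)), class = "node_profile")
  withr::with_seed(8, {
    base <- lapply(1:10, function(k) mkprof(rep(0.1, 90), paste0("a", k)))
    same <- lapply(1:10, function(k) mkprof(rep(0.1, 90), paste0("b", k)))
  })
  null_res <- roiwise_comparison(base, same, atlas)
  expect_false(any(null_res$significant))

  # one fully separated ROI among 89 identical ones
  sep <- lapply(seq_along(base), function(k) {
    p <- base[[k]]; p$ratio[37] <- 0.5 + 0.01 * k; p
  })
  res <- roiwise_comparison(sep, same, atlas)
  expect_true(res$significant[37])
  expect_equal(sum(res$significant), 1L)
  expect_equal(res$p_adjusted, naive_bh(res$p_value), tolerance = 1e-12)
  expect_error(roiwise_comparison(sep[1:2], same, atlas), "at least 3")
})

test_that("widespread-vs-localized recovery: significant ROIs concentrate
           in the widespread-only target set", {
  # scaled-down replicate count; the full 20-replicate d>0 check is in
  # test-acceptance.R
  atlas <- aal90_atlas()
  wide_only <- setdiff(preset_widespread(atlas)$target_nodes,
                       preset_localized(atlas)$target_nodes)
  hits <- vapply(1:3, function(s) {
    cfg <- generator_config(n_controls = 20, n_patients_localized = 15,
                            n_patients_widespread = 20, seed = 500 + s)
    cohort <- simulate_cohort(cfg)
    ctrl <- cohort_group(cohort, "control")
    d <- fit_control_distributions(ctrl)
    zpos <- lapply(cohort_group(cohort, "FBTCS+"), zscore_subject, dists = d)
    zneg <- lapply(cohort_group(cohort, "FBTCS-"), zscore_subject, dists = d)
    pp <- lapply(zpos, netabnorm:::profile_at, z_threshold = 2.5)
    pn <- lapply(zneg, netabnorm:::profile_at, z_threshold = 2.5)
    res <- roiwise_comparison(pp, pn, atlas)
    sig <- which(res$significant)
    if (length(sig) == 0) return(NA_real_)
    mean(sig %in% wide_only)
  }, 0)
  expect_true(all(hits >= 0.7, na.rm = TRUE))
  expect_true(any(!is.na(hits)))
})
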