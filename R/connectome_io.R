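# Connectivity-matrix and cohort I/O, validation, and reorientation of
# matrices into an ipsilateral/contralateral frame.

#' Construct a connectivity matrix object
#'
#' A connectivity matrix is one subject's symmetric weighted adjacency
#' over the atlas regions, weighted by FA (dimensionless, in `[0, 1]`)
#' or MD (diffusivity units).  A weight of exactly 0 encodes "no
#' connection in the scaffold", never a measured value of zero.
#'
#' @param weights Square numeric matrix, symmetric with zero diagonal.
#' @param subject_id Subject identifier.
#' @param modality `"FA"` or `"MD"`.
#' @return A `conn_matrix` (numeric matrix with subject metadata).
#' @export
conn_matrix <- function(weights, subject_id, modality = c("FA", "MD")) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  validate_conn_matrix(weights, subject_id, modality)
  structure(weights, subject_id = as.character(subject_id),
            modality = modality, class = c("conn_matrix", "matrix", "array"))
}

validate_conn_matrix <- function(weights, subject_id, modality) {
  id <- as.character(subject_id)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("subject ", id, ": weights must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("subject ", id, ": matrix is not symmetric")
  if (max(abs(diag(weights))) > 0)
    stop("subject ", id, ": diagonal must be zero")
  if (any(weights < 0))
    stop("subject ", id, ": negative weights")
  if (modality == "FA" && any(weights > 1))
    stop("subject ", id, ": FA weights must lie in [0, 1]")
  invisible(weights)
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> subject %s, modality %s, %d x %d, %d edges\n",
              attr(x, "subject_id"), attr(x, "modality"),
              nrow(x), ncol(x), sum(ut_values(x) > 0)))
  invisible(x)
}

# Binary scaffold (logical matrix) of a connectivity matrix.
scaffold_of <- function(m) unclass(m) > 0

#' Write a connectivity matrix as delimited text
#'
#' Plain text, one row per line, space separated, no header, row order =
#' atlas ROI order.  Weights are written with 17 significant digits so a
#' write/read round trip reproduces them exactly.
#'
#' @param m A `conn_matrix` (or plain matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path) {
  txt <- apply(unclass(m), 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Read a connectivity matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited square numeric matrices with
#' no header.
#'
#' @param path File path.
#' @inheritParams conn_matrix
#' @return A `conn_matrix`.
#' @export
read_connectivity_matrix <- function(path, subject_id, modality = "FA") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  vals <- scan(path, what = numeric(), sep = sep, quiet = TRUE)
  n <- round(sqrt(length(vals)))
  if (n * n != length(vals))
    stop("subject ", subject_id, ": file does not contain a square matrix")
  conn_matrix(matrix(vals, n, n, byrow = TRUE), subject_id, modality)
}

#' Read a cohort: manifest plus one matrix file per subject
#'
#' The manifest is a CSV with header columns `subject_id`, `group`,
#' `side` and optionally `sex`, `age`, `hs`, `outcome` (extra columns
#' are ignored).  Matrix files are looked up in `matrix_dir` as
#' `<subject_id>.txt` (also `.csv`/`.tsv`).  All matrices are validated
#' against the connectivity-matrix invariants and against each other for
#' an identical binary scaffold (constant density across subjects).
#' Subjects with a manifest row but no matrix file are reported by id in
#' a warning and dropped.
#'
#' @param manifest_path CSV manifest path.
#' @param matrix_dir Directory holding matrix files.
#' @param modality `"FA"` or `"MD"`.
#' @param atlas Atlas the matrices are defined over.
#' @return A `conn_cohort`: list with `manifest` (data frame),
#'   `matrices` (named list of `conn_matrix`), `scaffold` (logical
#'   matrix), `modality`, `atlas`.
#' @export
read_cohort <- function(manifest_path, matrix_dir, modality = c("FA", "MD"),
                        atlas = aal90_atlas()) {
  modality <- match.arg(modality)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  validate_manifest(manifest)
  found <- vapply(manifest$subject_id, function(id) {
    for (ext in c(".txt", ".csv", ".tsv")) {
      p <- file.path(matrix_dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(found)) {
    warning("no matrix file for subject(s): ",
            paste(manifest$subject_id[is.na(found)], collapse = ", "),
            "; dropped from cohort")
    manifest <- manifest[!is.na(found), , drop = FALSE]
    found <- found[!is.na(found)]
  }
  mats <- Map(read_connectivity_matrix, found, manifest$subject_id,
              MoreArgs = list(modality = modality))
  names(mats) <- manifest$subject_id
  as_conn_cohort(manifest, mats, modality, atlas)
}

validate_manifest <- function(manifest) {
  need <- c("subject_id", "group", "side")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject_id in manifest")
  ok_groups <- c("control", "FBTCS-", "FBTCS+")
  if (!all(manifest$group %in% ok_groups))
    stop("manifest group must be one of ", paste(ok_groups, collapse = ", "))
  if (!all(manifest$side %in% c("left", "right", "none")))
    stop("manifest side must be left, right, or none")
  if (any(manifest$group == "control" & manifest$side != "none"))
    stop("controls must have side = none")
  invisible(manifest)
}

# Assemble and cross-validate a cohort from parts.
as_conn_cohort <- function(manifest, matrices, modality, atlas) {
  n <- nrow(atlas)
  for (m in matrices)
    if (nrow(m) != n)
      stop("subject ", attr(m, "subject_id"), ": expected ", n, " x ", n,
           " matrix, found ", nrow(m), " x ", ncol(m))
  scaffold <- check_shared_scaffold(matrices)
  structure(list(manifest = manifest, matrices = matrices,
                 scaffold = scaffold, modality = modality, atlas = atlas),
            class = "conn_cohort")
}

# Verify all subjects share one binary scaffold; on mismatch, name the
# subject and the offending edges.
check_shared_scaffold <- function(matrices) {
  ref <- scaffold_of(matrices[[1]])
  for (m in matrices[-1]) {
    sc <- scaffold_of(m)
    if (!identical(sc, ref)) {
      diff <- which(sc != ref & upper.tri(ref), arr.ind = TRUE)
      shown <- utils::head(diff, 5L)
      stop("subject ", attr(m, "subject_id"),
           ": scaffold differs from cohort scaffold at edge(s) ",
           paste(sprintf("(%d,%d)", shown[, 1], shown[, 2]), collapse = ", "),
           if (nrow(diff) > nrow(shown)) sprintf(" and %d more", nrow(diff) - nrow(shown)) else "")
    }
  }
  ref
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat(sprintf("<conn_cohort> %d subjects (%s), modality %s, density %.3f\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$group)),
                            as.integer(table(x$manifest$group))), collapse = ", "),
              x$modality,
              mean(ut_values(x$scaffold))))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `manifest.csv` and one delimited matrix file per subject into
#' `dir`.
#'
#' @param cohort A `conn_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (id in names(cohort$matrices))
    write_connectivity_matrix(cohort$matrices[[id]],
                              file.path(dir, paste0(id, ".txt")))
  invisible(dir)
}

#' Subset a cohort's matrices by group label
#'
#' @param cohort A `conn_cohort`.
#' @param group One of `"control"`, `"FBTCS-"`, `"FBTCS+"`.
#' @return Named list of `conn_matrix` objects.
#' @export
cohort_group <- function(cohort, group) {
  ids <- cohort$manifest$subject_id[cohort$manifest$group == group]
  cohort$matrices[ids]
}

#' Reorient a matrix to an ipsilateral/contralateral frame
#'
#' Subjects whose epilepsy side differs from `reference_side` have their
#' rows and columns permuted by swapping every left/right homologue pair,
#' so that after reorientation "ipsilateral" regions occupy the
#' reference-side slots for every subject.  Applying the flip twice
#' restores the original matrix.
#'
#' @param m A `conn_matrix`.
#' @param side The subject's epilepsy side, `"left"` or `"right"`.
#' @param atlas Atlas supplying the homologue pairs.
#' @param reference_side Side whose slots represent "ipsilateral" after
#'   reorientation; default `"right"` (left-sided subjects get flipped).
#' @return A `conn_matrix` in the common frame.
#' @export
flip_to_ipsi_contra <- function(m, side, atlas = aal90_atlas(),
                                reference_side = c("right", "left")) {
  side <- match.arg(side, c("left", "right"))
  reference_side <- match.arg(reference_side)
  if (side == reference_side) return(m)
  perm <- homologue_index(atlas)
  if (anyNA(perm)) stop("atlas homologue table is incomplete")
  out <- unclass(m)[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(unclass(m))
  structure(out, subject_id = attr(m, "subject_id"),
            modality = attr(m, "modality"),
            class = c("conn_matrix", "matrix", "array"))
}

# Apply the homologue permutation to a per-node vector (used to express
# node-level summaries of flipped subjects in the common frame).
flip_node_values <- function(values, atlas) {
  values[homologue_index(atlas)]
}
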