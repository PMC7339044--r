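# Serialization: wish-lists as YAML (mirroring the protocol table column
# for column), masks and dose volumes as NIfTI, the dose-influence matrix
# as MatrixMarket text with a JSON sidecar, results as tidy CSV + JSON,
# and the run manifest.

dose_value_to_yaml <- function(v) {
  if (inherits(v, "pct_of")) list(value = v$value, of = v$of) else v
}

yaml_to_dose_value <- function(v, where) {
  if (is.list(v)) {
    extra <- setdiff(names(v), c("value", "of"))
    if (length(extra))
      stop(sprintf("unknown keys %s in %s", paste(extra, collapse = ", "),
                   where), call. = FALSE)
    return(pct_of(v$value, v$of))
  }
  v
}

#' Save a wish-list to YAML
#'
#' @param wl a \code{wishlist}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_wishlist <- function(wl, path) {
  stopifnot(inherits(wl, "wishlist"))
  out <- list(
    name = wl$name,
    slack_delta = wl$slack_delta,
    prescription = list(pd_high = wl$prescription$pd_high,
                        pd_low = wl$prescription$pd_low,
                        n_fractions = wl$prescription$n_fractions),
    constraints = lapply(wl$constraints, function(cc)
      list(structure = cc$structure, fun = cc$kind,
           limit = dose_value_to_yaml(cc$limit))),
    objectives = lapply(wl$objectives, function(oo) {
      o <- list(priority = oo$priority, structure = oo$structure,
                fun = oo$kind, goal = dose_value_to_yaml(oo$goal),
                sufficient = dose_value_to_yaml(oo$sufficient),
                enabled = oo$enabled)
      if (!is.null(oo$pd)) o$pd <- dose_value_to_yaml(oo$pd)
      if (!is.null(oo$alpha)) o$alpha <- oo$alpha
      if (!is.null(oo$k)) o$k <- oo$k
      o
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Load a wish-list from YAML
#'
#' Validates the schema strictly: unknown keys and malformed rows are
#' rejected with the offending row and field named.
#'
#' @param path YAML file written by \code{\link{save_wishlist}} (or by
#'   hand in the same layout).
#' @param structures optional \code{structure_set}; when given, every
#'   referenced structure name is checked against it.
#' @return A \code{wishlist}.
#' @export
load_wishlist <- function(path, structures = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  extra <- setdiff(names(y), c("name", "slack_delta", "prescription",
                               "constraints", "objectives"))
  if (length(extra))
    stop("unknown top-level keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  rxk <- setdiff(names(y$prescription),
                 c("pd_high", "pd_low", "n_fractions"))
  if (length(rxk))
    stop("unknown prescription keys: ", paste(rxk, collapse = ", "),
         call. = FALSE)
  rx <- prescription(pd_high = y$prescription$pd_high,
                     pd_low = y$prescription$pd_low,
                     n_fractions = y$prescription$n_fractions)
  cons <- lapply(seq_along(y$constraints), function(i) {
    cc <- y$constraints[[i]]
    extra <- setdiff(names(cc), c("structure", "fun", "limit"))
    if (length(extra))
      stop(sprintf("constraint %d: unknown field(s) %s", i,
                   paste(extra, collapse = ", ")), call. = FALSE)
    for (fld in c("structure", "fun", "limit"))
      if (is.null(cc[[fld]]))
        stop(sprintf("constraint %d: missing field '%s'", i, fld),
             call. = FALSE)
    hard_constraint(cc$structure, cc$fun,
                    yaml_to_dose_value(cc$limit,
                                       sprintf("constraint %d limit", i)))
  })
  objs <- lapply(seq_along(y$objectives), function(i) {
    oo <- y$objectives[[i]]
    extra <- setdiff(names(oo), c("priority", "structure", "fun", "goal",
                                  "sufficient", "enabled", "pd", "alpha",
                                  "k"))
    if (length(extra))
      stop(sprintf("objective %d: unknown field(s) %s", i,
                   paste(extra, collapse = ", ")), call. = FALSE)
    for (fld in c("priority", "structure", "fun", "goal"))
      if (is.null(oo[[fld]]))
        stop(sprintf("objective %d: missing field '%s'", i, fld),
             call. = FALSE)
    planning_objective(
      oo$priority, oo$structure, oo$fun,
      goal = yaml_to_dose_value(oo$goal, sprintf("objective %d goal", i)),
      sufficient = if (is.null(oo$sufficient)) {
        yaml_to_dose_value(oo$goal, "")
      } else yaml_to_dose_value(oo$sufficient,
                                sprintf("objective %d sufficient", i)),
      pd = if (is.null(oo$pd)) NULL else
        yaml_to_dose_value(oo$pd, sprintf("objective %d pd", i)),
      alpha = oo$alpha, k = oo$k,
      enabled = if (is.null(oo$enabled)) TRUE else oo$enabled)
  })
  if (!is.null(structures)) {
    known <- names(structures$masks)
    for (i in seq_along(cons))
      if (!cons[[i]]$structure %in% known)
        stop(sprintf("constraint %d references unknown structure '%s'",
                     i, cons[[i]]$structure), call. = FALSE)
    for (i in seq_along(objs))
      if (!objs[[i]]$structure %in% known)
        stop(sprintf("objective %d references unknown structure '%s'",
                     i, objs[[i]]$structure), call. = FALSE)
  }
  wishlist(rx, cons, objs,
           slack_delta = if (is.null(y$slack_delta)) 1e-3 else y$slack_delta,
           name = if (is.null(y$name)) basename(path) else y$name)
}

nifti_affine <- function(grid) {
  aff <- diag(4)
  aff[1, 1] <- grid$spacing[1]
  aff[2, 2] <- grid$spacing[2]
  aff[3, 3] <- grid$spacing[3]
  aff[1:3, 4] <- grid$origin
  aff
}

#' Export phantom masks as NIfTI files (one per structure)
#'
#' @param phantom a \code{phantom} (or \code{structure_set}).
#' @param dir output directory (created if absent).
#' @return Character vector of written file paths.
#' @export
export_masks_nifti <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- phantom$grid
  aff <- nifti_affine(grid)
  paths <- character(0)
  for (nm in names(phantom$masks)) {
    img <- RNifti::asNifti(array(as.integer(phantom$masks[[nm]]),
                                 grid$shape))
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::pixdim(img) <- grid$spacing
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  paths
}

#' Import binary masks from a directory of NIfTI files
#'
#' @param dir directory containing one NIfTI per structure (file name =
#'   structure name).
#' @param grid optional \code{grid_spec} to validate/attach; inferred from
#'   the first image otherwise.
#' @return A list with \code{grid} and \code{masks}.
#' @export
import_masks_nifti <- function(dir, grid = NULL) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no NIfTI files in ", dir, call. = FALSE)
  masks <- list()
  for (f in files) {
    img <- RNifti::readNifti(f)
    nm <- sub("\\.nii(\\.gz)?$", "", basename(f))
    if (is.null(grid)) {
      pd <- attr(img, "pixdim")
      grid <- grid_spec(dim(img), pd[seq_len(3)])
    }
    if (!identical(dim(img), as.integer(grid$shape)))
      stop(sprintf("mask '%s' does not match the grid shape", nm),
           call. = FALSE)
    masks[[nm]] <- array(as.array(img) > 0.5, grid$shape)
  }
  list(grid = grid, masks = masks)
}

#' Export a dose distribution as NIfTI
#'
#' @param dose numeric dose vector over the dose-influence rows.
#' @param dij the \code{dose_influence} the dose was computed with.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_dose_nifti <- function(dose, dij, path) {
  grid <- dij$grid
  vol <- array(0, grid$shape)
  vol[dij$voxel_index] <- dose
  img <- RNifti::asNifti(vol)
  RNifti::qform(img) <- structure(nifti_affine(grid), code = 2L)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Persist a dose-influence matrix
#'
#' Writes the sparse matrix in MatrixMarket text format with a JSON
#' sidecar describing the beam configuration, beamlet bookkeeping, voxel
#' indices and grid.
#'
#' @param dij a \code{dose_influence}.
#' @param stem output path stem: writes \code{<stem>.mtx} and
#'   \code{<stem>.json}.
#' @return The two file paths, invisibly.
#' @export
save_dose_influence <- function(dij, stem) {
  mtx <- paste0(stem, ".mtx")
  js <- paste0(stem, ".json")
  Matrix::writeMM(dij$matrix, mtx)
  jsonlite::write_json(
    list(config = unclass(dij$config),
         beam_of_beamlet = dij$beam_of_beamlet,
         beamlet_u = dij$beamlet_u, beamlet_z = dij$beamlet_z,
         beam_angles = dij$beam_angles, voxel_index = dij$voxel_index,
         grid = list(shape = dij$grid$shape, spacing = dij$grid$spacing,
                     origin = dij$grid$origin)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(mtx, js))
}

#' Load a persisted dose-influence matrix
#'
#' @param stem path stem used with \code{\link{save_dose_influence}}.
#' @return A \code{dose_influence}.
#' @export
load_dose_influence <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- do.call(beam_config, as.list(meta$config))
  structure(list(matrix = m, beam_of_beamlet = meta$beam_of_beamlet,
                 beamlet_u = meta$beamlet_u, beamlet_z = meta$beamlet_z,
                 beam_angles = meta$beam_angles, config = cfg,
                 voxel_index = meta$voxel_index,
                 grid = grid_spec(meta$grid$shape, meta$grid$spacing,
                                  meta$grid$origin)),
            class = "dose_influence")
}

#' Write trade-off results as tidy CSV and per-patient JSON
#'
#' Produces \code{metrics.csv} (one metric per row: patient, plan, metric,
#' value), \code{curves.csv} (patient, coverage level, NTCP with/without
#' diabetes), one \code{patient_<id>.json} per patient, and, when a cohort
#' summary is supplied, \code{cohort_levels.csv} and
#' \code{cohort_regressions.csv}. Row order is deterministic.
#'
#' @param patients list of \code{patient_tradeoff} objects (may be empty).
#' @param out_dir output directory (created if absent).
#' @param summary optional \code{cohort_summary}.
#' @return Character vector of written files, invisibly.
#' @export
write_results <- function(patients, out_dir, summary = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  metric_cols <- c("ptv_low_coverage", "ptv_high_coverage",
                   "ctv_low_coverage", "ctv_high_coverage", "rectum_geud",
                   "rectum_geud_eqd2", "rectum_mean", "bladder_mean",
                   "ntcp_with_diabetes", "ntcp_without_diabetes")
  rows <- list()
  curves <- list()
  for (p in patients) {
    m <- p$metrics
    for (i in seq_len(nrow(m)))
      for (mc in metric_cols)
        rows[[length(rows) + 1L]] <-
          data.frame(patient = p$id, plan = m$plan[i], metric = mc,
                     value = m[[mc]][i], stringsAsFactors = FALSE)
    cv <- p$curve
    cv$patient <- p$id
    curves[[length(curves) + 1L]] <-
      cv[, c("patient", "coverage", "ntcp_with", "ntcp_without")]
  }
  mpath <- file.path(out_dir, "metrics.csv")
  utils::write.csv(if (length(rows)) do.call(rbind, rows) else
    data.frame(patient = integer(0), plan = character(0),
               metric = character(0), value = numeric(0)),
    mpath, row.names = FALSE)
  written <- c(written, mpath)
  cpath <- file.path(out_dir, "curves.csv")
  utils::write.csv(if (length(curves)) do.call(rbind, curves) else
    data.frame(patient = integer(0), coverage = numeric(0),
               ntcp_with = numeric(0), ntcp_without = numeric(0)),
    cpath, row.names = FALSE)
  written <- c(written, cpath)

  for (p in patients) {
    jp <- file.path(out_dir, sprintf("patient_%d.json", p$id))
    jsonlite::write_json(
      list(id = p$id, overlap_pct = p$overlap_pct,
           prv_margin_mm = p$prv_margin_mm,
           metrics = p$metrics, curve = p$curve,
           diabetes_compensation = diabetes_compensation(p)),
      jp, auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, jp)
  }

  if (!is.null(summary)) {
    lp <- file.path(out_dir, "cohort_levels.csv")
    utils::write.csv(summary$levels, lp, row.names = FALSE)
    rp <- file.path(out_dir, "cohort_regressions.csv")
    utils::write.csv(summary$regressions, rp, row.names = FALSE)
    written <- c(written, lp, rp)
  }
  invisible(written)
}

#' Write a run manifest
#'
#' Records the package version, seeds, configuration, timestamps and
#' per-plan solver statuses so a run can be reproduced.
#'
#' @param path output JSON file.
#' @param seeds named list/vector of seeds used.
#' @param config any JSON-serializable configuration list.
#' @param statuses optional data.frame/list of per-stage statuses.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, seeds, config = list(), statuses = NULL) {
  jsonlite::write_json(
    list(package = "prioplan",
         version = as.character(utils::packageVersion("prioplan")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seeds = seeds, config = config, statuses = statuses),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
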