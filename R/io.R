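# File formats. Conventions in files: 0-based frame indices, 0-based pixel
# coordinates (x-right / y-down), angles in degrees.

validate_annotation <- function(ann) {
  if (!is.list(ann)) stop_invalid("annotation must be a list")
  for (f in c("fps", "pixel_pitch", "frames")) {
    if (is.null(ann[[f]]))
      stop_invalid("annotation schema violation at $%s: field missing",
                   if (f == "pixel_pitch") "pixel_pitch_mm" else f)
  }
  if (!is_scalar_number(ann$pixel_pitch) || ann$pixel_pitch <= 0)
    stop_invalid("annotation schema violation at $pixel_pitch_mm: must be a positive number")
  if (!length(ann$frames)) stop_invalid("annotation schema violation at $frames: empty")
  n_aca <- vapply(seq_along(ann$frames), function(i) {
    fr <- ann$frames[[i]]
    if (is.null(fr$aca)) stop_invalid("annotation schema violation at $frames[%d]$aca: missing", i)
    nrow(as_points(fr$aca))
  }, integer(1))
  if (length(unique(n_aca)) != 1L)
    stop_invalid("annotation schema violation: ACA point count differs across frames")
  invisible(ann)
}

#' Read and write landmark annotations
#'
#' JSON schema: `{video_id, fps, pixel_pitch_mm, frames: [{idx, margin:
#' [[x,y],[x,y]], aca: [[x,y],...]}]}` with 0-based frame indices and
#' 0-based x-right/y-down pixel coordinates. `write_annotation()` followed by
#' `read_annotation()` is the identity.
#'
#' @param path Path to a `.json` file.
#' @return A `landmark_annotation` list with `video_id`, `fps`,
#'   `pixel_pitch` (mm/px) and per-frame `margin` (2 x 2 matrix) and `aca`
#'   (m x 2 matrix) coordinates.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_invalid("annotation file '%s' not found", path)
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(j$pixel_pitch_mm))
    stop_invalid("annotation schema violation at $pixel_pitch_mm: field missing")
  to_pts <- function(x) {
    if (is.matrix(x)) as_points(x)
    else as_points(do.call(rbind, lapply(x, as.numeric)))
  }
  frames <- lapply(j$frames, function(fr) {
    if (is.null(fr$idx)) stop_invalid("annotation schema violation at $frames[]$idx: missing")
    list(idx = as.integer(fr$idx),
         margin = if (!is.null(fr$margin)) to_pts(fr$margin) else NULL,
         aca = to_pts(fr$aca))
  })
  ann <- structure(list(video_id = j$video_id %||% "video",
                        fps = j$fps, pixel_pitch = j$pixel_pitch_mm,
                        frames = frames),
                   class = "landmark_annotation")
  validate_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param ann A `landmark_annotation` (as produced by [render_video()]).
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  frames <- lapply(ann$frames, function(fr) {
    out <- list(idx = fr$idx,
                aca = unname(lapply(seq_len(nrow(fr$aca)), function(r) fr$aca[r, ])))
    if (!is.null(fr$margin))
      out$margin <- unname(lapply(1:2, function(r) fr$margin[r, ]))
    out
  })
  jsonlite::write_json(list(video_id = ann$video_id, fps = ann$fps,
                            pixel_pitch_mm = ann$pixel_pitch, frames = frames),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write grayscale frame stacks
#'
#' Frames are stored as zero-padded 8-bit grayscale PNG files
#' (`frame_0000.png`, ...) in a directory; intensities are in `[0, 1]`. The
#' PNG round trip is lossless at 8-bit quantisation.
#'
#' @param frames An `H x W x N` array or list of matrices with values in
#'   `[0, 1]`.
#' @param dir Directory for the PNG files (created if missing).
#' @return `read_frames()` returns an `H x W x N` array.
#' @export
write_frames <- function(frames, dir) {
  fl <- frames_as_list(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fl)) {
    img <- pmin(pmax(fl[[i]], 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  if (!dir.exists(dir)) stop_invalid("frame directory '%s' not found", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_invalid("no PNG frames found in '%s'", dir)
  imgs <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("mixed frame sizes in '%s'", dir)
  array(unlist(imgs), dim = c(dims[1, 1], dims[2, 1], length(imgs)))
}

#' Read and write trajectory CSV files
#'
#' Columns: `frame` (0-based), `t_s`, `pd_mm`.
#'
#' @param traj A [pupil_trajectory()].
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pupil_trajectory"))
  utils::write.csv(data.frame(frame = traj$frame, t_s = traj$t, pd_mm = traj$pd),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param video_id Identifier for the loaded trajectory.
#' @export
read_trajectory <- function(path, video_id = NULL) {
  d <- utils::read.csv(path)
  for (cn in c("frame", "t_s", "pd_mm"))
    if (is.null(d[[cn]])) stop_invalid("trajectory CSV is missing column '%s'", cn)
  fps <- 1 / stats::median(diff(d$t_s))
  pupil_trajectory(d$pd_mm, fps = fps, t = d$t_s,
                   video_id = video_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write per-frame transforms and alignment residuals
#'
#' @param report The `report` data frame from [align_video()] (columns
#'   `frame`, `theta_deg`, `tx_px`, `ty_px`, `rms_pre`, `rms_post`).
#' @param path CSV path.
#' @export
write_transforms <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Resolved pipeline configuration
#'
#' Collects every tunable of the pipeline stages. A resolved copy is written
#' next to any [run_pipeline()] output so runs are reproducible from config
#' plus seed; the JSON round trip is lossless.
#'
#' @param dataset A [dataset_config()].
#' @param v_on,k Constriction-onset rule (see
#'   [detect_constriction_window()]).
#' @param abscissa,fit_span Quadratic-fit options (see
#'   [kinematic_summary()]).
#' @param variant,alpha Group-statistics options.
#' @param cv_k,cv_seed,ci_B,threshold,l2 Evaluation options.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = dataset_config(), v_on = 0.1, k = 2,
                            abscissa = "seconds", fit_span = "window",
                            variant = "student_pooled", alpha = 0.05,
                            cv_k = 5, cv_seed = 42L, ci_B = 2000L,
                            threshold = 0.5, l2 = 1e-2) {
  structure(list(dataset = dataset, v_on = v_on, k = k, abscissa = abscissa,
                 fit_span = fit_span, variant = variant, alpha = alpha,
                 cv_k = cv_k, cv_seed = cv_seed, ci_B = ci_B,
                 threshold = threshold, l2 = l2),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to serialise.
#' @param path JSON (or YAML, if the yaml package is installed) config path.
#' @export
write_config <- function(config, path) {
  u <- unclass(config)
  u$dataset <- unclass(u$dataset)
  u$dataset$geometry <- unclass(u$dataset$geometry)
  u$dataset$jitter <- unclass(u$dataset$jitter)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("the yaml package is required for YAML configs")
    yaml::write_yaml(u, path)
  } else {
    jsonlite::write_json(u, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  u <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  ds <- u$dataset
  cfg <- pipeline_config(
    dataset = dataset_config(
      n_closure = ds$n_closure, n_normal = ds$n_normal, dialect = ds$dialect,
      fps = ds$fps, record_len = ds$record_len,
      geometry = do.call(scene_geometry, ds$geometry[names(ds$geometry) %in%
        names(formals(scene_geometry))]),
      jitter = jitter_params(ds$jitter$rot_sd, ds$jitter$shift_sd, ds$jitter$seed),
      render = ds$render, seed = ds$seed),
    v_on = u$v_on, k = u$k, abscissa = u$abscissa, fit_span = u$fit_span,
    variant = u$variant, alpha = u$alpha, cv_k = u$cv_k, cv_seed = u$cv_seed,
    ci_B = u$ci_B, threshold = u$threshold, l2 = u$l2)
  cfg
}
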