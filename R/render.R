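#' Scene geometry for schematic AS-OCT B-scan frames
#'
#' Describes the schematic anterior-segment scene rendered by
#' [render_video()]: a bright corneal arc, a horizontal iris band broken by
#' the pupil gap, and the two anterior-chamber-angle (ACA) corners where the
#' arc meets the iris plane. The rendering is a geometric stand-in for real
#' B-scans: downstream stages consume the landmark coordinates, not the
#' intensities.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param pixel_pitch Physical pixel size in mm/px.
#' @param iris_center (x, y) pixel coordinates of the pupil centre on the
#'   iris plane (0-based, x-right / y-down).
#' @param iris_thickness Iris band thickness in px.
#' @param cornea_apex_y,cornea_curv Corneal arc `y = apex + curv * (x - cx)^2`.
#' @param aca_left,aca_right (x, y) coordinates of the true ACA corners.
#' @return An object of class `scene_geometry`.
#' @export
scene_geometry <- function(frame_width = 240, frame_height = 160,
                           pixel_pitch = 0.05,
                           iris_center = c(120, 100), iris_thickness = 14,
                           cornea_apex_y = 20, cornea_curv = 0.0073,
                           aca_left = c(20, 93), aca_right = c(220, 93)) {
  if (!is_scalar_number(pixel_pitch) || pixel_pitch <= 0)
    stop_invalid("`pixel_pitch` must be positive")
  geom <- list(frame_width = as.integer(frame_width),
               frame_height = as.integer(frame_height),
               pixel_pitch = pixel_pitch,
               iris_center = as.numeric(iris_center),
               iris_thickness = iris_thickness,
               cornea_apex_y = cornea_apex_y, cornea_curv = cornea_curv,
               aca_left = as.numeric(aca_left), aca_right = as.numeric(aca_right))
  for (p in list(geom$aca_left, geom$aca_right)) {
    if (p[1] < 0 || p[1] > frame_width - 1 || p[2] < 0 || p[2] > frame_height - 1)
      stop_invalid("ACA corners must lie inside the frame bounds")
  }
  structure(geom, class = "scene_geometry")
}

#' Per-frame rigid jitter parameters
#'
#' Models involuntary eye movement during recording as an independent rigid
#' perturbation of every frame: a rotation about the image centre with
#' standard deviation `rot_sd` degrees and a translation with standard
#' deviation `shift_sd` px per axis.
#'
#' @param rot_sd Rotation SD in degrees (>= 0).
#' @param shift_sd Translation SD in px (>= 0).
#' @param seed Integer seed controlling the jitter (and speckle) draw.
#' @return An object of class `jitter_params`.
#' @export
jitter_params <- function(rot_sd = 1, shift_sd = 3, seed = 1L) {
  if (!is_scalar_number(rot_sd) || rot_sd < 0) stop_invalid("`rot_sd` must be >= 0")
  if (!is_scalar_number(shift_sd) || shift_sd < 0) stop_invalid("`shift_sd` must be >= 0")
  structure(list(rot_sd = rot_sd, shift_sd = shift_sd, seed = as.integer(seed)),
            class = "jitter_params")
}

# Render the clean (un-jittered) frame for a pupil gap of g px.
render_scene <- function(g, geom, speckle) {
  h <- geom$frame_height; w <- geom$frame_width
  cx <- geom$iris_center[1]; cy <- geom$iris_center[2]
  img <- speckle
  # iris band with pupil gap: columns x_l <= c < x_r are dark
  rows <- which(abs((0:(h - 1)) - cy) <= geom$iris_thickness / 2)
  x_l <- cx - g / 2; x_r <- cx + g / 2
  cols <- 0:(w - 1)
  iris_cols <- which(!(cols >= x_l & cols < x_r))
  img[rows, iris_cols] <- 0.8
  # corneal arc, ~2 px thick
  arc_y <- geom$cornea_apex_y + geom$cornea_curv * (cols - cx)^2
  for (j in seq_along(cols)) {
    rr <- round(arc_y[j]) + (0:1)
    rr <- rr[rr >= 0 & rr <= h - 1]
    img[rr + 1, j] <- 0.9
  }
  img
}

#' Render a schematic AS-OCT video with ground-truth landmarks
#'
#' Draws, for every frame of the trajectory, a schematic B-scan whose iris
#' band is broken by a pupil gap of `round(pd / pixel_pitch)` px centred on
#' the iris centre, then perturbs the frame by a sampled rigid jitter
#' transform. The returned annotation holds the true post-jitter
#' pupillary-margin and ACA-corner coordinates, and the true per-frame
#' transforms are returned alongside.
#'
#' @param traj A [pupil_trajectory()].
#' @param geom A [scene_geometry()].
#' @param jitter A [jitter_params()]; `rot_sd = shift_sd = 0` renders a
#'   perfectly still video.
#' @return A list of class `oct_video`: `frames` (H x W x N array in `[0,1]`),
#'   `annotation` (see [read_annotation()] for the schema) and `transforms`
#'   (list of the injected [rigid_transform()]s).
#' @export
render_video <- function(traj, geom = scene_geometry(), jitter = jitter_params()) {
  stopifnot(inherits(traj, "pupil_trajectory"), inherits(geom, "scene_geometry"),
            inherits(jitter, "jitter_params"))
  n <- nrow(traj)
  g_all <- round(traj$pd / geom$pixel_pitch)
  if (any(g_all >= geom$frame_width))
    stop_invalid("pupil gap (%d px) exceeds the frame width (%d px)",
                 max(g_all), geom$frame_width)
  h <- geom$frame_height; w <- geom$frame_width
  cx <- geom$iris_center[1]; cy <- geom$iris_center[2]
  centre <- c((w - 1) / 2, (h - 1) / 2)
  with_seed(jitter$seed, {
    speckle <- matrix(0.05 + 0.08 * stats::runif(h * w), h, w)
    thetas <- stats::rnorm(n, 0, jitter$rot_sd)
    shifts <- matrix(stats::rnorm(2 * n, 0, jitter$shift_sd), n, 2)
  })
  frames <- array(0, dim = c(h, w, n))
  transforms <- vector("list", n)
  ann_frames <- vector("list", n)
  for (i in seq_len(n)) {
    g <- g_all[i]
    clean <- render_scene(g, geom, speckle)
    # rotation about the image centre expressed as an origin-centred transform
    R <- rot_matrix(thetas[i])
    t_eff <- centre - as.vector(R %*% centre) + shifts[i, ]
    T_i <- rigid_transform(thetas[i], t_eff[1], t_eff[2])
    transforms[[i]] <- T_i
    frames[, , i] <- warp_frame(clean, T_i, interp = "bilinear", fill = 0.05)
    margin <- rbind(c(cx - g / 2, cy), c(cx + g / 2, cy))
    aca <- rbind(geom$aca_left, geom$aca_right)
    ann_frames[[i]] <- list(idx = i - 1L,
                            margin = apply_transform(T_i, margin),
                            aca = apply_transform(T_i, aca))
  }
  ann <- structure(list(video_id = attr(traj, "video_id"),
                        fps = attr(traj, "fps"),
                        pixel_pitch = geom$pixel_pitch,
                        frames = ann_frames),
                   class = "landmark_annotation")
  structure(list(frames = frames, annotation = ann, transforms = transforms),
            class = "oct_video")
}

#' Dataset configuration for the synthetic generator
#'
#' @param n_closure,n_normal Number of angle-closure / normal videos.
#' @param dialect Device dialect setting the frame rate: `"casia"` (8 fps)
#'   or `"zeiss"` (14 fps recording rate).
#' @param fps Frames per second; overrides the dialect when given.
#' @param record_len Recording length in seconds.
#' @param geometry A [scene_geometry()].
#' @param jitter A [jitter_params()].
#' @param render Render frame stacks (`TRUE`) or generate trajectories and
#'   landmark-free manifests only.
#' @param seed Master seed; the dataset is byte-reproducible given the seed.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(n_closure = 159, n_normal = 210,
                           dialect = c("casia", "zeiss"), fps = NULL,
                           record_len = 7.5, geometry = scene_geometry(),
                           jitter = jitter_params(), render = TRUE, seed = 1L) {
  dialect <- match.arg(dialect)
  if (n_closure < 0 || n_normal < 0) stop_invalid("video counts must be >= 0")
  fps <- fps %||% switch(dialect, casia = 8, zeiss = 14)
  structure(list(n_closure = as.integer(n_closure), n_normal = as.integer(n_normal),
                 dialect = dialect, fps = fps, record_len = record_len,
                 geometry = geometry, jitter = jitter, render = isTRUE(render),
                 seed = as.integer(seed)),
            class = "dataset_config")
}

#' Generate a synthetic AS-OCT video dataset on disk
#'
#' Draws subject parameters from the two group presets, simulates
#' trajectories (and, when `config$render` is `TRUE`, schematic frame
#' stacks), and writes a dataset directory: `manifest.csv` (columns
#' `video_id`, `label`, `fps`, `n_frames`, `preset`, `format`), one
#' trajectory CSV and one annotation JSON per video, and per-video PNG frame
#' directories when rendering. Fully reproducible from `config$seed`.
#'
#' @param config A [dataset_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the manifest data frame, the trajectories
#'   and (when rendered) per-video lists holding the `annotation`, the true
#'   `transforms` and the on-disk `frames_dir`.
#' @export
make_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "dataset_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_invalid("cannot create output directory '%s'", out_dir)
  labels <- c(rep("angle_closure", config$n_closure), rep("normal", config$n_normal))
  n <- length(labels)
  params <- c(
    if (config$n_closure > 0)
      sample_group_params("angle_closure", config$n_closure, seed = config$seed) else list(),
    if (config$n_normal > 0)
      sample_group_params("normal", config$n_normal, seed = config$seed + 1L) else list())
  manifest <- data.frame(video_id = character(0), label = character(0),
                         fps = numeric(0), n_frames = integer(0),
                         preset = character(0), format = character(0))
  trajectories <- vector("list", n)
  videos <- if (config$render) vector("list", n) else NULL
  for (i in seq_len(n)) {
    vid <- sprintf("video_%03d", i)
    traj <- simulate_trajectory(params[[i]], fps = config$fps,
                                record_len = config$record_len,
                                seed = config$seed + 100L + i, video_id = vid)
    trajectories[[i]] <- traj
    write_trajectory(traj, file.path(out_dir, paste0(vid, "_trajectory.csv")))
    fmt <- "trajectory_csv"
    if (config$render) {
      jit <- jitter_params(config$jitter$rot_sd, config$jitter$shift_sd,
                           seed = config$seed + 10000L + i)
      vid_obj <- render_video(traj, config$geometry, jit)
      write_annotation(vid_obj$annotation, file.path(out_dir, paste0(vid, "_annotation.json")))
      frames_dir <- file.path(out_dir, paste0(vid, "_frames"))
      write_frames(vid_obj$frames, frames_dir)
      # frames stay on disk; keeping whole cohorts of stacks in memory is
      # what the per-video PNG layout is there to avoid
      videos[[i]] <- list(annotation = vid_obj$annotation,
                          transforms = vid_obj$transforms,
                          frames_dir = frames_dir)
      fmt <- "png_dir"
    }
    manifest <- rbind(manifest, data.frame(
      video_id = vid, label = labels[i], fps = config$fps,
      n_frames = nrow(traj), preset = labels[i], format = fmt))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, trajectories = trajectories, videos = videos))
}
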