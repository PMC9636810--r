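#' 2D rigid transform
#'
#' Rotation about the image origin (pixel (0,0), x-right / y-down, angle in
#' degrees, mathematically positive) followed by a translation in pixels.
#'
#' @param theta Rotation angle in degrees.
#' @param tx,ty Translation components in pixels.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0) {
  stopifnot(is_scalar_number(theta), is_scalar_number(tx), is_scalar_number(ty))
  structure(list(theta = theta, tx = tx, ty = ty), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: theta = %.4f deg, t = (%.4f, %.4f) px\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

rot_matrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param pts An n x 2 matrix of (x, y) pixel coordinates.
#' @return The transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, pts) {
  stopifnot(inherits(transform, "rigid_transform"))
  pts <- as_points(pts)
  out <- pts %*% t(rot_matrix(transform$theta))
  out[, 1] <- out[, 1] + transform$tx
  out[, 2] <- out[, 2] + transform$ty
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- rot_matrix(transform$theta)
  t_inv <- -crossprod(R, c(transform$tx, transform$ty))
  rigid_transform(-transform$theta, t_inv[1], t_inv[2])
}

#' @rdname apply_transform
#' @param first,second Transforms; the composition applies `first`, then
#'   `second`.
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  t2 <- apply_transform(second, matrix(c(first$tx, first$ty), 1, 2))
  th <- second$theta + first$theta
  th <- ((th + 180) %% 360) - 180
  rigid_transform(th, t2[1], t2[2])
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = TRUE)
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop_invalid("points must be an n x 2 matrix")
  storage.mode(pts) <- "double"
  pts
}

#' Least-squares rigid transform between point sets
#'
#' Closed-form (Procrustes/Kabsch) estimate of the rotation + translation
#' (no scaling, no reflection) minimising the mean squared distance between
#' `transform(src)` and `dst`. With a single point pair the rotation is 0
#' and the transform is the pure translation.
#'
#' @param src,dst Matching n x 2 point matrices.
#' @return A [rigid_transform()].
#' @export
estimate_rigid <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) stop_invalid("`src` and `dst` must have the same number of points")
  if (nrow(src) < 1L) stop_invalid("at least one point pair is required")
  if (nrow(src) == 1L) {
    d <- dst[1, ] - src[1, ]
    return(rigid_transform(0, d[1], d[2]))
  }
  sc <- colMeans(src); dc <- colMeans(dst)
  s0 <- sweep(src, 2, sc); d0 <- sweep(dst, 2, dc)
  if (all(abs(s0) < 1e-12))
    stop_invalid("degenerate geometry: all source points coincide, rotation is unidentifiable")
  H <- crossprod(s0, d0)
  sv <- svd(H)
  S <- diag(c(1, det(sv$v %*% t(sv$u))))
  R <- sv$v %*% S %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t_vec <- dc - R %*% sc
  rigid_transform(theta, t_vec[1], t_vec[2])
}

#' Warp a frame by a rigid transform
#'
#' Resamples the input frame so that scene content is moved by `transform`
#' (forward convention: output pixel `x` takes the intensity at
#' `transform^{-1}(x)`). Samples falling outside the input take `fill`.
#'
#' @param frame A numeric matrix (rows = y, columns = x, intensities in any
#'   range).
#' @param transform A [rigid_transform()].
#' @param interp `"bilinear"` (default) or `"nearest"`; the identity
#'   transform under nearest interpolation returns the input bit-exactly.
#' @param fill Intensity for out-of-bounds samples.
#' @return A matrix of the same shape as `frame`.
#' @export
warp_frame <- function(frame, transform, interp = c("bilinear", "nearest"),
                       fill = 0) {
  stopifnot(is.matrix(frame), inherits(transform, "rigid_transform"))
  interp <- match.arg(interp)
  h <- nrow(frame); w <- ncol(frame)
  inv <- invert_transform(transform)
  # 0-based pixel-centre coordinates of every output pixel
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  src <- apply_transform(inv, cbind(gx, gy))
  sx <- src[, 1]; sy <- src[, 2]
  out <- rep(fill, h * w)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    out[ok] <- frame[cbind(iy[ok] + 1, ix[ok] + 1)]
  } else {
    ok <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
    # clamp floors so the exact right/bottom edge falls in the last cell
    x0k <- pmin(floor(sx[ok]), w - 2); y0k <- pmin(floor(sy[ok]), h - 2)
    fxk <- sx[ok] - x0k; fyk <- sy[ok] - y0k
    v00 <- frame[cbind(y0k + 1, x0k + 1)]
    v10 <- frame[cbind(y0k + 1, x0k + 2)]
    v01 <- frame[cbind(y0k + 2, x0k + 1)]
    v11 <- frame[cbind(y0k + 2, x0k + 2)]
    out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v10 * fxk * (1 - fyk) +
      v01 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  matrix(out, h, w)
}

#' Align all frames of a video to a reference frame
#'
#' For each frame the rigid transform taking its marked anterior-chamber-angle
#' (ACA) landmarks onto those of the reference frame is estimated with
#' [estimate_rigid()] and applied with [warp_frame()]. The residual report
#' gives the pre- and post-alignment RMS ACA-landmark distance to the
#' reference; least-squares alignment can never increase it.
#'
#' @param frames A list of matrices or an `H x W x N` array.
#' @param ann A landmark annotation covering all frames.
#' @param reference 1-based index of the reference frame (default the first).
#' @param interp Interpolation passed to [warp_frame()].
#' @return List with `frames` (aligned, same container as input),
#'   `transforms` (list of [rigid_transform()]) and `report` (data frame
#'   with 0-based `frame`, `theta_deg`, `tx_px`, `ty_px`, `rms_pre`,
#'   `rms_post`).
#' @export
align_video <- function(frames, ann, reference = 1L, interp = "bilinear") {
  frames_list <- frames_as_list(frames)
  validate_annotation(ann)
  n <- length(frames_list)
  if (length(ann$frames) != n)
    stop_invalid("annotation covers %d frames but the video has %d",
                 length(ann$frames), n)
  if (reference < 1 || reference > n) stop_invalid("reference frame out of range")
  aca_ref <- as_points(ann$frames[[reference]]$aca)
  transforms <- vector("list", n)
  report <- data.frame(frame = seq_len(n) - 1L, theta_deg = NA_real_,
                       tx_px = NA_real_, ty_px = NA_real_,
                       rms_pre = NA_real_, rms_post = NA_real_)
  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    aca_i <- as_points(ann$frames[[i]]$aca)
    T_i <- tryCatch(estimate_rigid(aca_i, aca_ref), error = function(e)
      stop_invalid("frame %d: %s", i - 1L, conditionMessage(e)))
    transforms[[i]] <- T_i
    moved <- apply_transform(T_i, aca_i)
    report$theta_deg[i] <- T_i$theta
    report$tx_px[i] <- T_i$tx
    report$ty_px[i] <- T_i$ty
    report$rms_pre[i] <- sqrt(mean((aca_i - aca_ref)^2))
    report$rms_post[i] <- sqrt(mean((moved - aca_ref)^2))
    aligned[[i]] <- warp_frame(frames_list[[i]], T_i, interp = interp)
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    aligned <- array(unlist(aligned), dim = dim(frames))
  }
  list(frames = aligned, transforms = transforms, report = report)
}

frames_as_list <- function(frames) {
  if (is.list(frames)) {
    stopifnot(all(vapply(frames, is.matrix, logical(1))))
    return(frames)
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    return(lapply(seq_len(dim(frames)[3]), function(i) frames[, , i]))
  }
  stop_invalid("`frames` must be a list of matrices or an H x W x N array")
}
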