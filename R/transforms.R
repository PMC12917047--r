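#' Rigid transforms
#'
#' A rigid transform is a rotation (3x3 orthonormal matrix, determinant +1)
#' followed by a translation, mapping coordinates in micrometres. 2D problems
#' are embedded in 3D with rotation about the z axis, so the same machinery
#' serves planar fibre movies and 3D intravital stacks.
#'
#' @param rotation 3x3 orthonormal rotation matrix with det +1.
#' @param translation numeric length-3 translation in um.
#' @param frame optional integer frame index the transform belongs to.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            frame = NA_integer_) {
  rotation <- as.matrix(rotation)
  if (nrow(rotation) == 2L && ncol(rotation) == 2L) {
    R3 <- diag(3)
    R3[1:2, 1:2] <- rotation
    rotation <- R3
  }
  translation <- as.numeric(translation)
  if (length(translation) == 2L) translation <- c(translation, 0)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must have determinant +1 (no reflection)")
  structure(list(rotation = rotation, translation = translation,
                 frame = as.integer(frame)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform", if (!is.na(x$frame)) paste0("frame ", x$frame), ">\n")
  cat("  rotation angle (z):", format(rotation_angle_deg(x), digits = 6),
      "deg\n")
  cat("  translation:", paste(format(x$translation, digits = 6),
                              collapse = ", "), "um\n")
  invisible(x)
}

#' Planar rotation helper
#'
#' Builds a rigid transform rotating by `angle_deg` about the z axis through
#' `centre`, then translating by `translation`.
#'
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @param translation length-2 or -3 translation in um.
#' @param centre length-2 or -3 centre of rotation in um.
#' @param frame optional frame index.
#' @export
planar_transform <- function(angle_deg = 0, translation = c(0, 0, 0),
                             centre = c(0, 0, 0), frame = NA_integer_) {
  th <- angle_deg * pi / 180
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (length(centre) == 2L) centre <- c(centre, 0)
  if (length(translation) == 2L) translation <- c(translation, 0)
  # rotate about `centre`: x -> R (x - c) + c + t
  rigid_transform(R, as.numeric(centre - R %*% centre + translation), frame)
}

#' Rotation angle about z, in degrees
#' @param tf a `rigid_transform`.
#' @export
rotation_angle_deg <- function(tf) {
  atan2(tf$rotation[2, 1], tf$rotation[1, 1]) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param xyz numeric matrix (n x 2 or n x 3) or length-2/3 vector of
#'   coordinates in um.
#' @return n x 3 matrix of transformed coordinates.
#' @export
rt_apply <- function(tf, xyz) {
  xyz <- to_xyz(xyz)
  t(tf$rotation %*% t(xyz)) + rep(tf$translation, each = nrow(xyz))
}

#' Compose rigid transforms: `rt_compose(a, b)` applies `b` first, then `a`
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  frame = a$frame)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @export
rt_invert <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$translation), frame = tf$frame)
}

to_xyz <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  if (ncol(p) == 2L) p <- cbind(p, 0)
  stopifnot(ncol(p) == 3L)
  storage.mode(p) <- "double"
  p
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Kabsch/Procrustes estimate of the rigid transform minimising
#' sum ||T(moving_i) - fixed_i||^2 over rotations with determinant +1.
#' Used frame-to-frame on landmark series (e.g. ~50 manually tracked fixed
#' points such as blood vessels in intravital movies).
#'
#' @param moving,fixed n x 2 or n x 3 matrices of corresponding points (um),
#'   same row order.
#' @param frame optional frame index stored on the result.
#' @return `rigid_transform` with attributes `rms` (root-mean-square residual,
#'   um) and `n_points`.
#' @export
estimate_rigid_from_points <- function(moving, fixed, frame = NA_integer_) {
  moving <- to_xyz(moving); fixed <- to_xyz(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("moving and fixed must contain the same number of points")
  n <- nrow(moving)
  if (n < 2L) stop("at least 2 corresponding point pairs are required")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("point coordinates must be finite")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  if (max(abs(A)) < 1e-12 && max(abs(B)) < 1e-12) {
    # all points coincident: pure translation
    tf <- rigid_transform(diag(3), cf - cm, frame)
    attr(tf, "rms") <- 0; attr(tf, "n_points") <- n
    return(tf)
  }
  H <- crossprod(A, B)              # 3x3 covariance
  # degenerate in 3D: points spanning < 2 dimensions leave the rotation
  # about the spanned axis unconstrained
  sv_a <- svd(A, nu = 0, nv = 0)$d
  planar <- max(abs(A[, 3])) < 1e-12 && max(abs(B[, 3])) < 1e-12
  if (!planar && sv_a[2] < 1e-9 * max(sv_a[1], 1))
    stop("degenerate configuration: points are collinear, ",
         "3D rotation is not identifiable")
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tf <- rigid_transform(R, cf - as.numeric(R %*% cm), frame)
  res <- rt_apply(tf, moving) - fixed
  attr(tf, "rms") <- sqrt(mean(rowSums(res^2)))
  attr(tf, "n_points") <- n
  tf
}

#' Moment-based rigid registration of binary masks
#'
#' Aligns a segmented-fibre mask to a reference mask by matching centroids and
#' principal axes of the second central moments. The 180-degree ambiguity of
#' the principal axis is resolved by picking the rotation with the smaller
#' angle (inter-frame fibre motion is assumed well below 90 degrees).
#' Near-isotropic masks (axis ratio < 1.05) carry no orientation information:
#' a translation-only transform is returned with attribute
#' `translation_only = TRUE`.
#'
#' @param mask_t,mask_ref binary (0/1 or logical) matrices; rows index y,
#'   columns index x.
#' @param pixel_size_um physical pixel size in um (isotropic).
#' @param frame optional frame index.
#' @return `rigid_transform` mapping mask_t coordinates (um) onto mask_ref.
#' @export
estimate_rigid_from_masks <- function(mask_t, mask_ref, pixel_size_um = 1,
                                      frame = NA_integer_) {
  m1 <- mask_moments(mask_t); m0 <- mask_moments(mask_ref)
  translation_only <- m1$axis_ratio < 1.05 || m0$axis_ratio < 1.05
  angle <- if (translation_only) 0 else {
    a <- (m0$theta - m1$theta) %% pi
    if (a > pi / 2) a <- a - pi          # minimal-rotation branch
    a
  }
  th <- angle
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  c1 <- m1$centroid * pixel_size_um
  c0 <- m0$centroid * pixel_size_um
  tf <- rigid_transform(R2, c(c0 - as.numeric(R2 %*% c1), 0), frame)
  attr(tf, "translation_only") <- translation_only
  tf
}

mask_moments <- function(mask) {
  mask <- as.matrix(mask)
  if (is.logical(mask)) mask <- mask * 1
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  x <- idx[, 2]; y <- idx[, 1]          # x = column, y = row
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  cov <- matrix(c(mxx, mxy, mxy, myy), 2, 2)
  e <- eigen(cov, symmetric = TRUE)
  ratio <- sqrt(max(e$values[1], 0) / max(e$values[2], .Machine$double.eps))
  theta <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
  list(centroid = c(cx, cy), theta = theta, axis_ratio = ratio)
}

#' Accumulate frame-to-previous transforms into frame-to-reference transforms
#'
#' Registration is computed iteratively, each frame aligned to the previous
#' one; composing the chain gives, for every frame, the transform into the
#' frame-0 (reference) coordinate system: C_t = C_(t-1) o T_t, C_0 = identity.
#'
#' @param transforms list of `rigid_transform`, each carrying `frame` in
#'   1..T, mapping frame-t coordinates onto frame-(t-1) coordinates. Every
#'   intermediate frame must be present.
#' @return list of T+1 `rigid_transform` for frames 0..T (frame 0 = identity),
#'   each mapping that frame's coordinates into the reference system.
#' @export
accumulate_transforms <- function(transforms) {
  if (length(transforms) == 0L) return(list(rigid_transform(frame = 0L)))
  frames <- vapply(transforms, function(tf) tf$frame, integer(1))
  if (anyNA(frames)) stop("every transform must carry a frame index")
  o <- order(frames)
  transforms <- transforms[o]; frames <- frames[o]
  expected <- seq_len(max(frames))
  missing <- setdiff(expected, frames)
  if (length(missing))
    stop("missing frame-to-previous transform for frame(s): ",
         paste(missing, collapse = ", "))
  out <- vector("list", max(frames) + 1L)
  out[[1]] <- rigid_transform(frame = 0L)
  for (t in seq_along(transforms)) {
    ct <- rt_compose(out[[t]], transforms[[t]])
    ct$frame <- frames[t]
    out[[t + 1L]] <- ct
  }
  out
}

#' Correct tracks into the static (reference-frame) referential
#'
#' Replaces each point p observed at frame f by C_f(p), expressing all
#' trajectories relative to the immobilised fibre or tissue. Annotations are
#' untouched.
#'
#' @param ts a [track_set].
#' @param transforms list of `rigid_transform` frame-to-reference transforms
#'   (as returned by [accumulate_transforms()]); matched to points by `frame`.
#' @return a corrected [track_set].
#' @export
correct_tracks <- function(ts, transforms) {
  stopifnot(inherits(ts, "track_set"))
  frames <- vapply(transforms, function(tf) tf$frame, integer(1))
  need <- sort(unique(ts$points$frame))
  missing <- setdiff(need, frames)
  if (length(missing))
    stop("no transform for frame(s): ", paste(missing, collapse = ", "))
  idx <- match(ts$points$frame, frames)
  pts <- as.matrix(ts$points[, c("x_um", "y_um", "z_um")])
  out <- pts
  for (k in sort(unique(idx))) {
    sel <- idx == k
    out[sel, ] <- rt_apply(transforms[[k]], pts[sel, , drop = FALSE])
  }
  ts$points$x_um <- out[, 1]; ts$points$y_um <- out[, 2]
  ts$points$z_um <- out[, 3]
  ts
}

#' Write / read a transform series as CSV
#'
#' Columns: frame, r11..r33 (row-major rotation), tx, ty, tz (um).
#' @param transforms list of `rigid_transform`.
#' @param path file path.
#' @export
write_transforms_csv <- function(transforms, path) {
  rows <- lapply(transforms, function(tf) {
    r <- t(tf$rotation)                 # row-major flatten
    c(frame = tf$frame, stats::setNames(as.numeric(r),
        c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")),
      tx = tf$translation[1], ty = tf$translation[2], tz = tf$translation[3])
  })
  df <- as.data.frame(do.call(rbind, rows))
  num <- setdiff(names(df), "frame")
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transforms_csv
#' @export
read_transforms_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                   "r31", "r32", "r33")]),
                3, 3, byrow = TRUE)
    rigid_transform(R, as.numeric(df[i, c("tx", "ty", "tz")]),
                    frame = df$frame[i])
  })
}

#' Landmark-series registration
#'
#' Estimates frame-to-previous rigid transforms from a labelled landmark
#' series (same label = same physical landmark), accumulates them into
#' frame-to-reference transforms, and flags frames whose residual exceeds
#' `residual_threshold_um` — such frames propagate the previous transform, and
#' the scene is marked excluded from motility analysis (it remains usable for
#' lineage analysis).
#'
#' @param landmarks tibble with columns frame, label, x_um, y_um and
#'   optionally z_um.
#' @param residual_threshold_um per-frame RMS residual (um) above which the
#'   frame's registration is treated as failed.
#' @return list with `correction` (frame-to-reference transform list),
#'   `rms` (per-frame residual tibble), `flagged_frames`, and
#'   `motility_excluded` (logical).
#' @export
register_landmarks <- function(landmarks, residual_threshold_um = 2) {
  stopifnot(all(c("frame", "label", "x_um", "y_um") %in% names(landmarks)))
  if (!"z_um" %in% names(landmarks)) landmarks$z_um <- 0
  frames <- sort(unique(landmarks$frame))
  per_frame <- split(landmarks, landmarks$frame)
  chain <- list(); rms <- numeric(0); flagged <- integer(0)
  prev_tf <- NULL
  for (i in seq_along(frames)[-1]) {
    cur <- per_frame[[as.character(frames[i])]]
    ref <- per_frame[[as.character(frames[i - 1])]]
    shared <- intersect(cur$label, ref$label)
    if (length(shared) < 3L)
      stop("fewer than 3 shared landmarks between frames ",
           frames[i - 1], " and ", frames[i])
    m <- as.matrix(cur[match(shared, cur$label), c("x_um", "y_um", "z_um")])
    f <- as.matrix(ref[match(shared, ref$label), c("x_um", "y_um", "z_um")])
    tf <- estimate_rigid_from_points(m, f, frame = frames[i])
    r <- attr(tf, "rms")
    if (r > residual_threshold_um) {
      # failed frame: carry the previous frame-to-previous transform forward
      flagged <- c(flagged, frames[i])
      tf <- if (is.null(prev_tf)) rigid_transform(frame = frames[i]) else {
        tf2 <- prev_tf; tf2$frame <- frames[i]; tf2
      }
    }
    prev_tf <- tf
    chain[[length(chain) + 1L]] <- tf
    rms <- c(rms, r)
  }
  list(correction = accumulate_transforms(chain),
       rms = tibble::tibble(frame = frames[-1], rms_um = rms),
       flagged_frames = flagged,
       motility_excluded = length(flagged) > 0L)
}
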