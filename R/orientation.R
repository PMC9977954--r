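#' @title Principal-axes orientation and ensemble analytics
#' @name orientation
#' @description
#' The relative orientation of the two partners is described with aircraft
#' pitch/roll/yaw angles. For each partner, a right-handed frame is built
#' from the principal components of its Calpha coordinates, eigenvalues in
#' descending order: the longitudinal axis is PC1 with its sign fixed toward
#' the centroid of user-chosen "nose" residues, the vertical axis is PC2 with
#' its sign fixed toward a reference direction (the membrane normal; by
#' default +z of the input coordinates), and the transverse axis completes
#' the right-handed frame. Solving X_receptor = R X_arrestin for the rotation
#' R, the angles are
#'
#'   pitch = atan2(-R31, sqrt(R11^2 + R21^2))
#'   roll  = atan2(R32 / cos(pitch), R33 / cos(pitch))
#'   yaw   = atan2(R21 / cos(pitch), R11 / cos(pitch))
#'
#' reported in degrees. Near-degenerate principal components (adjacent
#' eigenvalues within 1 percent) make the axis ordering unstable and raise a
#' warning.
NULL

#' Nose definition fixing the axis signs of a frame
#'
#' @param residues List of [residue_ref()]s whose centroid fixes the sign of
#'   the longitudinal axis (at least one).
#' @param reference Length-3 direction fixing the sign of the vertical axis
#'   (default `c(0, 0, 1)`, the membrane normal of the input file).
#' @return List of class `xl_nose`.
#' @export
nose_definition <- function(residues, reference = c(0, 0, 1)) {
  if (!length(residues)) stop("at least one nose residue required",
                              call. = FALSE)
  if (sqrt(sum(reference^2)) < 1e-12)
    stop("reference direction must be non-zero", call. = FALSE)
  out <- list(residues = residues, reference = reference)
  class(out) <- "xl_nose"
  out
}

#' Principal-axes frame of a coordinate set
#'
#' @param xyz n x 3 Calpha coordinate matrix (n >= 3, non-collinear).
#' @param nose_centroid Length-3 point toward which the longitudinal axis
#'   points (centroid of the nose residues).
#' @param reference Length-3 direction fixing the vertical-axis sign.
#' @param tie_tol Relative eigenvalue gap below which a degeneracy warning is
#'   raised (default 0.01).
#' @return List of class `xl_frame`: `origin` (centroid) and `axes`, a 3 x 3
#'   matrix whose columns are the longitudinal, vertical and transverse unit
#'   vectors (right-handed).
#' @export
principal_frame <- function(xyz, nose_centroid, reference = c(0, 0, 1),
                            tie_tol = 0.01) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("need at least 3 points", call. = FALSE)
  origin <- colMeans(xyz)
  centered <- sweep(xyz, 2, origin)
  ev <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)
  if (ev$values[2] <= 1e-10 * max(ev$values[1], 1))
    stop("degenerate (collinear) coordinates: principal frame undefined",
         call. = FALSE)
  gaps <- abs(diff(ev$values)) / pmax(ev$values[-3], .Machine$double.eps)
  if (any(gaps < tie_tol))
    warning("near-tied principal components (gap < ", tie_tol * 100,
            "%): axis ordering may be unstable", call. = FALSE)
  long <- ev$vectors[, 1]
  if (sum(long * (nose_centroid - origin)) < 0) long <- -long
  vert <- ev$vectors[, 2]
  if (sum(vert * reference) < 0) vert <- -vert
  trans <- c(long[2] * vert[3] - long[3] * vert[2],
             long[3] * vert[1] - long[1] * vert[3],
             long[1] * vert[2] - long[2] * vert[1])
  out <- list(origin = origin, axes = cbind(longitudinal = long,
                                            vertical = vert,
                                            transverse = trans))
  class(out) <- "xl_frame"
  out
}

check_rotation <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a proper rotation (orthonormal, det +1)",
         call. = FALSE)
  invisible(R)
}

#' Rotation aligning the arrestin frame onto the receptor frame
#'
#' @param frame_receptor,frame_arrestin `xl_frame` objects (or 3 x 3 axis
#'   matrices with axes as columns).
#' @return 3 x 3 rotation `R` solving `X_receptor = R X_arrestin`.
#' @export
relative_rotation <- function(frame_receptor, frame_arrestin) {
  Xr <- if (inherits(frame_receptor, "xl_frame")) frame_receptor$axes
        else frame_receptor
  Xa <- if (inherits(frame_arrestin, "xl_frame")) frame_arrestin$axes
        else frame_arrestin
  check_rotation(unname(Xr)); check_rotation(unname(Xa))
  R <- Xr %*% t(Xa)
  check_rotation(R)
  R
}

#' Pitch, roll and yaw of a rotation matrix
#'
#' Aircraft-convention angles in degrees: pitch in `[-90, 90]`, roll and yaw
#' in `(-180, 180]`. At gimbal lock (`|cos(pitch)| < 1e-8`) the roll is set
#' to 0, the remaining rotation is folded into the yaw, and the result is
#' flagged with attribute `gimbal = TRUE`.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return Named numeric vector `c(pitch, roll, yaw)` in degrees.
#' @export
euler_angles <- function(R) {
  check_rotation(unname(R))
  deg <- 180 / pi
  beta <- atan2(-R[3, 1], sqrt(R[1, 1]^2 + R[2, 1]^2))
  gimbal <- abs(cos(beta)) < 1e-8
  if (gimbal) {
    gamma <- 0
    alpha <- atan2(-R[1, 2], R[2, 2])
  } else {
    gamma <- atan2(R[3, 2] / cos(beta), R[3, 3] / cos(beta))
    alpha <- atan2(R[2, 1] / cos(beta), R[1, 1] / cos(beta))
  }
  out <- c(pitch = beta * deg, roll = gamma * deg, yaw = alpha * deg)
  attr(out, "gimbal") <- gimbal
  out
}

#' Rotation matrix from pitch, roll and yaw
#'
#' Inverse of [euler_angles()]: `R = Rz(yaw) Ry(pitch) Rx(roll)`.
#'
#' @param pitch,roll,yaw Angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_angles <- function(pitch, roll, yaw) {
  r <- pi / 180
  cb <- cos(pitch * r); sb <- sin(pitch * r)
  cg <- cos(roll * r); sg <- sin(roll * r)
  ca <- cos(yaw * r); sa <- sin(yaw * r)
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cg, sg, 0, -sg, cg), 3, 3)
  Rz %*% Ry %*% Rx
}

ca_matrix <- function(structure, chains) {
  a <- structure$atoms
  sel <- a$elety == "CA" & a$chain %in% chains
  if (!any(sel)) stop("no CA atoms in chain(s) ", paste(chains, collapse = ","),
                      call. = FALSE)
  as.matrix(a[sel, c("x", "y", "z")])
}

nose_centroid <- function(structure, nose) {
  pts <- do.call(rbind, lapply(nose$residues, function(r) {
    rows <- residue_rows(structure, r)
    if (!length(rows)) stop("nose residue ", format(r), " not found",
                            call. = FALSE)
    ca <- rows[structure$atoms$elety[rows] == "CA"]
    i <- if (length(ca)) ca[1] else rows[1]
    unlist(structure$atoms[i, c("x", "y", "z")])
  }))
  colMeans(pts)
}

#' Per-frame orientation angles and RMSD over an ensemble
#'
#' For every frame: build the receptor and arrestin principal frames, solve
#' for the relative rotation and report pitch/roll/yaw in degrees. The RMSD
#' column is the arrestin Calpha RMSD from frame 1 after least-squares
#' superposition of the receptor Calphas onto frame 1.
#'
#' @param ensemble An `xl_ensemble` holding both partners.
#' @param receptor_chains,arrestin_chains Chain ids of the two partners.
#' @param receptor_nose,arrestin_nose [nose_definition()]s; their `reference`
#'   fixes the vertical-axis sign of the respective frame.
#' @return Data.frame with columns `frame`, `pitch_deg`, `roll_deg`,
#'   `yaw_deg`, `rmsd_A`; attribute `max_deviation` holds the maximal
#'   absolute angle deviation from frame 1.
#' @export
ensemble_orientation <- function(ensemble, receptor_chains, arrestin_chains,
                                 receptor_nose, arrestin_nose) {
  nf <- n_frames(ensemble)
  top <- ensemble$topology
  rec_sel <- top$atoms$elety == "CA" & top$atoms$chain %in% receptor_chains
  arr_sel <- top$atoms$elety == "CA" & top$atoms$chain %in% arrestin_chains
  if (!any(rec_sel) || !any(arr_sel))
    stop("empty receptor or arrestin CA selection", call. = FALSE)
  out <- data.frame(frame = seq_len(nf), pitch_deg = NA_real_,
                    roll_deg = NA_real_, yaw_deg = NA_real_, rmsd_A = NA_real_)
  rec0 <- ensemble$xyz[rec_sel, , 1]
  arr0 <- ensemble$xyz[arr_sel, , 1]
  for (k in seq_len(nf)) {
    st <- frame_structure(ensemble, k)
    rec_xyz <- ensemble$xyz[rec_sel, , k]
    arr_xyz <- ensemble$xyz[arr_sel, , k]
    fr_rec <- tryCatch(
      principal_frame(rec_xyz, nose_centroid(st, receptor_nose),
                      receptor_nose$reference),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                               call. = FALSE))
    fr_arr <- tryCatch(
      principal_frame(arr_xyz, nose_centroid(st, arrestin_nose),
                      arrestin_nose$reference),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                               call. = FALSE))
    ang <- euler_angles(relative_rotation(fr_rec, fr_arr))
    fit <- superpose(rec_xyz, rec0)
    arr_fit <- transform_coords(arr_xyz, fit$rotation, fit$translation)
    out[k, 2:5] <- c(ang, sqrt(mean(rowSums((arr_fit - arr0)^2))))
  }
  dev <- vapply(2:4, function(j) max(abs(out[[j]] - out[[j]][1])), numeric(1))
  attr(out, "max_deviation") <- c(pitch = dev[1], roll = dev[2], yaw = dev[3])
  out
}

anchor_index <- function(structure, ref) {
  rows <- residue_rows(structure, ref)
  if (!length(rows))
    stop("residue ", format(ref), " not found in topology", call. = FALSE)
  elety <- structure$atoms$elety[rows]
  want <- if (identical(structure$atoms$resname[rows[1]], "GLY")) "CA" else "CB"
  hit <- rows[elety == want]
  if (!length(hit))
    stop("residue ", format(ref), " has no ", want, " anchor", call. = FALSE)
  hit[1]
}

#' Distance statistics of residue pairs over an ensemble
#'
#' Anchor-anchor (Cbeta, Calpha for glycine) distances of every pair in every
#' frame, summarised per pair: min, quartiles, median, max, the fraction of
#' frames below each cutoff, and whether the pair ever comes within each
#' cutoff. Default cutoffs are the 10.2 Angstrom adduct span and the 15.0
#' Angstrom flexibility margin.
#'
#' @param ensemble An `xl_ensemble`.
#' @param pairs List of two-element lists of [residue_ref()]s.
#' @param cutoffs Distance cutoffs in Angstroms.
#' @return Data.frame, one row per pair, with distance statistics in
#'   Angstroms plus `frac_within_*` and `ever_within_*` columns.
#' @export
distance_trace <- function(ensemble, pairs, cutoffs = c(10.2, 15.0)) {
  top <- ensemble$topology
  ia <- vapply(pairs, function(p) anchor_index(top, p[[1]]), integer(1))
  ib <- vapply(pairs, function(p) anchor_index(top, p[[2]]), integer(1))
  nf <- n_frames(ensemble)
  D <- matrix(NA_real_, nf, length(pairs))
  for (k in seq_len(nf)) {
    A <- matrix(ensemble$xyz[ia, , k], ncol = 3)
    B <- matrix(ensemble$xyz[ib, , k], ncol = 3)
    D[k, ] <- sqrt(rowSums((A - B)^2))
  }
  out <- data.frame(
    pair = vapply(pairs, function(p)
      paste(format(p[[1]]), format(p[[2]]), sep = " - "), character(1)),
    min_A = apply(D, 2, min),
    q25_A = apply(D, 2, stats::quantile, probs = 0.25),
    median_A = apply(D, 2, stats::median),
    q75_A = apply(D, 2, stats::quantile, probs = 0.75),
    max_A = apply(D, 2, max)
  )
  for (ct in cutoffs) {
    out[[paste0("frac_within_", ct)]] <- colMeans(D < ct)
    out[[paste0("ever_within_", ct)]] <- apply(D < ct, 2, any)
  }
  attr(out, "distances") <- D
  out
}

residue_atom_idx <- function(structure, ref, heavy_only = TRUE) {
  rows <- residue_rows(structure, ref)
  if (!length(rows))
    stop("residue ", format(ref), " not found in topology", call. = FALSE)
  if (heavy_only)
    rows <- rows[!(toupper(structure$atoms$element[rows]) %in% c("H", "D"))]
  rows
}

#' Contact persistence of residue pairs over an ensemble
#'
#' Fraction of frames in which the minimum heavy-atom distance between the
#' two residues of a pair is below `cutoff`. With `group = TRUE` the pairs
#' are treated as alternatives (e.g., a salt bridge dynamically switching
#' between acceptor residues) and the any-of-group fraction is also reported.
#'
#' @param ensemble An `xl_ensemble`.
#' @param pairs List of two-element lists of [residue_ref()]s.
#' @param cutoff Contact cutoff in Angstroms (default 4.0).
#' @param group Also report the fraction of frames in which any pair of the
#'   list is in contact.
#' @return Data.frame with per-pair `persistence` fractions; when
#'   `group = TRUE`, attribute `any_of_group` holds the union fraction.
#' @export
contact_persistence <- function(ensemble, pairs, cutoff = 4.0, group = FALSE) {
  top <- ensemble$topology
  nf <- n_frames(ensemble)
  in_contact <- matrix(FALSE, nf, length(pairs))
  for (j in seq_along(pairs)) {
    ia <- residue_atom_idx(top, pairs[[j]][[1]])
    ib <- residue_atom_idx(top, pairs[[j]][[2]])
    for (k in seq_len(nf)) {
      A <- matrix(ensemble$xyz[ia, , k], ncol = 3)
      B <- matrix(ensemble$xyz[ib, , k], ncol = 3)
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      in_contact[k, j] <- sqrt(max(0, min(d2))) < cutoff
    }
  }
  out <- data.frame(
    pair = vapply(pairs, function(p)
      paste(format(p[[1]]), format(p[[2]]), sep = " - "), character(1)),
    persistence = colMeans(in_contact)
  )
  if (group) attr(out, "any_of_group") <- mean(apply(in_contact, 1, any))
  out
}
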