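#' @title Rigid-body Metropolis Monte Carlo pose sampling
#' @name sampler
#' @description
#' Desk-scale optimizer of one partner's rigid-body pose (6 degrees of
#' freedom) under the flat-bottom restraint energy plus a soft-sphere clash
#' term. One compound move per step: a rotation about the mobile partner's
#' Calpha centroid by a normally distributed angle around a uniformly random
#' axis, plus a normally distributed translation per axis; Metropolis
#' acceptance at temperature kT. Flexible-region remodeling is out of scope;
#' alternative conformers should be supplied as alternative input structures.
#' The default kT of 1 makes a single unit-weight restraint violated by 1
#' Angstrom beyond its wall (energy 1) acceptable about 37 percent of the
#' time. Seeds are mandatory: every run is a pure function of its
#' configuration.
NULL

#' Metropolis acceptance rule
#'
#' @param delta_e Energy change of the proposed move.
#' @param kT Temperature parameter (> 0, energy units).
#' @param u Uniform random number in `[0, 1)`.
#' @return `TRUE` when `delta_e <= 0`, else `u < exp(-delta_e / kT)`.
#' @export
metropolis_accept <- function(delta_e, kT, u) {
  if (kT <= 0) stop("kT must be > 0", call. = FALSE)
  delta_e <= 0 | u < exp(-delta_e / kT)
}

#' Sampler configuration
#'
#' @param steps Monte Carlo steps per trial (>= 1).
#' @param kT Temperature parameter (> 0); default 1.
#' @param rot_sd Rotational proposal scale, degrees (default 5).
#' @param trans_sd Translational proposal scale per axis, Angstroms
#'   (default 0.5).
#' @param trials Independent trials (default 1); trial k uses seed
#'   `seed + k - 1`.
#' @param seed Mandatory integer random seed.
#' @param adapt Adapt step scales every 500 steps toward 30-50 percent
#'   acceptance (default `FALSE`).
#' @param trace_every Record the energy trace every this many steps.
#' @return List of class `xl_sampler_config`.
#' @export
sampler_config <- function(steps, kT = 1, rot_sd = 5, trans_sd = 0.5,
                           trials = 1, seed, adapt = FALSE,
                           trace_every = max(1L, steps %/% 1000L)) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  if (kT <= 0 || rot_sd <= 0 || trans_sd <= 0)
    stop("kT and step scales must be > 0", call. = FALSE)
  cfg <- list(steps = as.integer(steps), kT = kT, rot_sd = rot_sd,
              trans_sd = trans_sd, trials = as.integer(trials),
              seed = as.integer(seed), adapt = adapt,
              trace_every = as.integer(trace_every))
  class(cfg) <- "xl_sampler_config"
  cfg
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis vector (normalised internally).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3 x 3 proper rotation matrix.
#' @export
axis_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_axis <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# Energy of a candidate pose. Anchor and clash coordinates of the mobile
# partner are transformed as centre + R (x - centre) + t.
pose_energy <- function(R, tr, centre, fix_anchor, mob_anchor_c, wts, lo, hi,
                        fix_ca, fix_ca2, mob_ca_c, clash_rmin, clash_weight) {
  shift <- centre + tr
  e <- 0
  if (length(wts)) {
    moved_anchor <- mob_anchor_c %*% t(R)
    moved_anchor[, 1] <- moved_anchor[, 1] + shift[1]
    moved_anchor[, 2] <- moved_anchor[, 2] + shift[2]
    moved_anchor[, 3] <- moved_anchor[, 3] + shift[3]
    d <- sqrt(rowSums((fix_anchor - moved_anchor)^2))
    e <- sum(wts * (pmax(d - hi, 0)^2 + pmax(lo - d, 0)^2))
  }
  if (clash_weight > 0) {
    moved_ca <- mob_ca_c %*% t(R)
    moved_ca[, 1] <- moved_ca[, 1] + shift[1]
    moved_ca[, 2] <- moved_ca[, 2] + shift[2]
    moved_ca[, 3] <- moved_ca[, 3] + shift[3]
    d2 <- outer(fix_ca2, rowSums(moved_ca^2), "+") -
      2 * tcrossprod(fix_ca, moved_ca)
    dmat <- sqrt(pmax(d2, 0))
    e <- e + clash_weight * sum(pmax(clash_rmin - dmat, 0)^2)
  }
  e
}

#' Optimize a rigid-body pose by Metropolis Monte Carlo
#'
#' The receptor stays fixed; the mobile partner's pose is sampled under the
#' total energy (flat-bottom restraint penalties plus Calpha soft-sphere
#' clash). Runs `config$trials` independent trials and reports the best pose,
#' best energy and a thinned energy trace for each.
#'
#' @param receptor Fixed `xl_structure`.
#' @param mobile Mobile `xl_structure` (its input pose is the start unless
#'   `start_pose` is given).
#' @param restraints An `xl_restraints` table; receptor-side anchors must
#'   resolve in `receptor`, arrestin-side anchors in `mobile`.
#' @param config An [sampler_config()].
#' @param clash_weight Weight of the clash term (default 1; 0 disables).
#' @param clash_rmin Clash wall in Angstroms (default 4.0).
#' @param start_pose Optional list with `rotation` and `translation` applied
#'   to the mobile partner before sampling starts.
#' @return List of class `xl_sampling`: per-trial `best_pose` (first pose
#'   attaining the minimal energy; rotation/translation about the mobile
#'   Calpha centroid), `mean_pose` (average over all minimum-energy samples,
#'   projected back onto the rotation group -- with flat-bottom restraints
#'   the optimum is a plateau and this plateau centroid is the recommended
#'   point estimate of the pose), `best_energy`, `trace` (data.frame
#'   step/energy/best), `acceptance`, plus `seed` and the best trial index
#'   `best_trial`.
#' @export
mmc_optimize <- function(receptor, mobile, restraints, config,
                         clash_weight = 1, clash_rmin = 4.0,
                         start_pose = NULL) {
  rec_refs <- lapply(seq_len(nrow(restraints)), function(i)
    residue_ref(restraints$receptor_chain[i], restraints$receptor_resno[i]))
  mob_refs <- lapply(seq_len(nrow(restraints)), function(i)
    residue_ref(restraints$arrestin_chain[i], restraints$arrestin_resno[i]))
  fix_anchor <- matrix(0, 0, 3)
  mob_anchor <- matrix(0, 0, 3)
  if (nrow(restraints)) {
    fix_anchor <- do.call(rbind, lapply(rec_refs, anchor_coordinate,
                                        structure = receptor))
    mob_anchor <- do.call(rbind, lapply(mob_refs, anchor_coordinate,
                                        structure = mobile))
  }
  fix_ca <- coords(receptor)[receptor$atoms$elety == "CA", , drop = FALSE]
  mob_ca0 <- coords(mobile)[mobile$atoms$elety == "CA", , drop = FALSE]
  if (!nrow(restraints) && clash_weight == 0)
    warning("no restraints and no clash term: the energy landscape is flat",
            call. = FALSE)
  centre <- colMeans(mob_ca0)
  lo <- restraints$lo; hi <- restraints$hi
  wts <- sqrt(restraints$yield)
  mob_anchor_c <- sweep(mob_anchor, 2, centre)
  mob_ca_c <- sweep(mob_ca0, 2, centre)
  fix_ca2 <- rowSums(fix_ca^2)

  trials <- vector("list", config$trials)
  for (trial in seq_len(config$trials)) {
    set.seed(config$seed + trial - 1L)
    R <- if (is.null(start_pose)) diag(3) else start_pose$rotation
    tr <- if (is.null(start_pose)) c(0, 0, 0) else start_pose$translation
    rot_sd <- config$rot_sd; trans_sd <- config$trans_sd
    e <- pose_energy(R, tr, centre, fix_anchor, mob_anchor_c, wts, lo, hi,
                     fix_ca, fix_ca2, mob_ca_c, clash_rmin, clash_weight)
    best_e <- e; best_R <- R; best_t <- tr
    # running average over minimum-energy samples: with flat-bottom
    # restraints the optimum is a plateau, and its centroid is the natural
    # point estimate of the pose (reset whenever a strictly lower energy
    # level is reached)
    R_sum <- R; t_sum <- tr; n_min <- 1L
    n_acc <- 0L; acc_window <- 0L
    n_trace <- config$steps %/% config$trace_every
    trace <- data.frame(step = integer(n_trace), energy = numeric(n_trace),
                        best = numeric(n_trace))
    ti <- 0L
    for (step in seq_len(config$steps)) {
      dR <- axis_rotation(random_axis(), stats::rnorm(1, 0, rot_sd))
      dt <- stats::rnorm(3, 0, trans_sd)
      R2 <- dR %*% R
      t2 <- tr + dt
      e2 <- pose_energy(R2, t2, centre, fix_anchor, mob_anchor_c, wts, lo,
                        hi, fix_ca, fix_ca2, mob_ca_c, clash_rmin,
                        clash_weight)
      if (metropolis_accept(e2 - e, config$kT, stats::runif(1))) {
        R <- R2; tr <- t2; e <- e2
        n_acc <- n_acc + 1L; acc_window <- acc_window + 1L
        if (e < best_e) {
          best_e <- e; best_R <- R; best_t <- tr
          R_sum <- matrix(0, 3, 3); t_sum <- c(0, 0, 0); n_min <- 0L
        }
      }
      if (e <= best_e + 1e-12) {
        R_sum <- R_sum + R; t_sum <- t_sum + tr; n_min <- n_min + 1L
      }
      if (config$adapt && step %% 500L == 0L) {
        rate <- acc_window / 500
        if (rate < 0.3) { rot_sd <- rot_sd * 0.8; trans_sd <- trans_sd * 0.8 }
        if (rate > 0.5) { rot_sd <- rot_sd * 1.25; trans_sd <- trans_sd * 1.25 }
        acc_window <- 0L
      }
      if (step %% config$trace_every == 0L) {
        ti <- ti + 1L
        trace$step[ti] <- step; trace$energy[ti] <- e; trace$best[ti] <- best_e
      }
    }
    sv <- svd(R_sum)
    R_mean <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
    trials[[trial]] <- list(
      best_pose = list(rotation = best_R, translation = best_t,
                       centre = centre),
      mean_pose = list(rotation = R_mean, translation = t_sum / n_min,
                       centre = centre),
      best_energy = best_e,
      trace = trace[seq_len(ti), , drop = FALSE],
      acceptance = n_acc / config$steps
    )
  }
  out <- list(trials = trials,
              best_trial = which.min(vapply(trials, `[[`, numeric(1),
                                            "best_energy")),
              seed = config$seed)
  class(out) <- "xl_sampling"
  out
}

#' @export
print.xl_sampling <- function(x, ...) {
  e <- vapply(x$trials, `[[`, numeric(1), "best_energy")
  cat(sprintf("xl_sampling: %d trial(s), best energy %.4g (trial %d)\n",
              length(x$trials), min(e), x$best_trial))
  invisible(x)
}

#' Apply a sampled pose to a structure
#'
#' @param structure An `xl_structure` (the mobile partner as passed to
#'   [mmc_optimize()]).
#' @param pose A `best_pose` element of an `xl_sampling` result, or any list
#'   with `rotation`, `translation` and `centre`.
#' @return The transformed `xl_structure`.
#' @export
apply_pose <- function(structure, pose) {
  xyz <- coords(structure)
  moved <- sweep(sweep(xyz, 2, pose$centre) %*% t(pose$rotation), 2,
                 -(pose$centre + pose$translation))
  set_coords(structure, moved)
}
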