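#' @title Seeded synthetic-data generators
#' @name synthetic
#' @description
#' Every stage of the pipeline has a generator producing inputs with the
#' statistical structure that stage assumes, together with the ground truth,
#' so recovery can be tested without any external data. Pseudo-proteins are
#' directionally persistent self-avoiding Calpha walks with 3.8 Angstrom
#' spacing and ideal 1.53 Angstrom Cbeta placement: enough realism for anchor
#' geometry, with no side chains, folds or membranes. All generators are pure
#' functions of their arguments and seed.
NULL

unit3 <- function(v) v / sqrt(sum(v^2))

# Persistent self-avoiding CA walk; persistence > 0 elongates the body so its
# principal components are well separated.
pseudo_ca_walk <- function(n_res, spacing = 3.8, persistence = 0.6,
                           min_sep = 3.5, max_try = 200) {
  P <- matrix(0, n_res, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n_res) {
    placed <- FALSE
    for (k in seq_len(max_try)) {
      cand_dir <- unit3(persistence * dir + stats::rnorm(3, 0, 0.6))
      cand <- P[i - 1, ] + spacing * cand_dir
      prev <- P[seq_len(max(1, i - 2)), , drop = FALSE]
      if (all(sqrt(rowSums(sweep(prev, 2, cand)^2)) >= min_sep)) {
        P[i, ] <- cand; dir <- cand_dir; placed <- TRUE; break
      }
    }
    if (!placed) stop("self-avoiding walk failed; try another seed",
                      call. = FALSE)
  }
  sweep(P, 2, colMeans(P))
}

cb_from_ca <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    mid <- if (i == 1) ca[2, ] else if (i == n) ca[n - 1, ]
           else (ca[i - 1, ] + ca[i + 1, ]) / 2
    v <- ca[i, ] - mid
    if (sqrt(sum(v^2)) < 1e-6) v <- stats::rnorm(3)
    cb[i, ] <- ca[i, ] + 1.53 * unit3(v)
  }
  cb
}

pseudo_structure <- function(ca, cb, chain) {
  n <- nrow(ca)
  atoms <- data.frame(
    serial = seq_len(2L * n),
    elety = rep(c("CA", "CB"), n),
    altloc = "", resname = "ALA", chain = chain,
    resno = rep(seq_len(n), each = 2L), insert = "",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    occ = 1, element = "C", stringsAsFactors = FALSE
  )
  new_structure(atoms)
}

#' Merge two structures into one
#'
#' @param a,b `xl_structure` objects with disjoint chain ids.
#' @return An `xl_structure` holding both partners.
#' @export
combine_structures <- function(a, b) {
  if (length(intersect(unique(a$atoms$chain), unique(b$atoms$chain))))
    stop("chain ids must be disjoint", call. = FALSE)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

#' Generate a toy two-body complex with planted crosslink restraints
#'
#' Builds two pseudo-protein bodies, docks the mobile one against the fixed
#' one at a random (seed-determined) relative pose that is clash free, and
#' plants `n_pairs` crosslink restraints whose anchor distances at the true
#' pose spread evenly across `distance_range`, inside the 4.0-10.2 Angstrom
#' flat bottom, so the restraint energy at the truth is exactly zero. Yields
#' follow a decreasing distance-yield model,
#' `B = clip(0.6 - 0.04 (d - 4), 0.05, 0.6) + noise`, loosely mimicking the
#' observed spread of yields against model distances.
#'
#' @param n_receptor,n_mobile Residue counts (>= 5).
#' @param n_pairs Planted restraint count.
#' @param distance_range Planted anchor-distance band (default `c(6, 9)`,
#'   the middle of the flat bottom).
#' @param yield_noise_sd Noise on the planted yields (default 0.02).
#' @param seed Mandatory integer seed.
#' @return List: `receptor` and `mobile` (`xl_structure`s, mobile already at
#'   the true pose), `complex` (both merged; chains `"R"` and `"A"`),
#'   `restraints` (an `xl_restraints` table), `true_pose` (the placement
#'   transform applied to the centred mobile body) and `seed`.
#' @export
make_toy_complex <- function(n_receptor = 30, n_mobile = 30, n_pairs = 12,
                             distance_range = c(6, 9),
                             yield_noise_sd = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_receptor < 5 || n_mobile < 5)
    stop("bodies need at least 5 residues", call. = FALSE)
  set.seed(seed)
  # canonicalize a body: principal axes onto x/y/z (long axis along x)
  canonical <- function(ca) {
    ev <- eigen(crossprod(sweep(ca, 2, colMeans(ca))), symmetric = TRUE)
    V <- ev$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    sweep(ca, 2, colMeans(ca)) %*% V
  }
  for (walk_try in 1:8) {
  rec_ca <- canonical(pseudo_ca_walk(n_receptor))
  rec_cb <- cb_from_ca(rec_ca)
  mob_ca_canon <- canonical(pseudo_ca_walk(n_mobile))

  for (attempt in 1:10) {
    # bounded random twist keeps the long axes roughly parallel so the
    # docked interface stays broad enough to plant spread-out pairs
    R0 <- axis_rotation(random_axis(), stats::rnorm(1, 0, 15))
    ca_r <- mob_ca_canon %*% t(R0)
    cb_r <- cb_from_ca(ca_r)
    mob_ca0 <- ca_r
    mob_cb0 <- cb_r
    offsets <- seq(60, 5, by = -0.25)
    best <- NULL
    for (t0 in offsets) {
      sh <- c(0, 0, t0)
      d2 <- outer(rowSums(rec_ca^2), rowSums(sweep(ca_r, 2, -sh)^2), "+") -
        2 * tcrossprod(rec_ca, sweep(ca_r, 2, -sh))
      if (sqrt(max(0, min(d2))) < 4.5) break
      dcb <- outer(rowSums(rec_cb^2), rowSums(sweep(cb_r, 2, -sh)^2), "+") -
        2 * tcrossprod(rec_cb, sweep(cb_r, 2, -sh))
      dcb <- sqrt(pmax(dcb, 0))
      elig <- which(dcb >= distance_range[1] & dcb <= distance_range[2],
                    arr.ind = TRUE)
      # at most two restraints per residue so the planted anchors spread
      # over the interface
      if (nrow(elig)) {
        elig <- elig[order(dcb[elig]), , drop = FALSE]
        used_r <- integer(0); used_m <- integer(0); keep <- logical(nrow(elig))
        for (q in seq_len(nrow(elig))) {
          if (sum(used_r == elig[q, 1]) < 2L && sum(used_m == elig[q, 2]) < 2L) {
            keep[q] <- TRUE
            used_r <- c(used_r, elig[q, 1]); used_m <- c(used_m, elig[q, 2])
          }
        }
        elig <- elig[keep, , drop = FALSE]
      }
      if (nrow(elig) >= n_pairs &&
          (is.null(best) || nrow(elig) > nrow(best$elig)))
        best <- list(shift = sh, elig = elig, dcb = dcb)
    }
    if (!is.null(best)) {
      # a third of the pairs from each end of the distance band (short
      # contacts and near-wall pairs are what make the set pose-defining),
      # the rest evenly spaced across the middle
      m <- nrow(best$elig)
      k <- max(1L, n_pairs %/% 3L)
      take <- unique(c(seq_len(k), m - seq_len(k) + 1L,
                       round(seq(k + 1, m - k, length.out = n_pairs - 2 * k))))
      extra <- setdiff(seq_len(m), take)
      if (length(take) < n_pairs)
        take <- c(take, sample(extra, n_pairs - length(take)))
      sel <- best$elig[take[seq_len(n_pairs)], , drop = FALSE]
      d_sel <- best$dcb[sel]
      yields <- pmin(pmax(0.6 - 0.04 * (d_sel - 4), 0.05), 0.6) +
        stats::rnorm(n_pairs, 0, yield_noise_sd)
      yields <- pmin(pmax(yields, 0.01), 1)
      receptor <- pseudo_structure(rec_ca, rec_cb, "R")
      mobile <- pseudo_structure(sweep(mob_ca0, 2, -best$shift),
                                 sweep(mob_cb0, 2, -best$shift), "A")
      restraints <- restraint_table(
        receptor_chain = "R", receptor_resno = sel[, 1],
        arrestin_chain = "A", arrestin_resno = sel[, 2],
        yield_fraction = yields
      )
      return(list(receptor = receptor, mobile = mobile,
                  complex = combine_structures(receptor, mobile),
                  restraints = restraints,
                  true_pose = list(rotation = R0, translation = best$shift),
                  seed = seed))
    }
  }
  }
  stop("could not plant ", n_pairs, " pairs: spec infeasible for these sizes",
       call. = FALSE)
}

#' Simulate a replicate blot quantification table
#'
#' Per replicate, the observed yield is `clip(true_yield + N(0, sd), 0, 1)`;
#' band and total intensities are reported with totals drawn uniformly from
#' `[800, 1200]` densitometry units. Control rows are drawn from the
#' background-noise distribution. The ground-truth significance label marks
#' pairs whose true yield exceeds the control mean by at least `margin`.
#'
#' @param true_yields Named numeric vector of per-pair true yields in
#'   `[0, 1]` (names become `pair_id`s).
#' @param n_replicates Replicates per pair (default 3).
#' @param noise_sd Replicate noise standard deviation (default 0.05).
#' @param control_mean,control_sd,n_control Background-noise control
#'   distribution (defaults 0.02, 0.01, 20).
#' @param margin Ground-truth effect-size margin (default 0.1).
#' @param seed Mandatory integer seed.
#' @return List: `table` (measurement data.frame with pair and control rows)
#'   and `truth` (data.frame of `pair_id`, `true_yield`,
#'   `expected_significant`).
#' @export
simulate_blot_table <- function(true_yields, n_replicates = 3,
                                noise_sd = 0.05, control_mean = 0.02,
                                control_sd = 0.01, n_control = 20,
                                margin = 0.1, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (any(true_yields < 0 | true_yields > 1))
    stop("true yields must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  ids <- names(true_yields)
  if (is.null(ids)) ids <- paste0("pair", seq_along(true_yields))
  rows <- lapply(seq_along(true_yields), function(i) {
    y <- pmin(pmax(true_yields[i] + stats::rnorm(n_replicates, 0, noise_sd),
                   0), 1)
    total <- stats::runif(n_replicates, 800, 1200)
    data.frame(pair_id = ids[i], receptor_residue = NA_character_,
               arrestin_residue = NA_character_,
               replicate = seq_len(n_replicates),
               band = y * total, total = total, condition = "pair",
               stringsAsFactors = FALSE)
  })
  yc <- pmin(pmax(stats::rnorm(n_control, control_mean, control_sd), 0), 1)
  totc <- stats::runif(n_control, 800, 1200)
  ctrl <- data.frame(pair_id = "control", receptor_residue = NA_character_,
                     arrestin_residue = NA_character_,
                     replicate = seq_len(n_control),
                     band = yc * totc, total = totc, condition = "control",
                     stringsAsFactors = FALSE)
  list(
    table = rbind(do.call(rbind, rows), ctrl),
    truth = data.frame(pair_id = ids, true_yield = unname(true_yields),
                       expected_significant =
                         unname(true_yields) > control_mean + margin)
  )
}

# Nose definition + vertical reference derived from a body's own base-frame
# principal components, so synthetic trajectories analyse consistently.
auto_nose <- function(structure, chain) {
  ca <- ca_matrix(structure, chain)
  centred <- sweep(ca, 2, colMeans(ca))
  ev <- eigen(crossprod(centred) / nrow(ca), symmetric = TRUE)
  proj <- centred %*% ev$vectors[, 1]
  resno <- structure$atoms$resno[structure$atoms$elety == "CA" &
                                   structure$atoms$chain == chain]
  top2 <- resno[order(proj, decreasing = TRUE)[1:2]]
  nose_definition(lapply(top2, function(r) residue_ref(chain, r)),
                  reference = ev$vectors[, 2])
}

#' Simulate a two-body trajectory with planted orientation angles
#'
#' Starting from a base complex, each frame applies to the mobile partner the
#' rotation that realises planted pitch/roll/yaw angles (the base orientation
#' plus independent normal deviations) about its centroid, plus normal
#' translational noise. The planted per-frame angle table is returned so
#' orientation analytics have an exact recovery target. Default angular
#' spreads emulate the modest orientation fluctuations seen in unbiased
#' simulations of the receptor-arrestin complex (maximal deviations of
#' roughly 13, 17 and 25 degrees for pitch, roll and yaw over long
#' trajectories, i.e. standard deviations of a few degrees).
#'
#' @param receptor,mobile `xl_structure`s of the two partners (e.g. from
#'   [make_toy_complex()]).
#' @param angular_sd Named standard deviations in degrees,
#'   `c(pitch = 4, roll = 5, yaw = 7)` by default.
#' @param translation_sd Translational noise per axis, Angstroms
#'   (default 0.5).
#' @param n_frames Number of frames (default 200).
#' @param seed Mandatory integer seed.
#' @return List: `ensemble` (`xl_ensemble` of the full complex), `planted`
#'   (data.frame frame/pitch_deg/roll_deg/yaw_deg), `receptor_nose`,
#'   `arrestin_nose` (the [nose_definition()]s under which the planted angles
#'   are defined) and `base_angles`.
#' @export
simulate_trajectory <- function(receptor, mobile,
                                angular_sd = c(pitch = 4, roll = 5, yaw = 7),
                                translation_sd = 0.5, n_frames = 200, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  set.seed(seed)
  rec_chain <- unique(receptor$atoms$chain)
  mob_chain <- unique(mobile$atoms$chain)
  rec_nose <- auto_nose(receptor, rec_chain[1])
  arr_nose <- auto_nose(mobile, mob_chain[1])
  fr_rec <- principal_frame(ca_matrix(receptor, rec_chain),
                            nose_centroid(receptor, rec_nose),
                            rec_nose$reference)
  fr_arr <- principal_frame(ca_matrix(mobile, mob_chain),
                            nose_centroid(mobile, arr_nose),
                            arr_nose$reference)
  R0 <- relative_rotation(fr_rec, fr_arr)
  base <- euler_angles(R0)
  Xr <- fr_rec$axes; Xa <- fr_arr$axes
  base_complex <- combine_structures(receptor, mobile)
  n_atoms <- nrow(base_complex$atoms)
  mob_idx <- base_complex$atoms$chain %in% mob_chain
  mob_xyz <- coords(mobile)
  centre <- colMeans(ca_matrix(mobile, mob_chain))
  xyz <- array(NA_real_, c(n_atoms, 3, n_frames))
  base_xyz <- coords(base_complex)
  planted <- data.frame(frame = seq_len(n_frames), pitch_deg = NA_real_,
                        roll_deg = NA_real_, yaw_deg = NA_real_)
  for (k in seq_len(n_frames)) {
    dev <- stats::rnorm(3, 0, angular_sd)
    ang <- base[1:3] + dev
    Rt <- rotation_from_angles(ang[1], ang[2], ang[3])
    Q <- t(Rt) %*% Xr %*% t(Xa)
    shift <- stats::rnorm(3, 0, translation_sd)
    moved <- sweep(sweep(mob_xyz, 2, centre) %*% t(Q), 2, -(centre + shift))
    fr_xyz <- base_xyz
    fr_xyz[mob_idx, ] <- moved
    xyz[, , k] <- fr_xyz
    planted[k, 2:4] <- ang
  }
  list(ensemble = new_ensemble(base_complex, xyz), planted = planted,
       receptor_nose = rec_nose, arrestin_nose = arr_nose,
       base_angles = base)
}
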