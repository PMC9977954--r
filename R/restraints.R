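#' @title Yield-weighted flat-bottom distance restraints and model scoring
#' @name restraints
#' @description
#' Each validated crosslink becomes a soft flat-bottom harmonic restraint on
#' the anchor-anchor (Cbeta-Cbeta) distance d between its two residues,
#' weighted by the square root of its crosslinking yield B:
#'
#'   E = sqrt(B) * ( max(d - hi, 0)^2 + max(lo - d, 0)^2 )
#'
#' with walls at lo = 4.0 Angstroms (penalising atomic clash) and hi = 10.2
#' Angstroms (the maximal Cbeta-Cbeta span of the BrEtY-Cys adduct). The
#' penalty is exactly zero anywhere inside the flat bottom and grows
#' quadratically outside, so the energy carries units of weighted square
#' Angstroms (no force constant). B is stored as a fraction in [0, 1] (the
#' densitometry ratio); rankings are invariant to that convention, absolute
#' energies are not.
NULL

#' Build a restraint table
#'
#' @param receptor_chain,receptor_resno,arrestin_chain,arrestin_resno Vectors
#'   identifying the two anchor residues of each restraint (author numbering).
#' @param yield_fraction Crosslinking yields B in `[0, 1]`.
#' @param lo,hi Flat-bottom walls in Angstroms (defaults 4.0 and 10.2).
#' @return Data.frame of class `xl_restraints`.
#' @export
restraint_table <- function(receptor_chain, receptor_resno,
                            arrestin_chain, arrestin_resno,
                            yield_fraction, lo = 4.0, hi = 10.2) {
  if (any(lo <= 0) || any(lo >= hi))
    stop("walls must satisfy 0 < lo < hi", call. = FALSE)
  if (any(yield_fraction < 0))
    stop("yields must be >= 0", call. = FALSE)
  out <- data.frame(
    receptor_chain = receptor_chain, receptor_resno = as.integer(receptor_resno),
    arrestin_chain = arrestin_chain, arrestin_resno = as.integer(arrestin_resno),
    yield = yield_fraction, lo = lo, hi = hi, stringsAsFactors = FALSE
  )
  class(out) <- c("xl_restraints", "data.frame")
  out
}

#' Read a restraint list from TSV
#'
#' Columns: `receptor_chain`, `receptor_residue`, `arrestin_chain`,
#' `arrestin_residue`, `yield`.
#'
#' @param file Path to the TSV file.
#' @param lo,hi Flat-bottom walls applied to every restraint.
#' @return An `xl_restraints` table.
#' @export
read_restraints <- function(file, lo = 4.0, hi = 10.2) {
  x <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  restraint_table(x$receptor_chain, x$receptor_residue,
                  x$arrestin_chain, x$arrestin_residue, x$yield,
                  lo = lo, hi = hi)
}

#' Write a restraint list as TSV
#'
#' @param restraints An `xl_restraints` table.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_restraints <- function(restraints, file) {
  out <- data.frame(
    receptor_chain = restraints$receptor_chain,
    receptor_residue = restraints$receptor_resno,
    arrestin_chain = restraints$arrestin_chain,
    arrestin_residue = restraints$arrestin_resno,
    yield = restraints$yield
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Flat-bottom harmonic penalty
#'
#' @param d Anchor-anchor distance(s), Angstroms (>= 0).
#' @param B Restraint weight(s): crosslinking yield fraction (>= 0).
#' @param lo,hi Flat-bottom walls (defaults 4.0 and 10.2 Angstroms).
#' @return Penalty energy `sqrt(B) * (max(d - hi, 0)^2 + max(lo - d, 0)^2)`,
#'   exactly 0 for `lo <= d <= hi`.
#' @export
penalty_energy <- function(d, B, lo = 4.0, hi = 10.2) {
  if (any(d < 0) || any(!is.finite(d)))
    stop("distances must be finite and >= 0", call. = FALSE)
  if (any(B < 0) || any(!is.finite(B)))
    stop("weights must be finite and >= 0", call. = FALSE)
  sqrt(B) * (pmax(d - hi, 0)^2 + pmax(lo - d, 0)^2)
}

restraint_pairs <- function(restraints) {
  lapply(seq_len(nrow(restraints)), function(i) {
    list(residue_ref(restraints$receptor_chain[i], restraints$receptor_resno[i]),
         residue_ref(restraints$arrestin_chain[i], restraints$arrestin_resno[i]))
  })
}

#' Score a model against a restraint list
#'
#' Measures every restraint's anchor-anchor distance in the structure,
#' evaluates the flat-bottom penalty, and counts satisfied restraints at the
#' given distance cutoffs (defaults: the 10.2 Angstrom adduct span and the
#' 15.0 Angstrom flexibility margin).
#'
#' @param structure An `xl_structure` holding both partners.
#' @param restraints An `xl_restraints` table.
#' @param cutoffs Satisfaction cutoffs in Angstroms.
#' @param fallback_ca Passed to [anchor_coordinate()].
#' @return List of class `xl_report`: `per_restraint` data.frame (distance,
#'   yield, penalty, one `satisfied_<cutoff>` flag per cutoff), `total_energy`
#'   and named `n_within` counts.
#' @export
score_model <- function(structure, restraints, cutoffs = c(10.2, 15.0),
                        fallback_ca = FALSE) {
  d <- pair_distances(structure, restraint_pairs(restraints), fallback_ca)
  e <- penalty_energy(d, restraints$yield, restraints$lo, restraints$hi)
  per <- data.frame(
    receptor = paste0(restraints$receptor_chain, ":", restraints$receptor_resno),
    arrestin = paste0(restraints$arrestin_chain, ":", restraints$arrestin_resno),
    distance_A = d, yield_fraction = restraints$yield, penalty = e
  )
  for (ct in cutoffs) per[[paste0("satisfied_", ct)]] <- d <= ct
  n_within <- vapply(cutoffs, function(ct) sum(d <= ct), integer(1))
  names(n_within) <- paste0("within_", cutoffs)
  report <- list(per_restraint = per, total_energy = sum(e),
                 n_within = n_within, cutoffs = cutoffs)
  class(report) <- "xl_report"
  report
}

#' @export
print.xl_report <- function(x, ...) {
  cat(sprintf("xl_report: %d restraints, total energy %.4g\n",
              nrow(x$per_restraint), x$total_energy))
  for (i in seq_along(x$n_within))
    cat(sprintf("  within %.1f A: %d\n", x$cutoffs[i], x$n_within[i]))
  invisible(x)
}

#' Write a scoring report as TSV
#'
#' @param report An `xl_report`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, file) {
  utils::write.table(report$per_restraint, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Rank models by total restraint energy
#'
#' Ascending total energy; ties broken by the satisfaction count at the first
#' cutoff (more is better), then by input order.
#'
#' @param structures List of `xl_structure` objects.
#' @param restraints An `xl_restraints` table.
#' @param cutoffs Satisfaction cutoffs (first one used for tie-breaks).
#' @return Data.frame with `model` (input index), `total_energy` and
#'   `n_within` columns, ordered best first.
#' @export
rank_models <- function(structures, restraints, cutoffs = c(10.2, 15.0)) {
  if (!length(structures)) stop("no structures to rank", call. = FALSE)
  reports <- lapply(structures, score_model, restraints = restraints,
                    cutoffs = cutoffs)
  e <- vapply(reports, `[[`, numeric(1), "total_energy")
  s <- vapply(reports, function(r) unname(r$n_within[1]), integer(1))
  ord <- order(e, -s, seq_along(e))
  data.frame(model = ord, total_energy = e[ord],
             n_within = s[ord])
}

#' Soft-sphere clash energy between two coordinate sets
#'
#' Quadratic penalty on inter-set point pairs closer than `r_min`; a crude
#' excluded-volume term used alongside the restraint energy during pose
#' sampling (typically on Calpha atoms).
#'
#' @param coords_a,coords_b n x 3 coordinate matrices.
#' @param r_min Minimum allowed separation (default 4.0 Angstroms).
#' @param weight Scalar multiplier.
#' @return `weight * sum(max(r_min - d, 0)^2)` over all inter-set pairs.
#' @export
clash_energy <- function(coords_a, coords_b, r_min = 4.0, weight = 1.0) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!nrow(a) || !nrow(b)) stop("empty coordinate set", call. = FALSE)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d <- sqrt(pmax(d2, 0))
  weight * sum(pmax(r_min - d, 0)^2)
}
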