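#' @title Crosslinker chemistry: adduct span and formula masses
#' @name crosslinker-geometry
#' @description
#' The thiol-trapping probe O-(2-bromoethyl)-tyrosine (BrEtY) reacts with a
#' nearby cysteine thiol to form a stable thioether, so a validated crosslink
#' places the two anchor (Cbeta) atoms within the maximal span of the
#' BrEtY-Cys adduct. That span is estimated here by enumerating the rotatable
#' torsions of the linker chain on a grid under ideal covalent geometry (the
#' para-substituted ring treated as a rigid collinear segment), discarding
#' self-clashing conformers, and taking the maximal anchor-anchor distance.
#' Formula masses use lightest-isotope atomic masses with an electron-mass
#' correction for ions.
NULL

#' Define a crosslinker probe
#'
#' A chain probe is an ordered list of points from one anchor (Cbeta) to the
#' other, each placed at a bond `length` from the previous point, at `angle`
#' degrees (at the previous point) and, from the fourth point on, a torsion
#' that is either enumerated (`rotatable`) or held fixed. Rigid groups such
#' as a para-substituted benzene enter as one fixed collinear segment of the
#' appropriate cross-ring span. A radius probe carries only a maximal span.
#'
#' @param name Probe name.
#' @param formula Named integer vector of element counts (optional).
#' @param charge Net charge (default 0).
#' @param chain Data.frame with columns `label`, `length` (Angstroms, NA for
#'   the first point), `angle` (degrees at the previous point, NA for the
#'   first two points) and `rotatable` (logical).
#' @param span For radius-only probes, the fixed maximal span in Angstroms.
#' @return Object of class `xl_probe`.
#' @export
crosslinker_probe <- function(name, formula = NULL, charge = 0,
                              chain = NULL, span = NULL) {
  if (is.null(chain) && is.null(span))
    stop("a probe needs either a chain specification or a fixed span",
         call. = FALSE)
  if (!is.null(chain)) {
    if (nrow(chain) < 2L)
      stop("chain probe must connect two anchors (>= 2 points)",
           call. = FALSE)
    if (any(chain$length[-1] <= 0) || anyNA(chain$length[-1]))
      stop("bond lengths must be positive; chain is disconnected",
           call. = FALSE)
    ang <- chain$angle[-(1:2)]
    if (any(is.na(ang) | ang <= 0 | ang > 180))
      stop("angles must lie in (0, 180] degrees", call. = FALSE)
  }
  if (!is.null(formula) && (any(formula <= 0) || any(formula != round(formula))))
    stop("formula counts must be positive integers", call. = FALSE)
  structure(list(name = name, formula = formula, charge = charge,
                 chain = chain, span = span), class = "xl_probe")
}

#' Built-in BrEtY-cysteine adduct probe
#'
#' Chain Cbeta(BrEtY)-Cgamma(ring)...Czeta-O-CH2-CH2-S-Cbeta(Cys) with ideal
#' covalent geometry: bond lengths 1.51 (Cbeta-Car), 2.79 (rigid para ring
#' span), 1.37 (Car-O), 1.43 (O-CH2), 1.53 (CH2-CH2), 1.81 (CH2-S), 1.81
#' (S-Cbeta) Angstroms; angles 117 deg at the aryl ether oxygen, tetrahedral
#' (109.47 deg) at the sp3 carbons and 99 deg at the thioether sulfur. The
#' exocyclic bonds at the para positions are collinear with the ring axis,
#' so the first three segments form one rigid collinear stack.
#'
#' @return An `xl_probe`.
#' @export
brety_cys_probe <- function() {
  chain <- data.frame(
    label = c("CB1", "CG", "CZ", "OH", "C1", "C2", "SG", "CB2"),
    length = c(NA, 1.51, 2.79, 1.37, 1.43, 1.53, 1.81, 1.81),
    angle = c(NA, NA, 180, 180, 117, 109.47, 109.47, 99),
    rotatable = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  crosslinker_probe("BrEtY-Cys", formula = c(C = 11, H = 15, Br = 1,
                                             N = 1, O = 3),
                    charge = 0, chain = chain)
}

#' Built-in Bpa probe (radius only)
#'
#' p-benzoyl-L-phenylalanine inserts within about 3.1 Angstroms of its
#' carbonyl oxygen, reaching up to roughly 9-10 Angstroms from its Cbeta;
#' it is represented as a radius-only probe with a 9.5 Angstrom span.
#'
#' @return An `xl_probe`.
#' @export
bpa_probe <- function() {
  crosslinker_probe("Bpa", formula = c(C = 16, H = 15, N = 1, O = 3),
                    span = 9.5)
}

# Place a point at bond length l from c, angle theta (deg) at c, torsion phi
# (deg) about the b->c axis relative to a. Collinear a-b-c (rigid stacks)
# falls back to an arbitrary perpendicular: the torsion is then geometrically
# redundant because the whole upstream chain lies on the axis.
place_point <- function(a, b, c, l, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  u <- c - b; u <- u / sqrt(sum(u^2))
  n <- c(u[2] * (b - a)[3] - u[3] * (b - a)[2],
         u[3] * (b - a)[1] - u[1] * (b - a)[3],
         u[1] * (b - a)[2] - u[2] * (b - a)[1])
  n <- -n
  if (sqrt(sum(n^2)) < 1e-8) {
    t0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- c(t0[2] * u[3] - t0[3] * u[2],
           t0[3] * u[1] - t0[1] * u[3],
           t0[1] * u[2] - t0[2] * u[1])
  }
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  c + (-l * cos(th)) * u + l * sin(th) * (cos(ph) * m + sin(ph) * n)
}

build_chain <- function(chain, torsions) {
  n <- nrow(chain)
  P <- matrix(0, n, 3)
  P[2, ] <- c(chain$length[2], 0, 0)
  ti <- 1L
  if (n >= 3) {
    for (i in 3:n) {
      phi <- 0
      if (i >= 4 && chain$rotatable[i]) {
        phi <- torsions[ti]; ti <- ti + 1L
      }
      a <- if (i == 3) P[1, ] + c(0, 0, 1) else P[i - 3, ]
      P[i, ] <- place_point(a, P[i - 2, ], P[i - 1, ], chain$length[i],
                            chain$angle[i], phi)
    }
  }
  P
}

#' Maximal anchor-to-anchor span of a crosslinker probe
#'
#' Enumerates every rotatable torsion of the chain on a regular grid,
#' discards conformers in which any pair of points three or more bonds apart
#' comes closer than `clash_cutoff`, and returns the maximal distance between
#' the two chain ends. Radius-only probes return their fixed span.
#'
#' @param probe An `xl_probe`.
#' @param torsion_step Grid spacing in degrees (default 15).
#' @param clash_cutoff Self-clash distance in Angstroms (default 2.0).
#' @param details Return the number of conformers enumerated as an attribute.
#' @return Maximal span in Angstroms.
#' @export
max_span <- function(probe, torsion_step = 15, clash_cutoff = 2.0,
                     details = FALSE) {
  if (!inherits(probe, "xl_probe")) stop("not an xl_probe", call. = FALSE)
  if (is.null(probe$chain)) return(probe$span)
  chain <- probe$chain
  n <- nrow(chain)
  rot <- which(chain$rotatable & seq_len(n) >= 4)
  grid <- seq(-180, 180 - torsion_step, by = torsion_step)
  combos <- if (length(rot))
    as.matrix(do.call(expand.grid, rep(list(grid), length(rot))))
  else matrix(0, 1, 0)
  best <- -Inf
  pairs_ij <- which(outer(seq_len(n), seq_len(n),
                          function(i, j) j - i >= 3), arr.ind = TRUE)
  for (k in seq_len(nrow(combos))) {
    P <- build_chain(chain, combos[k, ])
    dd <- sqrt(rowSums((P[pairs_ij[, 1], , drop = FALSE] -
                        P[pairs_ij[, 2], , drop = FALSE])^2))
    if (length(dd) && any(dd < clash_cutoff)) next
    span <- sqrt(sum((P[n, ] - P[1, ])^2))
    if (span > best) best <- span
  }
  if (!is.finite(best))
    stop("all conformers self-clash; check the chain specification",
         call. = FALSE)
  if (details) attr(best, "n_conformers") <- nrow(combos)
  best
}

# Lightest-isotope atomic masses (u) and the electron mass.
.monoisotopic <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.99491461956,
  S = 31.97207100, Br = 78.9183371, P = 30.97376163
)
.electron_mass <- 0.000548579909

parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || !length(formula))
      stop("empty or unnamed formula", call. = FALSE)
    return(formula)
  }
  if (!nzchar(formula)) stop("empty formula", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula, call. = FALSE)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Monoisotopic mass-to-charge ratio
#'
#' Sums lightest-isotope atomic masses, subtracts `charge` electron masses,
#' and divides by `|charge|` (taken as 1 for neutral species).
#'
#' @param formula Molecular formula, either a string such as `"C11H15BrNO3"`
#'   or a named count vector.
#' @param charge Net charge (electrons removed when positive).
#' @return Monoisotopic m/z in u.
#' @export
monoisotopic_mass <- function(formula, charge = 0) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- sum(.monoisotopic[names(counts)] * as.numeric(counts)) -
    charge * .electron_mass
  m / max(1, abs(charge))
}
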