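# Per-nucleotide geometric descriptors: backbone torsions alpha-zeta, the
# glycosidic torsion chi with its syn/anti label, ribose endocyclic
# torsions nu0-nu4, the eta/theta pseudotorsion systems over three virtual
# bond definitions, and the Altona-Sundaralingam pseudorotation phase,
# amplitude and sugar-pucker conformer label.
#
# All angles are reported in degrees on [0, 360). Undefined angles (chain
# termini, unresolved neighbours, missing atoms, degenerate geometry) are
# NA, never sentinel numbers.

.DEG <- 180 / pi

.wrap360 <- function(x) ((x %% 360) + 360) %% 360

# signed angular difference a - b wrapped to (-180, 180]
.angdiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Signed dihedral angle between the plane through `p1,p2,p3` and the plane
#' through `p2,p3,p4`, measured about the `p2 -> p3` axis and reduced to
#' `[0, 360)` degrees. Invariant under rigid motion of all four points.
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates (angstroms).
#' @return Angle in degrees in `[0, 360)`, or `NA` when the geometry is
#'   degenerate (coincident consecutive points or a collinear triple) or
#'   any coordinate is missing.
#' @examples
#' dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 0: cis
#' dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, -1, 0)) # 180: trans
#' @export
dihedral <- function(p1, p2, p3, p4) {
  if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) return(NA_real_)
  if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10) return(NA_real_)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_) # collinear triple
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  .wrap360(atan2(y, x) * .DEG)
}

# NeRF atom placement: position D such that |C-D| = bond,
# angle(B,C,D) = angle_deg and torsion(A,B,C,D) = torsion_deg.
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg / .DEG
  tor <- torsion_deg / .DEG
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ---- residue-level atom access ------------------------------------------

.res_atom <- function(res, name) {
  if (is.null(res) || !isTRUE(res$resolved)) return(NULL)
  a <- res$atoms
  if (is.null(a) || !(name %in% rownames(a))) return(NULL)
  a[name, ]
}

.is_purine <- function(res) {
  !is.null(res) && isTRUE(res$parent_base %in% c("A", "G"))
}

# Centroid of base ring heavy atoms: the pyrimidine six-ring, plus the
# imidazole ring atoms for purines. NULL when fewer than 3 ring atoms.
.base_center <- function(res) {
  if (is.null(res) || !isTRUE(res$resolved)) return(NULL)
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  if (.is_purine(res)) ring <- c(ring, "N7", "C8", "N9")
  have <- ring[ring %in% rownames(res$atoms)]
  if (length(have) < 3L) return(NULL)
  colMeans(res$atoms[have, , drop = FALSE])
}

# ---- descriptor computations --------------------------------------------

#' Backbone and glycosidic torsions of one residue
#'
#' Standard atom quadruples:
#' alpha `O3'(i-1)-P-O5'-C5'`, beta `P-O5'-C5'-C4'`, gamma `O5'-C5'-C4'-C3'`,
#' delta `C5'-C4'-C3'-O3'`, epsilon `C4'-C3'-O3'-P(i+1)`,
#' zeta `C3'-O3'-P(i+1)-O5'(i+1)`; chi is `O4'-C1'-N9-C4` for purines and
#' `O4'-C1'-N1-C2` for pyrimidines. Any angle whose atoms are missing
#' (termini, unresolved neighbours) is `NA`.
#'
#' The syn/anti label follows the standard +/-90 degree window about cis:
#' chi in `[0, 90) U [270, 360)` is syn, otherwise anti.
#'
#' @param chain An [rna_chain] object.
#' @param i 1-based residue index.
#' @return Named list with `alpha`..`zeta`, `chi` (degrees or `NA`) and
#'   `chi_class` (`"syn"`, `"anti"` or `NA`).
#' @export
backbone_torsions <- function(chain, i) {
  res <- chain$residues[[i]]
  prev <- if (i > 1L) chain$residues[[i - 1L]] else NULL
  nxt <- if (i < length(chain$residues)) chain$residues[[i + 1L]] else NULL
  und <- list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
              delta = NA_real_, epsilon = NA_real_, zeta = NA_real_,
              chi = NA_real_, chi_class = NA_character_)
  if (!isTRUE(res$resolved)) return(und)

  P <- .res_atom(res, "P"); O5 <- .res_atom(res, "O5'")
  C5 <- .res_atom(res, "C5'"); C4s <- .res_atom(res, "C4'")
  C3 <- .res_atom(res, "C3'"); O3 <- .res_atom(res, "O3'")
  O4 <- .res_atom(res, "O4'"); C1 <- .res_atom(res, "C1'")
  out <- und
  out$alpha <- dihedral(.res_atom(prev, "O3'"), P, O5, C5)
  out$beta <- dihedral(P, O5, C5, C4s)
  out$gamma <- dihedral(O5, C5, C4s, C3)
  out$delta <- dihedral(C5, C4s, C3, O3)
  out$epsilon <- dihedral(C4s, C3, O3, .res_atom(nxt, "P"))
  out$zeta <- dihedral(C3, O3, .res_atom(nxt, "P"), .res_atom(nxt, "O5'"))
  if (.is_purine(res)) {
    out$chi <- dihedral(O4, C1, .res_atom(res, "N9"), .res_atom(res, "C4"))
  } else {
    out$chi <- dihedral(O4, C1, .res_atom(res, "N1"), .res_atom(res, "C2"))
  }
  if (!is.na(out$chi)) {
    out$chi_class <- if (out$chi < 90 || out$chi >= 270) "syn" else "anti"
  }
  out
}

#' Pseudotorsion angles of one residue
#'
#' Three virtual-bond systems, each summarizing the backbone with two
#' torsions per residue: eta/theta over P and C4' atoms
#' (eta_i: `C4'(i-1)-P(i)-C4'(i)-P(i+1)`,
#' theta_i: `P(i)-C4'(i)-P(i+1)-C4'(i+1)`), the primed system over P and
#' C1', and the double-primed system over P and the base centre (centroid
#' of base ring heavy atoms). The eta family is undefined at the first
#' residue and the theta family at the last; missing atoms in either
#' neighbour make only the affected angles undefined.
#'
#' @inheritParams backbone_torsions
#' @return Named list with `eta`, `theta`, `eta_prime`, `theta_prime`,
#'   `eta_pprime`, `theta_pprime` (degrees or `NA`).
#' @export
pseudotorsions <- function(chain, i) {
  res <- chain$residues[[i]]
  prev <- if (i > 1L) chain$residues[[i - 1L]] else NULL
  nxt <- if (i < length(chain$residues)) chain$residues[[i + 1L]] else NULL
  out <- list(eta = NA_real_, theta = NA_real_,
              eta_prime = NA_real_, theta_prime = NA_real_,
              eta_pprime = NA_real_, theta_pprime = NA_real_)
  if (!isTRUE(res$resolved)) return(out)
  P <- .res_atom(res, "P"); Pn <- .res_atom(nxt, "P")
  sys <- list(
    c("eta", "theta"),
    c("eta_prime", "theta_prime"),
    c("eta_pprime", "theta_pprime")
  )
  anchor <- list(
    function(r) .res_atom(r, "C4'"),
    function(r) .res_atom(r, "C1'"),
    .base_center
  )
  for (k in 1:3) {
    A_prev <- anchor[[k]](prev)
    A_here <- anchor[[k]](res)
    A_next <- anchor[[k]](nxt)
    out[[sys[[k]][1]]] <- dihedral(A_prev, P, A_here, Pn)
    out[[sys[[k]][2]]] <- dihedral(P, A_here, Pn, A_next)
  }
  out
}

#' Ribose endocyclic torsions of one residue
#'
#' nu0 `C4'-O4'-C1'-C2'`, nu1 `O4'-C1'-C2'-C3'`, nu2 `C1'-C2'-C3'-C4'`,
#' nu3 `C2'-C3'-C4'-O4'`, nu4 `C3'-C4'-O4'-C1'`, degrees in `[0, 360)`.
#'
#' @inheritParams backbone_torsions
#' @return Numeric vector `c(nu0, ..., nu4)` with `NA` for missing atoms.
#' @export
ribose_torsions <- function(chain, i) {
  res <- chain$residues[[i]]
  if (!isTRUE(res$resolved)) return(rep(NA_real_, 5L))
  g <- function(n) .res_atom(res, n)
  C1 <- g("C1'"); C2 <- g("C2'"); C3 <- g("C3'"); C4 <- g("C4'"); O4 <- g("O4'")
  c(nu0 = dihedral(C4, O4, C1, C2),
    nu1 = dihedral(O4, C1, C2, C3),
    nu2 = dihedral(C1, C2, C3, C4),
    nu3 = dihedral(C2, C3, C4, O4),
    nu4 = dihedral(C3, C4, O4, C1))
}

.PUCKER_LABELS <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Pseudorotation phase, amplitude and sugar-pucker label
#'
#' Altona-Sundaralingam pseudorotation of the five-membered ribose ring:
#' with endocyclic torsions `nu_j = nu_max * cos(P + 144 * (j - 2))`, the
#' phase satisfies
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 * nu2 * (sin 36 + sin 72))`,
#' quadrant-corrected so that `nu2 = nu_max * cos P` with `nu_max >= 0`.
#' The conformer label is the 36-degree bin of the pseudorotation wheel
#' containing P, with the C3'-endo bin at `[0, 36)`.
#'
#' @param nu Numeric vector of the five endocyclic torsions nu0..nu4 in
#'   degrees (any wrap convention; folded to signed values internally).
#' @return List with `phase` (degrees in `[0, 360)` or `NA`), `amplitude`
#'   (`nu_max >= 0`, degrees) and `pucker_label` (`NA` for a planar ring).
#' @export
sugar_pucker <- function(nu) {
  if (length(nu) != 5L) stop("nu must contain the five torsions nu0..nu4")
  if (anyNA(nu)) {
    return(list(phase = NA_real_, amplitude = NA_real_,
                pucker_label = NA_character_))
  }
  s <- unname(.angdiff(nu, 0))  # fold to signed (-180, 180]
  den_const <- 2 * (sin(36 / .DEG) + sin(72 / .DEG))
  b <- (s[5] + s[2]) - (s[4] + s[1])      # (nu4 + nu1) - (nu3 + nu0)
  a <- s[3]                               # nu2 = nu_max * cos P
  amplitude <- sqrt(a^2 + (b / den_const)^2)
  if (amplitude < 1e-9) {
    return(list(phase = NA_real_, amplitude = 0,
                pucker_label = NA_character_))
  }
  phase <- .wrap360(atan2(b, a * den_const) * .DEG)
  bin <- floor(phase / 36) + 1L
  list(phase = phase, amplitude = amplitude,
       pucker_label = .PUCKER_LABELS[[bin]])
}

#' Annotate every residue of a chain with its geometric descriptors
#'
#' Computes all per-nucleotide descriptors (backbone torsions, chi with
#' syn/anti class, nu0..nu4, the three pseudotorsion systems and the
#' pseudorotation phase/amplitude/pucker label) for a normalized chain.
#' Unresolved residues yield fully undefined records. The helix form label
#' is never computed from coordinates; it stays `"none"` until an external
#' annotation is ingested (see [ingest_external_annotation()]).
#'
#' @param chain An [rna_chain] object.
#' @return A data.frame with one row per residue and columns `index`,
#'   `nt_code`, `alpha`..`zeta`, `chi`, `chi_class`, `nu0`..`nu4`, `eta`,
#'   `theta`, `eta_prime`, `theta_prime`, `eta_pprime`, `theta_pprime`,
#'   `phase`, `amplitude`, `pucker_label`, `form_label`.
#' @export
annotate_chain <- function(chain) {
  stopifnot(inherits(chain, "rna_chain"))
  L <- length(chain$residues)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    res <- chain$residues[[i]]
    bt <- backbone_torsions(chain, i)
    pt <- pseudotorsions(chain, i)
    nu <- ribose_torsions(chain, i)
    sp <- sugar_pucker(nu)
    rows[[i]] <- data.frame(
      index = i, nt_code = res$nt_code,
      alpha = bt$alpha, beta = bt$beta, gamma = bt$gamma, delta = bt$delta,
      epsilon = bt$epsilon, zeta = bt$zeta,
      chi = bt$chi, chi_class = bt$chi_class,
      nu0 = nu[[1]], nu1 = nu[[2]], nu2 = nu[[3]], nu3 = nu[[4]],
      nu4 = nu[[5]],
      eta = pt$eta, theta = pt$theta,
      eta_prime = pt$eta_prime, theta_prime = pt$theta_prime,
      eta_pprime = pt$eta_pprime, theta_pprime = pt$theta_pprime,
      phase = sp$phase, amplitude = sp$amplitude,
      pucker_label = sp$pucker_label,
      form_label = "none",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
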