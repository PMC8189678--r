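# Synthetic fixtures with known ground truth: idealized RNA helices whose
# riboses are built to an exact pseudorotation state, toy multiple
# sequence alignments with both gap dialects, and selection tables
# (chain list, redundancy equivalence classes, family mappings).

# run expr with a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# ---- specs ---------------------------------------------------------------

#' Specification of a synthetic idealized RNA helix
#'
#' Describes a regular single-stranded helix whose riboses all share one
#' exact pseudorotation state. Defaults emulate an A-form-like geometry
#' (C3'-endo pucker at phase 18 degrees, amplitude 40 degrees, rise
#' 2.81 angstroms, twist 32.7 degrees per residue).
#'
#' @param n_residues Number of residues (positive integer).
#' @param sequence String over `A`, `C`, `G`, `U` of length `n_residues`;
#'   by default drawn uniformly under `seed`.
#' @param pucker_phase_deg Pseudorotation phase P in `[0, 360)`.
#' @param pucker_amplitude_deg Pucker amplitude nu_max in `(0, 90)`.
#' @param rise_per_residue Helical rise in angstroms.
#' @param twist_per_residue Helical twist in degrees.
#' @param chi_deg Glycosidic torsion chi applied to every base.
#' @param coordinate_noise_sd Isotropic Gaussian noise s.d. per atom
#'   coordinate, angstroms (>= 0).
#' @param seed Integer seed controlling sequence draw and noise.
#' @return Validated object of class `helix_spec`.
#' @export
helix_spec <- function(n_residues = 12L, sequence = NULL,
                       pucker_phase_deg = 18, pucker_amplitude_deg = 40,
                       rise_per_residue = 2.81, twist_per_residue = 32.7,
                       chi_deg = 200, coordinate_noise_sd = 0, seed = 1L) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      n_residues < 1 || n_residues != round(n_residues)) {
    stop("n_residues must be a positive integer")
  }
  n_residues <- as.integer(n_residues)
  if (is.null(sequence)) {
    sequence <- .with_seed(seed, paste(
      sample(c("A", "C", "G", "U"), n_residues, replace = TRUE),
      collapse = ""))
  }
  if (nchar(sequence) != n_residues ||
      grepl("[^ACGU]", sequence)) {
    stop("sequence must use the ACGU alphabet and have length n_residues")
  }
  if (pucker_phase_deg < 0 || pucker_phase_deg >= 360) {
    stop("pucker_phase_deg must lie in [0, 360)")
  }
  if (pucker_amplitude_deg <= 0 || pucker_amplitude_deg >= 90) {
    stop("pucker_amplitude_deg must lie in (0, 90)")
  }
  if (coordinate_noise_sd < 0) stop("coordinate_noise_sd must be >= 0")
  structure(list(n_residues = n_residues, sequence = sequence,
                 pucker_phase_deg = pucker_phase_deg,
                 pucker_amplitude_deg = pucker_amplitude_deg,
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 chi_deg = chi_deg,
                 coordinate_noise_sd = coordinate_noise_sd,
                 seed = as.integer(seed)),
            class = "helix_spec")
}

#' Specification of a toy multiple sequence alignment
#'
#' @param n_sequences Number of synthetic homolog rows.
#' @param consensus Consensus sequence over `A`, `C`, `G`, `U`.
#' @param deletion_rate Per-position probability of a `-` deletion gap.
#' @param insertion_rate Per-row, per-junction probability of a one-base
#'   insertion (padded with `.` in the other rows).
#' @param substitution_rate Per-position probability of a base change.
#' @param seed Integer seed.
#' @return Validated object of class `toy_msa_spec`.
#' @export
toy_msa_spec <- function(n_sequences, consensus, deletion_rate = 0.05,
                         insertion_rate = 0.02, substitution_rate = 0.1,
                         seed = 1L) {
  if (!nzchar(consensus) || grepl("[^ACGU]", consensus)) {
    stop("consensus must be a non-empty string over {A,C,G,U}")
  }
  if (n_sequences < 1) stop("n_sequences must be positive")
  for (p in c(deletion_rate, insertion_rate, substitution_rate)) {
    if (p < 0 || p > 1) stop("rates must be probabilities in [0, 1]")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 consensus = consensus, deletion_rate = deletion_rate,
                 insertion_rate = insertion_rate,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "toy_msa_spec")
}

# ---- exact-pucker ribose construction ------------------------------------

# Forward pseudorotation: nu_j = nu_max * cos(P + 144 * (j - 2)), j = 0..4.
.pseudorotation_nu <- function(phase_deg, amplitude_deg) {
  j <- 0:4
  amplitude_deg * cos((phase_deg + 144 * (j - 2)) / .DEG)
}

# Build ring O4', C1', C2', C3', C4' whose measured endocyclic torsions
# equal `nu`: nu1/nu2 are imposed exactly during sequential placement,
# and the three placement bond angles plus the four bond lengths are
# solved by Levenberg-Marquardt so that the closure torsions nu0/nu3/nu4
# match too (to ~1e-7 degrees). The bond lengths must be free: a ring
# with all five lengths fixed cannot realize the pseudorotation torsion
# pattern exactly, so they are softly anchored at ideal values and move
# by a few millangstroms at most.
.build_ribose_ring <- function(nu) {
  ideal <- c(1.414, 1.526, 1.525, 1.527)  # O4'-C1', C1'-C2', C2'-C3', C3'-C4'
  ring_at <- function(par) {
    a <- par[1:3]; b <- par[4:7]
    O4 <- c(0, 0, 0)
    C1 <- c(b[1], 0, 0)
    d <- (180 - a[1]) / .DEG
    C2 <- C1 + b[2] * c(cos(d), sin(d), 0)
    C3 <- .place_atom(O4, C1, C2, b[3], a[2], nu[2])
    C4 <- .place_atom(C1, C2, C3, b[4], a[3], nu[3])
    list(O4 = O4, C1 = C1, C2 = C2, C3 = C3, C4 = C4)
  }
  resid <- function(par) {
    r <- ring_at(par)
    m <- c(dihedral(r$C4, r$O4, r$C1, r$C2),
           dihedral(r$C2, r$C3, r$C4, r$O4),
           dihedral(r$C3, r$C4, r$O4, r$C1))
    c(.angdiff(m, c(nu[1], nu[4], nu[5])), 1e-4 * (par[4:7] - ideal))
  }
  fit <- minpack.lm::nls.lm(
    par = c(106, 101.5, 102.5, ideal), fn = resid,
    control = minpack.lm::nls.lm.control(ftol = 1e-18, ptol = 1e-15,
                                         maxiter = 1000))
  if (max(abs(resid(fit$par)[1:3])) > 1e-5) {
    stop("ribose ring construction did not converge for the requested pucker")
  }
  ring_at(fit$par)
}

# planar base-ring templates (x toward the chi-defining atom, ring at y < 0)
.base_template <- function(base) {
  if (base %in% c("A", "G")) {
    rbind(N9 = c(0, 0), C4 = c(1.37, 0),
          C5 = c(1.793, -1.303), N7 = c(0.685, -2.108),
          C8 = c(-0.423, -1.303),
          C6 = c(3.143, -1.590), N1 = c(4.066, -0.565),
          C2 = c(3.640, 0.747), N3 = c(2.290, 1.034))
  } else {
    rbind(N1 = c(0, 0), C2 = c(1.38, 0),
          N3 = c(2.07, -1.195), C4 = c(1.38, -2.39),
          C5 = c(0, -2.39), C6 = c(-0.69, -1.195))
  }
}

# Full nucleotide template: ribose with exact pucker, backbone substituents
# and a planar base set to the requested chi.
.nucleotide_template <- function(phase_deg, amplitude_deg, base, chi_deg) {
  nu <- .pseudorotation_nu(phase_deg, amplitude_deg)
  ring <- .build_ribose_ring(nu)
  nu2 <- dihedral(ring$C1, ring$C2, ring$C3, ring$C4)
  atoms <- list("O4'" = ring$O4, "C1'" = ring$C1, "C2'" = ring$C2,
                "C3'" = ring$C3, "C4'" = ring$C4)
  # exocyclic substituents (fixed ideal internal coordinates)
  atoms[["C5'"]] <- .place_atom(ring$C2, ring$C3, ring$C4, 1.510, 115,
                                .wrap360(nu2 + 122))
  atoms[["O3'"]] <- .place_atom(ring$C1, ring$C2, ring$C3, 1.423, 110,
                                .wrap360(nu2 - 122))
  atoms[["O2'"]] <- .place_atom(ring$C4, ring$C3, ring$C2, 1.414, 110, 240)
  atoms[["O5'"]] <- .place_atom(ring$C3, ring$C4, atoms[["C5'"]],
                                1.440, 111, 54)
  atoms[["P"]] <- .place_atom(ring$C4, atoms[["C5'"]], atoms[["O5'"]],
                              1.593, 120, 175)
  # glycosidic nitrogen, then the chi-defining atom at the requested torsion
  gly <- if (base %in% c("A", "G")) "N9" else "N1"
  chi_atom <- if (base %in% c("A", "G")) "C4" else "C2"
  nu0 <- dihedral(ring$C4, ring$O4, ring$C1, ring$C2)
  atoms[[gly]] <- .place_atom(ring$C4, ring$O4, ring$C1, 1.48, 108,
                              .wrap360(nu0 + 120))
  atoms[[chi_atom]] <- .place_atom(ring$O4, ring$C1, atoms[[gly]],
                                   1.37, 126, chi_deg)
  # lay the rest of the planar base in the plane through N, chi-atom, C1'
  tpl <- .base_template(base)
  e1 <- atoms[[chi_atom]] - atoms[[gly]]
  e1 <- e1 / sqrt(sum(e1^2))
  v <- ring$C1 - atoms[[gly]]
  e2 <- v - sum(v * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  for (nm in rownames(tpl)) {
    if (nm %in% names(atoms)) next
    atoms[[nm]] <- atoms[[gly]] + tpl[nm, 1] * e1 + tpl[nm, 2] * e2
  }
  do.call(rbind, atoms)
}

# ---- helix generator -----------------------------------------------------

#' Generate a synthetic helix and write it as mmCIF
#'
#' Builds an idealized single-stranded RNA helix from a per-residue
#' template (ribose constructed to the exact requested pseudorotation
#' phase and amplitude, planar base at fixed chi) repeated by the helical
#' rise and twist, writes it as a minimal mmCIF file, and returns the
#' in-memory chain. The 5'-terminal residue is written without a P atom,
#' as in real structures, so that terminal undefined-angle handling is
#' exercised downstream. Deterministic given `spec$seed`.
#'
#' @param spec A [helix_spec()].
#' @param out_path Output mmCIF path, or `NULL` to skip writing.
#' @param structure_id,chain_id Identifiers stamped on the chain.
#' @param resolution,release_date Metadata stamped on the chain.
#' @return The generated [rna_chain] (normalized, indices 1..L).
#' @export
make_helix_mmcif <- function(spec, out_path = NULL,
                             structure_id = "1SYN", chain_id = "A",
                             resolution = 2.0,
                             release_date = "2020-01-15") {
  stopifnot(inherits(spec, "helix_spec"))
  bases <- strsplit(spec$sequence, "")[[1]]
  templates <- list()
  residues <- vector("list", spec$n_residues)
  tw <- spec$twist_per_residue / .DEG
  for (i in seq_len(spec$n_residues)) {
    b <- bases[[i]]
    if (is.null(templates[[b]])) {
      templates[[b]] <- .nucleotide_template(spec$pucker_phase_deg,
                                             spec$pucker_amplitude_deg,
                                             b, spec$chi_deg)
    }
    M <- templates[[b]]
    a <- tw * (i - 1)
    R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    coords <- M %*% t(R)
    coords[, 3] <- coords[, 3] + spec$rise_per_residue * (i - 1)
    if (i == 1L) coords <- coords[rownames(coords) != "P", , drop = FALSE]
    res <- .new_residue(as.character(i), b, atoms = coords, index = i)
    residues[[i]] <- res
  }
  if (spec$coordinate_noise_sd > 0) {
    residues <- .with_seed(spec$seed, {
      for (i in seq_along(residues)) {
        at <- residues[[i]]$atoms
        residues[[i]]$atoms <- at +
          matrix(stats::rnorm(length(at), 0, spec$coordinate_noise_sd),
                 nrow(at), 3)
      }
      residues
    })
  }
  chain <- rna_chain(structure_id, chain_id, residues,
                     resolution = resolution, release_date = release_date)
  if (!is.null(out_path)) write_mmcif(chain, out_path)
  chain
}

# ---- toy alignments ------------------------------------------------------

#' Generate a toy multiple sequence alignment
#'
#' Emits `n_sequences` synthetic homolog rows derived from the consensus
#' by per-position substitutions, deletions (`-`) and insertions (the
#' inserting row gets a base, every other row is padded with `.`,
#' emulating the two gap dialects of covariance-model alignments). When
#' `chain_sequence` is given, a row named `chain_name` carrying it (with
#' alignment padding inserted) is included. Deterministic given the seed.
#'
#' @param spec A [toy_msa_spec()].
#' @param chain_sequence Optional chain sequence (may contain `-` at
#'   unresolved positions); must have the consensus length.
#' @param out_path Optional path prefix; writes `<prefix>.stk` (Stockholm
#'   1.0) and `<prefix>.afa` (aligned FASTA).
#' @param chain_name Row name for the chain sequence.
#' @return Named character vector of aligned rows (equal lengths).
#' @export
make_toy_alignment <- function(spec, chain_sequence = NULL, out_path = NULL,
                               chain_name = "chain") {
  stopifnot(inherits(spec, "toy_msa_spec"))
  L <- nchar(spec$consensus)
  cons <- strsplit(spec$consensus, "")[[1]]
  if (!is.null(chain_sequence) && nchar(chain_sequence) != L) {
    stop("chain_sequence must have the consensus length")
  }
  .with_seed(spec$seed, {
    base_rows <- list()
    for (s in seq_len(spec$n_sequences)) {
      row <- cons
      sub <- stats::runif(L) < spec$substitution_rate
      row[sub] <- vapply(row[sub], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
      del <- stats::runif(L) < spec$deletion_rate
      row[del] <- "-"
      base_rows[[paste0("seq", s)]] <- row
    }
    if (!is.null(chain_sequence)) {
      base_rows[[chain_name]] <- strsplit(chain_sequence, "")[[1]]
    }
    # insertions: per row and junction 0..L; union defines '.' padding
    ins <- lapply(base_rows, function(r)
      which(stats::runif(L + 1) < spec$insertion_rate) - 1L)
    if (!is.null(chain_sequence)) ins[[chain_name]] <- integer(0)
    out <- lapply(base_rows, function(r) character(0))
    for (j in 0:L) {
      inserting <- names(base_rows)[vapply(names(base_rows), function(n)
        j %in% ins[[n]], logical(1))]
      if (length(inserting)) {
        for (n in names(base_rows)) {
          out[[n]] <- c(out[[n]],
                        if (n %in% inserting)
                          sample(c("a", "c", "g", "u"), 1L) else ".")
        }
      }
      if (j < L) {
        for (n in names(base_rows)) out[[n]] <- c(out[[n]], base_rows[[n]][j + 1])
      }
    }
    aln <- vapply(out, paste, character(1), collapse = "")
    if (!is.null(out_path)) {
      write_stockholm(aln, paste0(out_path, ".stk"))
      write_afasta(aln, paste0(out_path, ".afa"))
    }
    aln
  })
}

# ---- selection tables ----------------------------------------------------

#' Generate synthetic selection tables
#'
#' Emits the three tables driving chain selection: a chain list with
#' resolutions drawn uniformly in (0, 6] angstroms, a partition of the
#' chains into redundancy equivalence classes, and a family-mapping table
#' where some chains carry direct mappings and others are only inferable
#' through their class. Deterministic given `seed`.
#'
#' @param n_chains Number of chains (>= `n_classes`).
#' @param n_classes Number of equivalence classes.
#' @param n_families Number of RNA families to draw mappings from.
#' @param p_direct Probability that a chain carries a direct mapping.
#' @param seed Integer seed.
#' @return Object of class `selection_tables`: list of data.frames
#'   `chains` (structure_id, chain_id, resolution), `classes` (class_id,
#'   structure_id, chain_id) and `mappings` (structure_id, chain_id,
#'   family, start, end).
#' @export
make_selection_tables <- function(n_chains, n_classes, n_families = 3L,
                                  p_direct = 0.6, seed = 1L) {
  if (n_chains < n_classes || n_classes < 1) {
    stop("need n_chains >= n_classes >= 1")
  }
  .with_seed(seed, {
    sid <- sprintf("1S%02d", seq_len(n_chains))
    chains <- data.frame(structure_id = sid, chain_id = "A",
                         resolution = round(stats::runif(n_chains, 1e-6, 6), 2),
                         stringsAsFactors = FALSE)
    cls <- c(seq_len(n_classes),
             sample(seq_len(n_classes), n_chains - n_classes, replace = TRUE))
    classes <- data.frame(class_id = sprintf("EC_%03d", cls),
                          structure_id = sid, chain_id = "A",
                          stringsAsFactors = FALSE)
    fams <- sprintf("RF%05d", seq_len(n_families))
    direct <- stats::runif(n_chains) < p_direct
    mappings <- data.frame(structure_id = character(0),
                           chain_id = character(0), family = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
    for (i in which(direct)) {
      mappings <- rbind(mappings, data.frame(
        structure_id = sid[i], chain_id = "A",
        family = sample(fams, 1L), start = 1L,
        end = sample(20:80, 1L), stringsAsFactors = FALSE))
    }
    structure(list(chains = chains, classes = classes, mappings = mappings),
              class = "selection_tables")
  })
}

#' Write selection tables to CSV files
#'
#' @param tables A `selection_tables` object.
#' @param dir Output directory; writes `chains.csv`, `classes.csv`,
#'   `mappings.csv`.
#' @return `dir`, invisibly.
#' @export
write_selection_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "selection_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (n in c("chains", "classes", "mappings")) {
    utils::write.csv(tables[[n]], file.path(dir, paste0(n, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read selection tables from CSV files
#'
#' @param chains,classes,mappings Paths to the three CSV tables.
#' @return A `selection_tables` object.
#' @export
read_selection_tables <- function(chains, classes, mappings) {
  structure(list(
    chains = utils::read.csv(chains, stringsAsFactors = FALSE),
    classes = utils::read.csv(classes, stringsAsFactors = FALSE),
    mappings = utils::read.csv(mappings, stringsAsFactors = FALSE)),
    class = "selection_tables")
}
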