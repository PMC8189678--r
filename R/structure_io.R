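# mmCIF chain extraction and normalization: renumbering from one,
# ligand/ion/water removal, modified-base folding to parent bases, and
# materialization of unresolved polymer positions.

.WATERS_IONS <- c("HOH", "DOD", "WAT",
                  "NA", "K", "LI", "RB", "CS", "MG", "CA", "SR", "BA",
                  "MN", "FE", "FE2", "CO", "NI", "CU", "ZN", "CD", "HG",
                  "CL", "BR", "IOD", "F")

.STANDARD_NT <- c("A", "C", "G", "U")

# Bundled modified-ribonucleotide parent table (inst/extdata); cached.
.modified_nt_env <- new.env(parent = emptyenv())

.modified_nt_table <- function() {
  if (is.null(.modified_nt_env$tab)) {
    path <- system.file("extdata", "modified_nucleotides.csv",
                        package = "rnaforge")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    .modified_nt_env$tab <- stats::setNames(tab$parent, tab$comp_id)
  }
  .modified_nt_env$tab
}

#' Map a chemical component id to its parent base
#'
#' Standard `A`, `C`, `G`, `U` map to themselves unmodified; entries of the
#' bundled modified-ribonucleotide table (curated from the wwPDB chemical
#' component dictionary `one_letter_code`/parent fields for common modified
#' residues) map to their parent base with `is_modified = TRUE`; anything
#' else maps to `("N", TRUE)`.
#'
#' @param component_id Chemical component identifier (e.g. `"PSU"`).
#' @return List with `parent_base` (one of A, C, G, U, N) and `is_modified`.
#' @examples
#' map_modified_base("G")    # G, unmodified
#' map_modified_base("PSU")  # pseudouridine -> U, modified
#' @export
map_modified_base <- function(component_id) {
  if (!is.character(component_id) || length(component_id) != 1L ||
      is.na(component_id) || !nzchar(component_id)) {
    stop("component_id must be a non-empty string")
  }
  comp <- toupper(component_id)
  if (comp %in% .STANDARD_NT) {
    return(list(parent_base = comp, is_modified = FALSE))
  }
  tab <- .modified_nt_table()
  if (comp %in% names(tab)) {
    return(list(parent_base = unname(tab[[comp]]), is_modified = TRUE))
  }
  list(parent_base = "N", is_modified = TRUE)
}

.is_nucleotide_comp <- function(comp) {
  comp <- toupper(comp)
  comp %in% .STANDARD_NT | comp %in% names(.modified_nt_table())
}

# ---- containers ----------------------------------------------------------

.new_residue <- function(auth_label, comp_id, atoms = NULL,
                         group = "ATOM", index = NA_integer_) {
  resolved <- !is.null(atoms) && nrow(atoms) > 0L
  mb <- map_modified_base(comp_id)
  nt <- if (!resolved) {
    "-"
  } else if (mb$is_modified) {
    if (mb$parent_base == "N") "N" else tolower(mb$parent_base)
  } else {
    mb$parent_base
  }
  list(index = index, auth_label = auth_label, nt_code = nt,
       is_modified = mb$is_modified, parent_base = mb$parent_base,
       comp_id = toupper(comp_id), group = group,
       atoms = atoms, resolved = resolved)
}

#' RNA chain container
#'
#' An ordered list of residues (with atom coordinates and provenance
#' metadata) extracted from one polymer chain of a structure file.
#' Residues are numbered 1..L after [normalize_numbering()]; original
#' author identifiers are retained in each residue's `auth_label`.
#'
#' @param structure_id PDB-style structure identifier.
#' @param chain_id Chain identifier within the structure.
#' @param residues List of residue records (internal layout).
#' @param resolution Resolution in angstroms, or `NA` when unknown.
#' @param release_date ISO-8601 date string, or `NA`.
#' @param mapping Optional list `(family, start, end)` set by the
#'   selection stage.
#' @return An object of class `rna_chain`.
#' @export
rna_chain <- function(structure_id, chain_id, residues,
                      resolution = NA_real_, release_date = NA_character_,
                      mapping = NULL) {
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 resolution = resolution, release_date = release_date,
                 residues = residues, mapping = mapping),
            class = "rna_chain")
}

#' @export
print.rna_chain <- function(x, ...) {
  L <- length(x$residues)
  nres <- sum(vapply(x$residues, function(r) isTRUE(r$resolved), logical(1)))
  cat(sprintf("<rna_chain %s_%s: %d residues (%d resolved), resolution %s>\n",
              x$structure_id, x$chain_id, L, nres,
              ifelse(is.na(x$resolution), "unknown",
                     format(x$resolution))))
  cat(" sequence: ", chain_sequence(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.rna_chain <- function(x) length(x$residues)

#' Chain sequence with '-' at unresolved positions
#'
#' @param chain An [rna_chain] object.
#' @return Single string over the nucleotide alphabet plus `-`; modified
#'   bases appear as lowercase parent letters.
#' @export
chain_sequence <- function(chain) {
  paste(vapply(chain$residues, `[[`, character(1), "nt_code"), collapse = "")
}

# ---- parsing -------------------------------------------------------------

.col_or <- function(df, names, default = NULL) {
  for (n in names) if (n %in% colnames(df)) return(df[[n]])
  default
}

#' Parse an mmCIF file into RNA chains
#'
#' Reads the `atom_site` records (model 1 only, first alternate location
#' only), splits them by chain, drops waters and monatomic ions, and
#' returns one [rna_chain] per polymer chain containing at least one
#' ribonucleotide. Unresolved polymer positions are materialized as
#' unresolved residues when the file's `entity_poly_seq` category implies
#' them; gaps in author numbering alone never create residues. By default
#' each chain is then normalized: ligands removed ([strip_ligands()]) and
#' residues renumbered from one ([normalize_numbering()]).
#'
#' @param path Path to an mmCIF file.
#' @param chains Optional character vector restricting extraction to these
#'   chain identifiers.
#' @param normalize Apply [strip_ligands()] and [normalize_numbering()]
#'   (default `TRUE`).
#' @return List of [rna_chain] objects. Chains with zero nucleotides
#'   (e.g. protein or backbone-only chains) are skipped with a warning.
#' @export
parse_mmcif <- function(path, chains = NULL, normalize = TRUE) {
  cats <- read_mmcif_categories(path)
  as_df <- cats$atom_site
  if (is.null(as_df)) stop("no atom_site category in mmCIF file: ", path)

  atom_id <- .col_or(as_df, c("label_atom_id", "auth_atom_id"))
  comp_id <- .col_or(as_df, c("label_comp_id", "auth_comp_id"))
  asym_id <- .col_or(as_df, c("label_asym_id", "auth_asym_id"))
  if (is.null(atom_id) || is.null(comp_id) || is.null(asym_id) ||
      !all(c("Cartn_x", "Cartn_y", "Cartn_z") %in% colnames(as_df))) {
    stop("atom_site category lacks required items in ", path)
  }
  auth_seq <- .col_or(as_df, c("auth_seq_id", "label_seq_id"))
  label_seq <- .col_or(as_df, c("label_seq_id"),
                       default = rep(NA_character_, nrow(as_df)))
  ins <- .col_or(as_df, c("pdbx_PDB_ins_code"),
                 default = rep("?", nrow(as_df)))
  entity <- .col_or(as_df, c("label_entity_id"),
                    default = rep(NA_character_, nrow(as_df)))
  group <- .col_or(as_df, c("group_PDB"), default = rep("ATOM", nrow(as_df)))
  model <- .col_or(as_df, c("pdbx_PDB_model_num"),
                   default = rep("1", nrow(as_df)))
  alt <- .col_or(as_df, c("label_alt_id"), default = rep(".", nrow(as_df)))

  keep <- model == model[[1]]                          # model 1 only
  keep <- keep & !(toupper(comp_id) %in% .WATERS_IONS) # no waters/ions
  idx <- which(keep)
  # keep first-listed altloc per (chain, residue, atom)
  akey <- paste(asym_id[idx], auth_seq[idx], ins[idx], atom_id[idx])
  idx <- idx[!duplicated(akey)]

  resolution <- suppressWarnings(as.numeric(
    .col_or(cats$refine, "ls_d_res_high",
            .col_or(cats$em_3d_reconstruction, "resolution", NA))[1]))
  release_date <- .col_or(cats$pdbx_database_status,
                          "recvd_initial_deposition_date", NA_character_)[1]
  structure_id <- .col_or(cats$entry, "id",
                          toupper(sub("[.].*$", "", basename(path))))[1]

  out <- list()
  for (ch in unique(asym_id[idx])) {
    if (!is.null(chains) && !(ch %in% chains)) next
    ci <- idx[asym_id[idx] == ch]
    rkey <- paste(auth_seq[ci], ins[ci])
    first <- ci[!duplicated(rkey)]
    residues <- list()
    seen_seq <- integer(0)
    for (k in seq_along(first)) {
      ri <- ci[rkey == rkey[!duplicated(rkey)][k]]
      coords <- cbind(as.numeric(as_df$Cartn_x[ri]),
                      as.numeric(as_df$Cartn_y[ri]),
                      as.numeric(as_df$Cartn_z[ri]))
      rownames(coords) <- atom_id[ri]
      lab <- auth_seq[ri[1]]
      if (!ins[ri[1]] %in% c("?", ".", "")) {
        lab <- paste0(lab, ins[ri[1]])
      }
      res <- .new_residue(lab, comp_id[ri[1]], atoms = coords,
                          group = group[ri[1]])
      ls <- suppressWarnings(as.integer(label_seq[ri[1]]))
      res$label_seq <- ls
      residues[[length(residues) + 1L]] <- res
      if (!is.na(ls)) seen_seq <- c(seen_seq, ls)
    }
    # materialize unresolved residues declared by entity_poly_seq
    eps <- cats$entity_poly_seq
    ent <- entity[ci[1]]
    if (!is.null(eps) && !is.na(ent) &&
        all(c("entity_id", "num", "mon_id") %in% colnames(eps))) {
      poly <- eps[eps$entity_id == ent, , drop = FALSE]
      nums <- suppressWarnings(as.integer(poly$num))
      missing_i <- which(!is.na(nums) & !(nums %in% seen_seq))
      for (m in missing_i) {
        res <- .new_residue(NA_character_, poly$mon_id[m], atoms = NULL)
        res$label_seq <- nums[m]
        residues[[length(residues) + 1L]] <- res
      }
      # polymer residues in sequence order, non-polymer entries after
      ls_all <- vapply(residues, function(r)
        if (is.null(r$label_seq) || is.na(r$label_seq)) Inf
        else as.numeric(r$label_seq), numeric(1))
      residues <- residues[order(ls_all, seq_along(residues))]
    }
    n_nt <- sum(vapply(residues, function(r)
      .is_nucleotide_comp(r$comp_id), logical(1)))
    if (n_nt == 0L) {
      warning("chain ", ch, " of ", structure_id,
              " contains no nucleotides; skipped")
      next
    }
    chain <- rna_chain(structure_id, ch, residues,
                       resolution = resolution,
                       release_date = release_date)
    if (normalize) {
      chain <- strip_ligands(chain)
      chain <- normalize_numbering(chain)
    }
    out[[length(out) + 1L]] <- chain
  }
  out
}

#' Renumber a chain's residues from one to its length
#'
#' Rewrites residue indices to 1..L in polymer order, retaining the
#' original author identifiers (which may contain letters, negative
#' numbers, or offsets by a thousand) in `auth_label`. Idempotent.
#'
#' @param chain An [rna_chain] object.
#' @return The chain with consecutive indices.
#' @export
normalize_numbering <- function(chain) {
  stopifnot(inherits(chain, "rna_chain"))
  labs <- vapply(chain$residues, function(r)
    if (is.null(r$auth_label)) NA_character_ else as.character(r$auth_label),
    character(1))
  dup <- unique(labs[!is.na(labs) & duplicated(labs)])
  if (length(dup)) {
    stop("duplicate author labels within chain ", chain$chain_id, ": ",
         paste(dup, collapse = ", "))
  }
  for (i in seq_along(chain$residues)) chain$residues[[i]]$index <- i
  chain
}

.has_phosphate_link <- function(chain, i) {
  res <- chain$residues[[i]]
  if (!isTRUE(res$resolved)) return(FALSE)
  near <- function(a, b) !is.null(a) && !is.null(b) &&
    sqrt(sum((a - b)^2)) < 2.2
  prev <- if (i > 1L) chain$residues[[i - 1L]] else NULL
  nxt <- if (i < length(chain$residues)) chain$residues[[i + 1L]] else NULL
  near(.res_atom(res, "P"), .res_atom(prev, "O3'")) ||
    near(.res_atom(nxt, "P"), .res_atom(res, "O3'"))
}

#' Remove ligands and small molecules from a chain
#'
#' A residue is treated as a ligand and removed when its component id is
#' not a ribonucleotide or a recognized modified ribonucleotide AND it is
#' either marked non-polymer (`HETATM`) or lacks both a C1' atom and a
#' phosphate linkage to a neighbouring residue. Detection is heuristic by
#' nature; every removal is reported via `message()`.
#'
#' @param chain An [rna_chain] object.
#' @return The chain without ligand residues (possibly empty).
#' @export
strip_ligands <- function(chain) {
  stopifnot(inherits(chain, "rna_chain"))
  keep <- logical(length(chain$residues))
  for (i in seq_along(chain$residues)) {
    res <- chain$residues[[i]]
    if (.is_nucleotide_comp(res$comp_id)) {
      keep[i] <- TRUE
    } else if (!isTRUE(res$resolved)) {
      keep[i] <- TRUE  # unresolved polymer positions are not ligands
    } else {
      nonpoly <- identical(res$group, "HETATM")
      nt_like <- ("C1'" %in% rownames(res$atoms)) ||
        .has_phosphate_link(chain, i)
      keep[i] <- !nonpoly && nt_like
    }
    if (!keep[i]) {
      message("removed ligand ", res$comp_id, " (", res$auth_label,
              ") from chain ", chain$structure_id, "_", chain$chain_id)
    }
  }
  chain$residues <- chain$residues[keep]
  chain
}

# ---- writing -------------------------------------------------------------

#' Write an RNA chain back to mmCIF
#'
#' Emits a minimal mmCIF file (entry id, resolution, deposition date,
#' `entity_poly_seq`, `atom_site`) that [parse_mmcif()] reads back
#' loss-free. Unresolved residues appear only in `entity_poly_seq`.
#'
#' @param chain An [rna_chain] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(chain, path) {
  stopifnot(inherits(chain, "rna_chain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", chain$structure_id),
               paste0("_entry.id ", .cif_quote(chain$structure_id))), con)
  if (!is.na(chain$resolution)) {
    writeLines(paste0("_refine.ls_d_res_high ",
                      format(chain$resolution)), con)
  }
  if (!is.na(chain$release_date)) {
    writeLines(paste0("_pdbx_database_status.recvd_initial_deposition_date ",
                      chain$release_date), con)
  }
  writeLines("#", con)
  L <- length(chain$residues)
  poly <- data.frame(entity_id = "1", num = as.character(seq_len(L)),
                     mon_id = vapply(chain$residues, `[[`, character(1),
                                     "comp_id"))
  .cif_write_loop(con, "entity_poly_seq", poly)
  rows <- list()
  aid <- 0L
  for (i in seq_len(L)) {
    res <- chain$residues[[i]]
    if (!isTRUE(res$resolved)) next
    at <- res$atoms
    for (k in seq_len(nrow(at))) {
      aid <- aid + 1L
      rows[[aid]] <- data.frame(
        group_PDB = res$group, id = as.character(aid),
        type_symbol = substr(gsub("[^A-Za-z].*$", "", rownames(at)[k]), 1, 1),
        label_atom_id = rownames(at)[k],
        label_alt_id = ".", label_comp_id = res$comp_id,
        label_asym_id = chain$chain_id, label_entity_id = "1",
        label_seq_id = as.character(i),
        pdbx_PDB_ins_code = "?",
        Cartn_x = sprintf("%.9f", at[k, 1]),
        Cartn_y = sprintf("%.9f", at[k, 2]),
        Cartn_z = sprintf("%.9f", at[k, 3]),
        occupancy = "1.00",
        auth_seq_id = if (is.na(res$auth_label)) as.character(i)
                      else res$auth_label,
        auth_asym_id = chain$chain_id,
        pdbx_PDB_model_num = "1",
        stringsAsFactors = FALSE)
    }
  }
  .cif_write_loop(con, "atom_site", do.call(rbind, rows))
  invisible(path)
}
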