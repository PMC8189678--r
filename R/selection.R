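# Chain selection from provided tables: resolution filtering, family
# mapping inference through redundancy equivalence classes, and chain
# copy/truncation when several families map to one chain.

#' Filter a chain list by resolution
#'
#' Keeps chains whose resolution is known and at most `threshold`
#' angstroms (boundary included, 4.0 by default). Chains with unknown
#' resolution (e.g. NMR structures) are excluded.
#'
#' @param chains data.frame with columns `structure_id`, `chain_id`,
#'   `resolution`.
#' @param threshold Resolution cutoff in angstroms (> 0).
#' @return The filtered data.frame.
#' @export
filter_by_resolution <- function(chains, threshold = 4.0) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive resolution in angstroms")
  }
  res <- suppressWarnings(as.numeric(chains$resolution))
  chains[!is.na(res) & res <= threshold, , drop = FALSE]
}

#' Infer family mappings through equivalence classes
#'
#' Chains with direct mappings keep them. A chain without a direct
#' mapping inherits every family mapped to any chain of its equivalence
#' class (`inferred = TRUE`). A chain mapped to k > 1 families yields k
#' selected rows, each truncated to its mapping's residue range, so that
#' one portion per family can be saved. Chains with neither a direct nor
#' an inferable mapping are dropped. When several classmates provide the
#' same family with different ranges, the widest range wins; inferred
#' ranges are later clipped to the recipient chain's length at dataset
#' build time. Output is canonically sorted and independent of input row
#' order.
#'
#' @param tables A `selection_tables` object (see
#'   [make_selection_tables()], [read_selection_tables()]).
#' @return data.frame of selected chains: `structure_id`, `chain_id`,
#'   `family`, `start`, `end`, `inferred`.
#' @export
infer_mappings <- function(tables) {
  stopifnot(inherits(tables, "selection_tables"))
  chains <- tables$chains
  classes <- tables$classes
  mappings <- tables$mappings
  key <- function(df) paste(df$structure_id, df$chain_id, sep = "_")
  ckey <- key(chains)

  if (nrow(mappings)) {
    known <- key(mappings) %in% ckey
    if (any(!known)) {
      warning("mappings reference unknown chains: ",
              paste(unique(key(mappings)[!known]), collapse = ", "),
              "; ignored")
      mappings <- mappings[known, , drop = FALSE]
    }
    if (any(mappings$start < 1 | mappings$start > mappings$end)) {
      stop("mapping ranges must satisfy 1 <= start <= end")
    }
  }

  class_of <- stats::setNames(classes$class_id, key(classes))
  out <- list()
  for (i in seq_len(nrow(chains))) {
    k <- ckey[[i]]
    direct <- mappings[key(mappings) == k, , drop = FALSE]
    if (nrow(direct)) {
      cand <- direct
      inferred <- FALSE
    } else {
      if (!k %in% names(class_of)) next
      cls <- class_of[[k]]
      mates <- names(class_of)[class_of == cls & names(class_of) != k]
      cand <- mappings[key(mappings) %in% mates, , drop = FALSE]
      if (!nrow(cand)) next
      inferred <- TRUE
    }
    # one row per family; widest range wins among duplicates
    for (fam in sort(unique(cand$family))) {
      cf <- cand[cand$family == fam, , drop = FALSE]
      widths <- cf$end - cf$start
      best <- cf[order(-widths, cf$start)[1], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        structure_id = chains$structure_id[[i]],
        chain_id = chains$chain_id[[i]],
        family = fam, start = best$start, end = best$end,
        inferred = inferred, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(structure_id = character(0), chain_id = character(0),
                      family = character(0), start = integer(0),
                      end = integer(0), inferred = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$structure_id, res$chain_id, res$family), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select chains: resolution filter then mapping inference
#'
#' Convenience wrapper applying [filter_by_resolution()] to the chain
#' list and then [infer_mappings()] on the surviving chains.
#'
#' @inheritParams infer_mappings
#' @param resolution_max Resolution threshold in angstroms.
#' @return data.frame as returned by [infer_mappings()], joined with each
#'   chain's resolution.
#' @export
select_chains <- function(tables, resolution_max = 4.0) {
  stopifnot(inherits(tables, "selection_tables"))
  kept <- filter_by_resolution(tables$chains, resolution_max)
  # inference runs on the full tables: a filtered-out classmate's mapping
  # still propagates to the chains that survive the filter
  sel <- infer_mappings(tables)
  kk <- paste(kept$structure_id, kept$chain_id, sep = "_")
  sel <- sel[paste(sel$structure_id, sel$chain_id, sep = "_") %in% kk, ,
             drop = FALSE]
  rownames(sel) <- NULL
  res_of <- stats::setNames(kept$resolution, kk)
  sel$resolution <- unname(res_of[paste(sel$structure_id, sel$chain_id,
                                        sep = "_")])
  sel
}

#' Truncate a chain to a mapping's residue range
#'
#' Copies the chain, keeps the residues of the closed range
#' `[start, end]` on normalized indices (clipped to the chain length,
#' with a message when clipping occurs), renumbers from one, and records
#' the mapping on the chain.
#'
#' @param chain An [rna_chain] object (normalized).
#' @param family Family accession.
#' @param start,end Closed residue range on normalized indices.
#' @return The truncated [rna_chain] with `$mapping` set.
#' @export
truncate_chain <- function(chain, family, start, end) {
  stopifnot(inherits(chain, "rna_chain"))
  L <- length(chain$residues)
  if (start < 1 || start > end) stop("need 1 <= start <= end")
  if (end > L) {
    message("mapping range [", start, ", ", end, "] clipped to chain length ",
            L, " for ", chain$structure_id, "_", chain$chain_id)
    end <- L
  }
  if (start > L) stop("mapping range starts beyond chain length")
  chain$residues <- chain$residues[start:end]
  chain <- normalize_numbering(chain)
  chain$mapping <- list(family = family, start = start, end = end)
  chain
}
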