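# Gap-aware merging of the per-residue 3D record stream with the aligned
# chain row, reconciling the two gap dialects: '-' in the 3D sequence
# marks an unresolved residue, '-' in the alignment a deletion to the
# family consensus, '.' insertion padding.

.fold_base <- function(x) chartr("acgu", "ACGU", x)

#' Map chain residues to alignment columns
#'
#' Two-pointer merge of the gapped chain sequence (`-` = unresolved
#' residue) with the chain's aligned row (`-` = deletion gap, `.` =
#' insertion padding), applying, in order:
#' \enumerate{
#'   \item symbol match (base facing the same base, or `-` facing `-`):
#'     pair the positions and advance both;
#'   \item unresolved residue facing a non-gap: look ahead in the aligned
#'     row for the next `-` before the next base (ignoring `.`); if none,
#'     for the next `.` before the next base; pair with the first found
#'     (consuming it); if neither exists the residue keeps unknown
#'     homology;
#'   \item alignment gap facing a resolved base: skip the column;
#'   \item two differing bases: mismatch error (the sequences do not
#'     describe the same molecule).
#' }
#'
#' @param seq3d Chain sequence over bases and `-` (unresolved).
#' @param seqaln Aligned chain row over bases, `-` and `.`.
#' @return data.frame with one row per chain position, in order:
#'   `chain_index` (1..L), `alignment_column` (or `NA`), `nt_code`,
#'   `nt_align_code` (equal to `nt_code` until [fill_missing()]),
#'   `homology_known`. Non-`NA` `alignment_column` values are strictly
#'   increasing.
#' @examples
#' remap("ACG", "A.CG")  # residues 1,2,3 -> columns 1,3,4
#' remap("A-G", "AG")    # residue 2 keeps unknown homology
#' @export
remap <- function(seq3d, seqaln) {
  s3 <- strsplit(seq3d, "")[[1]]
  sa <- strsplit(seqaln, "")[[1]]
  if (any(!s3 %in% c("A", "C", "G", "U", "a", "c", "g", "u", "N", "-"))) {
    stop("seq3d may contain bases and '-' only")
  }
  f3 <- .fold_base(s3)
  fa <- .fold_base(sa)
  is_base_a <- !(fa %in% c("-", "."))
  L <- length(s3)
  ci <- integer(0); ac <- integer(0); hk <- logical(0)
  i <- 1L; j <- 1L
  mismatch <- function(i, j) {
    stop("sequence mismatch between 3D chain and alignment at residue ", i,
         " ('", s3[i], "') vs column ", j, " ('", sa[j], "')",
         call. = FALSE)
  }
  while (i <= L) {
    if (j > length(sa)) {
      if (f3[i] != "-") {
        stop("sequence mismatch: residue ", i, " ('", s3[i],
             "') has no remaining alignment column", call. = FALSE)
      }
      ci <- c(ci, i); ac <- c(ac, NA_integer_); hk <- c(hk, FALSE)
      i <- i + 1L
      next
    }
    a3 <- f3[i]; aa <- fa[j]
    if (a3 == aa || (a3 == "N" && is_base_a[j])) {
      # case 1: identical symbols (base==base or gap==gap)
      ci <- c(ci, i); ac <- c(ac, j); hk <- c(hk, TRUE)
      i <- i + 1L; j <- j + 1L
    } else if (a3 == "-") {
      # case 2: unresolved residue facing a non-matching alignment symbol:
      # search up to (not including) the next base for '-', then for '.'
      horizon <- j
      while (horizon <= length(sa) && !is_base_a[horizon]) {
        horizon <- horizon + 1L
      }
      cand <- if (horizon > j) (j:(horizon - 1L)) else integer(0)
      hit <- cand[fa[cand] == "-"][1]
      if (is.na(hit)) hit <- cand[fa[cand] == "."][1]
      if (!is.na(hit)) {
        ci <- c(ci, i); ac <- c(ac, hit); hk <- c(hk, TRUE)
        i <- i + 1L; j <- hit + 1L  # consume the matched gap column
      } else {
        ci <- c(ci, i); ac <- c(ac, NA_integer_); hk <- c(hk, FALSE)
        i <- i + 1L
      }
    } else if (aa %in% c("-", ".")) {
      # case 3: alignment gap facing a resolved base: skip the column
      j <- j + 1L
    } else {
      mismatch(i, j)  # case 4
    }
  }
  if (j <= length(sa) && any(is_base_a[j:length(sa)])) {
    k <- (j:length(sa))[is_base_a[j:length(sa)]][1]
    stop("sequence mismatch: alignment column ", k, " ('", sa[k],
         "') has no remaining chain residue", call. = FALSE)
  }
  data.frame(chain_index = ci, alignment_column = ac,
             nt_code = s3, nt_align_code = s3,
             homology_known = hk, stringsAsFactors = FALSE)
}

#' Fill unresolved positions with the family consensus
#'
#' When enabled, every unresolved position (`nt_code == "-"`) with known
#' homology receives the consensus base of its alignment column in
#' `nt_align_code`; `nt_code` keeps the gap character so the information
#' that the residue is unresolved is never lost. Positions with unknown
#' homology have no consensus and keep the gap in both fields.
#'
#' @param positions data.frame from [remap()].
#' @param pssm data.frame from [compute_pssm()] for the chain's family
#'   alignment; `alignment_column` values index its rows.
#' @param enabled Set `FALSE` to return `positions` unchanged.
#' @return `positions` with `nt_align_code` updated.
#' @export
fill_missing <- function(positions, pssm, enabled = TRUE) {
  if (!enabled) return(positions)
  idx <- which(positions$nt_code == "-" & positions$homology_known)
  for (i in idx) {
    col <- positions$alignment_column[[i]]
    if (is.na(col) || col < 1L || col > nrow(pssm)) {
      stop("alignment_column ", col, " outside the PSSM")
    }
    cons <- pssm$consensus[[col]]
    if (cons != "-") positions$nt_align_code[[i]] <- cons
  }
  positions
}
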