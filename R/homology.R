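# Multiple sequence alignments: Stockholm / aligned-FASTA IO preserving
# the two gap dialects ('-' deletion vs '.' insertion padding), PSSM
# summarization by plain base counts, pairwise sequence identity and
# Ward clustering of identity matrices.

.MSA_BASES <- c("A", "C", "G", "U")

#' Read a multiple sequence alignment
#'
#' Reads Stockholm 1.0 or aligned FASTA into a named character vector of
#' equal-length rows. Both gap symbols are preserved as distinct
#' characters (`-` deletion with respect to the consensus, `.` insertion
#' padding). `T`/`t` are accepted and normalized to `U`/`u` with a note,
#' since DNA-alphabet inputs occur in rRNA sequence databases. Lowercase
#' letters (the covariance-model insertion convention) are preserved here
#' and folded to uppercase during PSSM computation.
#'
#' @param path Path to the alignment file.
#' @param format `"stockholm"` or `"afasta"`; `"auto"` (default) decides
#'   from the first line.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "afasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "afasta"
  }
  rows <- if (format == "stockholm") {
    .read_stockholm(path)
  } else {
    seqs <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(seqs), names(seqs))
  }
  if (length(rows) == 0L) stop("empty alignment: ", path)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment rows in ", path, " (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  if (any(grepl("[Tt]", rows))) {
    message("note: 'T' symbols normalized to 'U' in ", basename(path))
    rows <- chartr("Tt", "Uu", rows)
  }
  pos <- regexpr("[^ACGUNacgun.~-]", rows)
  if (any(pos > 0)) {
    i <- which(pos > 0)[[1]]
    stop("unknown alignment symbol '",
         substring(rows[[i]], pos[[i]], pos[[i]]), "' in row '",
         names(rows)[i], "' at column ", pos[[i]])
  }
  chartr("~", "-", rows)
}

.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1]])) {
    stop("not a Stockholm file: ", path)
  }
  rows <- character(0)
  for (line in lines[-1]) {
    if (grepl("^\\s*$", line) || startsWith(line, "#")) next
    if (startsWith(line, "//")) break
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm row: ", line)
    # interleaved blocks concatenate per name
    if (parts[1] %in% names(rows)) {
      rows[[parts[1]]] <- paste0(rows[[parts[1]]], parts[2])
    } else {
      rows[[parts[1]]] <- parts[2]
    }
  }
  rows
}

#' Write an alignment in Stockholm 1.0 format
#' @param rows Named character vector of equal-length aligned rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(rows, path) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-20s %s", names(rows), unname(rows)),
               "//"), path)
  invisible(path)
}

#' Write an alignment in aligned-FASTA format
#' @inheritParams write_stockholm
#' @return `path`, invisibly.
#' @export
write_afasta <- function(rows, path) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  writeLines(as.vector(rbind(paste0(">", names(rows)), unname(rows))), path)
  invisible(path)
}

#' Summarize an alignment into a position-specific scoring matrix
#'
#' One profile per column: base frequencies (plain counts, no sequence
#' weighting), a pooled gap fraction covering both gap dialects, the
#' count of sequences and the consensus symbol. Lowercase letters are
#' folded to uppercase; `N` and other ambiguity/modified codes count as
#' `other`. The consensus is the base of maximal frequency (ties broken
#' alphabetically A < C < G < U), or `-` when the gap fraction exceeds
#' every base frequency.
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @return data.frame with one row per column: `column`, `freq_A`,
#'   `freq_C`, `freq_G`, `freq_U`, `freq_other`, `gap_fraction`,
#'   `consensus`, `depth`.
#' @export
compute_pssm <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  n <- nrow(mat)
  L <- ncol(mat)
  out <- vector("list", L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap <- col %in% c("-", ".")
    fr <- vapply(.MSA_BASES, function(b) sum(col == b), numeric(1)) / n
    other <- sum(!gap & !(col %in% .MSA_BASES)) / n
    gapf <- sum(gap) / n
    cons <- if (gapf > max(fr) && gapf > other) {
      "-"
    } else if (other > max(fr)) {
      "N"
    } else {
      .MSA_BASES[which.max(fr)]  # which.max takes the first (alphabetical) tie
    }
    out[[j]] <- data.frame(column = j, freq_A = fr[["A"]], freq_C = fr[["C"]],
                           freq_G = fr[["G"]], freq_U = fr[["U"]],
                           freq_other = other, gap_fraction = gapf,
                           consensus = cons, depth = n,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pairwise sequence identity of two aligned rows
#'
#' Fraction of identical-base columns among columns where at least one of
#' the two rows has a base; columns gapped in both rows are ignored.
#' Case-insensitive; both gap dialects count as gaps.
#'
#' @param row_i,row_j Equal-length aligned sequences.
#' @return Identity fraction in `[0, 1]`, or `NA` when every column is
#'   gapped in both rows.
#' @export
sequence_identity <- function(row_i, row_j) {
  a <- strsplit(toupper(row_i), "")[[1]]
  b <- strsplit(toupper(row_j), "")[[1]]
  if (length(a) != length(b)) stop("rows must be aligned (equal length)")
  agap <- a %in% c("-", ".")
  bgap <- b %in% c("-", ".")
  scored <- !(agap & bgap)
  if (!any(scored)) return(NA_real_)
  sum(scored & !agap & !bgap & a == b) / sum(scored)
}

#' Pairwise identity matrix of aligned chains
#'
#' @param alignment Named character vector of aligned rows.
#' @return Symmetric matrix of identity fractions with unit diagonal for
#'   non-empty rows, labelled by row names.
#' @export
identity_matrix <- function(alignment) {
  n <- length(alignment)
  m <- matrix(NA_real_, n, n, dimnames = list(names(alignment),
                                              names(alignment)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- if (i == j) {
        if (grepl("[^.-]", alignment[[i]])) 1 else NA_real_
      } else {
        sequence_identity(alignment[[i]], alignment[[j]])
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Cluster chains by sequence identity with Ward's method
#'
#' Agglomerative hierarchical clustering (Ward linkage, `stats::hclust`
#' method `ward.D2`) on the dissimilarity `1 - identity`. Used to order
#' the identity-matrix panels of a family.
#'
#' @param matrix Square symmetric identity matrix (see [identity_matrix()]).
#' @return An `hclust` object; leaf order in `$order`.
#' @export
cluster_chains <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 2L) {
    stop("clustering needs at least 2 chains")
  }
  d <- stats::as.dist(1 - matrix)
  stats::hclust(d, method = "ward.D2")
}
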