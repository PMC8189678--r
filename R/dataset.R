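# Dataset assembly: per-chain nucleotide records joined with homology
# columns in a single-file relational store (written as an SQL dump in
# SQLite dialect, with a matching reader), per-chain CSV export with
# composable date/resolution/family filters, and ingestion of external
# base-pair / helix-form annotations.

.LW_FAMILIES <- as.vector(outer(c("c", "t"),
                                c("WW", "WH", "WS", "HH", "HS", "SS"),
                                paste0))

.NT_NUMERIC <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "chi", "nu0", "nu1", "nu2", "nu3", "nu4",
                 "eta", "theta", "eta_prime", "theta_prime",
                 "eta_pprime", "theta_pprime", "phase", "amplitude",
                 "freq_A", "freq_C", "freq_G", "freq_U", "freq_other",
                 "gap_fraction")

# column order of the nucleotides table / exported CSVs
.NT_COLUMNS <- c("chain_key", "index", "auth_label", "nt_code",
                 "nt_align_code", "is_modified",
                 "alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "chi", "chi_class", "nu0", "nu1", "nu2", "nu3", "nu4",
                 "eta", "theta", "eta_prime", "theta_prime",
                 "eta_pprime", "theta_pprime",
                 "phase", "amplitude", "pucker_label", "form_label",
                 "paired", "pair_type", "alignment_column",
                 "freq_A", "freq_C", "freq_G", "freq_U", "freq_other",
                 "gap_fraction")

.store_schema <- function() {
  list(
    chains = c(chain_key = "TEXT", structure_id = "TEXT", chain_id = "TEXT",
               family = "TEXT", mapping_start = "INTEGER",
               mapping_end = "INTEGER", inferred = "INTEGER",
               resolution = "REAL", release_date = "TEXT",
               length = "INTEGER"),
    families = c(family = "TEXT", n_columns = "INTEGER", depth = "INTEGER"),
    align_columns = c(family = "TEXT", column = "INTEGER", freq_A = "REAL",
                      freq_C = "REAL", freq_G = "REAL", freq_U = "REAL",
                      freq_other = "REAL", gap_fraction = "REAL",
                      consensus = "TEXT"),
    nucleotides = stats::setNames(
      ifelse(.NT_COLUMNS %in% .NT_NUMERIC, "REAL",
             ifelse(.NT_COLUMNS %in% c("index", "paired", "alignment_column",
                                       "is_modified"),
                    "INTEGER", "TEXT")),
      .NT_COLUMNS)
  )
}

#' Ingest external base-pair and helix-form annotations
#'
#' Populates the `paired`, `pair_type` and `form_label` fields of a
#' chain's descriptor table from an annotation file in a documented JSON
#' dialect (as produced by DSSR-style annotators):
#' `{"pairs": [{"chain1", "index1", "chain2", "index2", "lw"}, ...],`
#' `"forms": [{"chain", "index", "form"}, ...]}`.
#' Interactions whose label is not one of the 12 Leontis-Westhof families
#' (cis/trans x WW, WH, WS, HH, HS, SS) are carried under the catch-all
#' label `other`. `paired` receives the partner's residue index for
#' intra-chain interactions and stays 0 for inter-chain ones (whose label
#' is still recorded). Multiple interactions per base accumulate in
#' `pair_type` (comma-separated); `paired` keeps the first intra-chain
#' partner. With `annotation_file = NULL` all fields keep their defaults
#' (`paired` 0, empty `pair_type`, form `none`).
#'
#' @param descriptors data.frame from [annotate_chain()].
#' @param annotation_file Path to the JSON annotation file, or `NULL`.
#' @param chain_id The chain these descriptors belong to.
#' @return `descriptors` with `paired`, `pair_type`, `form_label` set.
#' @export
ingest_external_annotation <- function(descriptors, annotation_file = NULL,
                                       chain_id = "A") {
  L <- nrow(descriptors)
  if (is.null(descriptors$paired)) descriptors$paired <- 0L
  if (is.null(descriptors$pair_type)) descriptors$pair_type <- NA_character_
  if (is.null(descriptors$form_label)) descriptors$form_label <- "none"
  if (is.null(annotation_file)) return(descriptors)
  ann <- tryCatch(
    jsonlite::fromJSON(annotation_file, simplifyDataFrame = TRUE),
    error = function(e) stop("malformed annotation file ", annotation_file,
                             ": ", conditionMessage(e)))
  classify <- function(lw) {
    if (is.null(lw) || is.na(lw) || !(lw %in% .LW_FAMILIES)) "other" else lw
  }
  add_label <- function(cur, lab) {
    if (is.na(cur) || !nzchar(cur)) lab else paste(cur, lab, sep = ",")
  }
  pairs <- ann$pairs
  if (!is.null(pairs) && NROW(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, ]
      ends <- list(list(ch = p$chain1, i = p$index1, other_ch = p$chain2,
                        other_i = p$index2),
                   list(ch = p$chain2, i = p$index2, other_ch = p$chain1,
                        other_i = p$index1))
      lab <- classify(p$lw)
      # either end referencing a residue outside this chain's range makes
      # the whole entry unusable: warn and leave the fields at defaults
      oob <- vapply(ends, function(e)
        identical(e$ch, chain_id) && (is.na(e$i) || e$i < 1 || e$i > L),
        logical(1))
      if (any(oob)) {
        warning("annotation references residue ",
                ends[[which(oob)[1]]]$i, " outside chain ", chain_id,
                "; entry skipped")
        next
      }
      for (e in ends) {
        if (!identical(e$ch, chain_id)) next
        descriptors$pair_type[[e$i]] <-
          add_label(descriptors$pair_type[[e$i]], lab)
        if (identical(e$other_ch, chain_id) &&
            descriptors$paired[[e$i]] == 0L) {
          descriptors$paired[[e$i]] <- as.integer(e$other_i)
        }
      }
    }
  }
  forms <- ann$forms
  if (!is.null(forms) && NROW(forms)) {
    for (r in seq_len(nrow(forms))) {
      f <- forms[r, ]
      if (!identical(f$chain, chain_id)) next
      if (is.na(f$index) || f$index < 1 || f$index > L) {
        warning("form annotation references residue ", f$index,
                " outside chain ", chain_id, "; skipped")
        next
      }
      descriptors$form_label[[f$index]] <-
        if (f$form %in% c("A", "B", "Z")) f$form else "none"
    }
  }
  descriptors
}

# ---- store construction --------------------------------------------------

.chain_key <- function(structure_id, chain_id, family) {
  fam <- ifelse(is.na(family) | !nzchar(family), "unmapped", family)
  paste(structure_id, chain_id, fam, sep = "|")
}

#' Build the relational dataset store
#'
#' Assembles chains, their per-nucleotide geometric descriptors, their
#' alignment mappings and the family PSSMs into one referentially intact
#' relational store (tables `chains`, `families`, `align_columns`,
#' `nucleotides`) and writes it as a single SQL-dump file. Rebuilding
#' from unchanged inputs writes a byte-identical dump.
#'
#' @param chains List of [rna_chain] objects (possibly family-truncated
#'   copies; `$mapping` carries family and range).
#' @param descriptors List of data.frames from [annotate_chain()] (after
#'   optional [ingest_external_annotation()]), parallel to `chains`.
#' @param positions List of data.frames from [remap()]/[fill_missing()]
#'   or `NULL` entries for chains without homology, parallel to `chains`.
#' @param pssms Named list (by family accession) of [compute_pssm()]
#'   data.frames.
#' @param out_path Path of the dump file to write, or `NULL`.
#' @return Object of class `dataset_store` (list of data.frame tables).
#' @export
build_store <- function(chains, descriptors, positions = NULL, pssms = list(),
                        out_path = NULL) {
  n <- length(chains)
  stopifnot(length(descriptors) == n)
  if (is.null(positions)) positions <- vector("list", n)
  schema <- .store_schema()

  chain_rows <- vector("list", n)
  nt_rows <- vector("list", n)
  for (k in seq_len(n)) {
    ch <- chains[[k]]
    fam <- if (!is.null(ch$mapping)) ch$mapping$family else NA_character_
    ckey <- .chain_key(ch$structure_id, ch$chain_id, fam)
    L <- length(ch$residues)
    chain_rows[[k]] <- data.frame(
      chain_key = ckey, structure_id = ch$structure_id,
      chain_id = ch$chain_id, family = fam,
      mapping_start = if (!is.null(ch$mapping)) ch$mapping$start else NA_integer_,
      mapping_end = if (!is.null(ch$mapping)) ch$mapping$end else NA_integer_,
      inferred = if (!is.null(ch$mapping) && !is.null(ch$mapping$inferred))
        as.integer(ch$mapping$inferred) else NA_integer_,
      resolution = ch$resolution, release_date = ch$release_date,
      length = L, stringsAsFactors = FALSE)

    d <- descriptors[[k]]
    if (nrow(d) != L) {
      stop("descriptor table of ", ckey, " has ", nrow(d),
           " rows for a chain of length ", L)
    }
    if (is.null(d$paired)) d$paired <- 0L
    if (is.null(d$pair_type)) d$pair_type <- NA_character_
    if (is.null(d$form_label)) d$form_label <- "none"
    auth <- vapply(ch$residues, function(r)
      if (is.null(r$auth_label) || is.na(r$auth_label)) NA_character_
      else as.character(r$auth_label), character(1))
    mods <- vapply(ch$residues, function(r) isTRUE(r$is_modified), logical(1))
    nt <- data.frame(chain_key = ckey, index = seq_len(L),
                     auth_label = auth, nt_code = d$nt_code,
                     nt_align_code = d$nt_code,
                     is_modified = as.integer(mods),
                     stringsAsFactors = FALSE)
    for (col in setdiff(.NT_COLUMNS, names(nt))) {
      nt[[col]] <- if (col %in% names(d)) d[[col]] else NA
    }
    pos <- positions[[k]]
    nt$alignment_column <- NA_integer_
    nt[c("freq_A", "freq_C", "freq_G", "freq_U", "freq_other",
         "gap_fraction")] <- NA_real_
    if (!is.null(pos)) {
      if (nrow(pos) != L) stop("position table of ", ckey, " has wrong length")
      nt$nt_align_code <- pos$nt_align_code
      nt$alignment_column <- ifelse(pos$homology_known,
                                    pos$alignment_column, NA_integer_)
      if (!is.null(pssms[[fam]])) {
        p <- pssms[[fam]]
        ok <- !is.na(nt$alignment_column)
        cols <- c("freq_A", "freq_C", "freq_G", "freq_U", "freq_other",
                  "gap_fraction")
        nt[ok, cols] <- p[nt$alignment_column[ok], cols]
      }
    }
    nt_rows[[k]] <- nt[, .NT_COLUMNS]
  }

  fams <- sort(names(pssms))
  families <- data.frame(
    family = fams,
    n_columns = vapply(fams, function(f) nrow(pssms[[f]]), integer(1),
                       USE.NAMES = FALSE),
    depth = vapply(fams, function(f) as.integer(pssms[[f]]$depth[1]),
                   integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rownames(families) <- NULL
  align_columns <- if (length(fams)) {
    do.call(rbind, lapply(fams, function(f)
      cbind(data.frame(family = f, stringsAsFactors = FALSE),
            pssms[[f]][, c("column", "freq_A", "freq_C", "freq_G", "freq_U",
                           "freq_other", "gap_fraction", "consensus")])))
  } else {
    data.frame(family = character(0), column = integer(0), freq_A = numeric(0),
               freq_C = numeric(0), freq_G = numeric(0), freq_U = numeric(0),
               freq_other = numeric(0), gap_fraction = numeric(0),
               consensus = character(0), stringsAsFactors = FALSE)
  }

  chains_tab <- do.call(rbind, chain_rows)
  ord <- order(chains_tab$chain_key)
  chains_tab <- chains_tab[ord, , drop = FALSE]
  nucleotides <- do.call(rbind, nt_rows[ord])
  rownames(chains_tab) <- rownames(nucleotides) <-
    rownames(align_columns) <- NULL

  store <- structure(list(chains = chains_tab, families = families,
                          align_columns = align_columns,
                          nucleotides = nucleotides,
                          schema = schema),
                     class = "dataset_store")
  .check_store(store)
  if (!is.null(out_path)) write_store(store, out_path)
  store
}

#' @export
print.dataset_store <- function(x, ...) {
  cat(sprintf(
    "<dataset_store: %d chains, %d families, %d alignment columns, %d nucleotides>\n",
    nrow(x$chains), nrow(x$families), nrow(x$align_columns),
    nrow(x$nucleotides)))
  invisible(x)
}

.check_store <- function(store) {
  nt <- store$nucleotides
  bad <- setdiff(nt$chain_key, store$chains$chain_key)
  if (length(bad)) {
    stop("referential integrity violation: nucleotides reference unknown ",
         "chain(s) ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(store$chains$chain_key)) {
    stop("referential integrity violation: duplicate chain_key ",
         store$chains$chain_key[duplicated(store$chains$chain_key)][1])
  }
  ak <- paste(store$align_columns$family, store$align_columns$column)
  mapped <- !is.na(nt$alignment_column)
  if (any(mapped)) {
    fam_of <- stats::setNames(store$chains$family, store$chains$chain_key)
    ref <- paste(fam_of[nt$chain_key[mapped]], nt$alignment_column[mapped])
    hasfam <- !is.na(fam_of[nt$chain_key[mapped]])
    missing <- unique(ref[hasfam & !(ref %in% ak)])
    if (length(missing)) {
      stop("referential integrity violation: alignment column(s) ",
           paste(missing, collapse = ", "), " absent from align_columns")
    }
  }
  invisible(TRUE)
}

# ---- SQL dump serialization ---------------------------------------------

.sql_value <- function(x, type) {
  if (is.na(x)) return("NULL")
  if (type == "TEXT") {
    return(paste0("'", gsub("'", "''", as.character(x)), "'"))
  }
  if (type == "INTEGER") return(sprintf("%d", as.integer(x)))
  sprintf("%.17g", as.numeric(x))
}

#' Write a dataset store as a single-file SQL dump
#'
#' Emits `CREATE TABLE` and `INSERT` statements in SQLite dialect, in a
#' canonical deterministic order, so that identical stores produce
#' byte-identical files. The file can be loaded back with [read_store()]
#' or piped into any SQLite shell.
#'
#' @param store A `dataset_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "dataset_store"))
  schema <- store$schema
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("BEGIN TRANSACTION;", con)
  for (tab in names(schema)) {
    cols <- schema[[tab]]
    writeLines(sprintf("CREATE TABLE %s (%s);", tab,
                       paste(names(cols), cols, collapse = ", ")), con)
    df <- store[[tab]]
    if (is.null(df) || !nrow(df)) next
    vals <- vapply(seq_len(nrow(df)), function(r)
      paste(vapply(names(cols), function(cn)
        .sql_value(df[[cn]][[r]], cols[[cn]]), character(1)),
        collapse = ","),
      character(1))
    writeLines(sprintf("INSERT INTO %s (%s) VALUES (%s);", tab,
                       paste(names(cols), collapse = ","), vals), con)
  }
  writeLines("COMMIT;", con)
  invisible(path)
}

# split a VALUES(...) payload on top-level commas, respecting '' quoting
.split_sql_values <- function(s) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  buf <- character(0)
  inq <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (inq) {
      if (ch == "'") {
        if (i < length(chars) && chars[[i + 1L]] == "'") {
          buf <- c(buf, "'"); i <- i + 2L; next
        }
        inq <- FALSE
      } else {
        buf <- c(buf, ch)
      }
    } else if (ch == "'") {
      inq <- TRUE
      buf <- c(buf, "\x01")  # marks "was quoted"
    } else if (ch == ",") {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  c(out, paste(buf, collapse = ""))
}

#' Read a dataset store from its SQL dump
#'
#' Parses the dialect written by [write_store()] (CREATE TABLE +
#' one-row INSERT statements) back into a `dataset_store`.
#'
#' @param path Path to a dump written by [write_store()].
#' @return A `dataset_store` object.
#' @export
read_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  schema <- list()
  rows <- list()
  for (line in lines) {
    if (grepl("^CREATE TABLE ", line)) {
      tab <- sub("^CREATE TABLE ([^ ]+) .*$", "\\1", line)
      body <- sub("^CREATE TABLE [^(]+\\((.*)\\);$", "\\1", line)
      defs <- strsplit(body, ", ", fixed = TRUE)[[1]]
      parts <- strsplit(defs, " ")
      schema[[tab]] <- stats::setNames(
        vapply(parts, `[[`, character(1), 2L),
        vapply(parts, `[[`, character(1), 1L))
      rows[[tab]] <- list()
    } else if (grepl("^INSERT INTO ", line)) {
      tab <- sub("^INSERT INTO ([^ ]+) .*$", "\\1", line)
      payload <- sub("^[^(]+\\([^)]*\\) VALUES \\((.*)\\);$", "\\1", line)
      rows[[tab]][[length(rows[[tab]]) + 1L]] <- .split_sql_values(payload)
    }
  }
  store <- list()
  for (tab in names(schema)) {
    cols <- schema[[tab]]
    vals <- rows[[tab]]
    df <- if (length(vals)) {
      m <- do.call(rbind, vals)
      as.data.frame(m, stringsAsFactors = FALSE)
    } else {
      as.data.frame(matrix(character(0), 0, length(cols)),
                    stringsAsFactors = FALSE)
    }
    names(df) <- names(cols)
    for (cn in names(cols)) {
      v <- df[[cn]]
      was_quoted <- startsWith(v, "\x01")
      v[was_quoted] <- substring(v[was_quoted], 2L)
      isnull <- !was_quoted & v == "NULL"
      v[isnull] <- NA
      df[[cn]] <- switch(cols[[cn]],
                         TEXT = v,
                         INTEGER = as.integer(v),
                         REAL = as.numeric(v))
    }
    store[[tab]] <- df
  }
  store$schema <- schema
  structure(store, class = "dataset_store")
}

# ---- queries and CSV export ---------------------------------------------

#' Filter store chains by resolution, release date and family
#'
#' Filters compose conjunctively. `released_before` is a strict
#' "earlier than" comparison on ISO-8601 date strings.
#'
#' @param store A `dataset_store`.
#' @param resolution_max Maximum resolution in angstroms, or `NULL`.
#' @param released_before ISO date string, or `NULL`.
#' @param family Family accession, or `NULL`.
#' @return The filtered `chains` table.
#' @export
query_chains <- function(store, resolution_max = NULL,
                         released_before = NULL, family = NULL) {
  ch <- store$chains
  keep <- rep(TRUE, nrow(ch))
  if (!is.null(resolution_max)) {
    keep <- keep & !is.na(ch$resolution) & ch$resolution <= resolution_max
  }
  if (!is.null(released_before)) {
    keep <- keep & !is.na(ch$release_date) &
      as.Date(ch$release_date) < as.Date(released_before)
  }
  if (!is.null(family)) keep <- keep & !is.na(ch$family) & ch$family == family
  ch[keep, , drop = FALSE]
}

#' Export per-chain CSV files
#'
#' Writes one CSV file per selected chain (one row per nucleotide, the
#' documented fixed column order of the nucleotides table), named
#' `<structure>_<chain>_<family>.csv`. The CSV dialect is
#' comma-separated, header row, UTF-8, empty string for null; the
#' null-vs-zero distinction of nullable numeric fields survives a
#' round-trip through [read_chain_csv()].
#'
#' @inheritParams query_chains
#' @param dir Output directory.
#' @return Character vector of the files written (possibly empty, with a
#'   logged notice).
#' @export
export_csv <- function(store, dir, resolution_max = NULL,
                       released_before = NULL, family = NULL) {
  sel <- query_chains(store, resolution_max, released_before, family)
  if (!nrow(sel)) {
    message("no chains match the export filters; nothing written")
    return(invisible(character(0)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (ck in sel$chain_key) {
    nt <- store$nucleotides[store$nucleotides$chain_key == ck, ,
                            drop = FALSE]
    out <- nt[, setdiff(.NT_COLUMNS, "chain_key"), drop = FALSE]
    fname <- file.path(dir, paste0(gsub("[|]", "_", ck), ".csv"))
    utils::write.csv(out, fname, row.names = FALSE, na = "")
    files <- c(files, fname)
  }
  invisible(files)
}

#' Read back a per-chain CSV written by [export_csv()]
#'
#' @param path CSV file path.
#' @return data.frame with the nucleotide columns restored to their
#'   declared types (empty strings back to `NA`).
#' @export
read_chain_csv <- function(path) {
  schema <- .store_schema()$nucleotides
  cols <- setdiff(.NT_COLUMNS, "chain_key")
  classes <- ifelse(schema[cols] == "TEXT", "character",
                    ifelse(schema[cols] == "INTEGER", "integer", "numeric"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = unname(classes))
  # dialect: empty string encodes null in character fields
  for (cn in cols[classes == "character"]) {
    df[[cn]][!is.na(df[[cn]]) & df[[cn]] == ""] <- NA_character_
  }
  df
}
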