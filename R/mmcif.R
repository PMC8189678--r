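# Minimal mmCIF category reader/writer.
#
# Handles the subset of the STAR/CIF grammar that PDBx/mmCIF coordinate
# files use: data_ blocks, single key-value items, loop_ tables, values
# quoted with ' or ", semicolon-delimited multi-line values, and # comments.
# Categories are returned as character data.frames keyed by category name
# (e.g. "atom_site"), items as columns.

.cif_tokenize <- function(lines) {
  tokens <- character(0)
  n <- length(lines)
  i <- 1L
  tok_re <- "'[^']*'|\"[^\"]*\"|[^[:space:]]+"
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      # multi-line value: everything until the next line starting with ';'
      val <- sub("^;", "", line)
      i <- i + 1L
      while (i <= n && !startsWith(lines[[i]], ";")) {
        val <- paste(val, lines[[i]], sep = "\n")
        i <- i + 1L
      }
      tokens <- c(tokens, paste0("\r", val))  # \r marks "already unquoted"
      i <- i + 1L
      next
    }
    m <- regmatches(line, gregexpr(tok_re, line))[[1]]
    if (length(m)) {
      hash <- which(startsWith(m, "#"))
      if (length(hash)) m <- m[seq_len(min(hash) - 1L)]
    }
    tokens <- c(tokens, m)
    i <- i + 1L
  }
  tokens
}

.cif_unquote <- function(x) {
  if (startsWith(x, "\r")) return(substring(x, 2L))
  if (nchar(x) >= 2L) {
    f <- substring(x, 1L, 1L)
    if ((f == "'" || f == "\"") && endsWith(x, f)) {
      return(substring(x, 2L, nchar(x) - 1L))
    }
  }
  x
}

.cif_is_tag <- function(x) startsWith(x, "_")
.cif_is_stop <- function(x) {
  .cif_is_tag(x) || x %in% c("loop_") ||
    startsWith(x, "data_") || startsWith(x, "save_")
}

#' Read mmCIF categories from a file
#'
#' Parses a PDBx/mmCIF file into a named list of character data frames,
#' one per category (`atom_site`, `entity_poly_seq`, ...). Only the first
#' `data_` block is read. This is a low-level helper; most users want
#' [parse_mmcif()].
#'
#' @param path Path to an mmCIF file.
#' @return Named list of data.frames (all columns character). Single
#'   key-value items become one-row data frames.
#' @export
read_mmcif_categories <- function(path) {
  if (!file.exists(path)) stop("mmCIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tokens <- .cif_tokenize(lines)
  if (length(tokens) == 0L) stop("not a valid mmCIF file (empty): ", path)

  cats <- list()
  add_item <- function(tag, values) {
    parts <- strsplit(sub("^_", "", tag), ".", fixed = TRUE)[[1]]
    cat_name <- parts[[1]]
    item <- if (length(parts) > 1L) paste(parts[-1], collapse = ".") else "value"
    col <- vapply(values, .cif_unquote, character(1), USE.NAMES = FALSE)
    if (is.null(cats[[cat_name]])) {
      cats[[cat_name]] <<- structure(list(), class = "data.frame",
                                     row.names = seq_along(col))
    }
    cats[[cat_name]][[item]] <<- col
  }

  j <- 1L
  n <- length(tokens)
  seen_data <- FALSE
  while (j <= n) {
    t <- tokens[[j]]
    if (startsWith(t, "data_")) {
      if (seen_data) break  # only first block
      seen_data <- TRUE
      j <- j + 1L
    } else if (t == "loop_") {
      j <- j + 1L
      tags <- character(0)
      while (j <= n && .cif_is_tag(tokens[[j]])) {
        tags <- c(tags, tokens[[j]]); j <- j + 1L
      }
      vals <- character(0)
      while (j <= n && !.cif_is_stop(tokens[[j]])) {
        vals <- c(vals, tokens[[j]]); j <- j + 1L
      }
      if (length(tags) == 0L || length(vals) %% length(tags) != 0L) {
        stop("malformed mmCIF loop in ", path)
      }
      mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
      for (k in seq_along(tags)) add_item(tags[[k]], mat[, k])
    } else if (.cif_is_tag(t)) {
      if (j + 1L > n) stop("dangling mmCIF tag ", t, " in ", path)
      add_item(t, tokens[[j + 1L]])
      j <- j + 2L
    } else {
      stop("unexpected token '", t, "' in mmCIF file ", path)
    }
  }
  if (!seen_data) stop("not a valid mmCIF file (no data_ block): ", path)
  cats
}

.cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "?"
  needs <- grepl("[[:space:]'\"]", x) | startsWith(x, "_") | startsWith(x, "#")
  x[needs] <- ifelse(grepl("'", x[needs]),
                     paste0("\"", x[needs], "\""),
                     paste0("'", x[needs], "'"))
  x
}

# Write one loop_ category; df columns become items in order.
.cif_write_loop <- function(con, category, df) {
  writeLines(c("loop_", paste0("_", category, ".", names(df))), con)
  cols <- lapply(df, .cif_quote)
  writeLines(do.call(paste, cols), con)
  writeLines("#", con)
}
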