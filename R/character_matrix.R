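# Discrete character matrices --------------------------------------------
#
# Cells are stored as character strings: a single state ("0".."9"), a
# polymorphic set joined with "/" ("0/2"), or NA for missing. Downstream
# code converts cells to integer state sets on demand.

#' Construct a discrete character matrix
#'
#' Bundles a taxon-by-character matrix of coded states with per-character
#' ordering flags and weights, the shared container for all distance,
#' parsimony and simulation operations in the package.
#'
#' @param cells Character matrix (taxa in rows, characters in columns) with
#'   entries such as `"0"`, `"1"`, polymorphisms `"0/1"`, or `NA` for
#'   missing. Row names are the taxon labels.
#' @param ordering Per-character flag, `"unordered"` (default) or
#'   `"ordered"`. Recycled if length 1.
#' @param weights Per-character non-negative weights, default 1.
#' @return An object of class `character_matrix`: a list with elements
#'   `cells`, `taxon_labels`, `n_characters`, `ordering`, `weights` and
#'   `state_counts` (number of distinct observed states per character).
#' @export
character_matrix <- function(cells, ordering = "unordered", weights = 1) {
  if (!is.matrix(cells) || !is.character(cells))
    stop("`cells` must be a character matrix", call. = FALSE)
  taxa <- rownames(cells)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("taxon labels (rownames) must be present and unique", call. = FALSE)
  nc <- ncol(cells)
  ordering <- rep_len(match.arg(ordering, c("unordered", "ordered"),
                                several.ok = TRUE), nc)
  weights <- rep_len(as.numeric(weights), nc)
  if (any(weights < 0)) stop("character weights must be non-negative", call. = FALSE)
  bad <- which(!is.na(cells) & !grepl("^[0-9]+(/[0-9]+)*$", cells), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown state symbol '%s' for taxon '%s', character %d",
                 cells[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]], bad[1, 2]),
         call. = FALSE)
  obj <- structure(list(
    cells = cells,
    taxon_labels = taxa,
    n_characters = nc,
    ordering = ordering,
    weights = weights,
    state_counts = integer(nc)
  ), class = "character_matrix")
  obj$state_counts <- vapply(seq_len(nc), function(j) {
    length(unique(unlist(cell_states(cells[, j]))))
  }, integer(1))
  obj
}

# Integer state sets for a vector of cells; NULL marks a missing cell.
cell_states <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell)) NULL
    else as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
  })
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%d ordered, %.1f%% missing)\n",
              length(x$taxon_labels), x$n_characters,
              sum(x$ordering == "ordered"),
              100 * mean(is.na(x$cells))))
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

#' Per-taxon coding completeness
#'
#' Fraction of characters actually scored (non-missing) for each taxon;
#' feeds the missing-data correction of branch change counts.
#'
#' @param m A [character_matrix()].
#' @return Named numeric vector in (0, 1].
#' @export
taxon_completeness <- function(m) {
  out <- rowMeans(!is.na(m$cells))
  names(out) <- m$taxon_labels
  out
}

#' Read a discrete character matrix
#'
#' Reads NEXUS (`CHARACTERS`/`DATA` block) or TNT `xread` files into a
#' [character_matrix()]. `?` and `-` are treated as missing; `(ab)`, `{ab}`
#' and `[ab]` as polymorphisms.
#'
#' @param path File path.
#' @param dialect `"nexus"` or `"tnt"`.
#' @param ordering,weights Passed to [character_matrix()] (neither format's
#'   assumptions block is interpreted).
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, dialect = c("nexus", "tnt"),
                                  ordering = "unordered", weights = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  rows <- if (dialect == "nexus") {
    x <- ape::read.nexus.data(path)
    lapply(x, function(v) {
      v[v %in% c("?", "-")] <- NA
      v
    })
  } else {
    read_tnt_rows(path)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop(sprintf("parse error: row for taxon '%s' has %d characters, expected %d",
                 names(rows)[which(lens != lens[1])[1]],
                 lens[which(lens != lens[1])[1]], lens[1]), call. = FALSE)
  cells <- do.call(rbind, rows)
  rownames(cells) <- names(rows)
  character_matrix(cells, ordering = ordering, weights = weights)
}

# Minimal TNT xread parser: "xread ['comment'] nchar ntax" followed by
# taxon rows, terminated by ";". Polymorphisms in [..], (..) or {..}.
read_tnt_rows <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("'[^']*'", " ", txt)           # drop quoted comments
  m <- regmatches(txt, regexpr("xread.*?;", txt))
  if (length(m) == 0) stop("parse error: no xread block found", call. = FALSE)
  body <- sub("^xread", "", m)
  body <- sub(";$", "", body)
  toks <- strsplit(trimws(body), "[ \t\n\r]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2 || anyNA(suppressWarnings(as.integer(toks[1:2]))))
    stop("parse error: xread header must declare nchar and ntax", call. = FALSE)
  nchar_decl <- as.integer(toks[1])
  ntax_decl <- as.integer(toks[2])
  toks <- toks[-(1:2)]
  if (length(toks) != 2 * ntax_decl)
    stop(sprintf("parse error: expected %d taxon rows, found %d tokens",
                 ntax_decl, length(toks)), call. = FALSE)
  taxa <- toks[seq(1, length(toks), by = 2)]
  seqs <- toks[seq(2, length(toks), by = 2)]
  rows <- lapply(seq_along(taxa), function(i) {
    cells <- parse_state_string(seqs[i], taxa[i])
    if (length(cells) != nchar_decl)
      stop(sprintf("parse error: row for taxon '%s' has %d characters, expected %d",
                   taxa[i], length(cells), nchar_decl), call. = FALSE)
    cells
  })
  names(rows) <- taxa
  rows
}

# Split a compact state string (e.g. "01?[01]2") into per-character cells.
parse_state_string <- function(s, taxon) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{", "[")) {
      close <- c("(" = ")", "{" = "}", "[" = "]")[[ch]]
      j <- i + 1L
      states <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        states <- c(states, chars[j]); j <- j + 1L
      }
      if (j > length(chars))
        stop(sprintf("parse error: unclosed polymorphism for taxon '%s'", taxon),
             call. = FALSE)
      out <- c(out, paste(states, collapse = "/"))
      i <- j + 1L
    } else if (ch %in% c("?", "-")) {
      out <- c(out, NA_character_); i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      out <- c(out, ch); i <- i + 1L
    } else {
      stop(sprintf("unknown state symbol '%s' for taxon '%s', character %d",
                   ch, taxon, length(out) + 1L), call. = FALSE)
    }
  }
  out
}

#' Write a character matrix as NEXUS
#'
#' @param m A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(m, path) {
  fmt_cell <- function(cell) {
    if (is.na(cell)) "?"
    else if (grepl("/", cell)) paste0("(", gsub("/", "", cell), ")")
    else cell
  }
  rows <- apply(m$cells, 1, function(r) paste(vapply(r, fmt_cell, ""), collapse = ""))
  symbols <- paste(sort(unique(unlist(cell_states(as.vector(m$cells))))), collapse = "")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m$cells), m$n_characters),
    sprintf("FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";", symbols),
    "MATRIX",
    paste(m$taxon_labels, rows),
    ";",
    "END;"
  )
  writeLines(lines, path)
  invisible(path)
}
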