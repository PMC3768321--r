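# Trees, stratigraphic ranges and time bins ------------------------------

#' Read a (possibly dated) tree from Newick
#'
#' Branch lengths, when present, are interpreted as durations in Myr.
#'
#' @param path Newick file path.
#' @param taxa Optional character vector (or [character_matrix()]) whose
#'   labels the tips must match; a mismatch is an error naming the offending
#'   tips.
#' @return An `ape` `phylo` object, rooted.
#' @export
read_tree <- function(path, taxa = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("could not parse Newick in %s", path), call. = FALSE)
  if (!ape::is.rooted(tr)) stop("tree must be rooted", call. = FALSE)
  if (!is.null(taxa)) {
    if (inherits(taxa, "character_matrix")) taxa <- taxa$taxon_labels
    extra <- setdiff(tr$tip.label, taxa)
    if (length(extra) > 0)
      stop(sprintf("tree tips absent from character matrix: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  tr
}

#' Read stratigraphic ranges
#'
#' Expects a delimited table with columns `taxon`, `fad`, `lad` (first and
#' last appearance dates in Ma before present).
#'
#' @param path CSV/TSV file path (separator sniffed from the header line).
#' @return A `data.frame` with columns `taxon`, `fad`, `lad`, validated so
#'   that `fad >= lad > 0` for every taxon.
#' @export
read_ranges <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_ranges(df)
}

validate_ranges <- function(df) {
  need <- c("taxon", "fad", "lad")
  if (!all(need %in% names(df)))
    stop("range table must have columns taxon, fad, lad", call. = FALSE)
  df <- df[, need]
  df$fad <- as.numeric(df$fad)
  df$lad <- as.numeric(df$lad)
  bad <- which(df$fad < df$lad)
  if (length(bad) > 0)
    stop(sprintf("fad < lad for taxon '%s'", df$taxon[bad[1]]), call. = FALSE)
  if (nrow(df) > 0 && any(df$lad <= 0))
    stop(sprintf("lad must be > 0 Ma (taxon '%s')",
                 df$taxon[which(df$lad <= 0)[1]]), call. = FALSE)
  if (anyDuplicated(df$taxon))
    stop("duplicated taxon in range table", call. = FALSE)
  df
}

#' Define a set of time bins
#'
#' @param labels Bin labels, oldest first.
#' @param start,end Bin boundaries in Ma before present (`start > end`,
#'   strictly ordered, non-overlapping).
#' @return A `data.frame` with columns `label`, `start`, `end`, `duration`
#'   (Myr) and `midpoint` (Ma), of class `time_bins`.
#' @export
time_bins <- function(labels, start, end) {
  if (length(labels) != length(start) || length(start) != length(end))
    stop("labels, start and end must have the same length", call. = FALSE)
  if (any(start <= end)) stop("each bin needs start > end (ages in Ma)", call. = FALSE)
  if (is.unsorted(rev(start)) || any(end[-length(end)] < start[-1]))
    stop("bins must be ordered old to young and non-overlapping", call. = FALSE)
  structure(data.frame(label = labels, start = start, end = end,
                       duration = start - end, midpoint = (start + end) / 2,
                       stringsAsFactors = FALSE),
            class = c("time_bins", "data.frame"))
}

#' Late Permian to Early Jurassic stage bins
#'
#' The eleven stage/substage bins used for cynodont disparity and rate
#' analyses (Wuchiapingian-Changhsingian through Pliensbachian), with
#' durations 5, 7, 4, 6, 7, 4, 12, 10, 5, 7 and 7 Myr anchored at a
#' Permo-Triassic boundary of 252 Ma.
#'
#' @return A [time_bins()] table with 11 rows (t1-t11).
#' @export
cynodont_bins <- function() {
  dur <- c(5, 7, 4, 6, 7, 4, 12, 10, 5, 7, 7)
  labels <- c("WUC-CH", "IND-OLE", "ANS", "LAD", "CRN", "eNOR", "mNOR",
              "lNOR-RHT", "HET", "SIN", "PLB")
  ptb <- 252
  edges <- ptb + dur[1] - cumsum(c(0, dur))    # bin edges, old to young

  time_bins(labels, start = edges[-12], end = edges[-1])
}

#' Pooled rate-analysis bins
#'
#' The rate-through-time intervals: the stage bins up to the Rhaetian with
#' the three Jurassic stages pooled into one, giving nine intervals.
#'
#' @return A [time_bins()] table with 9 rows.
#' @export
cynodont_rate_bins <- function() {
  b <- cynodont_bins()
  time_bins(c(b$label[1:8], "HET-PLB"),
            start = c(b$start[1:8], b$start[9]),
            end = c(b$end[1:8], b$end[11]))
}

#' Cynodont diversity per stage bin
#'
#' Taxon counts per time bin for the cynodont study system: taxa included
#' in the tree and total described taxa, for the eleven [cynodont_bins()].
#'
#' @return A `data.frame` with columns `label`, `tree_taxa`, `total_taxa`.
#' @export
cynodont_diversity <- function() {
  b <- cynodont_bins()
  data.frame(label = b$label,
             tree_taxa = c(5, 9, 14, 7, 11, 4, 9, 5, 5, 7, 5),
             total_taxa = c(7, 9, 19, 8, 12, 8, 12, 10, 5, 12, 8),
             stringsAsFactors = FALSE)
}
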