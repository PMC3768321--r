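# Time-calibration of a topology from stratigraphic ranges ----------------

#' Time-calibrate a tree from first appearance dates
#'
#' Dates every node of a rooted topology from the tips' first appearance
#' dates (FADs). Three variants:
#' \describe{
#'   \item{basic}{each internal node is as old as the oldest FAD among its
#'     descendants, which leaves zero-length branches wherever a node and a
#'     descendant share the constraining FAD;}
#'   \item{mbl}{after basic dating, every branch is forced to at least
#'     `mbl` Myr by pushing ancestors older;}
#'   \item{equal}{zero-length branches are removed by spacing nodes that
#'     share a constraining FAD evenly along the time available from their
#'     first older ancestor.}
#' }
#' Tips are dated at their FAD; the root is placed at the oldest FAD plus
#' `root_buffer` (or older, if mbl pushes it).
#'
#' @param topology Rooted `phylo` (branch lengths ignored; polytomies are
#'   treated as hard).
#' @param ranges Range table with columns `taxon`, `fad`, `lad` covering
#'   every tip.
#' @param method `"basic"`, `"mbl"` or `"equal"`.
#' @param mbl Minimum branch length in Myr (mbl method only).
#' @param root_buffer Myr added above the oldest FAD to date the root.
#' @return A `phylo` with `edge.length` set to branch durations (Myr) and
#'   attributes `node_ages` (ages in Ma, indexed by ape node number),
#'   `root_age` and `calibration` (method metadata).
#' @export
calibrate_tree <- function(topology, ranges, method = c("basic", "mbl", "equal"),
                           mbl = 1, root_buffer = 2) {
  method <- match.arg(method)
  if (!ape::is.rooted(topology)) stop("topology must be rooted", call. = FALSE)
  ranges <- validate_ranges(ranges)
  tips <- topology$tip.label
  miss <- setdiff(tips, ranges$taxon)
  if (length(miss) > 0)
    stop(sprintf("missing FAD for tip(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  fad <- stats::setNames(ranges$fad, ranges$taxon)[tips]
  ntip <- length(tips)
  nnode <- topology$Nnode
  root <- ntip + 1L
  edge <- topology$edge
  post <- rev(order_edges_preorder(topology))   # child edges, tips first

  ages <- numeric(ntip + nnode)
  ages[seq_len(ntip)] <- fad
  # basic: postorder max of descendant ages
  maxdesc <- ages
  for (e in post) {
    p <- edge[e, 1]; c <- edge[e, 2]
    maxdesc[p] <- max(maxdesc[p], maxdesc[c])
  }
  ages[(ntip + 1L):(ntip + nnode)] <- maxdesc[(ntip + 1L):(ntip + nnode)]
  ages[root] <- max(fad) + root_buffer

  if (method == "mbl") {
    for (e in post) {
      p <- edge[e, 1]; c <- edge[e, 2]
      ages[p] <- max(ages[p], ages[c] + mbl)
    }
    ages[root] <- max(ages[root], max(fad) + root_buffer)
  } else if (method == "equal") {
    basic <- ages
    # height of the chain of equal-aged descendants below each node
    h <- integer(ntip + nnode)
    for (e in post) {
      p <- edge[e, 1]; c <- edge[e, 2]
      if (abs(basic[c] - basic[p]) < 1e-12)
        h[p] <- max(h[p], h[c] + 1L)
    }
    pre <- order_edges_preorder(topology)
    for (e in pre) {
      p <- edge[e, 1]; c <- edge[e, 2]
      if (c <= ntip) next
      # space c between its basic age and its (already final) parent so the
      # h[c] equal-aged levels below it each receive an equal share
      ages[c] <- basic[c] + (ages[p] - basic[c]) * h[c] / (h[c] + 1L)
    }
  }

  out <- topology
  out$edge.length <- ages[edge[, 1]] - ages[edge[, 2]]
  if (any(out$edge.length < -1e-9))
    stop("internal error: negative branch duration", call. = FALSE)
  out$edge.length[out$edge.length < 0] <- 0
  attr(out, "node_ages") <- ages
  attr(out, "root_age") <- ages[root]
  attr(out, "calibration") <- list(method = method, mbl = mbl,
                                   root_buffer = root_buffer)
  out
}

# Edge indices in preorder (root outward): reverse of ape's postorder.
order_edges_preorder <- function(tree) {
  rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
}

#' Node ages of a dated tree
#'
#' Returns per-node ages in Ma. Uses the `node_ages` attribute when present
#' (e.g. from [calibrate_tree()] or [simulate_dated_tree()]); otherwise
#' ages are computed from branch lengths with the youngest tip anchored at
#' `youngest_tip_age`.
#'
#' @param tree Dated `phylo`.
#' @param youngest_tip_age Age (Ma) assigned to the youngest tip when no
#'   `node_ages` attribute exists (default 0).
#' @return Numeric vector of ages indexed by ape node number.
#' @export
node_ages <- function(tree, youngest_tip_age = 0) {
  ages <- attr(tree, "node_ages")
  if (!is.null(ages)) return(ages)
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth + youngest_tip_age
}
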