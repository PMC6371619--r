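#' Rooted binary time-trees
#'
#' A `timetree` is the tree container used throughout the package: a rooted
#' binary topology over `n` tips with node *heights* (time before present;
#' tips at height 0) and optional per-branch rate multipliers for a relaxed
#' clock. Tips are nodes `1..n`, internal nodes `n+1..2n-1`; `parent[i]` is
#' the parent node id (0 for the root). Branch lengths in time units are
#' `heights[parent[i]] - heights[i]`.
#'
#' @param tip_label Character vector of unique tip names.
#' @param parent Integer vector of length `2n - 1`, 0 at the root.
#' @param heights Numeric vector of node heights, tips at 0.
#' @param rates Optional per-branch rate multipliers (length `2n - 1`,
#'   entry for the branch above each node; the root entry is ignored).
#' @param outgroup Optional tip label constrained to attach at the root.
#' @return An object of class `timetree`.
#' @export
timetree <- function(tip_label, parent, heights, rates = NULL, outgroup = NULL) {
  n <- length(tip_label)
  m <- 2L * n - 1L
  parent <- as.integer(parent)
  stopifnot(n >= 2L, length(parent) == m, length(heights) == m)
  if (anyDuplicated(tip_label)) stop("tip labels must be unique", call. = FALSE)
  if (sum(parent == 0L) != 1L) stop("tree must have exactly one root", call. = FALSE)
  if (!all(is.finite(heights))) stop("node heights must be finite", call. = FALSE)
  has_par <- parent != 0L
  if (any(heights[parent[has_par]] < heights[has_par] - 1e-12)) {
    stop("parent height must be >= child height on every branch", call. = FALSE)
  }
  if (is.null(rates)) rates <- rep(1, m)
  if (!is.null(outgroup) && !outgroup %in% tip_label) {
    stop("outgroup not among tip labels", call. = FALSE)
  }
  structure(
    list(ntip = n, tip_label = tip_label, parent = parent,
         heights = as.numeric(heights), rates = as.numeric(rates),
         outgroup = outgroup),
    class = "timetree"
  )
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("<timetree> %d tips, root height %.4g\n", x$ntip,
              max(x$heights)))
  invisible(x)
}

tt_root <- function(tree) which(tree$parent == 0L)

## children as a list indexed by node id
tt_children <- function(tree) {
  m <- length(tree$parent)
  kids <- vector("list", m)
  idx <- which(tree$parent != 0L)
  sp <- split(idx, tree$parent[idx])
  kids[as.integer(names(sp))] <- sp
  kids
}

## node ids in postorder (children strictly before parents); iterative DFS so
## zero-length branches are safe
tt_postorder <- function(tree, kids = tt_children(tree)) {
  m <- length(tree$parent)
  out <- integer(m); oi <- 0L
  stack <- integer(m); visited <- logical(m)
  stack[1L] <- tt_root(tree); top <- 1L
  while (top > 0L) {
    node <- stack[top]
    ch <- kids[[node]]
    if (is.null(ch) || visited[node]) {
      top <- top - 1L
      oi <- oi + 1L
      out[oi] <- node
    } else {
      visited[node] <- TRUE
      for (c in ch) { top <- top + 1L; stack[top] <- c }
    }
  }
  out
}

## per-node sorted tip index sets (descendants); tips indexed by position in
## `taxa` (defaults to the tree's own tip order)
tt_tipsets <- function(tree, taxa = tree$tip_label) {
  idx_of <- match(tree$tip_label, taxa)
  m <- length(tree$parent)
  sets <- vector("list", m)
  for (i in seq_len(tree$ntip)) sets[[i]] <- idx_of[i]
  for (node in tt_postorder(tree)) {
    if (node <= tree$ntip) next
    ch <- which(tree$parent == node)
    sets[[node]] <- sort(unlist(sets[ch]))
  }
  sets
}

## canonical clade keys ("i,j,k" over ingroup taxon indices) for internal
## nodes; the outgroup tip, if any, is excluded from the keys so that node
## identity is by ingroup taxon set
tt_clade_keys <- function(tree, taxa = tree$tip_label) {
  sets <- tt_tipsets(tree, taxa)
  og <- if (is.null(tree$outgroup)) NA_integer_ else match(tree$outgroup, taxa)
  m <- length(tree$parent)
  keys <- character(m)
  for (node in seq_len(m)) {
    s <- sets[[node]]
    if (!is.na(og)) s <- s[s != og]
    keys[node] <- paste(s, collapse = ",")
  }
  keys
}

clade_key_to_taxa <- function(key, taxa) taxa[as.integer(strsplit(key, ",", fixed = TRUE)[[1]])]

#' Convert a time-tree to an ape \code{phylo}
#'
#' @param x A `timetree`.
#' @param ... Unused.
#' @return An object of class `phylo` with branch lengths in time units.
#' @method as.phylo timetree
#' @export
as.phylo.timetree <- function(x, ...) {
  n <- x$ntip
  m <- length(x$parent)
  root <- tt_root(x)
  ## ape wants the root to be node n+1; build a node id remap
  remap <- integer(m)
  remap[seq_len(n)] <- seq_len(n)
  internals <- (n + 1L):m
  remap[root] <- n + 1L
  rest <- internals[internals != root]
  remap[rest] <- seq_along(rest) + n + 1L
  child <- which(x$parent != 0L)
  edge <- cbind(remap[x$parent[child]], remap[child])
  len <- x$heights[x$parent[child]] - x$heights[child]
  phy <- list(edge = edge, edge.length = pmax(len, 0),
              tip.label = x$tip_label, Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Build a time-tree from an ultrametric-rooted ape \code{phylo}
#'
#' Node heights are taken as distance below the maximum root-to-tip path;
#' tips must be contemporaneous up to `tol` (an outgroup tip may be listed to
#' exempt it from that check).
#'
#' @param phy A rooted binary `phylo` with branch lengths.
#' @param outgroup Optional outgroup tip label.
#' @param tol Tolerance for the contemporaneous-tips check.
#' @return A `timetree`.
#' @export
timetree_from_phylo <- function(phy, outgroup = NULL, tol = 1e-8) {
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stop("need a rooted, binary phylo", call. = FALSE)
  }
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  depth <- numeric(m)  # distance from root
  pr <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(pr$edge))) {
    depth[pr$edge[e, 2L]] <- depth[pr$edge[e, 1L]] + pr$edge.length[e]
  }
  ing <- seq_len(n)
  if (!is.null(outgroup)) ing <- ing[phy$tip.label[ing] != outgroup]
  h0 <- max(depth[ing])
  if (max(abs(depth[ing] - h0)) > tol * max(h0, 1)) {
    stop("ingroup tips are not contemporaneous", call. = FALSE)
  }
  heights <- h0 - depth
  heights[ing] <- 0
  parent <- integer(m)
  parent[pr$edge[, 2L]] <- pr$edge[, 1L]
  timetree(phy$tip.label, parent, heights, outgroup = outgroup)
}

## deep copy with modified fields (lists are copy-on-write; explicit for clarity)
tt_replace <- function(tree, parent = tree$parent, heights = tree$heights,
                       rates = tree$rates) {
  tree$parent <- parent; tree$heights <- heights; tree$rates <- rates
  tree
}

#' Serialize a time-tree to a Newick string
#'
#' Branch lengths are in time units; per-branch rate multipliers, when not
#' all 1, are carried in bracketed comments (`[&rate=...]`).
#'
#' @param tree A `timetree`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (with trailing `;`).
#' @export
timetree_newick <- function(tree, digits = 10) {
  kids <- tt_children(tree)
  has_rates <- any(abs(tree$rates - 1) > 1e-12)
  rec <- function(node) {
    lab <- if (node <= tree$ntip) tree$tip_label[node] else {
      paste0("(", paste(vapply(kids[[node]], rec, ""), collapse = ","), ")")
    }
    p <- tree$parent[node]
    if (p == 0L) return(paste0(lab, ";"))
    bl <- format(tree$heights[p] - tree$heights[node], digits = digits)
    cm <- if (has_rates) sprintf("[&rate=%s]", format(tree$rates[node], digits = digits)) else ""
    paste0(lab, cm, ":", bl)
  }
  rec(tt_root(tree))
}
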