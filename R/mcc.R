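## canonical ingroup taxa ordering used for clade keys across samples
canonical_taxa <- function(fit) {
  tr <- fit$samples[[1L]]$tree
  sort(setdiff(tr$tip_label, tr$outgroup))
}

as_post_samples <- function(fit, burn_in_fraction = NULL) {
  if (inherits(fit, "allele_mcmc")) return(post_burn_in(fit, burn_in_fraction))
  if (!length(fit)) stop("no post-burn-in samples", call. = FALSE)
  fit  # already a plain list of samples
}

## per-tree internal-clade table: key -> (node, height); duplicate keys (root
## vs ingroup MRCA when an outgroup hangs at the root) keep the lower node
tree_clade_table <- function(tree, taxa) {
  n <- tree$ntip
  internal <- (n + 1L):(2L * n - 1L)
  keys <- tt_clade_keys(tree, taxa)[internal]
  h <- tree$heights[internal]
  ord <- order(h)  # lower node wins on duplicates
  keep <- !duplicated(keys[ord])
  list(node = internal[ord][keep], key = keys[ord][keep], height = h[ord][keep])
}

#' Posterior clade supports
#'
#' For every ingroup clade (set of ingroup taxa below an internal node)
#' observed in the post-burn-in tree samples, the support is the fraction of
#' samples whose tree contains that clade; the mean height of the clade over
#' those samples is reported alongside.
#'
#' @param fit An `allele_mcmc` fit (or a plain list of posterior samples).
#' @param burn_in_fraction Override of the configured burn-in.
#' @return A tibble: clade (key of taxon indices), taxa (`;`-joined names),
#'   n_taxa, support, mean_height — sorted by support then clade size.
#' @export
clade_supports <- function(fit, burn_in_fraction = NULL) {
  ss <- as_post_samples(fit, burn_in_fraction)
  taxa <- sort(setdiff(ss[[1L]]$tree$tip_label, ss[[1L]]$tree$outgroup))
  counts <- new.env(parent = emptyenv())
  hsum <- new.env(parent = emptyenv())
  for (s in ss) {
    ct <- tree_clade_table(s$tree, taxa)
    for (i in seq_along(ct$key)) {
      k <- ct$key[i]
      counts[[k]] <- (counts[[k]] %||% 0) + 1
      hsum[[k]] <- (hsum[[k]] %||% 0) + ct$height[i]
    }
  }
  keys <- ls(counts)
  tibble::tibble(
    clade = keys,
    taxa = vapply(keys, function(k) paste(clade_key_to_taxa(k, taxa),
                                          collapse = ";"), "", USE.NAMES = FALSE),
    n_taxa = vapply(keys, function(k) length(clade_key_to_taxa(k, taxa)), 0L,
                    USE.NAMES = FALSE),
    support = vapply(keys, function(k) counts[[k]], 0,
                     USE.NAMES = FALSE) / length(ss),
    mean_height = vapply(keys, function(k) hsum[[k]] / counts[[k]], 0,
                         USE.NAMES = FALSE)
  ) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$n_taxa, .data$clade)
}

#' Maximum clade credibility (MCC) tree
#'
#' Among the sampled trees, returns the one maximizing the sum of log clade
#' supports (equivalently the product of supports) over its internal clades;
#' ties go to the earliest-sampled tree. Node heights of the returned tree
#' are the mean heights of each clade across the samples containing it
#' (clamped from below so parent-child height order is preserved), and each
#' internal node carries its clade support.
#'
#' @param fit An `allele_mcmc` fit (or list of posterior samples).
#' @param burn_in_fraction Override of the configured burn-in.
#' @return A [timetree] with extra fields `clade_support` (per-node, `NA`
#'   for tips), `clade_key`, and `node_info` (tibble).
#' @export
mcc_tree <- function(fit, burn_in_fraction = NULL) {
  ss <- as_post_samples(fit, burn_in_fraction)
  taxa <- sort(setdiff(ss[[1L]]$tree$tip_label, ss[[1L]]$tree$outgroup))
  sup <- clade_supports(ss)
  smap <- stats::setNames(sup$support, sup$clade)
  hmap <- stats::setNames(sup$mean_height, sup$clade)
  best <- -Inf; best_i <- 1L
  for (i in seq_along(ss)) {
    ct <- tree_clade_table(ss[[i]]$tree, taxa)
    sc <- sum(log(smap[ct$key]))
    if (sc > best + 1e-12) { best <- sc; best_i <- i }
  }
  tree <- ss[[best_i]]$tree
  n <- tree$ntip
  m <- 2L * n - 1L
  keys <- tt_clade_keys(tree, taxa)
  support <- rep(NA_real_, m)
  heights <- tree$heights
  internal <- (n + 1L):m
  support[internal] <- unname(smap[keys[internal]])
  heights[internal] <- unname(hmap[keys[internal]])
  ## duplicate-key pair (root over ingroup MRCA with outgroup): keep root above
  kids <- tt_children(tree)
  for (node in tt_postorder(tree)) {
    if (node <= n) next
    heights[node] <- max(heights[node], max(heights[kids[[node]]]))
  }
  tree$heights <- heights
  tree$clade_support <- support
  tree$clade_key <- keys
  tree$node_info <- tibble::tibble(
    node = internal, clade = keys[internal], support = support[internal],
    height = heights[internal])
  tree
}

#' Assign letter labels to well-supported MCC nodes
#'
#' Cosmetic labels (`A`, `B`, ...) by preorder traversal of the MCC tree
#' restricted to internal nodes whose clade support is at least
#' `support_floor`.
#'
#' @param mcc An MCC [timetree] from [mcc_tree()].
#' @param support_floor Minimum support for a node to receive a label.
#' @return Named character vector: clade key -> label.
#' @export
label_mcc_nodes <- function(mcc, support_floor = 0.5) {
  n <- mcc$ntip
  preorder <- rev(tt_postorder(mcc))
  nodes <- preorder[preorder > n]
  nodes <- nodes[!is.na(mcc$clade_support[nodes]) &
                   mcc$clade_support[nodes] >= support_floor]
  ## duplicate keys (outgroup hanging at the root): keep the lower node,
  ## which preorder visits last
  keys <- mcc$clade_key[nodes]
  keep <- !duplicated(keys, fromLast = TRUE)
  keys <- keys[keep]
  labs <- vapply(seq_along(keys), function(i) {
    if (i <= 26L) LETTERS[i]
    else paste0(LETTERS[((i - 1L) %% 26L) + 1L], (i - 1L) %/% 26L)
  }, "")
  stats::setNames(labs, keys)
}
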