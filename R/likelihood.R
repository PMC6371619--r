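## Felsenstein pruning machinery over the variant-site matrix.
##
## Internally sites are compressed to unique columns ("patterns") with
## multiplicities; partial likelihoods are 4 x n_pattern matrices per node,
## rescaled per column to avoid underflow.

## integer tip-state matrix (ntip x nsite), rows ordered as tree tips
tip_state_matrix <- function(tree, matrix) {
  if (!setequal(tree$tip_label, matrix$tbl$allele)) {
    stop("tree taxa and matrix alleles differ", call. = FALSE)
  }
  sts <- vm_states(matrix, tree$tip_label)
  m <- do.call(rbind, lapply(strsplit(sts, "", fixed = TRUE),
                             function(ch) match(ch, NUC)))
  rownames(m) <- tree$tip_label
  m
}

compress_patterns <- function(tipstates) {
  key <- apply(tipstates, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(states = tipstates[, first, drop = FALSE],
       weights = as.numeric(table(factor(map, levels = seq_len(sum(first))))),
       map = map)
}

## branch length (expected substitutions/site) above each node
branch_lengths_subst <- function(tree, mean_rate = 1) {
  has_par <- tree$parent != 0L
  bl <- numeric(length(tree$parent))
  bl[has_par] <- (tree$heights[tree$parent[has_par]] - tree$heights[has_par]) *
    mean_rate * tree$rates[has_par]
  pmax(bl, 0)
}

## children as a 2 x m matrix (0 for tips), the layout the C kernel wants
tt_children_matrix <- function(tree) {
  m <- length(tree$parent)
  ch <- matrix(0L, 2L, m)
  pos <- integer(m)
  for (i in seq_len(m)) {
    p <- tree$parent[i]
    if (p != 0L) {
      pos[p] <- pos[p] + 1L
      ch[pos[p], p] <- i
    }
  }
  ch
}

## below-partials for every node. tipstates: ntip x npat integer matrix.
## Returns list(part = stacked (4m x npat) partials, log_scale = per-pattern
## log rescaling total, ent = 16 x m transition-matrix entries). Node `i`'s
## partials are rows 4(i-1)+1..4i; its P matrix is matrix(ent[, i], 4, 4).
## `engine = "R"` runs the reference R implementation of the same recursion.
pruning_partials <- function(tree, tipstates, params, mean_rate = 1,
                             engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  n <- tree$ntip
  m <- 2L * n - 1L
  npat <- ncol(tipstates)
  bl <- branch_lengths_subst(tree, mean_rate)
  ent <- tn93_pmat_ent(params, bl)
  if (engine == "cpp") {
    res <- .prune_partials_cpp(n, tree$parent, ent, tipstates)
    return(list(part = res$partials, log_scale = res$log_scale, ent = ent))
  }
  kids <- tt_children_matrix(tree)
  po <- tt_postorder(tree)
  part <- matrix(0, 4L * m, npat)
  part[cbind(4L * (rep(seq_len(n), npat) - 1L) + as.vector(tipstates),
             rep(seq_len(npat), each = n))] <- 1
  log_scale <- numeric(npat)
  for (node in po) {
    if (node <= n) next
    c1 <- kids[1L, node]; c2 <- kids[2L, node]
    P1 <- matrix(ent[, c1], 4L, 4L); P2 <- matrix(ent[, c2], 4L, 4L)
    L <- (P1 %*% part[4L * (c1 - 1L) + 1:4, , drop = FALSE]) *
         (P2 %*% part[4L * (c2 - 1L) + 1:4, , drop = FALSE])
    sc <- pmax(L[1L, ], L[2L, ], L[3L, ], L[4L, ])
    sc[sc == 0] <- 1
    part[4L * (node - 1L) + 1:4, ] <- L * rep(1 / sc, each = 4L)
    log_scale <- log_scale + log(sc)
  }
  list(part = part, log_scale = log_scale, ent = ent)
}

## node accessors into the stacked partials
pp_node <- function(pr, node) pr$part[4L * (node - 1L) + 1:4, , drop = FALSE]
pp_pmat <- function(pr, node) matrix(pr$ent[, node], 4L, 4L)

## per-pattern log-likelihoods (length npat)
pattern_loglik <- function(tree, tipstates, params, mean_rate = 1,
                           engine = "cpp") {
  pr <- pruning_partials(tree, tipstates, params, mean_rate, engine = engine)
  root <- tt_root(tree)
  lik <- colSums(params$pi * pp_node(pr, root))
  log(lik) + pr$log_scale
}

#' Phylogenetic log-likelihood of a variant matrix on a time-tree
#'
#' Felsenstein pruning under the TN93 model, sites independent. The branch
#' length entering the substitution process is
#' `(parent height - child height) * mean_rate * branch multiplier`.
#' With `ascertainment = TRUE` the likelihood conditions on sites being
#' variable (each site's likelihood is divided by one minus the probability
#' of a constant site), for matrices from which invariant columns were
#' removed.
#'
#' @param tree A [timetree] whose tips match the matrix alleles.
#' @param matrix A `variant_matrix`.
#' @param params A [tn93_params].
#' @param clock A [clock_model]; only `mean_rate` enters here (branch
#'   multipliers live on the tree).
#' @param ascertainment Condition on variability? Default `FALSE`.
#' @return Log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, matrix, params,
                                clock = clock_model("strict"),
                                ascertainment = FALSE) {
  tipstates <- tip_state_matrix(tree, matrix)
  pat <- compress_patterns(tipstates)
  ll <- sum(pat$weights * pattern_loglik(tree, pat$states, params,
                                         clock$mean_rate))
  if (ascertainment) {
    const <- matrix(rep(1:4, each = tree$ntip), nrow = tree$ntip)
    pconst <- sum(exp(pattern_loglik(tree, const, params, clock$mean_rate)))
    ll <- ll - sum(pat$weights) * log1p(-pconst)
  }
  ll
}
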