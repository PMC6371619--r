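## vectorized categorical draw over the columns of a 4 x S weight matrix
sample_columns <- function(W) {
  c2 <- W[1L, ] + W[2L, ]
  c3 <- c2 + W[3L, ]
  tot <- c3 + W[4L, ]
  u <- stats::runif(ncol(W)) * tot
  as.integer(1L + (u >= W[1L, ]) + (u >= c2) + (u >= c3))
}

#' Jointly sample ancestral alleles at every internal node
#'
#' Standard stochastic backtrace: below-partials are computed by pruning,
#' the root state is drawn per site from its marginal posterior, and states
#' are then drawn conditionally down the tree. Leaves are clamped to their
#' observed alleles; sites are conditionally independent given the tree and
#' parameters. The node's sampled allele is the concatenation of its
#' per-site draws.
#'
#' @param sample A posterior sample from [run_mcmc()] (list with `tree` and
#'   `params`), or a [timetree] if `params` is supplied.
#' @param matrix A `variant_matrix` whose alleles match the tree's tips.
#' @param seed Optional integer seed.
#' @param params TN93 parameters (required when `sample` is a bare tree).
#' @param mean_rate Clock mean rate (default 1).
#' @return A tibble: node, clade (key over sorted ingroup taxa), states.
#' @export
sample_ancestral_alleles <- function(sample, matrix, seed = NULL,
                                     params = NULL, mean_rate = 1) {
  tree <- if (inherits(sample, "timetree")) sample else sample$tree
  params <- params %||% sample$params
  if (is.null(params)) stop("params required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- ancestral_backtrace(tree, matrix, params, mean_rate)
  n <- tree$ntip
  internal <- (n + 1L):(2L * n - 1L)
  keys <- tt_clade_keys(tree, sort(setdiff(tree$tip_label, tree$outgroup)))
  tibble::tibble(
    node = internal, clade = keys[internal],
    states = apply(st[internal, , drop = FALSE], 1L,
                   function(r) paste(NUC[r], collapse = "")))
}

## integer state matrix (all nodes x sites) from one joint draw
ancestral_backtrace <- function(tree, matrix, params, mean_rate = 1) {
  tipstates <- tip_state_matrix(tree, matrix)
  S <- ncol(tipstates)
  pr <- pruning_partials(tree, tipstates, params, mean_rate)
  n <- tree$ntip
  m <- 2L * n - 1L
  states <- matrix(0L, m, S)
  states[seq_len(n), ] <- tipstates
  root <- tt_root(tree)
  states[root, ] <- sample_columns(params$pi * pp_node(pr, root))
  for (node in rev(tt_postorder(tree))) {
    if (node == root || node <= n) next
    P <- pp_pmat(pr, node)
    ps <- states[tree$parent[node], ]
    W <- t(P)[, ps, drop = FALSE] * pp_node(pr, node)
    states[node, ] <- sample_columns(W)
  }
  states
}

#' Marginal ancestral-state posteriors at every node
#'
#' Exact per-site marginal posteriors by the inside-outside (pruning plus
#' preorder) recursion; the reference the joint backtrace is checked
#' against, and the basis of the product-of-marginals ancestor enumerator.
#'
#' @inheritParams sample_ancestral_alleles
#' @param tree A [timetree].
#' @return A list of 4 x n_sites probability matrices, one per node id
#'   (leaves included; a leaf's posterior is its clamped state).
#' @export
marginal_ancestral_posteriors <- function(tree, matrix, params, mean_rate = 1) {
  tipstates <- tip_state_matrix(tree, matrix)
  S <- ncol(tipstates)
  pr <- pruning_partials(tree, tipstates, params, mean_rate)
  n <- tree$ntip
  m <- 2L * n - 1L
  root <- tt_root(tree)
  above <- vector("list", m)
  above[[root]] <- matrix(params$pi, 4L, S)
  kids <- tt_children(tree)
  for (node in rev(tt_postorder(tree))) {
    if (node <= n) next
    ch <- kids[[node]]
    for (k in 1:2) {
      c1 <- ch[k]; c2 <- ch[3L - k]
      sib <- pp_pmat(pr, c2) %*% pp_node(pr, c2)
      above[[c1]] <- t(pp_pmat(pr, c1)) %*% (above[[node]] * sib)
    }
  }
  lapply(seq_len(m), function(node) {
    W <- above[[node]] * pp_node(pr, node)
    sweep(W, 2L, colSums(W), "/")
  })
}

#' Enumerate candidate ancestral alleles from per-site marginals
#'
#' Secondary estimator: treats sites as independent given the tree and
#' enumerates every allele whose product of per-site marginal posteriors at
#' a node exceeds `floor`. Ignores the across-site dependence that topology
#' uncertainty induces; the joint tally ([tally_node_alleles()]) is the
#' primary estimator.
#'
#' @param marginals A 4 x n_sites matrix of per-site posteriors at one node.
#' @param floor Minimum product probability retained.
#' @return A tibble: states, probability — sorted descending.
#' @export
enumerate_marginal_ancestors <- function(marginals, floor = 1e-6) {
  S <- ncol(marginals)
  res_states <- character(0); res_p <- numeric(0)
  rec <- function(prefix, p, site) {
    if (p < floor) return()
    if (site > S) {
      res_states[[length(res_states) + 1L]] <<- prefix
      res_p[[length(res_p) + 1L]] <<- p
      return()
    }
    for (x in order(marginals[, site], decreasing = TRUE)) {
      px <- marginals[x, site]
      if (p * px < floor) break
      rec(paste0(prefix, NUC[x]), p * px, site + 1L)
    }
  }
  rec("", 1, 1L)
  tibble::tibble(states = res_states, probability = res_p) |>
    dplyr::arrange(dplyr::desc(.data$probability), .data$states)
}

#' Tally jointly sampled ancestral alleles per MCC clade
#'
#' For every internal clade of the MCC tree, draws one joint ancestral
#' assignment per post-burn-in posterior sample whose tree contains that
#' clade and tallies the sampled alleles. The per-clade posteriors are
#' conditional on clade presence: `count / n_clade_samples`.
#'
#' @param fit An `allele_mcmc` fit (or plain list of posterior samples).
#' @param matrix The `variant_matrix` the fit was run on.
#' @param mcc The MCC [timetree] from [mcc_tree()] (defines the clades).
#' @param burn_in_fraction Override of the configured burn-in.
#' @param seed Optional integer seed for the joint draws.
#' @return A tibble: clade, states, count, n_clade_samples, posterior —
#'   the full per-clade distributions, not only the modes.
#' @export
tally_node_alleles <- function(fit, matrix, mcc, burn_in_fraction = NULL,
                               seed = NULL) {
  ss <- as_post_samples(fit, burn_in_fraction)
  if (!is.null(seed)) set.seed(seed)
  taxa <- sort(setdiff(mcc$tip_label, mcc$outgroup))
  mcc_keys <- unique(tree_clade_table(mcc, taxa)$key)
  counts <- new.env(parent = emptyenv())
  nsamp <- new.env(parent = emptyenv())
  for (s in ss) {
    draw <- sample_ancestral_alleles(s, matrix)
    ## the same clade key can appear twice (root + ingroup MRCA); keep the
    ## lower node's draw, consistent with tree_clade_table
    ct <- tree_clade_table(s$tree, taxa)
    states_of <- stats::setNames(draw$states[match(ct$node, draw$node)], ct$key)
    present <- intersect(mcc_keys, ct$key)
    for (k in present) {
      nsamp[[k]] <- (nsamp[[k]] %||% 0) + 1
      tab <- counts[[k]] %||% new.env(parent = emptyenv())
      a <- states_of[[k]]
      tab[[a]] <- (tab[[a]] %||% 0) + 1
      counts[[k]] <- tab
    }
  }
  missing <- setdiff(mcc_keys, ls(counts))
  if (length(missing)) {
    warning(length(missing), " MCC clade(s) present in no posterior sample; excluded")
  }
  purrr::map_dfr(ls(counts), function(k) {
    tab <- counts[[k]]
    al <- ls(tab)
    tibble::tibble(clade = k, states = al,
                   count = vapply(al, function(a) tab[[a]], 0),
                   n_clade_samples = nsamp[[k]]) |>
      dplyr::mutate(posterior = .data$count / .data$n_clade_samples)
  }) |>
    dplyr::arrange(.data$clade, dplyr::desc(.data$posterior), .data$states)
}

#' Best (modal) ancestral allele per clade
#'
#' The highest-posterior tallied allele at each clade; ties broken by the
#' lexicographically smallest states string. Status is `observed` when the
#' allele equals some input allele's states, else `predicted`.
#'
#' @param tallies Tibble from [tally_node_alleles()].
#' @param observed Character vector of observed allele states (optionally
#'   named by allele label).
#' @return A tibble: clade, states, posterior, status, matches_observed.
#' @export
best_ancestors <- function(tallies, observed = character()) {
  tallies |>
    dplyr::group_by(.data$clade) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$states, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      status = ifelse(.data$states %in% observed, "observed", "predicted"),
      matches_observed = names_of_match(.data$states, observed)) |>
    dplyr::select("clade", "states", "posterior", "status", "matches_observed")
}

names_of_match <- function(states, observed) {
  if (is.null(names(observed))) names(observed) <- rep("", length(observed))
  vapply(states, function(s) {
    i <- match(s, observed)
    if (is.na(i)) NA_character_ else names(observed)[i]
  }, "", USE.NAMES = FALSE)
}

#' Two largest posteriors of a clade's tally
#'
#' @param tallies Tibble from [tally_node_alleles()] (one or many clades).
#' @return A tibble: clade, best, second (0 when only one allele tallied).
#' @export
second_best_gap <- function(tallies) {
  tallies |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      best = max(.data$posterior),
      second = if (dplyr::n() > 1L) sort(.data$posterior, decreasing = TRUE)[2L] else 0,
      .groups = "drop")
}
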