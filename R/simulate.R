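#' Simulate a constant-size coalescent genealogy
#'
#' Standard n-coalescent: with `k` active lineages the waiting time to the
#' next merger is `Exponential(k(k-1)/(2 * pop_size))` and a uniformly random
#' pair coalesces. Tips are contemporaneous at height 0.
#'
#' @param n Number of tips (>= 2).
#' @param pop_size Effective population size (tree time units).
#' @param seed Optional integer seed.
#' @param tip_label Optional tip names (default `t1..tn`).
#' @return A [timetree].
#' @export
simulate_coalescent_tree <- function(n, pop_size = 1, seed = NULL,
                                     tip_label = NULL) {
  if (n < 2L) stop("need at least 2 lineages", call. = FALSE)
  if (pop_size <= 0) stop("pop_size must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tip_label <- tip_label %||% paste0("t", seq_len(n))
  m <- 2L * n - 1L
  parent <- integer(m)
  heights <- numeric(m)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / (2 * pop_size))
    pair <- sample(active, 2L)
    parent[pair] <- nxt
    heights[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  timetree(tip_label, parent, heights)
}

#' Graft a divergent outgroup above the root of a tree
#'
#' Adds a new root at `stem_factor` times the old root height, with the old
#' root and a new tip (the outgroup, at height 0) as its children.
#'
#' @param tree A [timetree].
#' @param label Outgroup tip name.
#' @param stem_factor New root height as a multiple of the old root height.
#' @return A [timetree] with `ntip + 1` tips and the outgroup recorded.
#' @export
add_outgroup <- function(tree, label = "Outgroup", stem_factor = 4) {
  n <- tree$ntip
  old_m <- 2L * n - 1L
  root_h <- max(tree$heights)
  ## renumber: tips 1..n stay, new tip n+1, internals shift by 1, new root last
  shift <- function(id) ifelse(id == 0L, 0L, ifelse(id <= n, id, id + 1L))
  m <- 2L * (n + 1L) - 1L
  parent <- integer(m); heights <- numeric(m); rates <- rep(1, m)
  parent[shift(seq_len(old_m))] <- shift(tree$parent)
  heights[shift(seq_len(old_m))] <- tree$heights
  rates[shift(seq_len(old_m))] <- tree$rates
  new_root <- m
  old_root <- shift(tt_root(tree))
  parent[old_root] <- new_root
  parent[n + 1L] <- new_root
  heights[new_root] <- stem_factor * root_h
  timetree(c(tree$tip_label, label), parent, heights, rates, outgroup = label)
}

#' Evolve sequences along a time-tree under TN93
#'
#' The root sequence is drawn from the stationary frequencies (unless
#' supplied) and every branch mutates each site independently with the TN93
#' transition matrix of its effective length
#' `(time duration) * mean_rate * branch multiplier`. All internal-node
#' states are recorded, so the truth is fully known. With
#' `max_one_change = TRUE`, sites are simulated by explicit mutation events
#' and conditioned (by rejection) on at most one event per site — a clean
#' regime for oracle tests where back/parallel substitutions would
#' complicate truth.
#'
#' @param tree A [timetree].
#' @param params A [tn93_params].
#' @param mean_rate Substitution rate per site per time unit.
#' @param n_sites Number of sites to simulate.
#' @param root_sequence Optional integer (1..4) or character root states.
#' @param seed Optional integer seed.
#' @param max_one_change Condition on at most one mutation event per site?
#' @return A `simulation_truth`: list with `tree`, `node_states` (integer
#'   matrix, nodes x sites), `params`, `mean_rate`.
#' @export
evolve_sequences <- function(tree, params, mean_rate, n_sites,
                             root_sequence = NULL, seed = NULL,
                             max_one_change = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  m <- 2L * tree$ntip - 1L
  root <- tt_root(tree)
  states <- matrix(0L, m, n_sites)
  if (is.null(root_sequence)) {
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = params$pi)
  } else {
    rs <- if (is.character(root_sequence)) {
      match(strsplit(paste(root_sequence, collapse = ""), "")[[1]], NUC)
    } else as.integer(root_sequence)
    stopifnot(length(rs) == n_sites)
    states[root, ] <- rs
  }
  if (max_one_change) {
    return(evolve_max_one_change(tree, params, mean_rate, n_sites, states, root))
  }
  bl <- branch_lengths_subst(tree, mean_rate)
  order <- rev(tt_postorder(tree))  # parents before children
  for (node in order) {
    if (node == root) next
    P <- tn93_transition_probs(params, bl[node])
    ps <- states[tree$parent[node], ]
    out <- integer(n_sites)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                              prob = P[s, ])
    }
    states[node, ] <- out
  }
  structure(list(tree = tree, node_states = states, params = params,
                 mean_rate = mean_rate), class = "simulation_truth")
}

## event-based simulation conditioned on <= 1 mutation event per site
evolve_max_one_change <- function(tree, params, mean_rate, n_sites, states, root) {
  bl <- branch_lengths_subst(tree, mean_rate)
  total <- sum(bl)
  Q <- tn93_rate_matrix(params)
  order <- rev(tt_postorder(tree))
  for (site in seq_len(n_sites)) {
    repeat {
      k <- stats::rpois(1L, total)
      if (k <= 1L) break
    }
    col <- rep(states[root, site], length(bl))
    if (k == 1L) {
      br <- sample.int(length(bl), 1L, prob = bl / total)
      old <- states[root, site]
      jump <- Q[old, ]; jump[old] <- 0
      new <- sample.int(4L, 1L, prob = jump)
      ## mutate the chosen branch's subtree
      below <- logical(length(bl))
      below[br] <- TRUE
      for (node in order) {
        p <- tree$parent[node]
        if (p != 0L && below[p]) below[node] <- TRUE
      }
      col[below] <- new
    }
    states[, site] <- col
  }
  structure(list(tree = tree, node_states = states, params = params,
                 mean_rate = mean_rate), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d tips, %d sites, rate %.3g\n",
              x$tree$ntip, ncol(x$node_states), x$mean_rate))
  invisible(x)
}

truth_sequences <- function(truth, nodes) {
  apply(truth$node_states[nodes, , drop = FALSE], 1L,
        function(r) paste(NUC[r], collapse = ""))
}

#' Leaf alleles of a simulation as an aligned set
#'
#' @param truth A `simulation_truth`.
#' @return An [aligned_alleles] object (outgroup carried over if present).
#' @export
truth_alignment <- function(truth) {
  n <- truth$tree$ntip
  aligned_alleles(truth$tree$tip_label, truth_sequences(truth, seq_len(n)),
                  outgroup = truth$tree$outgroup)
}

#' Simulate an allele study fixture with known truth
#'
#' Tuned preset emulating a clinical long-gene allele set: `n_alleles`
#' contemporaneous ingroup alleles on a constant-size coalescent genealogy
#' plus one divergent outgroup, sequences of `seq_length` sites under TN93
#' with the per-site mutation rate calibrated to the realized genealogy
#' length so the expected number of ingroup variant sites is
#' `target_variants`. Everything (genealogy, every ancestral sequence,
#' mutation placement) is recorded.
#'
#' @param seed Integer seed; fixes every draw.
#' @param n_alleles Ingroup alleles (default 48).
#' @param seq_length Sites simulated (default 21406).
#' @param target_variants Expected ingroup variant-site count (default 72).
#' @param pop_size Coalescent population size (default 1; time unit =
#'   coalescent unit).
#' @param params TN93 parameters (default: unequal frequencies, kappas 4/8 —
#'   transition-biased, GC != 50%, as typical for genomic SNP sets).
#' @param outgroup Add a divergent outgroup? Default `TRUE`.
#' @param stem_factor Outgroup root height multiple (see [add_outgroup()]).
#' @param keep_full_matrix Also return `full_matrix`, a `variant_matrix`
#'   over every simulated column (invariant columns included), for analyses
#'   of the complete alignment rather than the extracted variant sites.
#' @return A list: `truth` (`simulation_truth`), `alignment`
#'   ([aligned_alleles]), `matrix` (`variant_matrix` over the ingroup
#'   variant sites), `root_allele` (true ingroup-root states at those
#'   sites), `root_allele_full` (over all columns), `ancestral_states`
#'   (internal-node states at the variant sites), `mutation_rate`, and
#'   optionally `full_matrix`.
#' @export
make_study_fixture <- function(seed = 1, n_alleles = 48, seq_length = 21406,
                               target_variants = 72, pop_size = 1,
                               params = tn93_params(pi = c(0.27, 0.23, 0.22, 0.28),
                                                    kappa1 = 4, kappa2 = 8),
                               outgroup = TRUE, stem_factor = 4,
                               keep_full_matrix = FALSE) {
  set.seed(seed)
  tree <- simulate_coalescent_tree(n_alleles, pop_size,
                                   tip_label = sprintf("Allele%02d", seq_len(n_alleles)))
  ing_root <- tt_root(tree)
  ingroup_length <- sum(branch_lengths_subst(tree, 1))
  mu <- target_variants / (ingroup_length * seq_length)
  full <- if (outgroup) add_outgroup(tree, "Outgroup", stem_factor) else tree
  truth <- evolve_sequences(full, params, mean_rate = mu, n_sites = seq_length)
  aln <- truth_alignment(truth)
  vm <- extract_variant_sites(aln, reference = "Allele01")
  n <- full$ntip
  internal <- (n + 1L):(2L * n - 1L)
  anc <- truth$node_states[internal, vm$site_positions, drop = FALSE]
  anc_str <- apply(anc, 1L, function(r) paste(NUC[r], collapse = ""))
  keys <- tt_clade_keys(full, taxa = sort(vm_ingroup(vm)$allele))
  names(anc_str) <- keys[internal]
  ## the ingroup root in the grafted tree keeps its clade key (all ingroup taxa)
  ing_mrca <- if (outgroup) ing_root + 1L else ing_root
  root_full <- truth$node_states[ing_mrca, ]
  out <- list(truth = truth, alignment = aln, matrix = vm,
              root_allele = paste(NUC[root_full[vm$site_positions]], collapse = ""),
              root_allele_full = paste(NUC[root_full], collapse = ""),
              ancestral_states = anc_str, mutation_rate = mu)
  if (keep_full_matrix) {
    out$full_matrix <- variant_matrix(
      aln$names, aln$sequences, reference = "Allele01",
      outgroup = if (outgroup) "Outgroup" else NULL,
      alignment_length = seq_length)
  }
  out
}
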