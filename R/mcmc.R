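#' MCMC run configuration
#'
#' @param chain_length Generations per chain.
#' @param sample_every Thinning interval; samples are taken at generations
#'   0, `sample_every`, `2*sample_every`, ... so a chain of length `L`
#'   yields `L %/% sample_every + 1` samples.
#' @param burn_in_fraction Proportion of each chain discarded by summaries.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param n_chains Number of independent chains.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 200000, sample_every = 200,
                        burn_in_fraction = 0.1, seed = 1, n_chains = 1) {
  if (chain_length < sample_every || sample_every < 1) {
    stop("need chain_length >= sample_every >= 1", call. = FALSE)
  }
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(chain_length = as.integer(chain_length),
                 sample_every = as.integer(sample_every),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed), n_chains = as.integer(n_chains)),
            class = "mcmc_config")
}

#' Number of samples a chain configuration yields
#'
#' Sampling starts at generation 0, so `chain_length %/% sample_every + 1`
#' per chain.
#'
#' @param chain_length Generations.
#' @param sample_every Thinning interval.
#' @return Integer sample count.
#' @export
mcmc_sample_count <- function(chain_length, sample_every) {
  as.integer(chain_length %/% sample_every + 1L)
}

## UPGMA initial time-tree from pairwise Hamming distances (per site), with
## a minimum parent-child separation so no branch is exactly zero
initial_tree <- function(matrix, min_sep = NULL) {
  tbl <- matrix$tbl
  ing <- tbl$allele[!tbl$is_outgroup]
  S <- n_sites(matrix)
  chs <- vm_char_matrix(matrix)[ing, , drop = FALSE]
  d <- matrix(0, length(ing), length(ing), dimnames = list(ing, ing))
  for (i in seq_along(ing)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- sum(chs[i, ] != chs[j, ]) / S
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  tt <- timetree_from_phylo(phy)
  min_sep <- min_sep %||% max(1e-4 / S, 1e-8)
  ## enforce strictly increasing heights parent over children (bottom-up)
  kids <- tt_children(tt)
  for (node in tt_postorder(tt)) {
    if (node <= tt$ntip) next
    ch <- kids[[node]]
    tt$heights[node] <- max(tt$heights[node], max(tt$heights[ch]) + min_sep)
  }
  if (!is.null(matrix$outgroup)) tt <- add_outgroup(tt, matrix$outgroup,
                                                    stem_factor = 3)
  tt
}

## ---- proposal moves; each returns NULL (reject outright) or
## list(tree = ..., log_hastings = ...) -------------------------------------

propose_node_height <- function(tree) {
  n <- tree$ntip
  root <- tt_root(tree)
  cand <- setdiff((n + 1L):(2L * n - 1L), root)
  if (!length(cand)) return(NULL)
  node <- if (length(cand) == 1L) cand else sample(cand, 1L)
  ch <- which(tree$parent == node)
  lo <- max(tree$heights[ch]); hi <- tree$heights[tree$parent[node]]
  if (hi <= lo) return(NULL)
  h <- tree$heights
  h[node] <- stats::runif(1L, lo, hi)
  list(tree = tt_replace(tree, heights = h), log_hastings = 0)
}

propose_root_height <- function(tree, tune = 1.5) {
  root <- tt_root(tree)
  ch <- which(tree$parent == root)
  lo <- max(tree$heights[ch])
  delta <- tree$heights[root] - lo
  if (delta <= 0) return(NULL)
  s <- exp(tune * (stats::runif(1L) - 0.5))
  h <- tree$heights
  h[root] <- lo + delta * s
  list(tree = tt_replace(tree, heights = h), log_hastings = log(s))
}

propose_tree_scale <- function(tree, tune = 0.7) {
  n <- tree$ntip
  s <- exp(tune * (stats::runif(1L) - 0.5))
  h <- tree$heights
  internal <- (n + 1L):(2L * n - 1L)
  h[internal] <- h[internal] * s
  list(tree = tt_replace(tree, heights = h), log_hastings = length(internal) * log(s))
}

propose_narrow_exchange <- function(tree) {
  n <- tree$ntip
  root <- tt_root(tree)
  cand <- setdiff((n + 1L):(2L * n - 1L), root)
  p <- if (length(cand) == 1L) cand else sample(cand, 1L)
  g <- tree$parent[p]
  sibs <- which(tree$parent == g)
  u <- sibs[sibs != p]
  ch <- which(tree$parent == p)
  i <- if (length(ch) == 1L) ch else sample(ch, 1L)
  if (tree$heights[p] <= tree$heights[u]) return(NULL)
  par <- tree$parent
  par[i] <- g; par[u] <- p
  list(tree = tt_replace(tree, parent = par), log_hastings = 0)
}

## is a an ancestor of b?
is_ancestor <- function(parent, a, b) {
  x <- parent[b]
  while (x != 0L) { if (x == a) return(TRUE); x <- parent[x] }
  FALSE
}

propose_wide_exchange <- function(tree) {
  m <- length(tree$parent)
  root <- tt_root(tree)
  cand <- setdiff(seq_len(m), root)
  pair <- sample(cand, 2L)
  i <- pair[1L]; j <- pair[2L]
  pi_ <- tree$parent[i]; pj <- tree$parent[j]
  if (pi_ == pj) return(NULL)
  if (is_ancestor(tree$parent, i, j) || is_ancestor(tree$parent, j, i)) return(NULL)
  if (tree$heights[pi_] <= tree$heights[j] ||
      tree$heights[pj] <= tree$heights[i]) return(NULL)
  par <- tree$parent
  par[i] <- pj; par[j] <- pi_
  list(tree = tt_replace(tree, parent = par), log_hastings = 0)
}

propose_scale_scalar <- function(x, tune = 1.6) {
  s <- exp(tune * (stats::runif(1L) - 0.5))
  list(value = x * s, log_hastings = log(s))
}

propose_branch_rate <- function(tree, cats) {
  m <- length(tree$parent)
  root <- tt_root(tree)
  node <- sample(setdiff(seq_len(m), root), 1L)
  r <- tree$rates
  r[node] <- cats[sample.int(length(cats), 1L)]
  list(tree = tt_replace(tree, rates = r), log_hastings = 0)
}

outgroup_ok <- function(tree) {
  if (is.null(tree$outgroup)) return(TRUE)
  og <- match(tree$outgroup, tree$tip_label)
  tree$parent[og] == tt_root(tree)
}

## ---- posterior pieces ------------------------------------------------------

param_log_prior <- function(kappa1, kappa2, pop_size, priors) {
  stats::dlnorm(kappa1, priors$kappa_meanlog, priors$kappa_sdlog, log = TRUE) +
    stats::dlnorm(kappa2, priors$kappa_meanlog, priors$kappa_sdlog, log = TRUE) +
    stats::dlnorm(pop_size, priors$pop_meanlog, priors$pop_sdlog, log = TRUE)
}

#' Default priors for the sampled scalar parameters
#'
#' Lognormal priors on both transition/transversion ratios and on the
#' coalescent population size. Deliberately weak; exposed as configuration
#' because the analysis they mirror did not state its priors.
#'
#' @param kappa_meanlog,kappa_sdlog Lognormal prior on `kappa1`, `kappa2`.
#' @param pop_meanlog,pop_sdlog Lognormal prior on `pop_size`.
#' @return A named list.
#' @export
default_priors <- function(kappa_meanlog = 1, kappa_sdlog = 1.25,
                           pop_meanlog = 1, pop_sdlog = 2) {
  list(kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
       pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog)
}

#' Sample the posterior over time-trees and model parameters
#'
#' Metropolis–Hastings over (topology, node heights, kappa1, kappa2,
#' pop_size) with a TN93 pruning likelihood over the variant sites, a
#' constant-size coalescent tree prior, and lognormal parameter priors.
#' Proposals: node-height slide, root-height scale, whole-tree scale, narrow
#' and wide subtree exchange, multiplier scalers for the three scalars, and
#' (relaxed clock) per-branch rate-category reassignment. Base frequencies
#' are fixed at their empirical values. If the matrix has an outgroup it is
#' constrained to attach at the root, so the ingroup tree is rooted by it.
#'
#' @param matrix A `variant_matrix` with at least 3 ingroup alleles.
#' @param config An [mcmc_config].
#' @param clock A [clock_model]; `"strict"` (default) or
#'   `"lognormal_relaxed"` with fixed `sigma`.
#' @param priors See [default_priors()].
#' @param init Optional named list overriding initial values
#'   (`kappa1`, `kappa2`, `pop_size`, `tree`, and `pi` to replace the
#'   empirical base frequencies).
#' @param fixed Optional character vector of parameters to hold fixed at
#'   their initial values (any of "kappa1", "kappa2", "pop_size",
#'   "topology").
#' @param ascertainment Condition the likelihood on site variability?
#' @return An object of class `allele_mcmc`: list with `samples` (list of
#'   posterior samples: chain, generation, tree, kappa1, kappa2, pop_size,
#'   log_likelihood, log_prior, log_posterior), `trace` (tibble), `config`,
#'   `matrix`, `clock`, `acceptance` (per-move rates).
#' @export
run_mcmc <- function(matrix, config, clock = clock_model("strict"),
                     priors = default_priors(), init = list(),
                     fixed = character(), ascertainment = FALSE) {
  n_ing <- sum(!matrix$tbl$is_outgroup)
  if (n_ing < 3L) stop("need at least 3 ingroup taxa", call. = FALSE)
  pi_hat <- init$pi %||%
    empirical_base_freqs(matrix, include_outgroup = !is.null(matrix$outgroup))
  cats <- if (clock$kind == "lognormal_relaxed") {
    k <- clock$n_rate_categories %||% (2L * nrow(matrix$tbl) - 2L)
    rate_category_values(clock$sigma, k)
  } else NULL

  samples <- list()
  trace <- list()
  acc <- num <- c(height = 0, root = 0, scale = 0, narrow = 0, wide = 0,
                  kappa1 = 0, kappa2 = 0, pop = 0, rate = 0)
  weights <- c(height = 3, root = 0.5, scale = 0.5, narrow = 2, wide = 1,
               kappa1 = 0.5, kappa2 = 0.5, pop = 1,
               rate = if (is.null(cats)) 0 else 2)
  if ("topology" %in% fixed) weights[c("narrow", "wide")] <- 0

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    tree <- init$tree %||% initial_tree(matrix)
    if (!is.null(cats)) {
      tree$rates <- draw_branch_rates(clock, length(tree$parent))
      tree$rates[tt_root(tree)] <- 1
    }
    kappa1 <- init$kappa1 %||% 2
    kappa2 <- init$kappa2 %||% 2
    pop_size <- init$pop_size %||% max(max(tree$heights), 1e-3)
    params <- tn93_params(pi_hat, kappa1, kappa2)

    tipstates <- tip_state_matrix(tree, matrix)
    pat <- compress_patterns(tipstates)
    tiporder <- tree$tip_label
    loglik <- function(tr, prm) {
      ## tip rows follow tree tip ids, which never change across moves
      ll <- sum(pat$weights * pattern_loglik(tr, pat$states, prm))
      if (ascertainment) {
        const <- matrix(rep(1:4, each = tr$ntip), nrow = tr$ntip)
        pc <- sum(exp(pattern_loglik(tr, const, prm)))
        ll <- ll - sum(pat$weights) * log1p(-pc)
      }
      ll
    }

    ll <- loglik(tree, params)
    lcp <- coalescent_log_prior(tree, pop_size)
    lpp <- param_log_prior(kappa1, kappa2, pop_size, priors)
    if (!is.finite(ll)) stop("initial tree has zero likelihood", call. = FALSE)

    take_sample <- function(gen) {
      lp <- lcp + lpp
      samples[[length(samples) + 1L]] <<- list(
        chain = chain, generation = gen, tree = tree, params = params,
        kappa1 = kappa1, kappa2 = kappa2, pop_size = pop_size,
        log_likelihood = ll, log_prior = lp, log_posterior = ll + lp)
      trace[[length(trace) + 1L]] <<- tibble::tibble(
        chain = chain, generation = gen, log_posterior = ll + lp,
        log_likelihood = ll, log_prior = lp, kappa1 = kappa1,
        kappa2 = kappa2, pop_size = pop_size,
        root_height = max(tree$heights))
    }
    take_sample(0L)

    move_names <- names(weights)[weights > 0]
    move_probs <- weights[weights > 0] / sum(weights[weights > 0])
    moves <- sample(move_names, config$chain_length, replace = TRUE,
                    prob = move_probs)

    for (gen in seq_len(config$chain_length)) {
      mv <- moves[gen]
      num[mv] <- num[mv] + 1
      if (mv %in% c("height", "root", "scale", "narrow", "wide", "rate")) {
        prop <- switch(mv,
          height = propose_node_height(tree),
          root   = propose_root_height(tree),
          scale  = propose_tree_scale(tree),
          narrow = propose_narrow_exchange(tree),
          wide   = propose_wide_exchange(tree),
          rate   = propose_branch_rate(tree, cats))
        if (!is.null(prop) && outgroup_ok(prop$tree)) {
          ll2 <- loglik(prop$tree, params)
          lcp2 <- coalescent_log_prior(prop$tree, pop_size)
          a <- (ll2 + lcp2) - (ll + lcp) + prop$log_hastings
          if (is.finite(ll2) && log(stats::runif(1L)) < a) {
            tree <- prop$tree; ll <- ll2; lcp <- lcp2
            acc[mv] <- acc[mv] + 1
          }
        } else stats::runif(1L)  # keep the RNG stream aligned across rejects
      } else if (mv %in% c("kappa1", "kappa2")) {
        if (mv %in% fixed) { stats::runif(1L) }
        else {
          pr <- propose_scale_scalar(if (mv == "kappa1") kappa1 else kappa2)
          k1 <- if (mv == "kappa1") pr$value else kappa1
          k2 <- if (mv == "kappa2") pr$value else kappa2
          prm2 <- tn93_params(pi_hat, k1, k2)
          ll2 <- loglik(tree, prm2)
          lpp2 <- param_log_prior(k1, k2, pop_size, priors)
          a <- (ll2 + lpp2) - (ll + lpp) + pr$log_hastings
          if (is.finite(ll2) && log(stats::runif(1L)) < a) {
            kappa1 <- k1; kappa2 <- k2; params <- prm2
            ll <- ll2; lpp <- lpp2; acc[mv] <- acc[mv] + 1
          }
        }
      } else if (mv == "pop") {
        if ("pop_size" %in% fixed) { stats::runif(1L) }
        else {
          pr <- propose_scale_scalar(pop_size)
          lcp2 <- coalescent_log_prior(tree, pr$value)
          lpp2 <- param_log_prior(kappa1, kappa2, pr$value, priors)
          a <- (lcp2 + lpp2) - (lcp + lpp) + pr$log_hastings
          if (log(stats::runif(1L)) < a) {
            pop_size <- pr$value; lcp <- lcp2; lpp <- lpp2
            acc["pop"] <- acc["pop"] + 1
          }
        }
      }
      if (gen %% config$sample_every == 0L) take_sample(gen)
    }
  }

  structure(
    list(samples = samples, trace = dplyr::bind_rows(trace), config = config,
         matrix = matrix, clock = clock, priors = priors,
         acceptance = ifelse(num > 0, acc / num, NA_real_)),
    class = "allele_mcmc")
}

#' @export
print.allele_mcmc <- function(x, ...) {
  cat(sprintf("<allele_mcmc> %d chain(s) x %d generations, %d samples\n",
              x$config$n_chains, x$config$chain_length, length(x$samples)))
  invisible(x)
}

## post-burn-in samples (burn-in applied per chain, by generation)
post_burn_in <- function(fit, burn_in_fraction = NULL) {
  f <- burn_in_fraction %||% fit$config$burn_in_fraction
  cut <- f * fit$config$chain_length
  keep <- vapply(fit$samples, function(s) s$generation >= cut, TRUE)
  if (!any(keep)) stop("no post-burn-in samples", call. = FALSE)
  fit$samples[keep]
}

#' Tidy posterior parameter summaries
#'
#' One row per scalar parameter with the posterior median, central 95%
#' credible interval and effective sample size over the post-burn-in trace.
#'
#' @param x An `allele_mcmc` fit.
#' @param ... Unused.
#' @return A tibble with columns term, estimate, conf.low, conf.high, ess.
#' @method tidy allele_mcmc
#' @export
tidy.allele_mcmc <- function(x, ...) {
  cut <- x$config$burn_in_fraction * x$config$chain_length
  tr <- dplyr::filter(x$trace, .data$generation >= cut)
  terms <- c("kappa1", "kappa2", "pop_size", "root_height", "log_posterior")
  purrr::map_dfr(terms, function(tm) {
    v <- tr[[tm]]
    tibble::tibble(
      term = tm, estimate = stats::median(v),
      conf.low = unname(stats::quantile(v, 0.025)),
      conf.high = unname(stats::quantile(v, 0.975)),
      ess = suppressWarnings(effective_sample_size(v)))
  })
}

#' One-row fit summary
#'
#' @param x An `allele_mcmc` fit.
#' @param ... Unused.
#' @return A tibble: chains, generations, samples, post-burn-in samples,
#'   log-posterior ESS, mean topology-move acceptance.
#' @method glance allele_mcmc
#' @export
glance.allele_mcmc <- function(x, ...) {
  cut <- x$config$burn_in_fraction * x$config$chain_length
  tr <- dplyr::filter(x$trace, .data$generation >= cut)
  tibble::tibble(
    n_chains = x$config$n_chains, chain_length = x$config$chain_length,
    n_samples = length(x$samples), n_post_burn_in = nrow(tr),
    ess_log_posterior = suppressWarnings(effective_sample_size(tr$log_posterior)),
    accept_topology = mean(x$acceptance[c("narrow", "wide")], na.rm = TRUE))
}

#' Trace plot of sampled scalars
#'
#' @param object An `allele_mcmc` fit.
#' @param parameters Which trace columns to show.
#' @param ... Unused.
#' @return A ggplot object (one facet per parameter, colour per chain).
#' @method autoplot allele_mcmc
#' @export
autoplot.allele_mcmc <- function(object,
                                 parameters = c("log_posterior", "kappa1",
                                                "kappa2", "pop_size",
                                                "root_height"), ...) {
  long <- tidyr::pivot_longer(object$trace, dplyr::all_of(parameters),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain", y = NULL) +
    ggplot2::theme_minimal()
}
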