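test_that("sampling arithmetic: chain length over thinning plus the zero sample", {
  expect_equal(mcmc_sample_count(9e6, 1000), 9001L)
  expect_equal(mcmc_sample_count(100, 10), 11L)
  expect_error(mcmc_config(chain_length = 5, sample_every = 10), "chain_length")
  expect_error(mcmc_config(burn_in_fraction = 1), "burn_in_fraction")
})

test_that("run_mcmc emits the configured number of samples and is seed-deterministic", {
  vm <- tiny_matrix()
  cfg <- mcmc_config(chain_length = 400, sample_every = 40, seed = 7)
  fit1 <- run_mcmc(vm, cfg)
  expect_equal(length(fit1$samples), 11L)
  expect_equal(fit1$trace$generation, seq(0, 400, by = 40))
  fit2 <- run_mcmc(vm, cfg)
  expect_identical(fit1$trace, fit2$trace)
  fit3 <- run_mcmc(vm, mcmc_config(chain_length = 400, sample_every = 40, seed = 8))
  expect_false(identical(fit1$trace$log_posterior, fit3$trace$log_posterior))
  ## two chains: samples carry chain ids, count doubles
  fit4 <- run_mcmc(vm, mcmc_config(chain_length = 400, sample_every = 40,
                                   seed = 7, n_chains = 2))
  expect_equal(length(fit4$samples), 22L)
  expect_setequal(unique(fit4$trace$chain), 1:2)
})

test_that("fewer than 3 ingroup taxa is an input error", {
  vm <- variant_matrix(c("a", "b"), c("AC", "AG"), reference = "a")
  expect_error(run_mcmc(vm, mcmc_config(100, 10)), "at least 3")
})

test_that("every sampled state is internally consistent", {
  vm <- tiny_matrix()
  fit <- run_mcmc(vm, mcmc_config(chain_length = 600, sample_every = 30, seed = 3))
  p <- fit$samples[[1]]$params
  for (s in fit$samples[c(1, 10, 21)]) {
    expect_true(is.finite(s$log_posterior))
    expect_equal(s$log_posterior, s$log_likelihood + s$log_prior)
    ## recompute the likelihood from the stored state
    expect_equal(s$log_likelihood,
                 tree_log_likelihood(s$tree, vm,
                                     tn93_params(p$pi, s$kappa1, s$kappa2)),
                 tolerance = 1e-9)
    ## heights valid
    has_par <- s$tree$parent != 0
    expect_true(all(s$tree$heights[s$tree$parent[has_par]] >=
                      s$tree$heights[has_par]))
  }
})

test_that("outgroup stays attached at the root throughout the chain", {
  aln <- tiny_alignment()
  aln2 <- aligned_alleles(c(aln$names, "og"),
                          c(aln$sequences, "TCTTACATTC"), outgroup = "og")
  vm <- extract_variant_sites(aln2, reference = "a1")
  fit <- run_mcmc(vm, mcmc_config(chain_length = 800, sample_every = 40, seed = 5))
  for (s in fit$samples) {
    og <- match("og", s$tree$tip_label)
    expect_equal(s$tree$parent[og], phyloallele:::tt_root(s$tree))
  }
})

## unrooted topology class of a rooted 4-taxon tree, by its cherry
unrooted_class <- function(tree) {
  kids <- phyloallele:::tt_children(tree)
  for (node in (tree$ntip + 1):(2 * tree$ntip - 1)) {
    ch <- kids[[node]]
    if (all(ch <= tree$ntip)) {
      pair <- sort(tree$tip_label[ch])
      if (!all(c("t1") %in% pair)) pair <- sort(setdiff(tree$tip_label, pair))
      return(paste(pair, collapse = ""))
    }
  }
  stop("no cherry found")
}

test_that("4-taxon 1-site posterior topology frequencies match a prior-predictive oracle", {
  ## data: t1,t2 share A; t3,t4 share C -> favours the t1t2|t3t4 split
  taxa <- paste0("t", 1:4)
  vm <- variant_matrix(taxa, c("A", "A", "C", "C"), reference = "t1")
  p <- tn93_params(pi = c(0.3, 0.2, 0.3, 0.2), kappa1 = 2, kappa2 = 2)
  N <- 1

  ## oracle: importance-sample the coalescent prior, weight by likelihood
  set.seed(99)
  M <- 20000
  w <- numeric(M); cls <- character(M)
  for (i in 1:M) {
    tr <- simulate_coalescent_tree(4, pop_size = N)
    w[i] <- exp(tree_log_likelihood(tr, vm, p))
    cls[i] <- unrooted_class(tr)
  }
  oracle <- tapply(w, cls, sum) / sum(w)

  fit <- run_mcmc(vm, mcmc_config(chain_length = 60000, sample_every = 20,
                                  seed = 13, burn_in_fraction = 0.1),
                  init = list(kappa1 = 2, kappa2 = 2, pop_size = N,
                              pi = p$pi),
                  fixed = c("kappa1", "kappa2", "pop_size"))
  ss <- phyloallele:::post_burn_in(fit)
  got <- table(vapply(ss, function(s) unrooted_class(s$tree), "")) /
    length(ss)
  for (k in names(oracle)) {
    expect_lt(abs(oracle[[k]] - (if (k %in% names(got)) got[[k]] else 0)), 0.05)
  }
})
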