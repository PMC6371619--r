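test_that("pruning equals brute-force enumeration on 3-5 leaf, 1-3 site instances", {
  p <- tn93_params(pi = c(0.3, 0.2, 0.3, 0.2), kappa1 = 2.5, kappa2 = 5)
  cases <- expand.grid(n = 3:5, s = 1:3, rep = 1:2)
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; s <- cases$s[i]
    seed <- 1000 + i
    tree <- simulate_coalescent_tree(n, pop_size = 0.8, seed = seed)
    vm <- random_matrix(tree$tip_label, s, seed = seed + 1)
    expect_equal(tree_log_likelihood(tree, vm, p),
                 brute_force_loglik(tree, vm, p), tolerance = 1e-10)
  }
})

test_that("C++ and R pruning engines agree", {
  p <- tn93_params(pi = c(0.27, 0.23, 0.22, 0.28), kappa1 = 4, kappa2 = 8)
  tree <- simulate_coalescent_tree(12, pop_size = 1, seed = 9)
  vm <- random_matrix(tree$tip_label, 20, seed = 10)
  ts <- phyloallele:::tip_state_matrix(tree, vm)
  a <- phyloallele:::pattern_loglik(tree, ts, p, engine = "cpp")
  b <- phyloallele:::pattern_loglik(tree, ts, p, engine = "R")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pruning matches an independent ML implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  p <- tn93_params(pi = c(0.3, 0.2, 0.3, 0.2), kappa1 = 2.5, kappa2 = 5)
  tree <- simulate_coalescent_tree(8, pop_size = 1, seed = 21)
  vm <- random_matrix(tree$tip_label, 30, seed = 22)
  dat <- phangorn::phyDat(setNames(strsplit(vm$tbl$states, ""), vm$tbl$allele),
                          type = "DNA")
  fit <- suppressMessages(phangorn::pml(as.phylo(tree), dat, bf = p$pi,
                                        model = "TrN", k = 1))
  fit <- update(fit, Q = c(1, p$kappa1, 1, 1, p$kappa2, 1))
  expect_equal(tree_log_likelihood(tree, vm, p), unname(fit$logLik),
               tolerance = 1e-8)
})

test_that("two identical leaves at zero branch lengths give log pi per site", {
  p <- tn93_params(pi = c(0.4, 0.1, 0.2, 0.3))
  tree <- timetree(c("a", "b"), c(3L, 3L, 0L), c(0, 0, 0))
  vm <- variant_matrix(c("a", "b"), c("A", "A"), reference = "a")
  expect_equal(tree_log_likelihood(tree, vm, p), log(0.4))
  vm2 <- variant_matrix(c("a", "b"), c("T", "T"), reference = "a")
  expect_equal(tree_log_likelihood(tree, vm2, p), log(0.3))
})

test_that("duplicating a site doubles its log-likelihood contribution", {
  p <- tn93_params(kappa1 = 3, kappa2 = 3)
  tree <- simulate_coalescent_tree(4, pop_size = 1, seed = 77)
  one <- variant_matrix(tree$tip_label, c("A", "C", "A", "G"), reference = "t1")
  two <- variant_matrix(tree$tip_label, c("AA", "CC", "AA", "GG"), reference = "t1")
  expect_equal(tree_log_likelihood(tree, two, p),
               2 * tree_log_likelihood(tree, one, p), tolerance = 1e-12)
})

test_that("likelihood is invariant to leaf order in the matrix and mismatch errors", {
  p <- tn93_params()
  tree <- simulate_coalescent_tree(5, pop_size = 1, seed = 31)
  vm <- random_matrix(tree$tip_label, 6, seed = 32)
  perm <- sample(5)
  vm2 <- variant_matrix(vm$tbl$allele[perm], vm$tbl$states[perm],
                        reference = vm$tbl$allele[perm][1])
  expect_equal(tree_log_likelihood(tree, vm, p),
               tree_log_likelihood(tree, vm2, p), tolerance = 1e-12)
  vm3 <- variant_matrix(paste0("x", 1:5), vm$tbl$states, reference = "x1")
  expect_error(tree_log_likelihood(tree, vm3, p), "differ")
})

test_that("ascertainment correction conditions on variability", {
  p <- tn93_params(pi = c(0.3, 0.2, 0.3, 0.2), kappa1 = 2, kappa2 = 2)
  tree <- simulate_coalescent_tree(4, pop_size = 0.5, seed = 41)
  vm <- variant_matrix(tree$tip_label, c("AC", "AC", "CA", "CC"),
                       reference = "t1")
  ll <- tree_log_likelihood(tree, vm, p)
  lla <- tree_log_likelihood(tree, vm, p, ascertainment = TRUE)
  ## closed form of the correction: per site, divide by 1 - P(constant)
  const <- variant_matrix(tree$tip_label, c("A", "A", "A", "A"), reference = "t1")
  pconst <- sum(vapply(c("A", "C", "G", "T"), function(x) {
    vmx <- variant_matrix(tree$tip_label, rep(x, 4), reference = "t1")
    exp(tree_log_likelihood(tree, vmx, p))
  }, 0))
  expect_equal(lla, ll - 2 * log1p(-pconst), tolerance = 1e-10)
  expect_gt(lla, ll)  # conditioning on a subset raises the density
})

test_that("branch rate multipliers stretch branches for the likelihood", {
  p <- tn93_params()
  tree <- simulate_coalescent_tree(4, pop_size = 1, seed = 55)
  vm <- random_matrix(tree$tip_label, 5, seed = 56)
  doubled <- tree
  doubled$rates <- rep(2, length(tree$rates))
  stretched <- tree
  stretched$heights <- tree$heights * 2
  expect_equal(tree_log_likelihood(doubled, vm, p),
               tree_log_likelihood(stretched, vm, p), tolerance = 1e-12)
})
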