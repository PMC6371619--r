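test_that("coalescent tree moments match closed forms", {
  ## n = 2: E[TMRCA] = N
  set.seed(1)
  tm <- replicate(8000, max(simulate_coalescent_tree(2, 1.5)$heights))
  expect_lt(abs(mean(tm) - 1.5), 3 * sd(tm) / sqrt(length(tm)))
  ## n = 10: E[total length] = 2N * sum_{k=1}^{9} 1/k
  set.seed(2)
  tl <- replicate(4000, {
    tr <- simulate_coalescent_tree(10, 1)
    sum(phyloallele:::branch_lengths_subst(tr, 1))
  })
  expect_lt(abs(mean(tl) - 2 * sum(1 / (1:9))), 3 * sd(tl) / sqrt(length(tl)))
})

test_that("the simulator is reproducible under seed and validates n", {
  t1 <- simulate_coalescent_tree(8, 1, seed = 5)
  t2 <- simulate_coalescent_tree(8, 1, seed = 5)
  expect_identical(t1, t2)
  expect_error(simulate_coalescent_tree(1, 1), "at least 2")
})

test_that("zero mutation rate copies the root everywhere", {
  tr <- simulate_coalescent_tree(6, 1, seed = 11)
  truth <- evolve_sequences(tr, tn93_params(), mean_rate = 0, n_sites = 50,
                            seed = 12)
  expect_true(all(truth$node_states == rep(truth$node_states[11, ],
                                           each = 11)))
  aln <- truth_alignment(truth)
  expect_warning(vm <- extract_variant_sites(aln), "no variable sites")
  expect_length(vm$site_positions, 0)
})

test_that("a long branch drives states to the stationary distribution", {
  p <- tn93_params(pi = c(0.4, 0.1, 0.2, 0.3), kappa1 = 3, kappa2 = 3)
  tr <- timetree(c("a", "b"), c(3L, 3L, 0L), c(0, 0, 50))
  truth <- evolve_sequences(tr, p, mean_rate = 1, n_sites = 10000, seed = 13)
  counts <- tabulate(truth$node_states[1, ], 4)
  expect_gt(stats::chisq.test(counts, p = p$pi)$p.value, 0.001)
})

test_that("leaf-pair divergence matches the closed-form TN93 expectation", {
  p <- tn93_params(pi = c(0.27, 0.23, 0.22, 0.28), kappa1 = 4, kappa2 = 8)
  t <- 0.15
  tr <- timetree(c("a", "b"), c(3L, 3L, 0L), c(0, 0, t / 2))
  n <- 10000
  truth <- evolve_sequences(tr, p, mean_rate = 1, n_sites = n, seed = 14)
  P <- tn93_transition_probs(p, t)
  pdiff <- 1 - sum(p$pi * diag(P))
  got <- mean(truth$node_states[1, ] != truth$node_states[2, ])
  expect_lt(abs(got - pdiff), 3 * sqrt(pdiff * (1 - pdiff) / n))
})

test_that("max_one_change mode places at most one mutation per site", {
  tr <- simulate_coalescent_tree(8, 1, seed = 15)
  truth <- evolve_sequences(tr, tn93_params(), mean_rate = 0.05, n_sites = 300,
                            seed = 16, max_one_change = TRUE)
  ## each site shows at most 2 distinct states, and derived states form a
  ## clade of the truth genealogy
  for (site in seq_len(300)) {
    expect_lte(length(unique(truth$node_states[, site])), 2L)
  }
})

test_that("segregating sites track Watterson's expectation under low mutation", {
  n <- 10; L <- 2000; N <- 1; u <- 0.002
  theta <- 2 * N * u * L                 # per-locus
  expected <- theta * sum(1 / (1:(n - 1)))
  set.seed(17)
  S <- replicate(60, {
    tr <- simulate_coalescent_tree(n, N)
    truth <- evolve_sequences(tr, tn93_params(), mean_rate = u, n_sites = L)
    sum(apply(truth$node_states[seq_len(n), ], 2,
              function(col) length(unique(col))) > 1)
  })
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
})

test_that("the study preset hits its variant-site contract at the default seed", {
  fx <- make_study_fixture(1)
  nv <- length(fx$matrix$site_positions)
  expect_gte(nv, 60)
  expect_lte(nv, 90)
  expect_gte(invariant_fraction(fx$matrix), 0.99)
  expect_equal(length(fx$alignment$names), 49)
  expect_equal(fx$alignment$outgroup, "Outgroup")
  ## deterministic per seed
  fx2 <- make_study_fixture(1)
  expect_identical(fx$matrix$tbl, fx2$matrix$tbl)
  ## truth bookkeeping: leaf alleles equal the recorded leaf states
  expect_equal(nchar(fx$root_allele), nv)
})

test_that("the outgroup is divergent and attaches basally in an NJ sanity check", {
  fx <- make_study_fixture(2, n_alleles = 12, seq_length = 2000,
                           target_variants = 40)
  seqs <- fx$alignment$sequences
  names(seqs) <- fx$alignment$names
  nm <- fx$alignment$names
  d <- matrix(0, 13, 13, dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
    d[i, j] <- d[j, i] <- hamming(seqs[i], seqs[j])
  }
  ing <- setdiff(nm, "Outgroup")
  expect_gt(min(d["Outgroup", ing]), max(d[ing, ing]))
  ## NJ places the outgroup on its own side of the deepest split
  nj <- ape::nj(as.dist(d))
  rooted <- ape::root(nj, outgroup = "Outgroup", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, ing))
})
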