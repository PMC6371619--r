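## Independent oracles: brute-force enumeration over internal-state
## assignments (no pruning), used to validate the likelihood machinery.

## log-likelihood by exhaustive sum over all 4^(n-1) internal assignments
## per site; deliberately naive and independent of the pruning code path
brute_force_loglik <- function(tree, matrix, params, mean_rate = 1) {
  chs <- do.call(rbind, strsplit(matrix$tbl$states, ""))
  rownames(chs) <- matrix$tbl$allele
  tipstates <- matrix(match(chs[tree$tip_label, , drop = FALSE],
                            c("A", "C", "G", "T")),
                      nrow = tree$ntip)
  n <- tree$ntip; m <- 2L * n - 1L
  root <- which(tree$parent == 0L)
  internal <- (n + 1L):m
  Pm <- vector("list", m)
  for (i in seq_len(m)) {
    if (tree$parent[i] == 0L) next
    bl <- (tree$heights[tree$parent[i]] - tree$heights[i]) * mean_rate *
      tree$rates[i]
    Pm[[i]] <- tn93_transition_probs(params, bl)
  }
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), length(internal))))
  total <- 0
  for (site in seq_len(ncol(tipstates))) {
    s <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(m)
      st[seq_len(n)] <- tipstates[, site]
      st[internal] <- grid[g, ]
      pr <- params$pi[st[root]]
      for (i in seq_len(m)) {
        if (tree$parent[i] != 0L) pr <- pr * Pm[[i]][st[tree$parent[i]], st[i]]
      }
      s <- s + pr
    }
    total <- total + log(s)
  }
  unname(total)
}

## exact marginal root posterior per site by the same exhaustive sum,
## restricted to a fixed root state
brute_force_root_posterior <- function(tree, matrix, params, mean_rate = 1) {
  chs <- do.call(rbind, strsplit(matrix$tbl$states, ""))
  rownames(chs) <- matrix$tbl$allele
  tipstates <- matrix(match(chs[tree$tip_label, , drop = FALSE],
                            c("A", "C", "G", "T")),
                      nrow = tree$ntip)
  n <- tree$ntip; m <- 2L * n - 1L
  root <- which(tree$parent == 0L)
  internal <- (n + 1L):m
  others <- internal[internal != root]
  Pm <- vector("list", m)
  for (i in seq_len(m)) {
    if (tree$parent[i] == 0L) next
    bl <- (tree$heights[tree$parent[i]] - tree$heights[i]) * mean_rate *
      tree$rates[i]
    Pm[[i]] <- tn93_transition_probs(params, bl)
  }
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), length(others))))
  out <- matrix(0, 4, ncol(tipstates))
  for (site in seq_len(ncol(tipstates))) {
    for (rs in 1:4) {
      s <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(m)
        st[seq_len(n)] <- tipstates[, site]
        st[root] <- rs
        if (length(others)) st[others] <- grid[g, ]
        pr <- params$pi[rs]
        for (i in seq_len(m)) {
          if (tree$parent[i] != 0L) pr <- pr * Pm[[i]][st[tree$parent[i]], st[i]]
        }
        s <- s + pr
      }
      out[rs, site] <- s
    }
  }
  sweep(out, 2, colSums(out), "/")
}

## random states matrix over given taxa
random_matrix <- function(taxa, n_sites, seed) {
  set.seed(seed)
  states <- replicate(length(taxa),
                      paste(sample(c("A", "C", "G", "T"), n_sites, TRUE),
                            collapse = ""))
  variant_matrix(taxa, states, reference = taxa[1])
}
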