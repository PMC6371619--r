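## Small fixtures built in code, shared across test files.

## a fixed 5-allele x 10-column alignment with SNPs engineered at columns 3
## and 7 (ingroup only)
tiny_alignment <- function() {
  aligned_alleles(
    names = paste0("a", 1:5),
    sequences = c("ACGTACGTAC",
                  "ACGTACGTAC",
                  "ACTTACGTAC",   # column 3 G->T
                  "ACGTACATAC",   # column 7 G->A
                  "ACGTACGTAC"))
}

## deterministic small variant matrix (4 alleles x 5 sites, no outgroup)
tiny_matrix <- function() {
  variant_matrix(
    allele = c("w", "x", "y", "z"),
    states = c("ACGTA", "ACGTC", "ATGTA", "GCGTA"),
    reference = "w")
}

## write a fixture FASTA and return its path
write_tiny_fasta <- function(dir = withr::local_tempdir()) {
  path <- file.path(dir, "tiny.fasta")
  write_alignment(tiny_alignment(), path)
  path
}

## a 2-tree "posterior" over 4 taxa for hand-count MCC checks: topology
## ((a,b),(c,d)) vs ((a,c),(b,d)), unit heights
four_taxon_sample <- function(topology = c("ab", "ac"), generation = 0) {
  topology <- match.arg(topology)
  tips <- c("a", "b", "c", "d")
  parent <- if (topology == "ab") c(5L, 5L, 6L, 6L, 7L, 7L, 0L)
            else c(5L, 6L, 5L, 6L, 7L, 7L, 0L)
  tree <- timetree(tips, parent, c(0, 0, 0, 0, 1, 1.5, 3))
  list(chain = 1L, generation = generation, tree = tree,
       params = tn93_params(), kappa1 = 2, kappa2 = 2, pop_size = 1,
       log_likelihood = 0, log_prior = 0, log_posterior = 0)
}

## catalogue built from explicit template states/weights, bypassing MCMC:
## observed get weight 1, predicted get `posterior`
toy_catalogue <- function(observed, predicted = character(),
                          posterior = numeric()) {
  if (length(predicted)) {
    tal <- tibble::tibble(
      clade = paste0("1,", seq_along(predicted) + 1L),
      states = predicted,
      count = round(posterior * 100),
      n_clade_samples = 100,
      posterior = posterior)
  } else {
    tal <- tibble::tibble(clade = character(), states = character(),
                          count = numeric(), n_clade_samples = numeric(),
                          posterior = numeric())
  }
  build_catalogue(tal, observed, threshold = 0)
}

## brute-force all genotype-compatible template pairs (oracle for
## compatible_pairs)
brute_force_pairs <- function(g, templates) {
  ok <- list()
  for (i in seq_along(templates)) for (j in i:length(templates)) {
    a <- strsplit(templates[i], "")[[1]]
    b <- strsplit(templates[j], "")[[1]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    miss <- g$a1 == "N"
    if (all(miss | (lo == g$a1 & hi == g$a2))) {
      key <- paste(min(templates[i], templates[j]),
                   max(templates[i], templates[j]))
      ok[[key]] <- sort(c(templates[i], templates[j]))
    }
  }
  unname(ok[order(names(ok))])
}
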