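test_that("genotype construction canonicalizes and validates", {
  g <- genotype("ACG", "ATG", "s1")
  expect_equal(g$a1, c("A", "C", "G"))
  expect_equal(g$a2, c("A", "T", "G"))
  expect_identical(genotype("ACG", "ATG")$a1, genotype("ATG", "ACG")$a1)
  expect_error(genotype("AC", "ACG"), "length")
  expect_error(genotype("AXG", "ACG"), "states")
  expect_error(genotype("ANG", "ACG"), "missing")
})

test_that("a homozygous catalogue genotype phases to the single self-pair", {
  ct <- toy_catalogue(c(X = "ACGT", Y = "ATGT"))
  res <- phase_genotype(merge_alleles("ACGT", "ACGT"), ct)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$allele_a, "ACGT")
  expect_equal(res$pairs$allele_b, "ACGT")
  expect_equal(res$confidence, 1)
})

test_that("compatible_pairs matches the brute-force oracle on random template sets", {
  set.seed(314)
  for (rep in 1:30) {
    S <- sample(3:6, 1)
    templates <- unique(replicate(sample(3:7, 1),
      paste(sample(c("A", "C"), S, TRUE), collapse = "")))
    names(templates) <- paste0("T", seq_along(templates))
    ct <- toy_catalogue(templates)
    pick <- sample(templates, 2, replace = TRUE)
    g <- merge_alleles(pick[1], pick[2])
    got <- compatible_pairs(g, ct)
    oracle <- brute_force_pairs(g, unname(templates))
    expect_equal(nrow(got), length(oracle))
    if (length(oracle)) {
      expect_equal(got$allele_a, vapply(oracle, `[`, "", 1))
      expect_equal(got$allele_b, vapply(oracle, `[`, "", 2))
    }
  }
})

test_that("an ambiguous genotype returns every explaining pair", {
  ## AC/CA and AA/CC both explain the het-het genotype {A,C}{A,C}
  ct <- toy_catalogue(c(a = "AC", b = "CA", c = "AA", d = "CC"))
  res <- compatible_pairs(merge_alleles("AC", "CA"), ct)
  expect_equal(nrow(res), 2)
  expect_setequal(paste(res$allele_a, res$allele_b),
                  c("AC CA", "AA CC"))
})

test_that("pair scores follow the two-tier weights and normalize", {
  ## a single observed x predicted pair: score = 1 * posterior
  ct <- toy_catalogue(c(X = "AAAA"), predicted = c("CCAA", "AACC"),
                      posterior = c(0.8, 0.2))
  g <- merge_alleles("AAAA", "CCAA")
  res <- phase_genotype(g, ct)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$score, 0.8)
  expect_equal(res$confidence, 1)

  ## two pairs, both observed: equal scores, confidence 0.5
  ct2 <- toy_catalogue(c(a = "AC", b = "CA", c = "AA", d = "CC"))
  r2 <- phase_genotype(merge_alleles("AC", "CA"), ct2)
  expect_equal(nrow(r2$pairs), 2)
  expect_equal(r2$pairs$score, c(1, 1))
  expect_equal(r2$confidence, 0.5)
  expect_equal(sum(r2$pairs$normalized), 1)

  ## observed x pred(.8) vs observed x pred(.2): confidence .8
  ct3 <- toy_catalogue(c(X = "AA", Y = "AC"), predicted = c("CA", "CC"),
                       posterior = c(0.8, 0.2))
  r3 <- phase_genotype(merge_alleles("AA", "CC"), ct3)
  expect_equal(nrow(r3$pairs), 2)
  expect_equal(r3$confidence, 0.8 / (0.8 + 0.2))
})

test_that("scoring a pair with an allele outside the catalogue is a contract violation", {
  ct <- toy_catalogue(c(X = "AA"))
  pairs <- tibble::tibble(allele_a = "AA", allele_b = "GG",
                          label_a = "X", label_b = "?",
                          status_a = "observed", status_b = "observed")
  expect_error(score_pairs(pairs, ct), "absent")
})

test_that("confidence is invariant to catalogue order and to irrelevant additions", {
  ct <- toy_catalogue(c(X = "AA", Y = "AC"), predicted = c("CA", "CC"),
                      posterior = c(0.8, 0.2))
  ct_rev <- toy_catalogue(c(Y = "AC", X = "AA"), predicted = c("CC", "CA"),
                          posterior = c(0.2, 0.8))
  g <- merge_alleles("AA", "CC")
  expect_equal(phase_genotype(g, ct)$confidence,
               phase_genotype(g, ct_rev)$confidence)
  ## adding an irrelevant template never removes a compatible pair
  before <- compatible_pairs(g, ct)
  ct_plus <- update_catalogue(ct, "GG", label = "Z")
  after <- compatible_pairs(g, ct_plus)
  expect_true(all(paste(before$allele_a, before$allele_b) %in%
                    paste(after$allele_a, after$allele_b)))
})

test_that("merge-then-phase ranks the true pair first when it is the unique explanation", {
  set.seed(2718)
  ok <- 0L
  for (rep in 1:100) {
    S <- 8
    templates <- unique(replicate(6, paste(sample(c("A", "C", "G", "T"), S,
                                                  TRUE), collapse = "")))
    names(templates) <- paste0("T", seq_along(templates))
    ct <- toy_catalogue(templates)
    pick <- sample(templates, 2)
    g <- merge_alleles(pick[1], pick[2])
    res <- phase_genotype(g, ct)
    oracle <- brute_force_pairs(g, unname(templates))
    if (length(oracle) == 1) {
      ok <- ok + 1L
      expect_equal(sort(c(res$pairs$allele_a[1], res$pairs$allele_b[1])),
                   sort(unname(pick)))
    }
  }
  expect_gt(ok, 50)  # most random fixtures are uniquely explained
})

test_that("flag_novel finds the complement implied by a partial match", {
  ## X in catalogue; Z = one substitution away from catalogue allele Y
  X <- "AAAAA"; Y <- "CCAAA"; Z <- "CCCAA"
  ct <- toy_catalogue(c(X = X, Y = Y))
  g <- merge_alleles(X, Z)
  res <- phase_genotype(g, ct)
  expect_equal(nrow(res$pairs), 0)
  nov <- res$novel_candidates
  ## both templates are compatible, so both forced complements are
  ## candidates; Z must be among them, at distance 1 from Y via partner X
  z <- nov[nov$states == Z, ]
  expect_equal(nrow(z), 1)
  expect_equal(z$partner, X)
  expect_equal(z$nearest, Y)
  expect_equal(z$distance, 1L)
  expect_true(all(nov$status == "novel"))
  expect_true(all(nov$distance == 1L))
})

test_that("a fully homozygous unknown allele is returned as the single novel candidate", {
  ct <- toy_catalogue(c(X = "AAAA", Y = "CCCC"))
  nov <- flag_novel(merge_alleles("AACC", "AACC"), ct)
  expect_equal(nov$states, "AACC")
  expect_equal(nov$distance, 2L)
})

test_that("a genotype conflicting with every template at most het sites warns empty", {
  ct <- toy_catalogue(c(X = "AAAA"))
  ## het at 4 sites {C,G}: X incompatible at all 4
  g <- genotype("CCCC", "GGGG")
  expect_warning(nov <- flag_novel(g, ct), "50%")
  expect_equal(nrow(nov), 0)
})

test_that("flag_novel -> update_catalogue -> phase closes the loop", {
  X <- "AAAAA"; Y <- "CCAAA"; Z <- "CCCAA"
  ct <- toy_catalogue(c(X = X, Y = Y))
  g <- merge_alleles(X, Z)
  expect_equal(nrow(compatible_pairs(g, ct)), 0)
  nov <- flag_novel(g, ct)
  expect_true(Z %in% nov$states)
  ct2 <- update_catalogue(ct, Z, label = "Znew")
  res <- phase_genotype(g, ct2)
  expect_equal(nrow(res$pairs), 1)
  expect_setequal(c(res$pairs$allele_a, res$pairs$allele_b), c(X, Z))
  expect_equal(res$confidence, 1)
})

test_that("missing sites constrain nothing", {
  ct <- toy_catalogue(c(X = "AAAA", Y = "ACAA"))
  g <- genotype("NAAA", "NCAA")   # site 1 missing, site 2 het A/C
  res <- compatible_pairs(g, ct)
  expect_equal(nrow(res), 1)
  expect_setequal(c(res$allele_a, res$allele_b), c("AAAA", "ACAA"))
  ## oracle agrees
  oracle <- brute_force_pairs(g, c("AAAA", "ACAA"))
  expect_equal(length(oracle), 1)
})

test_that("genotype TSV reader assembles per-sample genotypes in site order", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "g.tsv")
  df <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                   site_position = c(10L, 20L, 10L, 20L),
                   state1 = c("A", "C", "G", "G"),
                   state2 = c("A", "T", "G", "G"))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  gts <- read_genotypes_tsv(p, site_positions = c(10L, 20L, 30L))
  expect_length(gts, 2)
  expect_equal(gts$s1$a1, c("A", "C", "N"))
  expect_equal(gts$s1$a2, c("A", "T", "N"))
  expect_equal(gts$s2$a1, c("G", "G", "N"))
})
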