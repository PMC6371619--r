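#' Write posterior tree samples as a NEXUS trees block
#'
#' @param fit An `allele_mcmc` fit.
#' @param path Output path.
#' @param max_trees Optional cap (evenly thinned) to keep files small.
#' @return `path`, invisibly.
#' @export
write_tree_samples <- function(fit, path, max_trees = NULL) {
  ss <- fit$samples
  if (!is.null(max_trees) && length(ss) > max_trees) {
    ss <- ss[unique(round(seq(1, length(ss), length.out = max_trees)))]
  }
  trees <- lapply(ss, function(s) as.phylo.timetree(s$tree))
  class(trees) <- "multiPhylo"
  names(trees) <- sprintf("STATE_%d_%d", vapply(ss, `[[`, 0, "chain"),
                          vapply(ss, `[[`, 0, "generation"))
  ape::write.nexus(trees, file = path, translate = TRUE)
  invisible(path)
}

#' Write the scalar trace as TSV
#'
#' @param fit An `allele_mcmc` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the MCC tree as annotated Newick
#'
#' Branch lengths in time units; internal nodes labelled with bracketed
#' comments carrying clade support and height.
#'
#' @param mcc MCC [timetree] from [mcc_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcc_tree <- function(mcc, path) {
  kids <- tt_children(mcc)
  rec <- function(node) {
    if (node <= mcc$ntip) {
      lab <- mcc$tip_label[node]
    } else {
      lab <- paste0("(", paste(vapply(kids[[node]], rec, ""), collapse = ","),
                    ")", sprintf("[&support=%.4g,height=%.6g]",
                                 mcc$clade_support[node], mcc$heights[node]))
    }
    p <- mcc$parent[node]
    if (p == 0L) return(paste0(lab, ";"))
    paste0(lab, ":", format(mcc$heights[p] - mcc$heights[node], digits = 10))
  }
  writeLines(rec(tt_root(mcc)), path)
  invisible(path)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full allele-prediction pipeline
#'
#' Executes extract (or simulate) -> infer -> mcc -> ancestors -> catalogue
#' (and optionally phase) and writes every stage's output under
#' `config$out`. All randomness flows from `config$seed`. Rerunning an
#' identical config and seed reproduces every output byte-for-byte (the
#' manifest's timestamp aside).
#'
#' Config keys (YAML file or list): `seed`; `out`; input as either `fasta`
#' (+ `reference`, `outgroup`) or `simulate` (preset parameters `n_alleles`,
#' `seq_length`, `target_variants`); `mcmc` (`chain_length`, `sample_every`,
#' `n_chains`, `burn_in_fraction`); `threshold` (catalogue floor, default
#' 0.1); `support_floor` (node labels, default 0.5); optional `genotypes`
#' (TSV path to phase).
#'
#' @param config A YAML file path or a named list.
#' @return A `run_manifest`: tibble of stages and outputs, plus seed,
#'   config hash and timestamps as attributes.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  out <- config$out %||% stop("config$out required", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out")])
  log_path <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                       sprintf(...)),
                               file = log_path, append = TRUE)
  cat(sprintf("phyloallele %s | seed %d | config %s\n",
              as.character(utils::packageVersion("phyloallele")), seed, cfg_hash),
      file = log_path)

  stages <- list()
  done <- function(stage, ...) {
    paths <- c(...)
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, output = unname(paths), exists = file.exists(paths))
    logline("stage %s: %s", stage, paste(basename(paths), collapse = ", "))
  }
  fail_manifest <- function(stage, msg) {
    mf <- dplyr::bind_rows(stages)
    attr(mf, "failed_stage") <- stage
    stop(sprintf("pipeline failed at stage '%s': %s", stage, msg), call. = FALSE)
  }

  ## -- input: simulate or load ----------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    fx <- make_study_fixture(
      seed = seed, n_alleles = sim$n_alleles %||% 48,
      seq_length = sim$seq_length %||% 21406,
      target_variants = sim$target_variants %||% 72)
    aln <- fx$alignment
    fasta <- file.path(out, "alignment.fasta")
    write_alignment(aln, fasta)
    truth_nwk <- file.path(out, "truth.nwk")
    writeLines(timetree_newick(fx$truth$tree), truth_nwk)
    truth_tsv <- file.path(out, "truth_ancestors.tsv")
    utils::write.table(
      tibble::tibble(clade = names(fx$ancestral_states),
                     states = unname(fx$ancestral_states)),
      truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    done("simulate", fasta = fasta, truth = truth_nwk, ancestors = truth_tsv)
    vm <- fx$matrix
    reference <- vm$reference
  } else {
    reference <- config$reference
    res <- tryCatch(load_alignment(config$fasta, outgroup = config$outgroup),
                    error = function(e) e)
    if (inherits(res, "error")) fail_manifest("extract", conditionMessage(res))
    aln <- res
    vm <- extract_variant_sites(aln, reference = reference)
    reference <- vm$reference
  }
  mpaths <- write_variant_matrix(vm, file.path(out, "variants"),
                                 locus = config$locus %||% "locus")
  done("extract", mpaths)

  ## -- infer ----------------------------------------------------------------
  mc <- config$mcmc %||% list()
  cfg <- mcmc_config(chain_length = mc$chain_length %||% 200000,
                     sample_every = mc$sample_every %||% 200,
                     burn_in_fraction = mc$burn_in_fraction %||% 0.1,
                     seed = seed, n_chains = mc$n_chains %||% 4)
  fit <- run_mcmc(vm, cfg)
  trace_path <- file.path(out, "trace.tsv")
  write_trace(fit, trace_path)
  trees_path <- file.path(out, "trees.nexus")
  write_tree_samples(fit, trees_path, max_trees = mc$max_trees_out %||% 500)
  done("infer", trace = trace_path, trees = trees_path)

  ## -- mcc ------------------------------------------------------------------
  mcc <- mcc_tree(fit)
  mcc_path <- file.path(out, "mcc.nwk")
  write_mcc_tree(mcc, mcc_path)
  done("mcc", mcc_path)

  ## -- ancestors + catalogue ------------------------------------------------
  set.seed(seed + 10000L)
  tal <- tally_node_alleles(fit, vm, mcc)
  labels <- label_mcc_nodes(mcc, config$support_floor %||% 0.5)
  obs <- observed_alleles(vm)
  cat_all <- build_catalogue(tal, obs, threshold = config$threshold %||% 0.1,
                             node_labels = labels,
                             reference_states = obs[[reference]],
                             taxa = sort(names(obs)))
  tal_path <- file.path(out, "tallies.tsv")
  utils::write.table(tal, tal_path, sep = "\t", quote = FALSE, row.names = FALSE)
  done("ancestors", tal_path)
  cat_path <- file.path(out, "catalogue.tsv")
  write_catalogue(cat_all, cat_path)
  rep_path <- file.path(out, "node_report.tsv")
  utils::write.table(node_report(cat_all), rep_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  done("catalogue", catalogue = cat_path, report = rep_path)

  ## -- phase (optional) -----------------------------------------------------
  if (!is.null(config$genotypes)) {
    gts <- read_genotypes_tsv(config$genotypes, vm$site_positions)
    results <- lapply(gts, phase_genotype, catalogue = cat_all)
    ph_path <- file.path(out, "phasing.tsv")
    write_phasing_report(results, ph_path)
    done("phase", ph_path)
  }

  manifest <- dplyr::bind_rows(stages)
  attr(manifest, "seed") <- seed
  attr(manifest, "config_hash") <- cfg_hash
  attr(manifest, "version") <- as.character(utils::packageVersion("phyloallele"))
  attr(manifest, "started") <- t0
  attr(manifest, "finished") <- Sys.time()
  class(manifest) <- c("run_manifest", class(manifest))
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
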