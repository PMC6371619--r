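#' Published ERMAP node alleles at the 72 SNP positions
#'
#' The curated table of best ancestral alleles at the labelled internal
#' nodes of the 48-allele ERMAP (Scianna blood group) phylogeny: each row is
#' a node with its allele name, states at the 72 variant positions in dash
#' notation relative to the reference allele `Allele1` (GenBank KX265235,
#' states shown 5'-to-3'), the allele's posterior probability at that node,
#' and whether it matches an observed allele. Shipped as a worked real-data
#' example and for exact desk checks of the string operations.
#'
#' @return A tibble: node, allele, dash, states (decoded), posterior,
#'   status, genbank.
#' @export
ermap_node_table <- function() {
  path <- system.file("extdata", "ermap_nodes.tsv", package = "phyloallele")
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character")
  ref <- ermap_reference_states()
  tibble::as_tibble(df) |>
    dplyr::mutate(posterior = as.numeric(.data$posterior),
                  states = vapply(.data$dash, decode_variant_string, "",
                                  reference = ref, USE.NAMES = FALSE))
}

#' Reference allele states (Allele1) over the 72 ERMAP SNP positions
#'
#' @return A 72-character states string.
#' @export
ermap_reference_states <- function() {
  "ATTGGCACCAGGCCGCCGCCCTGCTTAAGCCCTGGCGTGGTACTCGTCACGGTCCGCCGGGGCCGGATTAAA"
}

#' ERMAP alignment bookkeeping constants
#'
#' The full-length alignment behind the published ERMAP allele set: 48
#' alleles of 21,406 aligned nucleotides with 72 variable sites.
#'
#' @return A list: n_alleles, alignment_length, n_variant_sites.
#' @export
ermap_study_dimensions <- function() {
  list(n_alleles = 48L, alignment_length = 21406L, n_variant_sites = 72L)
}
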