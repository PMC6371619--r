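#' Aligned allele sets
#'
#' Construct the container for a pre-aligned set of same-locus allele
#' sequences. Sequences are upper-cased and validated: equal lengths, unique
#' names, nucleotides in `A,C,G,T` (gap `-` permitted only in columns where
#' every allele is gapped, which are dropped). IUPAC ambiguity codes are
#' rejected: the downstream model is defined over unambiguous states.
#'
#' @param names Character vector of allele identifiers.
#' @param sequences Character vector of equal-length nucleotide strings.
#' @param outgroup Optional identifier of the outgroup allele.
#' @param population Optional per-allele population label.
#' @return An object of class `aligned_alleles` with fields `names`,
#'   `sequences`, `length`, `outgroup`, `population`.
#' @export
aligned_alleles <- function(names, sequences, outgroup = NULL, population = NULL) {
  stopifnot(length(names) == length(sequences))
  if (length(names) < 2L) stop("need at least 2 records", call. = FALSE)
  if (anyDuplicated(names)) stop("duplicate allele names", call. = FALSE)
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("alignment error: sequences have unequal lengths", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- !(mat %in% c("A", "C", "G", "T", "-"))
  if (any(bad)) {
    stop(sprintf("unsupported character(s) in sequences: %s (IUPAC ambiguity codes are not supported)",
                 paste(unique(mat[bad]), collapse = ",")), call. = FALSE)
  }
  gap_cols <- colSums(mat == "-") > 0L
  if (any(gap_cols)) {
    shared <- colSums(mat == "-") == nrow(mat)
    if (!all(shared[gap_cols])) {
      stop("gaps present in a subset of alleles; only all-row gap columns are supported",
           call. = FALSE)
    }
    mat <- mat[, !gap_cols, drop = FALSE]
    sequences <- apply(mat, 1L, paste, collapse = "")
    len <- ncol(mat)
  }
  if (!is.null(outgroup) && !outgroup %in% names) {
    stop("outgroup name not found among alleles", call. = FALSE)
  }
  structure(
    list(names = names, sequences = unname(sequences), length = as.integer(len),
         outgroup = outgroup, population = population),
    class = "aligned_alleles"
  )
}

#' @export
print.aligned_alleles <- function(x, ...) {
  cat(sprintf("<aligned_alleles> %d alleles x %d columns%s\n", length(x$names),
              x$length,
              if (is.null(x$outgroup)) "" else paste0(", outgroup ", x$outgroup)))
  invisible(x)
}

#' Read an aligned multi-FASTA of allele sequences
#'
#' @param path Path to an aligned FASTA file (2+ records, equal lengths).
#' @param outgroup Optional record name flagged as the outgroup.
#' @return An [aligned_alleles] object.
#' @export
load_alignment <- function(path, outgroup = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- tryCatch(ape::read.FASTA(path),
                  error = function(e) stop("could not parse FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dna) < 2L) stop("need at least 2 FASTA records", call. = FALSE)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  aligned_alleles(names(dna), seqs, outgroup = outgroup)
}

#' Write an aligned allele set as FASTA
#'
#' @param aln An [aligned_alleles] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$names), aln$sequences))
  writeLines(lines, path)
  invisible(path)
}

seq_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$names
  m
}

#' Extract variable columns into a variant matrix
#'
#' Scans every alignment column and keeps those with at least two distinct
#' states among the counted alleles. By default the outgroup does not create
#' variant sites on its own (variability is assessed among the ingroup), but
#' its states at the retained columns are carried along for rooting.
#'
#' @param aln An [aligned_alleles] object.
#' @param reference Name of the allele used as reference for dash encoding.
#'   Defaults to the first ingroup allele.
#' @param include_outgroup Logical; if `TRUE` the outgroup participates in
#'   the variability test.
#' @return A `variant_matrix`: list with `tbl` (tibble: allele, states,
#'   dash, outgroup flag), `site_positions` (1-based alignment columns),
#'   `reference`, `outgroup`, `alignment_length`.
#' @export
extract_variant_sites <- function(aln, reference = NULL,
                                  include_outgroup = FALSE) {
  m <- seq_matrix(aln)
  counted <- rep(TRUE, nrow(m))
  if (!is.null(aln$outgroup) && !include_outgroup) {
    counted[aln$names == aln$outgroup] <- FALSE
  }
  nstate <- apply(m[counted, , drop = FALSE], 2L, function(col) length(unique(col)))
  pos <- which(nstate >= 2L)
  if (is.null(reference)) {
    ing <- if (is.null(aln$outgroup)) aln$names else
      aln$names[aln$names != aln$outgroup]
    reference <- ing[1L]
  }
  if (!reference %in% aln$names) stop("reference allele not found", call. = FALSE)
  if (length(pos) == 0L) {
    warning("no variable sites in alignment; returning an empty variant matrix")
  }
  states <- apply(m[, pos, drop = FALSE], 1L, paste, collapse = "")
  if (length(pos) == 0L) states <- rep("", nrow(m))
  ref_states <- states[aln$names == reference]
  is_og <- if (is.null(aln$outgroup)) rep(FALSE, length(aln$names)) else
    aln$names == aln$outgroup
  tbl <- tibble::tibble(
    allele = aln$names,
    states = unname(states),
    dash = vapply(unname(states), encode_variant_string, "", reference = ref_states),
    is_outgroup = is_og
  )
  new_variant_matrix(tbl, as.integer(pos), reference, aln$outgroup, aln$length)
}

new_variant_matrix <- function(tbl, site_positions, reference, outgroup,
                               alignment_length = NA_integer_) {
  stopifnot(all(nchar(tbl$states) == length(site_positions)))
  structure(
    list(tbl = tbl, site_positions = site_positions, reference = reference,
         outgroup = outgroup, alignment_length = alignment_length),
    class = "variant_matrix"
  )
}

#' Build a variant matrix directly from variant-site strings
#'
#' Used when the full alignment is not at hand but the per-allele states at
#' the variant sites are (for example a published SNP table in dash
#' notation).
#'
#' @param allele Character vector of allele names.
#' @param states Character vector of equal-length state strings (`A,C,G,T`),
#'   or dash-notation strings if `reference_states` is given.
#' @param reference Name of the reference allele (must be in `allele`
#'   unless `reference_states` supplies its states directly).
#' @param reference_states Full states string of the reference allele, used
#'   to decode dash notation.
#' @param site_positions Optional 1-based alignment positions of the sites.
#' @param outgroup Optional outgroup allele name.
#' @param alignment_length Optional source alignment length (for invariant-
#'   fraction bookkeeping).
#' @return A `variant_matrix`.
#' @export
variant_matrix <- function(allele, states, reference,
                           reference_states = NULL, site_positions = NULL,
                           outgroup = NULL, alignment_length = NA_integer_) {
  stopifnot(length(allele) == length(states))
  if (anyDuplicated(allele)) stop("duplicate allele names", call. = FALSE)
  if (!is.null(reference_states)) {
    states <- vapply(states, function(s) {
      if (grepl("-", s, fixed = TRUE)) decode_variant_string(s, reference_states) else s
    }, "")
  }
  states <- toupper(unname(states))
  if (length(unique(nchar(states))) != 1L) {
    stop("states strings have unequal lengths", call. = FALSE)
  }
  if (!all(strsplit(paste(states, collapse = ""), "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("states must be over A,C,G,T", call. = FALSE)
  }
  if (!reference %in% allele) stop("reference allele not found", call. = FALSE)
  if (is.null(site_positions)) site_positions <- seq_len(nchar(states[1L]))
  ref_states <- states[allele == reference]
  is_og <- if (is.null(outgroup)) rep(FALSE, length(allele)) else allele == outgroup
  tbl <- tibble::tibble(
    allele = allele, states = states,
    dash = vapply(states, encode_variant_string, "", reference = ref_states),
    is_outgroup = is_og
  )
  new_variant_matrix(tbl, as.integer(site_positions), reference, outgroup,
                     alignment_length)
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d alleles x %d sites (reference %s)\n",
              nrow(x$tbl), length(x$site_positions), x$reference))
  print(x$tbl, n = 5)
  invisible(x)
}

#' @method as_tibble variant_matrix
#' @export
as_tibble.variant_matrix <- function(x, ...) x$tbl

n_sites <- function(matrix) length(matrix$site_positions)

vm_ingroup <- function(matrix) dplyr::filter(matrix$tbl, !.data$is_outgroup)

vm_states <- function(matrix, allele) {
  matrix$tbl$states[match(allele, matrix$tbl$allele)]
}

## character matrix (alleles x sites) of states
vm_char_matrix <- function(matrix) {
  m <- do.call(rbind, strsplit(matrix$tbl$states, "", fixed = TRUE))
  rownames(m) <- matrix$tbl$allele
  m
}

#' Fraction of invariant alignment columns
#'
#' @param matrix A `variant_matrix` whose `alignment_length` is known, or a
#'   number of variant sites together with `alignment_length`.
#' @param alignment_length Total alignment columns (overrides the matrix
#'   field if given).
#' @return Proportion of invariant columns, in `[0, 1]`.
#' @export
invariant_fraction <- function(matrix, alignment_length = NULL) {
  nv <- if (inherits(matrix, "variant_matrix")) n_sites(matrix) else as.numeric(matrix)
  len <- alignment_length %||%
    (if (inherits(matrix, "variant_matrix")) matrix$alignment_length else NULL)
  if (is.null(len) || is.na(len)) stop("alignment length unknown", call. = FALSE)
  (len - nv) / len
}

#' Encode an allele relative to a reference in dash notation
#'
#' Position `i` is `-` when the allele matches the reference there, else the
#' allele's nucleotide.
#'
#' @param states Allele states string.
#' @param reference Reference states string of equal length.
#' @return Dash-notation string.
#' @export
encode_variant_string <- function(states, reference) {
  a <- strsplit(states, "", fixed = TRUE)[[1]]
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (length(a) != length(r)) stop("length mismatch", call. = FALSE)
  paste(ifelse(a == r, "-", a), collapse = "")
}

#' Decode a dash-notation string against a reference
#'
#' @param encoded Dash-notation string over `-,A,C,G,T`.
#' @param reference Reference states string of equal length.
#' @return Full states string.
#' @export
decode_variant_string <- function(encoded, reference) {
  e <- strsplit(encoded, "", fixed = TRUE)[[1]]
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (length(e) != length(r)) stop("length mismatch", call. = FALSE)
  bad <- !(e %in% c("-", "A", "C", "G", "T"))
  if (any(bad)) {
    stop("illegal character(s) in encoded string: ",
         paste(unique(e[bad]), collapse = ","), call. = FALSE)
  }
  paste(ifelse(e == "-", r, e), collapse = "")
}

#' Hamming distance between two equal-length allele strings
#'
#' @param a,b States strings of equal length.
#' @return Count of mismatching positions.
#' @export
hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  sum(x != y)
}

#' Write a variant matrix as TSV and a VCF-like site table
#'
#' The TSV has one row per allele (allele, dash notation, site_1..site_N);
#' the site table is one row per variant site (locus, position, REF, ALT,
#' haploid calls per allele).
#'
#' @param matrix A `variant_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.matrix.tsv` and
#'   `<prefix>.sites.tsv`.
#' @param locus Locus name for the site table.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_variant_matrix <- function(matrix, prefix, locus = "locus") {
  chs <- vm_char_matrix(matrix)
  wide <- tibble::as_tibble(chs, .name_repair = ~ paste0("site_", matrix$site_positions))
  out1 <- dplyr::bind_cols(
    tibble::tibble(allele = matrix$tbl$allele, dash = matrix$tbl$dash), wide)
  p1 <- paste0(prefix, ".matrix.tsv")
  utils::write.table(out1, p1, sep = "\t", quote = FALSE, row.names = FALSE)

  ref_row <- chs[matrix$reference, , drop = TRUE]
  sites <- purrr::map_dfr(seq_len(n_sites(matrix)), function(j) {
    col <- chs[, j]
    alt <- setdiff(unique(col), ref_row[j])
    tibble::tibble(
      CHROM = locus, POS = matrix$site_positions[j], REF = ref_row[j],
      ALT = paste(sort(alt), collapse = ","),
      !!!stats::setNames(as.list(col), rownames(chs)))
  })
  p2 <- paste0(prefix, ".sites.tsv")
  utils::write.table(sites, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = p1, sites = p2))
}

#' Read back a variant matrix written by [write_variant_matrix()]
#'
#' @param path Path to a `*.matrix.tsv` file.
#' @param reference Reference allele name (defaults to the first row).
#' @param outgroup Optional outgroup allele name.
#' @return A `variant_matrix`.
#' @export
read_variant_matrix <- function(path, reference = NULL, outgroup = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  site_cols <- grep("^site_", names(df), value = TRUE)
  pos <- as.integer(sub("^site_", "", site_cols))
  states <- apply(df[, site_cols, drop = FALSE], 1L, paste, collapse = "")
  variant_matrix(df$allele, states, reference %||% df$allele[1L],
                 site_positions = pos, outgroup = outgroup)
}
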