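#' Diploid genotypes over the variant sites
#'
#' A genotype is a per-site unordered pair of states. `genotype()` builds
#' one from two haplotype strings (the merge of two alleles); missing sites
#' may be encoded `N` in both strings and constrain nothing.
#'
#' @param h1,h2 Equal-length states strings over `A,C,G,T,N`.
#' @param sample_id Identifier.
#' @return An object of class `genotype`: list with `a1`, `a2` (site-wise
#'   sorted state vectors) and `sample_id`.
#' @export
genotype <- function(h1, h2, sample_id = "sample") {
  x <- strsplit(toupper(h1), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(h2), "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("haplotype length mismatch", call. = FALSE)
  ok <- c("A", "C", "G", "T", "N")
  if (!all(x %in% ok) || !all(y %in% ok)) {
    stop("genotype states must be A,C,G,T (or N for missing)", call. = FALSE)
  }
  if (any(xor(x == "N", y == "N"))) {
    stop("a missing site must be missing on both haplotypes", call. = FALSE)
  }
  structure(list(a1 = pmin(x, y), a2 = pmax(x, y), sample_id = sample_id),
            class = "genotype")
}

#' Merge two allele strings into an unphased genotype
#'
#' @param a,b Allele states strings.
#' @param sample_id Identifier.
#' @return A [genotype].
#' @export
merge_alleles <- function(a, b, sample_id = "sample") genotype(a, b, sample_id)

#' @export
print.genotype <- function(x, ...) {
  het <- sum(x$a1 != x$a2)
  cat(sprintf("<genotype> %s: %d sites, %d heterozygous\n", x$sample_id,
              length(x$a1), het))
  invisible(x)
}

gt_missing <- function(g) g$a1 == "N"
gt_het <- function(g) g$a1 != g$a2 & !gt_missing(g)

## site-wise complement of template `a` under genotype g, or NA if a is
## incompatible at some (non-missing) site
complement_allele <- function(a, g) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  miss <- gt_missing(g)
  comp <- ifelse(miss, x, ifelse(x == g$a1, g$a2,
                          ifelse(x == g$a2, g$a1, NA_character_)))
  if (anyNA(comp)) return(NA_character_)
  paste(comp, collapse = "")
}

template_incompatible_sites <- function(a, g) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  sum(!gt_missing(g) & x != g$a1 & x != g$a2)
}

#' All template pairs compatible with a genotype
#'
#' A pair `(a, b)` is compatible when at every (non-missing) site the
#' unordered pair of its states equals the genotype's pair. The search is
#' exhaustive over the template set but linear in it: each template forces
#' its complement site-wise, which is then looked up.
#'
#' @param g A [genotype].
#' @param catalogue An `allele_catalogue` (templates = observed alleles plus
#'   predicted entries), or a tibble from [catalogue_templates()].
#' @return A tibble: allele_a, allele_b (states, `allele_a <= allele_b`
#'   lexicographically), label_a, label_b, status_a, status_b.
#' @export
compatible_pairs <- function(g, catalogue) {
  tpl <- if (inherits(catalogue, "allele_catalogue")) {
    catalogue_templates(catalogue)
  } else catalogue
  if (!nrow(tpl)) return(empty_pairs())
  if (nchar(tpl$states[1L]) != length(g$a1)) stop("length mismatch", call. = FALSE)
  out <- list()
  if (any(gt_missing(g))) {
    ## missing sites leave the partner unconstrained there, so the forced-
    ## complement lookup does not apply; test pairs directly
    miss <- gt_missing(g)
    chars <- strsplit(tpl$states, "", fixed = TRUE)
    for (i in seq_len(nrow(tpl))) for (j in i:nrow(tpl))  {
      lo <- pmin(chars[[i]], chars[[j]]); hi <- pmax(chars[[i]], chars[[j]])
      if (all(miss | (lo == g$a1 & hi == g$a2))) {
        a <- min(tpl$states[i], tpl$states[j])
        b <- max(tpl$states[i], tpl$states[j])
        out[[paste(a, b)]] <- c(which(tpl$states == a)[1L],
                                which(tpl$states == b)[1L])
      }
    }
  } else {
    idx <- stats::setNames(seq_len(nrow(tpl)), tpl$states)
    for (i in seq_len(nrow(tpl))) {
      comp <- complement_allele(tpl$states[i], g)
      if (is.na(comp)) next
      j <- idx[comp]
      if (is.na(j)) next
      a <- min(tpl$states[i], comp); b <- max(tpl$states[i], comp)
      out[[paste(a, b)]] <- c(which(tpl$states == a)[1L],
                              which(tpl$states == b)[1L])
    }
  }
  if (!length(out)) return(empty_pairs())
  purrr::map_dfr(out, function(ij) {
    tibble::tibble(allele_a = tpl$states[ij[1L]], allele_b = tpl$states[ij[2L]],
                   label_a = tpl$label[ij[1L]], label_b = tpl$label[ij[2L]],
                   status_a = tpl$status[ij[1L]], status_b = tpl$status[ij[2L]])
  }) |>
    dplyr::arrange(.data$allele_a, .data$allele_b)
}

empty_pairs <- function() {
  tibble::tibble(allele_a = character(), allele_b = character(),
                 label_a = character(), label_b = character(),
                 status_a = character(), status_b = character())
}

#' Score compatible pairs and normalize into a phasing confidence
#'
#' Pair score is `w(a) * w(b)` with `w = 1` for observed (experimentally
#' confirmed) alleles and `w =` catalogue posterior for predicted alleles;
#' the confidence of the top pair is its score over the sum of all pair
#' scores. Deterministic ordering: score descending, then `allele_a`,
#' `allele_b`.
#'
#' @param pairs Tibble from [compatible_pairs()].
#' @param catalogue The `allele_catalogue` the pairs came from.
#' @param g Optional [genotype] (carried into the result).
#' @return An object of class `phasing_result`: list with `pairs` (tibble
#'   adding score, normalized score), `confidence`, `sample_id`.
#' @export
score_pairs <- function(pairs, catalogue, g = NULL) {
  tpl <- catalogue_templates(catalogue)
  w <- stats::setNames(tpl$weight, tpl$states)
  if (nrow(pairs)) {
    missing <- setdiff(c(pairs$allele_a, pairs$allele_b), names(w))
    if (length(missing)) {
      stop("pair contains allele(s) absent from the catalogue", call. = FALSE)
    }
  }
  scored <- pairs |>
    dplyr::mutate(score = unname(w[.data$allele_a]) * unname(w[.data$allele_b])) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$allele_a, .data$allele_b) |>
    dplyr::mutate(normalized = .data$score / sum(.data$score))
  structure(
    list(pairs = scored,
         confidence = if (nrow(scored)) scored$normalized[1L] else 0,
         sample_id = if (is.null(g)) NA_character_ else g$sample_id),
    class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("<phasing_result> %s: %d compatible pair(s), confidence %.3f\n",
              x$sample_id, nrow(x$pairs), x$confidence))
  if (nrow(x$pairs)) print(x$pairs, n = 5)
  invisible(x)
}

#' Tidy phasing result
#'
#' @param x A `phasing_result`.
#' @param ... Unused.
#' @return The ranked pair tibble with sample_id attached.
#' @method tidy phasing_result
#' @export
tidy.phasing_result <- function(x, ...) {
  dplyr::mutate(x$pairs, sample_id = x$sample_id, rank = dplyr::row_number())
}

#' Phase one genotype against the catalogue
#'
#' Convenience wrapper: [compatible_pairs()] then [score_pairs()]; when no
#' pair exists, novel-allele candidates are attached via [flag_novel()].
#'
#' @param g A [genotype].
#' @param catalogue An `allele_catalogue`.
#' @param max_novel Novel candidates to report when unphaseable.
#' @return A `phasing_result` (with a `novel_candidates` tibble field).
#' @export
phase_genotype <- function(g, catalogue, max_novel = 5) {
  res <- score_pairs(compatible_pairs(g, catalogue), catalogue, g)
  res$novel_candidates <- if (nrow(res$pairs)) empty_novel() else
    flag_novel(g, catalogue, max_results = max_novel)
  res
}

empty_novel <- function() {
  tibble::tibble(states = character(), partner = character(),
                 nearest = character(), distance = integer(),
                 status = character())
}

#' Candidate novel alleles implied by an unphaseable genotype
#'
#' For every catalogue template compatible with the genotype, the site-wise
#' forced complement is computed; complements absent from the catalogue are
#' candidate novel alleles, ranked by Hamming distance to their nearest
#' catalogue entry. A fully homozygous genotype implies a single allele,
#' returned directly when absent from the catalogue. When every template
#' conflicts with the genotype at more than half of its heterozygous sites,
#' no candidate is trustworthy: an empty set is returned with a warning.
#'
#' @param g A [genotype].
#' @param catalogue An `allele_catalogue`.
#' @param max_results Maximum candidates returned.
#' @return A tibble: states, partner (the compatible template), nearest
#'   (closest catalogue allele), distance, status (`"novel"`).
#' @export
flag_novel <- function(g, catalogue, max_results = 5) {
  tpl <- catalogue_templates(catalogue)
  n_het <- sum(gt_het(g))
  if (n_het == 0L) {
    implied <- paste(ifelse(gt_missing(g), "N", g$a1), collapse = "")
    if (implied %in% tpl$states) return(empty_novel())
    nn <- nearest_catalogue(implied, tpl$states)
    return(tibble::tibble(states = implied, partner = implied,
                          nearest = nn$states, distance = nn$distance,
                          status = "novel"))
  }
  incompat <- vapply(tpl$states, template_incompatible_sites, 0L, g = g)
  if (min(incompat) > 0L) {
    if (min(incompat) / n_het > 0.5) {
      warning("genotype conflicts with every catalogue allele at >50% of heterozygous sites")
    }
    return(empty_novel())
  }
  cand <- list()
  for (i in which(incompat == 0L)) {
    comp <- complement_allele(tpl$states[i], g)
    if (comp %in% tpl$states) next
    if (!is.null(cand[[comp]])) next
    nn <- nearest_catalogue(comp, tpl$states)
    cand[[comp]] <- tibble::tibble(states = comp, partner = tpl$states[i],
                                   nearest = nn$states,
                                   distance = nn$distance, status = "novel")
  }
  if (!length(cand)) return(empty_novel())
  dplyr::bind_rows(cand) |>
    dplyr::arrange(.data$distance, .data$states) |>
    utils::head(max_results)
}

nearest_catalogue <- function(states, templates) {
  d <- vapply(templates, hamming, 0, b = states)
  i <- which(d == min(d))
  i <- i[order(templates[i])][1L]
  list(states = templates[i], distance = as.integer(d[i]))
}

#' Read genotypes from a long TSV
#'
#' Expected columns: sample_id, site_position, state1, state2 (one row per
#' variant site per sample). Site positions must match the variant matrix's.
#'
#' @param path TSV path.
#' @param site_positions The variant matrix's site positions (defines site
#'   order; absent sites become missing `N`).
#' @return A named list of [genotype] objects.
#' @export
read_genotypes_tsv <- function(path, site_positions) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character"))
  split(df, df$sample_id) |>
    purrr::imap(function(d, id) {
      j <- match(site_positions, d$site_position)
      h1 <- ifelse(is.na(j), "N", d$state1[j])
      h2 <- ifelse(is.na(j), "N", d$state2[j])
      genotype(paste(h1, collapse = ""), paste(h2, collapse = ""), id)
    })
}

#' Write a phasing report TSV
#'
#' @param results A list of `phasing_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phasing_report <- function(results, path) {
  rows <- purrr::map_dfr(results, function(r) {
    if (nrow(r$pairs)) {
      dplyr::mutate(tidy(r), novel = "")
    } else {
      tibble::tibble(sample_id = r$sample_id, rank = NA_integer_,
                     novel = paste(r$novel_candidates$states, collapse = ";"))
    }
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
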