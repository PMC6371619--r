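#' Build the ranked catalogue of observed and predicted alleles
#'
#' Collects every tallied (allele, clade) pair with posterior at or above
#' `threshold`, marks each as `observed` (its states equal some input
#' allele's) or `predicted`, ranks entries within each clade by posterior,
#' and sorts the catalogue by posterior descending (ties by node label then
#' states). A deduplicated by-states view keeps each allele's maximum
#' posterior across clades.
#'
#' @param tallies Tibble from [tally_node_alleles()].
#' @param observed Named character vector of observed allele states
#'   (names are allele labels, e.g. from [observed_alleles()]).
#' @param threshold Posterior floor for inclusion (in `[0, 1)`).
#' @param node_labels Optional named vector clade key -> letter label (from
#'   [label_mcc_nodes()]).
#' @param reference_states Optional reference allele states for dash
#'   notation in reports.
#' @param taxa Optional canonical taxa vector for spelling out clades.
#' @return An object of class `allele_catalogue`.
#' @export
build_catalogue <- function(tallies, observed, threshold = 0,
                            node_labels = NULL, reference_states = NULL,
                            taxa = NULL) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)", call. = FALSE)
  if (length(observed) && is.null(names(observed))) {
    names(observed) <- paste0("obs", seq_along(observed))
  }
  entries <- tallies |>
    dplyr::filter(.data$posterior >= threshold) |>
    dplyr::group_by(.data$clade) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$states, .by_group = TRUE) |>
    dplyr::mutate(source_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      node_label = if (is.null(node_labels)) NA_character_
                   else unname(node_labels[.data$clade]),
      status = ifelse(.data$states %in% observed, "observed", "predicted"),
      matches_observed = names_of_match(.data$states, observed),
      dash = if (is.null(reference_states)) NA_character_
             else vapply(.data$states, encode_variant_string, "",
                         reference = reference_states)) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$node_label, .data$states) |>
    dplyr::select("node_label", "clade", "states", "dash", "posterior",
                  "status", "matches_observed", "source_rank",
                  "count", "n_clade_samples")
  structure(
    list(entries = entries, observed = observed, threshold = threshold,
         reference_states = reference_states, taxa = taxa),
    class = "allele_catalogue")
}

#' Deduplicated by-states view of a catalogue
#'
#' @param catalogue An `allele_catalogue`.
#' @return A tibble with one row per distinct allele: states, posterior
#'   (its maximum across clades), status, best clade/node.
#' @export
catalogue_by_states <- function(catalogue) {
  catalogue$entries |>
    dplyr::group_by(.data$states) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .by_group = TRUE) |>
    dplyr::summarise(
      posterior = .data$posterior[1L],
      status = .data$status[1L],
      node_label = .data$node_label[1L],
      clade = .data$clade[1L], .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$states)
}

#' Observed (input) alleles of a variant matrix
#'
#' @param matrix A `variant_matrix`.
#' @return Named character vector allele label -> states (ingroup only).
#' @export
observed_alleles <- function(matrix) {
  ing <- vm_ingroup(matrix)
  stats::setNames(ing$states, ing$allele)
}

#' Phasing templates of a catalogue
#'
#' The union of observed alleles and predicted entries, with the weight used
#' by [score_pairs()]: 1 for observed (experimentally confirmed) alleles,
#' the catalogue posterior (max across clades) for predicted ones.
#'
#' @param catalogue An `allele_catalogue`.
#' @return A tibble: label, states, status, weight.
#' @export
catalogue_templates <- function(catalogue) {
  by_states <- catalogue_by_states(catalogue)
  pred <- by_states |>
    dplyr::filter(!.data$states %in% catalogue$observed) |>
    dplyr::transmute(
      label = as.character(ifelse(is.na(.data$node_label),
                                  paste0("pred_", .data$states),
                                  paste0("pred_", .data$node_label))),
      states = .data$states, status = "predicted", weight = .data$posterior)
  obs <- tibble::tibble(label = names(catalogue$observed),
                        states = unname(catalogue$observed),
                        status = "observed", weight = 1)
  dplyr::bind_rows(obs, pred) |>
    dplyr::distinct(.data$states, .keep_all = TRUE)
}

#' @export
print.allele_catalogue <- function(x, ...) {
  by_states <- catalogue_by_states(x)
  cat(sprintf("<allele_catalogue> %d entries (%d distinct alleles, %d observed inputs), threshold %.3g\n",
              nrow(x$entries), nrow(by_states), length(x$observed), x$threshold))
  print(x$entries, n = 6)
  invisible(x)
}

#' Insert a newly confirmed allele into the catalogue
#'
#' The confirmed allele becomes an observed template with weight 1; if its
#' states match an existing predicted entry, that entry is promoted to
#' observed. Idempotent.
#'
#' @param catalogue An `allele_catalogue`.
#' @param confirmed States string of the confirmed allele.
#' @param label Optional allele label (default `new1`, `new2`, ...).
#' @return The updated `allele_catalogue`.
#' @export
update_catalogue <- function(catalogue, confirmed, label = NULL) {
  width <- if (length(catalogue$observed)) nchar(catalogue$observed[[1L]])
           else if (nrow(catalogue$entries)) nchar(catalogue$entries$states[1L])
           else NA_integer_
  if (!is.na(width) && nchar(confirmed) != width) {
    stop("confirmed allele has wrong length", call. = FALSE)
  }
  if (confirmed %in% catalogue$observed) return(catalogue)
  label <- label %||% paste0("new", sum(grepl("^new", names(catalogue$observed))) + 1L)
  catalogue$observed <- c(catalogue$observed, stats::setNames(confirmed, label))
  catalogue$entries <- catalogue$entries |>
    dplyr::mutate(
      status = ifelse(.data$states == confirmed, "observed", .data$status),
      matches_observed = ifelse(.data$states == confirmed, label,
                                .data$matches_observed))
  catalogue
}

#' Write a catalogue as TSV
#'
#' Columns: node_label, clade (semicolon-joined taxa when known), dash
#' notation, full states, posterior, status, cross-reference.
#'
#' @param catalogue An `allele_catalogue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  ent <- catalogue$entries
  clade_txt <- if (!is.null(catalogue$taxa)) {
    vapply(ent$clade, function(k)
      paste(clade_key_to_taxa(k, catalogue$taxa), collapse = ";"), "")
  } else ent$clade
  out <- tibble::tibble(
    node_label = ent$node_label, clade = clade_txt, dash = ent$dash,
    states = ent$states, posterior = ent$posterior, status = ent$status,
    cross_reference = ifelse(is.na(ent$matches_observed) | ent$matches_observed == "",
                             "na", ent$matches_observed))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-node best-ancestor report in dash notation
#'
#' One row per labelled MCC node: the modal ancestral allele, its posterior,
#' observed/predicted status and dash-notation states relative to the
#' reference — the shape of a published predicted-allele table.
#'
#' @param catalogue An `allele_catalogue` built with node labels and a
#'   reference.
#' @return A tibble sorted by node label.
#' @export
node_report <- function(catalogue) {
  catalogue$entries |>
    dplyr::filter(.data$source_rank == 1L, !is.na(.data$node_label)) |>
    dplyr::arrange(.data$node_label) |>
    dplyr::select("node_label", "dash", "states", "posterior", "status",
                  "matches_observed")
}

#' Catalogue posterior profile plot
#'
#' Entry posteriors by within-node rank, one line per labelled node —
#' visualizes how sharply the posterior mass drops after the best ancestor.
#'
#' @param object An `allele_catalogue`.
#' @param max_rank Ranks shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allele_catalogue
#' @export
autoplot.allele_catalogue <- function(object, max_rank = 10, ...) {
  df <- dplyr::filter(object$entries, .data$source_rank <= max_rank) |>
    dplyr::mutate(node = ifelse(is.na(.data$node_label), .data$clade,
                                .data$node_label))
  ggplot2::ggplot(df, ggplot2::aes(.data$source_rank, .data$posterior,
                                   group = .data$node, colour = .data$node)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = scales_breaks(max_rank)) +
    ggplot2::labs(x = "rank within node", y = "posterior probability",
                  colour = "node") +
    ggplot2::theme_minimal()
}

scales_breaks <- function(k) seq_len(k)
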