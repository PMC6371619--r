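#' Molecular clock models
#'
#' A strict clock gives every branch the same rate; the relaxed clock is the
#' discretized uncorrelated-lognormal variant: each branch carries one of
#' `n_rate_categories` equal-probability quantile midpoints of a mean-1
#' lognormal with log-scale standard deviation `sigma`.
#'
#' @param kind `"strict"` or `"lognormal_relaxed"`.
#' @param mean_rate Mean substitution rate (substitutions/site/time unit).
#' @param sigma Lognormal standard deviation of branch-rate multipliers
#'   (relaxed clock only; 0 collapses to strict).
#' @param n_rate_categories Number of discrete rate categories; `NULL` means
#'   "one per branch", resolved when the tree size is known.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "lognormal_relaxed"),
                        mean_rate = 1, sigma = 0.3, n_rate_categories = NULL) {
  kind <- match.arg(kind)
  if (mean_rate <= 0) stop("mean_rate must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  structure(list(kind = kind, mean_rate = mean_rate, sigma = sigma,
                 n_rate_categories = n_rate_categories),
            class = "clock_model")
}

## quantile midpoints of the mean-1 lognormal (meanlog = -sigma^2/2)
rate_category_values <- function(sigma, k) {
  if (sigma == 0) return(rep(1, k))
  p <- (seq_len(k) - 0.5) / k
  stats::qlnorm(p, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Draw per-branch rate multipliers
#'
#' @param clock A [clock_model].
#' @param n_branches Number of branches.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of positive multipliers (all 1 for a strict clock
#'   or `sigma = 0`).
#' @export
draw_branch_rates <- function(clock, n_branches, seed = NULL) {
  stopifnot(n_branches >= 1L)
  if (clock$kind == "strict" || clock$sigma == 0) return(rep(1, n_branches))
  if (!is.null(seed)) set.seed(seed)
  k <- clock$n_rate_categories %||% n_branches
  vals <- rate_category_values(clock$sigma, k)
  vals[sample.int(k, n_branches, replace = TRUE)]
}
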