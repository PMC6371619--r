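#' Constant-size coalescent log prior of a time-tree
#'
#' Standard constant-population coalescent density over node heights given
#' the topology: with `k` lineages extant over an inter-event interval of
#' duration `tau`, the interval contributes `-k(k-1)/2 * tau/N`, and every
#' coalescent event contributes `-log N`. Tips are contemporaneous at height
#' 0.
#'
#' @param tree A [timetree].
#' @param pop_size Constant effective population size `N` (> 0), in the
#'   tree's time units.
#' @return Log density (finite).
#' @export
coalescent_log_prior <- function(tree, pop_size) {
  if (pop_size <= 0) stop("pop_size must be positive", call. = FALSE)
  n <- tree$ntip
  ev <- sort(tree$heights[(n + 1L):(2L * n - 1L)])
  bounds <- c(0, ev)
  k <- seq(n, 2L)  # lineage count during each interval
  tau <- diff(bounds)
  sum(-k * (k - 1) / 2 * tau / pop_size) - (n - 1L) * log(pop_size)
}
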