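NUC <- c("A", "C", "G", "T")

#' TN93 substitution model parameters
#'
#' The Tamura–Nei (1993) model: arbitrary stationary base frequencies and
#' distinct purine (`A<->G`) and pyrimidine (`C<->T`) transition rates
#' relative to the transversion rate. `kappa1` (`kappa2`) is the purine
#' (pyrimidine) transition/transversion rate ratio. The generator is scaled
#' so one time unit equals one expected substitution per site at
#' stationarity.
#'
#' @param pi Base frequencies in A,C,G,T order (positive, sum 1).
#' @param kappa1 Purine transition/transversion ratio (> 0).
#' @param kappa2 Pyrimidine transition/transversion ratio (> 0).
#' @return An object of class `tn93_params`.
#' @export
tn93_params <- function(pi = rep(0.25, 4), kappa1 = 2, kappa2 = 2) {
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("pi must be 4 positive frequencies summing to 1", call. = FALSE)
  }
  if (kappa1 <= 0 || kappa2 <= 0) stop("kappa1, kappa2 must be positive", call. = FALSE)
  structure(list(pi = stats::setNames(pi, NUC), kappa1 = kappa1, kappa2 = kappa2),
            class = "tn93_params")
}

#' @export
print.tn93_params <- function(x, ...) {
  cat(sprintf("<tn93> pi=(%s) kappa1=%.3g kappa2=%.3g\n",
              paste(sprintf("%.3f", x$pi), collapse = ","), x$kappa1, x$kappa2))
  invisible(x)
}

## transversion rate beta such that the mean substitution rate is 1
tn93_beta <- function(params) {
  pi <- params$pi
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  unname(1 / (2 * (pi["A"] * pi["G"] * params$kappa1 +
                   pi["C"] * pi["T"] * params$kappa2 + piR * piY)))
}

#' TN93 rate matrix (generator)
#'
#' @param params A [tn93_params] object.
#' @return 4x4 generator `Q` (rows sum to 0) scaled to one expected
#'   substitution per site per time unit.
#' @export
tn93_rate_matrix <- function(params) {
  pi <- params$pi
  beta <- tn93_beta(params)
  a1 <- params$kappa1 * beta  # A<->G
  a2 <- params$kappa2 * beta  # C<->T
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in NUC) for (j in NUC) {
    if (i == j) next
    rate <- if ((i == "A" && j == "G") || (i == "G" && j == "A")) a1
            else if ((i == "C" && j == "T") || (i == "T" && j == "C")) a2
            else beta
    Q[i, j] <- rate * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' TN93 transition probability matrix
#'
#' Closed-form `P(t) = exp(Qt)` for the scaled TN93 generator; `t` is the
#' branch length in expected substitutions per site.
#'
#' @param params A [tn93_params] object.
#' @param t Branch length (>= 0).
#' @return 4x4 stochastic matrix in A,C,G,T order.
#' @export
tn93_transition_probs <- function(params, t) {
  if (t < 0) stop("branch length must be nonnegative", call. = FALSE)
  pi <- params$pi
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piC + piT
  beta <- tn93_beta(params)
  a1 <- params$kappa1 * beta
  a2 <- params$kappa2 * beta
  e2 <- exp(-beta * t)
  e3 <- exp(-(piR * a1 + piY * beta) * t)
  e4 <- exp(-(piY * a2 + piR * beta) * t)
  P <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  ## purine block
  P["A", "A"] <- piA + piA * piY / piR * e2 + piG / piR * e3
  P["A", "G"] <- piG + piG * piY / piR * e2 - piG / piR * e3
  P["G", "A"] <- piA + piA * piY / piR * e2 - piA / piR * e3
  P["G", "G"] <- piG + piG * piY / piR * e2 + piA / piR * e3
  ## pyrimidine block
  P["C", "C"] <- piC + piC * piR / piY * e2 + piT / piY * e4
  P["C", "T"] <- piT + piT * piR / piY * e2 - piT / piY * e4
  P["T", "C"] <- piC + piC * piR / piY * e2 - piC / piY * e4
  P["T", "T"] <- piT + piT * piR / piY * e2 + piC / piY * e4
  ## transversions
  for (i in c("A", "G")) for (j in c("C", "T")) P[i, j] <- pi[[j]] * (1 - e2)
  for (i in c("C", "T")) for (j in c("A", "G")) P[i, j] <- pi[[j]] * (1 - e2)
  P
}

## transition matrices for a vector of branch lengths at once (hot path of
## the pruning likelihood): 16 x B matrix, each column one column-major 4x4
## matrix in A,C,G,T order
tn93_pmat_ent <- function(params, bl) {
  pi <- params$pi
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piC + piT
  beta <- tn93_beta(params)
  a1 <- params$kappa1 * beta; a2 <- params$kappa2 * beta
  e2 <- exp(-beta * bl)
  e3 <- exp(-(piR * a1 + piY * beta) * bl)
  e4 <- exp(-(piY * a2 + piR * beta) * bl)
  B <- length(bl)
  ent <- matrix(0, 16, B)  # column-major 4x4 per branch
  idx <- function(i, j) (j - 1L) * 4L + i  # A=1,C=2,G=3,T=4
  ent[idx(1, 1), ] <- piA + piA * piY / piR * e2 + piG / piR * e3
  ent[idx(1, 3), ] <- piG + piG * piY / piR * e2 - piG / piR * e3
  ent[idx(3, 1), ] <- piA + piA * piY / piR * e2 - piA / piR * e3
  ent[idx(3, 3), ] <- piG + piG * piY / piR * e2 + piA / piR * e3
  ent[idx(2, 2), ] <- piC + piC * piR / piY * e2 + piT / piY * e4
  ent[idx(2, 4), ] <- piT + piT * piR / piY * e2 - piT / piY * e4
  ent[idx(4, 2), ] <- piC + piC * piR / piY * e2 - piC / piY * e4
  ent[idx(4, 4), ] <- piT + piT * piR / piY * e2 + piC / piY * e4
  for (i in c(1L, 3L)) for (j in c(2L, 4L)) ent[idx(i, j), ] <- pi[[NUC[j]]] * (1 - e2)
  for (i in c(2L, 4L)) for (j in c(1L, 3L)) ent[idx(i, j), ] <- pi[[NUC[j]]] * (1 - e2)
  ent
}

tn93_pmat_list <- function(params, bl) {
  ent <- tn93_pmat_ent(params, bl)
  lapply(seq_along(bl), function(b) matrix(ent[, b], 4L, 4L,
                                           dimnames = list(NUC, NUC)))
}

#' Empirical base frequencies of a variant matrix
#'
#' Counts states over all alleles and sites (ingroup only by default), with
#' a small pseudo-count so no frequency is exactly zero.
#'
#' @param matrix A `variant_matrix`.
#' @param include_outgroup Count the outgroup's states too?
#' @param pseudo Pseudo-count added per state.
#' @return Numeric frequency vector in A,C,G,T order.
#' @export
empirical_base_freqs <- function(matrix, include_outgroup = FALSE, pseudo = 1) {
  tbl <- if (include_outgroup) matrix$tbl else vm_ingroup(matrix)
  chars <- strsplit(paste(tbl$states, collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = NUC)) + pseudo
  as.numeric(counts / sum(counts))
}
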