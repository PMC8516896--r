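#' Phenotype transition-rate matrix
#'
#' A `rate_matrix` holds per-hour transition rates between phenotype dwell
#' states: off-diagonal entry `r[i, j] >= 0` is the rate (per hour) of
#' switching from state i to state j, and the diagonal is fixed at
#' `-rowSums(off-diagonals)` so each row sums to zero — the generator of a
#' continuous-time Markov chain over the states.
#'
#' @param rates square numeric matrix of non-negative off-diagonal rates in
#'   per hour; the diagonal is overwritten by the row-sum convention.
#' @param states character vector of state names; defaults to the matrix
#'   dimnames or, failing that, the five phenotype dwell states.
#' @return an object of class `rate_matrix` (a numeric matrix with the
#'   diagonal convention applied).
#' @export
#' @examples
#' q <- rate_matrix(matrix(c(0, 0.5, 0.25, 0), 2, 2, byrow = TRUE),
#'                  states = c("A", "B"))
#' stationary_distribution(q)
rate_matrix <- function(rates, states = NULL) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rates must be a square matrix")
  if (is.null(states)) {
    states <- rownames(rates)
    if (is.null(states)) {
      if (nrow(rates) == 5L) states <- phenotype_states() else
        states <- paste0("S", seq_len(nrow(rates)))
    }
  }
  assert_states(states)
  if (length(states) != nrow(rates)) stop("states length must match rates")
  if (!all(is.finite(rates))) stop("rates must be finite")
  off <- rates
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  diag(off) <- -rowSums(off)
  dimnames(off) <- list(states, states)
  structure(off, class = c("rate_matrix", "matrix", "array"))
}

#' @rdname rate_matrix
#' @param x a `rate_matrix`.
#' @export
is_rate_matrix <- function(x) inherits(x, "rate_matrix")

#' @export
print.rate_matrix <- function(x, digits = 3, ...) {
  cat("Phenotype transition-rate matrix (per hour), ",
      nrow(x), " states\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, digits), ...)
  if (!is.null(attr(x, "ci_lower"))) {
    cat("(bootstrap 95% CIs in attributes ci_lower / ci_upper)\n")
  }
  invisible(x)
}

#' Stationary distribution of a transition-rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for the generator's stationary occupancy
#' probabilities (the long-run fraction of time spent in each state).
#'
#' @param Q a [rate_matrix()].
#' @return named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(Q) {
  stopifnot(is_rate_matrix(Q))
  n <- nrow(Q)
  # append the normalisation constraint to the singular system t(Q) pi = 0
  A <- rbind(t(unclass(Q)), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  setNames(pi_hat / sum(pi_hat), rownames(Q))
}

#' Default five-state phenotype rate matrix
#'
#' A plausible generator over the dwell states AE, BB, FP, LA, INT used as
#' the default for synthetic simulations. Within-class exchanges (AE-BB,
#' FP-LA) are fast (up to ~1 per hour), direct FP-BB transitions are rare
#' (< 0.03 per hour), amoeboidal-mesenchymal traffic is mediated by AE and
#' LA, and the intermediate state is short-lived with stationary occupancy
#' near 10 percent.
#'
#' @return a [rate_matrix()] over the five dwell states.
#' @export
default_rate_matrix <- function() {
  s <- phenotype_states()
  q <- matrix(0, 5, 5, dimnames = list(s, s))
  q["AE", "BB"] <- 0.45; q["BB", "AE"] <- 0.55
  q["FP", "LA"] <- 0.50; q["LA", "FP"] <- 0.60
  q["AE", "FP"] <- 0.25; q["FP", "AE"] <- 0.20
  q["AE", "LA"] <- 0.30; q["LA", "AE"] <- 0.30
  q["BB", "LA"] <- 0.20; q["LA", "BB"] <- 0.15
  q["BB", "FP"] <- 0.02; q["FP", "BB"] <- 0.02
  q[s != "INT", "INT"] <- 0.30
  q["INT", s != "INT"] <- c(0.8, 0.6, 0.7, 0.7)
  rate_matrix(q)
}
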