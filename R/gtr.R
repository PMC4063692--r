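#' General time-reversible (GTR) substitution model
#'
#' Builds a normalized GTR rate matrix from six exchangeabilities and four
#' base frequencies. The generator is scaled so that one unit of branch
#' length corresponds to one expected substitution per site at
#' stationarity; with the default equal exchangeabilities and uniform
#' frequencies the model reduces to Jukes–Cantor, for which closed-form
#' distances exist and serve as the test oracle.
#'
#' @param rates Six non-negative exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param freqs Base frequencies (A, C, G, T), summing to 1.
#' @return Object of class `gtr_model`: list with `rates`, `freqs`, `Q`
#'   (normalized generator) and `scale` (the pre-normalization flux).
#' @export
gtr_model <- function(rates = rep(1, 6), freqs = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, length(freqs) == 4)
  if (any(rates < 0)) stop("exchangeabilities must be non-negative")
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("frequencies must be positive and sum to 1")
  if (all(rates == 0))
    warning("degenerate model: all exchangeabilities zero (no substitutions)")
  Q <- gtr_generator(rates, freqs)
  mu <- -sum(freqs * diag(Q))
  if (mu > 0) Q <- Q / mu
  structure(list(rates = rates, freqs = freqs, Q = Q, scale = mu),
            class = "gtr_model")
}

BASES <- c("A", "C", "G", "T")

# unnormalized reversible generator; rates order AC, AG, AT, CG, CT, GT
gtr_generator <- function(rates, freqs) {
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- S["C", "A"] <- rates[1]
  S["A", "G"] <- S["G", "A"] <- rates[2]
  S["A", "T"] <- S["T", "A"] <- rates[3]
  S["C", "G"] <- S["G", "C"] <- rates[4]
  S["C", "T"] <- S["T", "C"] <- rates[5]
  S["G", "T"] <- S["T", "G"] <- rates[6]
  Q <- S %*% diag(freqs)
  dimnames(Q) <- list(BASES, BASES)
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probabilities P(d) = exp(Q d) via the symmetrized eigensystem
# (valid for reversible Q with positive frequencies)
gtr_transition <- function(model, d) {
  freqs <- model$freqs
  sq <- sqrt(freqs)
  B <- diag(sq) %*% model$Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * d)) %*%
    t(e$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}
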