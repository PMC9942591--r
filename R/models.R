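#' @name models
#' @title Substitution models and the discrete-gamma rate prior
#' @description Reversible continuous-time Markov models of residue
#'   substitution (JTT for proteins, Jukes-Cantor for nucleotides), their
#'   transition matrices via symmetric eigendecomposition, and the
#'   equal-probability discretization of a mean-one gamma prior on
#'   site rates.
NULL

#' Build a substitution model
#'
#' Proteins use the JTT replacement model (embedded exchangeabilities and
#' stationary frequencies); nucleotides use Jukes-Cantor (uniform
#' exchangeabilities and frequencies). The rate matrix `Q` has
#' off-diagonals `S[i,j] * pi[j]`, rows summing to zero, and is normalized
#' so the expected substitution rate at stationarity is one per unit
#' branch length; detailed balance `pi[i] Q[i,j] = pi[j] Q[j,i]` holds by
#' construction.
#'
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return list of class `evo_model` with `states`, `S`, `pi`, `Q`, and a
#'   cached eigendecomposition used by [transition_matrix()].
#' @export
build_model <- function(alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    states <- .JTT_STATES
    k <- length(states)
    S <- matrix(0, k, k, dimnames = list(states, states))
    S[lower.tri(S)] <- .JTT_EXCH_LOWER
    S <- S + t(S)
    pi <- setNames(.JTT_FREQS, states)
    pi <- pi / sum(pi)
  } else {
    states <- .NUC_STATES
    k <- length(states)
    S <- matrix(1, k, k, dimnames = list(states, states))
    diag(S) <- 0
    pi <- setNames(rep(1 / k, k), states)
  }
  Q <- S * rep(pi, each = nrow(S))     # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  norm <- -sum(pi * diag(Q))           # expected rate at stationarity
  Q <- Q / norm

  # pi-weighted similarity transform makes B symmetric, so the eigensystem
  # is real and P(t) = V exp(L t) Vinv is numerically stable
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  V <- es$vectors / sp                 # diag(1/sp) %*% vectors
  Vinv <- t(es$vectors) * rep(sp, each = nrow(Q))

  structure(list(alphabet = alphabet, states = states, S = S, pi = pi,
                 Q = Q, eigvals = es$values, V = V, Vinv = Vinv),
            class = "evo_model")
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed from the model's cached symmetric
#' eigendecomposition. Rows sum to one; `P(0)` is the identity; as `t`
#' grows every row converges to the stationary frequencies.
#'
#' @param model an `evo_model`.
#' @param t elapsed time (branch length times rate multiplier), `>= 0`.
#' @return stochastic matrix over the model states.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$V %*% (exp(model$eigvals * t) * model$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Discretize a mean-one gamma prior on rates
#'
#' The gamma(shape = alpha, rate = alpha) prior is approximated by `K`
#' equal-probability categories; each category's rate is the exact mean of
#' the density over its inter-quantile bin, computed from the incomplete
#' gamma function, so the category means average to one.
#'
#' @param alpha gamma shape (> 0); small values mean strong rate
#'   heterogeneity across sites.
#' @param K number of categories (>= 1).
#' @return list of class `evo_gamma` with `alpha`, `K`, `rates`
#'   (increasing), `probs` (all `1/K`).
#' @export
discretize_gamma <- function(alpha, K = 16L) {
  stopifnot(alpha > 0, K >= 1L)
  K <- as.integer(K)
  breaks <- qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  # mean of gamma(a, a) over (lo, hi] = K * (F_{a+1}(hi) - F_{a+1}(lo)),
  # with F_{a+1} the CDF of gamma(a + 1, a)
  upper <- pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- pgamma(breaks[-(K + 1L)], shape = alpha + 1, rate = alpha)
  r <- K * (upper - lower)
  structure(list(alpha = alpha, K = K, rates = r, probs = rep(1 / K, K)),
            class = "evo_gamma")
}
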