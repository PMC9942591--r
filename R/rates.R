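#' @name rates
#' @title Empirical Bayes per-site rate estimation
#' @description Felsenstein-pruning site likelihoods on a fixed tree,
#'   maximum-likelihood fitting of the gamma shape of the rate prior, and
#'   per-site posterior mean rates with discrete credible intervals. All
#'   likelihoods are computed with per-node scaling so deep trees with
#'   hundreds of taxa do not underflow.
NULL

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-site log-likelihoods for the whole alignment at one rate multiplier.
# X is the integer-encoded alignment (taxa x sites, NA = missing); partials
# are carried as (n_states x n_sites) matrices and rescaled per node.
site_logliks <- function(tree, X, model, r) {
  ntip <- length(tree$tip.label)
  S <- ncol(X)
  k <- length(model$states)
  if (!setequal(rownames(X), tree$tip.label))
    evog_stop("evograde_label_mismatch_error",
              "alignment taxa and tree leaves differ")
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  partials <- vector("list", nnode)
  logscale <- numeric(S)

  tip_partial <- function(label) {
    x <- X[label, ]
    L <- matrix(1, k, S)
    obs <- which(!is.na(x))
    if (length(obs)) {
      L[, obs] <- 0
      L[cbind(x[obs], obs)] <- 1
    }
    L
  }

  edges <- tr$edge
  blen <- tr$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    child_partial <- if (child <= ntip) tip_partial(tr$tip.label[child])
                     else partials[[child]]
    P <- transition_matrix(model, r * blen[e])
    msg <- P %*% child_partial
    if (is.null(partials[[parent]])) {
      partials[[parent]] <- msg
    } else {
      partials[[parent]] <- partials[[parent]] * msg
      # rescale to keep columns away from underflow on deep trees
      mx <- apply(partials[[parent]], 2L, max)
      bad <- mx < 1e-200
      mx[bad] <- 1        # all-zero columns stay zero (-Inf loglik)
      partials[[parent]] <- sweep(partials[[parent]], 2L, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  root <- ntip + 1L
  root_partial <- if (is.null(partials[[root]])) tip_partial(tr$tip.label[root])
                  else partials[[root]]
  log(colSums(model$pi * root_partial)) + logscale
}

#' Log-likelihood of one alignment column
#'
#' Felsenstein pruning: partial likelihoods propagate from the leaves to
#' the root over branch transition matrices `P(r * b)`; gap/`X`/`N` leaves
#' contribute all-ones partials (missing data); the root is combined with
#' the stationary frequencies. An all-missing column has likelihood one.
#'
#' @param tree `ape::phylo` with branch lengths; leaves must match the
#'   names of `column`.
#' @param column named character vector: one residue per taxon.
#' @param model an `evo_model`.
#' @param r rate multiplier (>= 0).
#' @return the log-likelihood (a scalar).
#' @export
site_log_likelihood <- function(tree, column, model, r = 1) {
  stopifnot(r >= 0)
  mat <- matrix(toupper(column), ncol = 1L,
                dimnames = list(names(column), NULL))
  mat <- normalize_residues(mat, model$alphabet)
  X <- match(mat, model$states)
  dim(X) <- dim(mat)
  rownames(X) <- rownames(mat)
  site_logliks(tree, X, model, r)
}

#' Fit the gamma shape by maximum likelihood
#'
#' Maximizes the total log-likelihood, summed over sites and averaged over
#' the `K` discrete-gamma categories, by bounded one-dimensional search on
#' `log(alpha)` over `[log(0.05), log(20)]` (absolute tolerance 1e-3).
#' When the optimum sits at a search bound (e.g. an invariant alignment
#' carries no rate-variation signal), a warning is emitted and the
#' boundary value returned.
#'
#' @param aln an `evo_msa`.
#' @param tree `ape::phylo` over the alignment taxa.
#' @param model an `evo_model` (defaults to the alphabet's standard model).
#' @param K number of gamma categories.
#' @return the fitted shape `alpha`.
#' @export
estimate_alpha <- function(aln, tree, model = build_model(aln$alphabet),
                           K = 16L) {
  X <- encode_alignment(aln, model$states)
  lo <- log(0.05); hi <- log(20)
  obj <- function(la) {
    g <- discretize_gamma(exp(la), K)
    M <- vapply(g$rates, function(r) site_logliks(tree, X, model, r),
                numeric(ncol(X)))
    sum(apply(M, 1L, function(row) log_sum_exp(row + log(g$probs))))
  }
  opt <- tryCatch(
    optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-3),
    error = function(e) NULL)
  if (is.null(opt)) {
    evog_warn("gamma-shape optimization failed; falling back to alpha = 1")
    return(1.0)
  }
  alpha <- exp(opt$maximum)
  if (opt$maximum - lo < 1e-2 || hi - opt$maximum < 1e-2)
    evog_warn("gamma shape estimate alpha = %.3g sits at the search bound; little or no rate-variation signal",
              alpha)
  alpha
}

#' Posterior per-site rates and credible intervals
#'
#' Empirical Bayes: per site `i` and rate category `k`, the posterior
#' weight is proportional to the prior weight times the pruning likelihood
#' at that category's rate; the site's rate estimate is the posterior mean
#' over categories. The 95% credible interval is central and reported on
#' the discrete category grid. Sites with fewer than two informative
#' (non-missing) characters carry no signal and are assigned the prior.
#'
#' @param aln an `evo_msa`.
#' @param tree `ape::phylo` over the alignment taxa.
#' @param model an `evo_model`.
#' @param gamma an `evo_gamma` discretization (see [discretize_gamma()]).
#' @param ci_level credible level (default 0.95).
#' @return data.frame of class `site_rates` with columns `site`,
#'   `rate_hat`, `ci_low`, `ci_high`, `n_informative`; the per-site
#'   posterior category weights are in `attr(, "posterior")` and the
#'   discretization in `attr(, "gamma")`.
#' @export
posterior_rates <- function(aln, tree, model = build_model(aln$alphabet),
                            gamma, ci_level = 0.95) {
  X <- encode_alignment(aln, model$states)
  S <- ncol(X)
  M <- vapply(gamma$rates, function(r) site_logliks(tree, X, model, r),
              numeric(S))                       # S x K
  if (S == 1L) M <- matrix(M, nrow = 1L)
  n_inf <- colSums(!is.na(X))

  logp <- log(gamma$probs)
  W <- t(apply(M, 1L, function(row) {
    lw <- row + logp
    w <- exp(lw - max(lw))
    w / sum(w)
  }))
  if (gamma$K == 1L) W <- matrix(1, S, 1L)
  W[n_inf < 2L, ] <- rep(gamma$probs, each = sum(n_inf < 2L))

  rate_hat <- as.numeric(W %*% gamma$rates)
  tail_lo <- (1 - ci_level) / 2
  tail_hi <- 1 - tail_lo
  ci <- t(apply(W, 1L, function(w) {
    cum <- cumsum(w)
    a <- sum(cum < tail_lo)                 # largest index below the tail
    b <- which(cum >= tail_hi)[1L]
    c(gamma$rates[a + 1L], gamma$rates[b])
  }))

  out <- data.frame(site = seq_len(S), rate_hat = rate_hat,
                    ci_low = ci[, 1L], ci_high = ci[, 2L],
                    n_informative = n_inf, row.names = NULL)
  class(out) <- c("site_rates", "data.frame")
  attr(out, "posterior") <- W
  attr(out, "gamma") <- gamma
  out
}

#' Write per-site rates as TSV
#'
#' Columns: alignment column, query residue at that column, posterior mean
#' rate, credible bounds, and the number of informative characters.
#'
#' @param rates a `site_rates` data.frame.
#' @param aln the `evo_msa` the rates were computed from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rates_tsv <- function(rates, aln, path) {
  out <- data.frame(
    column = rates$site,
    query_residue = aln$mat[aln$query_id, rates$site],
    rate_hat = sprintf("%.6f", rates$rate_hat),
    ci_low = sprintf("%.6f", rates$ci_low),
    ci_high = sprintf("%.6f", rates$ci_high),
    n_informative = rates$n_informative)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
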