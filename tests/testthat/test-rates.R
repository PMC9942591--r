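test_that("pruning equals exhaustive enumeration on all small tree shapes", {
  model <- build_model("nucleotide")
  trees <- list(
    ape::read.tree(text = "(A:0.2,B:0.5);"),
    ape::read.tree(text = "(A:0.1,B:0.3,C:0.25);"),
    ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3);"),
    ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.2);"),
    ape::read.tree(text = "(((A:0.1,B:0.2):0.1,C:0.3):0.2,D:0.4);"),
    ape::read.tree(text = "(A:0.1,B:0.2,C:0.3,D:0.12);"))
  cols <- list(c(A = "A", B = "A", C = "G", D = "T"),
               c(A = "C", B = "C", C = "C", D = "C"),
               c(A = "A", B = "-", C = "G", D = "N"),
               c(A = "T", B = "G", C = "A", D = "C"))
  for (tr in trees) for (cl in cols) for (r in c(0.3, 1, 2.5)) {
    cc <- cl[tr$tip.label]
    names(cc) <- tr$tip.label
    expect_equal(site_log_likelihood(tr, cc, model, r),
                 bf_site_loglik(tr, cc, model, r), tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to re-rooting (reversibility)", {
  model <- build_model("nucleotide")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.2);")
  cc <- c(A = "A", B = "C", C = "G", D = "T")
  l0 <- site_log_likelihood(tr, cc, model, 1)
  for (og in c("A", "B", "C", "D")) {
    tr2 <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(site_log_likelihood(tr2, cc, model, 1), l0,
                 tolerance = 1e-10)
  }
  # protein model too
  mp <- build_model("protein")
  ccp <- c(A = "M", B = "K", C = "L", D = "V")
  lp <- site_log_likelihood(tr, ccp, mp, 1)
  tr3 <- ape::root(tr, outgroup = "C", resolve.root = TRUE)
  expect_equal(site_log_likelihood(tr3, ccp, mp, 1), lp, tolerance = 1e-10)
})

test_that("missing data and degenerate columns behave correctly", {
  model <- build_model("nucleotide")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3);")
  # all-gap column: probability one
  expect_equal(site_log_likelihood(tr, c(A = "-", B = "-", C = "-"), model),
               0, tolerance = 1e-12)
  # single-leaf pendant observation marginalizes to the stationary frequency
  tr1 <- ape::read.tree(text = "(A:0.7);")
  expect_equal(site_log_likelihood(tr1, c(A = "G"), model),
               log(model$pi[["G"]]), tolerance = 1e-12)
  # adding an identical taxon on a zero-length branch leaves the
  # likelihood unchanged
  tr4 <- ape::read.tree(text = "(((A:0.0,A2:0.0):0.1,B:0.2):0.15,C:0.3);")
  l3 <- site_log_likelihood(tr, c(A = "A", B = "C", C = "G"), model)
  l4 <- site_log_likelihood(tr4, c(A = "A", A2 = "A", B = "C", C = "G"),
                            model)
  expect_equal(l4, l3, tolerance = 1e-12)
  # mismatched taxa raise a typed error
  expect_error(site_log_likelihood(tr, c(A = "A", B = "C", Z = "G"), model),
               class = "evograde_label_mismatch_error")
})

test_that("deep trees do not underflow (per-node scaling)", {
  model <- build_model("nucleotide")
  sim <- simulate_dataset(300, 5, "nucleotide", alpha = 1, seed = 77,
                          scale = 0.4)
  col <- setNames(sim$alignment$mat[, 1], rownames(sim$alignment$mat))
  ll <- site_log_likelihood(sim$tree, col, model, 1)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("posterior rates are proper and bounded by the category range", {
  sim <- simulate_dataset(20, 80, "protein", alpha = 0.8, seed = 13)
  g <- discretize_gamma(0.8, 16L)
  pr <- posterior_rates(sim$alignment, sim$tree, gamma = g)
  W <- attr(pr, "posterior")
  expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-9)
  expect_true(all(pr$rate_hat >= g$rates[1] - 1e-12))
  expect_true(all(pr$rate_hat <= g$rates[16] + 1e-12))
  expect_true(all(pr$ci_low <= pr$rate_hat + 1e-12))
  expect_true(all(pr$ci_high >= pr$rate_hat - 1e-12))
})

test_that("a fully missing column is assigned the prior", {
  seqs <- c(q = "MKLV-", a = "MKIV-", b = "MRLV-", c = "MKLA-", d = "MELV-")
  aln <- new_alignment(seqs, "q")
  tr <- build_nj(pairwise_distances(aln))
  g <- discretize_gamma(1, 8L)
  pr <- posterior_rates(aln, tr, gamma = g)
  expect_equal(pr$rate_hat[5], 1, tolerance = 1e-9)
  expect_equal(attr(pr, "posterior")[5, ], g$probs, tolerance = 1e-12)
  expect_identical(pr$n_informative[5], 0)
})

test_that("conserved columns get lower rates than variable ones", {
  set.seed(2)
  rates <- c(rep(0.01, 20), rep(2.5, 20))
  sim <- simulate_dataset(30, 40, "nucleotide", rates = rates, seed = 41,
                          scale = 0.3)
  g <- discretize_gamma(1, 16L)
  pr <- posterior_rates(sim$alignment, sim$tree, gamma = g)
  expect_lt(mean(pr$rate_hat[1:20]), mean(pr$rate_hat))
  expect_lt(mean(pr$rate_hat[1:20]), mean(pr$rate_hat[21:40]))
})

test_that("gamma shape fitting recovers the truth and flags no-signal data", {
  sim <- simulate_dataset(30, 150, "nucleotide", alpha = 0.6, seed = 19,
                          scale = 0.2)
  a <- estimate_alpha(sim$alignment, sim$tree, K = 8)
  expect_gt(a, 0.3)
  expect_lt(a, 1.2)
  # invariant alignment: optimum at a bound, reported with a warning
  inv <- new_alignment(c(q = strrep("ACGT", 10), a = strrep("ACGT", 10),
                         b = strrep("ACGT", 10), c = strrep("ACGT", 10),
                         d = strrep("ACGT", 10)), "q")
  tri <- ape::read.tree(text = "(q:0.1,a:0.1,(b:0.1,(c:0.1,d:0.1):0.1):0.1);")
  expect_warning(estimate_alpha(inv, tri, K = 4), "bound")
})

test_that("the alpha likelihood profile is unimodal on simulated data", {
  sim <- simulate_dataset(25, 120, "nucleotide", alpha = 0.8, seed = 23,
                          scale = 0.2)
  model <- build_model("nucleotide")
  X <- evograde:::encode_alignment(sim$alignment, model$states)
  prof <- vapply(c(0.1, 0.25, 0.5, 0.8, 1.4, 3, 8, 18), function(alpha) {
    g <- discretize_gamma(alpha, 8L)
    M <- vapply(g$rates,
                function(r) evograde:::site_logliks(sim$tree, X, model, r),
                numeric(ncol(X)))
    sum(apply(M, 1, function(row) {
      m <- max(row + log(g$probs)); m + log(sum(exp(row + log(g$probs) - m)))
    }))
  }, 0)
  peak <- which.max(prof)
  expect_true(all(diff(prof[seq_len(peak)]) > 0))
  expect_true(all(diff(prof[peak:length(prof)]) < 0))
})

test_that("discrete credible intervals cover the generating rates", {
  sim <- simulate_dataset(40, 400, "nucleotide", alpha = 0.8, seed = 5,
                          scale = 0.15)
  a <- estimate_alpha(sim$alignment, sim$tree, K = 16)
  g <- discretize_gamma(a, 16L)
  pr <- posterior_rates(sim$alignment, sim$tree, gamma = g)
  breaks <- qgamma(seq(0, 1, length.out = 17), shape = a, rate = a)
  lo_edge <- breaks[match(pr$ci_low, g$rates)]
  hi_edge <- breaks[match(pr$ci_high, g$rates) + 1L]
  coverage <- mean(sim$true_rates >= lo_edge & sim$true_rates <= hi_edge)
  expect_gte(coverage, 0.90)
})

test_that("the per-site TSV carries columns, residues, and rates", {
  sim <- simulate_dataset(8, 20, "protein", alpha = 1, seed = 3)
  pr <- posterior_rates(sim$alignment, sim$tree,
                        gamma = discretize_gamma(1, 4L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rates_tsv(pr, sim$alignment, f)
  tab <- read.delim(f)
  expect_identical(nrow(tab), 20L)
  expect_named(tab, c("column", "query_residue", "rate_hat", "ci_low",
                      "ci_high", "n_informative"))
  expect_equal(tab$rate_hat, pr$rate_hat, tolerance = 1e-5)
})
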