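#' @name simulate
#' @title Forward simulation of sequence evolution with known site rates
#' @description Generates random trees (Yule splitting with exponential
#'   branch lengths) and evolves alignments along them under the exact
#'   substitution models the estimator assumes, with a known rate
#'   multiplier per site. Fully deterministic given a seed, so simulated
#'   fixtures are reproducible byte for byte.
NULL

#' Random tree by Yule splitting
#'
#' Starts from a two-leaf cherry and repeatedly splits a uniformly chosen
#' leaf into two until `n_leaves` leaves exist; every branch then receives
#' an independent exponential length with mean `scale`.
#'
#' @param n_leaves number of leaves (>= 2); labels are `t1..tn`.
#' @param scale mean branch length (expected substitutions/site on the
#'   model's unit-rate scale).
#' @param seed integer seed (mandatory: fixtures must be reproducible).
#' @return an `ape::phylo` tree.
#' @export
random_tree <- function(n_leaves, scale = 0.1, seed) {
  stopifnot(n_leaves >= 2L, !missing(seed))
  set.seed(seed)
  # grow a nested-list topology, then serialize to Newick for ape
  node_id <- 0L
  new_leaf <- function() {
    node_id <<- node_id + 1L
    sprintf("L%d", node_id)
  }
  children <- list()
  root <- "R"
  children[[root]] <- c(new_leaf(), new_leaf())
  leaves <- children[[root]]
  while (length(leaves) < n_leaves) {
    pick <- leaves[sample.int(length(leaves), 1L)]
    kids <- c(new_leaf(), new_leaf())
    children[[pick]] <- kids
    leaves <- c(setdiff(leaves, pick), kids)
  }
  to_newick <- function(node) {
    if (is.null(children[[node]])) node
    else sprintf("(%s,%s)", to_newick(children[[node]][1L]),
                 to_newick(children[[node]][2L]))
  }
  tr <- ape::read.tree(text = paste0(to_newick(root), ";"))
  tr$tip.label <- sprintf("t%d", seq_along(tr$tip.label))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / scale)
  tr
}

#' Evolve an alignment along a tree
#'
#' The root state of each site is drawn from the model's stationary
#' frequencies; along every branch the child state is drawn from the
#' transition matrix `P(r_i * b)` where `r_i` is the site's rate
#' multiplier and `b` the branch length. A site with rate 0 is copied
#' unchanged from the root to every leaf. No indels are simulated.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model an `evo_model`.
#' @param rates_per_site numeric vector of non-negative rate multipliers,
#'   one per site.
#' @param seed integer seed.
#' @param query_id which leaf is declared the query (default: first tip).
#' @return an `evo_msa` with `attr(, "true_rates")` set to
#'   `rates_per_site`.
#' @export
simulate_alignment <- function(tree, model, rates_per_site, seed,
                               query_id = tree$tip.label[1L]) {
  stopifnot(all(rates_per_site >= 0), !missing(seed))
  set.seed(seed)
  S <- length(rates_per_site)
  k <- length(model$states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  nnode <- ntip + tr$Nnode
  states <- matrix(NA_integer_, nnode, S)
  root <- ntip + 1L
  states[root, ] <- sample.int(k, S, replace = TRUE, prob = model$pi)

  # cumulative-probability trick: per edge, build the per-site transition
  # rows for the parent states in one shot, then invert uniform draws
  Ut <- upper.tri(matrix(0, k, k), diag = TRUE) * 1
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    b <- tr$edge.length[e]
    t_site <- rates_per_site * b
    # P[s, j] = sum_m V[s, m] exp(lambda_m t) Vinv[m, j]
    Wm <- exp(outer(t_site, model$eigvals))          # S x k
    probs <- (Wm * model$V[states[parent, ], , drop = FALSE]) %*% model$Vinv
    probs[probs < 0] <- 0
    probs <- probs / rowSums(probs)
    cum <- probs %*% Ut
    u <- runif(S)
    states[child, ] <- 1L + rowSums(cum < u)
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(row)
    paste(model$states[row], collapse = ""))
  names(seqs) <- tr$tip.label
  aln <- new_alignment(seqs, query_id = query_id, alphabet = model$alphabet)
  attr(aln, "true_rates") <- rates_per_site
  aln
}

#' Simulate a complete dataset with gamma-distributed site rates
#'
#' Convenience wrapper: draws a random tree, draws continuous per-site
#' rates from a mean-one gamma distribution (or takes explicit rates), and
#' evolves an alignment. The continuous draw deliberately does not use the
#' discretized categories, so estimator tests run against the prior the
#' model actually assumes.
#'
#' @param n_leaves,n_sites dataset dimensions.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param alpha gamma shape for the site-rate draw (ignored when `rates`
#'   is given).
#' @param rates optional explicit per-site rates.
#' @param scale mean branch length for [random_tree()].
#' @param seed integer seed (drives tree, rates, and evolution).
#' @return list with `tree`, `alignment`, `true_rates`, `model`.
#' @export
simulate_dataset <- function(n_leaves, n_sites,
                             alphabet = c("protein", "nucleotide"),
                             alpha = 1, rates = NULL, scale = 0.1, seed) {
  alphabet <- match.arg(alphabet)
  stopifnot(!missing(seed))
  model <- build_model(alphabet)
  tree <- random_tree(n_leaves, scale = scale, seed = seed)
  if (is.null(rates)) {
    set.seed(seed + 1L)
    rates <- rgamma(n_sites, shape = alpha, rate = alpha)
  }
  aln <- simulate_alignment(tree, model, rates, seed = seed + 2L)
  list(tree = tree, alignment = aln, true_rates = rates, model = model)
}

#' Write a simulated dataset to disk
#'
#' Emits the alignment (FASTA), the tree (Newick), and the generating
#' per-site rates (TSV: site, true_rate).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             tree = file.path(dir, "tree.nwk"),
             rates = file.path(dir, "true_rates.tsv"))
  write_alignment(sim$alignment, paths[["alignment"]])
  write_newick(sim$tree, paths[["tree"]])
  write.table(data.frame(site = seq_along(sim$true_rates),
                         true_rate = sim$true_rates),
              paths[["rates"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
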