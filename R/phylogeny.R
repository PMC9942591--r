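#' @name phylogeny
#' @title Distance-based tree construction and subtree extraction
#' @description Model-corrected pairwise distances (Poisson correction for
#'   proteins, Jukes-Cantor for nucleotides), neighbor-joining tree
#'   construction, Newick input/output with label validation against the
#'   alignment, and extraction of query-containing subtrees for re-analysis.
#'   Trees are `ape::phylo` objects throughout.
NULL

#' Model-corrected pairwise distances
#'
#' For each pair of sequences, `p` is the mismatch fraction over columns
#' where both are non-gap and non-missing. Protein distances use the
#' Poisson correction `-ln(1 - p)`; nucleotide distances use Jukes-Cantor
#' `-(3/4) ln(1 - (4/3) p)`. Saturated pairs (at or beyond the correction
#' singularity) and pairs with no shared columns receive `cap`.
#'
#' @param aln an `evo_msa`.
#' @param cap maximum distance, substitutions/site.
#' @return symmetric distance matrix with taxon dimnames, zero diagonal.
#' @export
pairwise_distances <- function(aln, cap = 5) {
  states <- if (aln$alphabet == "protein") .PROTEIN_STATES else .NUC_STATES
  X <- encode_alignment(aln, states)
  n <- nrow(X)
  if (n < 2L)
    evog_stop("evograde_degenerate_input_error",
              "need >= 2 sequences for distances")
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) {
    xi <- X[i, ]
    for (j in (i + 1L):n) {
      xj <- X[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      ns <- sum(ok)
      if (ns == 0L) {
        d <- cap
      } else {
        p <- sum(xi[ok] != xj[ok]) / ns
        d <- if (aln$alphabet == "protein") {
          if (p >= 1 - exp(-cap)) cap else -log(1 - p)
        } else {
          if (p >= 0.75 * (1 - exp(-4 * cap / 3))) cap
          else -0.75 * log(1 - 4 * p / 3)
        }
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei neighbor joining on a distance matrix; negative
#' estimated branch lengths are clamped to zero. The two-taxon case yields
#' a single edge split evenly between the leaves. The returned tree is
#' unrooted (pruning likelihoods are root-invariant under the reversible
#' models used here).
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an `ape::phylo` tree.
#' @export
build_nj <- function(D) {
  n <- nrow(D)
  if (is.null(n) || n < 2L)
    evog_stop("evograde_degenerate_input_error",
              "need >= 2 taxa to build a tree")
  if (n == 2L) {
    tr <- ape::read.tree(
      text = sprintf("(%s:%.10g,%s:%.10g);",
                     rownames(D)[1L], D[1L, 2L] / 2,
                     rownames(D)[2L], D[1L, 2L] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Read a Newick tree and validate its leaves against an alignment
#'
#' @param path Newick file path.
#' @param aln optional `evo_msa`; when given, the tree's leaf set must
#'   equal the alignment's taxon set.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path, aln = NULL) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    evog_stop("evograde_parse_error", "could not parse Newick file %s", path)
  if (!is.null(aln)) check_tree_labels(tr, aln)
  tr
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

check_tree_labels <- function(tree, aln) {
  taxa <- rownames(aln$mat)
  extra <- setdiff(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(extra) || length(missing))
    evog_stop("evograde_label_mismatch_error",
              "tree/alignment taxa differ (tree-only: %s; alignment-only: %s)",
              paste(head(extra, 3L), collapse = ","),
              paste(head(missing, 3L), collapse = ","))
  invisible(TRUE)
}

#' Extract a query-containing subtree and its restricted alignment
#'
#' The clade is selected by the set of leaf names that defines it: the
#' subtree rooted at the most recent common ancestor of `leaves`. The
#' restricted alignment keeps only the subtree's taxa and drops columns
#' that become all-gap. The result is suitable as input for a fresh
#' pipeline run on the subfamily.
#'
#' @param tree an `ape::phylo` covering the alignment taxa.
#' @param leaves character vector of leaf names defining the clade.
#' @param aln the `evo_msa` the tree belongs to.
#' @param min_homologues minimum leaf count for the subtree.
#' @return list with elements `tree` and `alignment`.
#' @export
extract_subtree <- function(tree, leaves, aln, min_homologues = 5L) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    evog_stop("evograde_label_mismatch_error",
              "leaves not in tree: %s", paste(head(unknown, 3L), collapse = ","))
  if (setequal(leaves, tree$tip.label)) {
    sub <- tree
    keep <- tree$tip.label
  } else {
    node <- ape::getMRCA(tree, leaves)
    sub <- ape::extract.clade(tree, node)
    keep <- sub$tip.label
  }
  if (!aln$query_id %in% keep)
    evog_stop("evograde_query_outside_subtree_error",
              "query '%s' is not inside the selected subtree", aln$query_id)
  if (length(keep) < min_homologues)
    evog_stop("evograde_too_few_homologues_error",
              "subtree has %d leaves; at least %d required",
              length(keep), min_homologues)
  mat <- aln$mat[keep, , drop = FALSE]
  not_all_gap <- colSums(mat != "-") > 0L
  seqs <- apply(mat[, not_all_gap, drop = FALSE], 1L, paste, collapse = "")
  sub_aln <- new_alignment(seqs, query_id = aln$query_id,
                           alphabet = aln$alphabet)
  list(tree = sub, alignment = sub_aln)
}
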