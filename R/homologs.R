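#' @name homolog_selection
#' @title Homologue filtering, redundancy clustering, and representative
#'   selection
#' @description Deterministic reduction of a homologue hit table to a
#'   diverse representative set: similarity-bound filtering, greedy
#'   identity clustering in E-value order, and evenly spaced sampling of
#'   cluster representatives. Sorting hits by E-value before clustering
#'   makes the whole selection canonical: the same multiset of hits always
#'   yields byte-identical output, regardless of input order.
NULL

#' Selection parameters
#'
#' Defaults follow common conservation-server practice: homologues between
#' 35% and 95% identity to the query with at least 60% query coverage are
#' kept, redundancy is removed at 95% identity, and 150 representatives are
#' retained. At least 5 sequences (including the query) are required;
#' fewer than 50 or more than 300 trigger warnings.
#'
#' @param min_identity,max_identity query-identity bounds (fractions).
#' @param min_coverage minimum query coverage (fraction).
#' @param redundancy_identity identity threshold for redundancy clustering.
#' @param n_representatives target number of representatives.
#' @param min_homologues hard minimum sequence count (query included).
#' @param warn_below,warn_above counts outside which a warning is emitted.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(min_identity = 0.35, max_identity = 0.95,
                             min_coverage = 0.60, redundancy_identity = 0.95,
                             n_representatives = 150L, min_homologues = 5L,
                             warn_below = 50L, warn_above = 300L) {
  stopifnot(min_identity >= 0, min_identity < max_identity, max_identity <= 1,
            n_representatives >= min_homologues)
  structure(list(
    min_identity = min_identity, max_identity = max_identity,
    min_coverage = min_coverage, redundancy_identity = redundancy_identity,
    n_representatives = as.integer(n_representatives),
    min_homologues = as.integer(min_homologues),
    warn_below = as.integer(warn_below), warn_above = as.integer(warn_above)
  ), class = "selection_config")
}

#' Build a hit table
#'
#' @param subject_id character vector of unique hit ids.
#' @param e_value non-negative E-values.
#' @param identity_to_query,coverage_of_query fractions in \[0, 1\].
#' @param sequence unaligned residue strings (non-empty).
#' @return data.frame of class `hit_table`.
#' @export
hit_table <- function(subject_id, e_value, identity_to_query,
                      coverage_of_query, sequence) {
  h <- data.frame(subject_id = as.character(subject_id),
                  e_value = as.numeric(e_value),
                  identity_to_query = as.numeric(identity_to_query),
                  coverage_of_query = as.numeric(coverage_of_query),
                  sequence = toupper(as.character(sequence)),
                  stringsAsFactors = FALSE)
  if (nrow(h)) {
    if (any(h$e_value < 0))
      evog_stop("evograde_parse_error", "negative E-value in hit table")
    if (any(h$identity_to_query < 0 | h$identity_to_query > 1) ||
        any(h$coverage_of_query < 0 | h$coverage_of_query > 1))
      evog_stop("evograde_parse_error",
                "identity/coverage must be fractions in [0, 1]")
    if (any(!nzchar(h$sequence)))
      evog_stop("evograde_missing_sequence_error",
                "hits without sequences cannot be used (no database fetching)")
    if (anyDuplicated(h$subject_id))
      evog_stop("evograde_parse_error", "duplicate subject_id in hit table")
  }
  class(h) <- c("hit_table", "data.frame")
  h
}

#' Read a hit table from disk
#'
#' Two layouts are accepted: BLAST tabular (`outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore, percent
#' identity divided by 100 on read, coverage computed from qstart/qend and
#' the query length) and a generic four-column TSV
#' (`subject_id  e_value  identity  coverage`, fractions or percentages).
#' Hit sequences come from a FASTA file keyed by `subject_id`.
#'
#' @param path hit table path (TSV).
#' @param sequences path to a FASTA file with one record per subject id.
#' @param format `"auto"`, `"blast6"`, or `"tsv"`.
#' @param query_length ungapped query length, required to derive coverage
#'   from BLAST tabular coordinates.
#' @return A [hit_table()].
#' @export
read_hits <- function(path, sequences, format = c("auto", "blast6", "tsv"),
                      query_length = NULL) {
  format <- match.arg(format)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) evog_stop("evograde_parse_error",
                                  "could not read hit table %s: %s",
                                  path, conditionMessage(e)))
  if (format == "auto") format <- if (ncol(tab) >= 12L) "blast6" else "tsv"
  if (format == "blast6") {
    if (ncol(tab) < 12L)
      evog_stop("evograde_parse_error",
                "BLAST tabular input needs >= 12 columns, got %d", ncol(tab))
    if (is.null(query_length))
      evog_stop("evograde_parse_error",
                "query_length is required to derive coverage from BLAST tabular")
    sid <- tab[[2L]]
    ident <- tab[[3L]] / 100
    cov <- pmin(1, abs(tab[[8L]] - tab[[7L]] + 1) / query_length)
    ev <- tab[[11L]]
  } else {
    if (ncol(tab) < 4L)
      evog_stop("evograde_parse_error",
                "generic hit TSV needs 4 columns (subject_id, e_value, identity, coverage)")
    sid <- tab[[1L]]
    ev <- as.numeric(tab[[2L]])
    ident <- as.numeric(tab[[3L]])
    cov <- as.numeric(tab[[4L]])
    # percentages tolerated: anything > 1 is interpreted as percent
    if (any(ident > 1)) ident <- ident / 100
    if (any(cov > 1)) cov <- cov / 100
  }
  seqs <- Biostrings::readBStringSet(sequences)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(sid, names(seqs))
  if (length(missing))
    evog_stop("evograde_missing_sequence_error",
              "no sequence provided for hit(s): %s",
              paste(head(missing, 5L), collapse = ", "))
  hit_table(sid, ev, ident, cov, as.character(seqs[sid]))
}

#' Sort hits canonically
#'
#' Ascending E-value; ties broken by lexicographic subject id so that the
#' ordering (and everything downstream of it) is deterministic.
#'
#' @param hits a [hit_table()].
#' @return the sorted hit table.
#' @export
sort_hits <- function(hits) {
  hits[order(hits$e_value, hits$subject_id, method = "radix"), , drop = FALSE]
}

#' Filter hits by similarity bounds
#'
#' Keeps hits whose identity to the query lies within
#' `[min_identity, max_identity]` and whose coverage is at least
#' `min_coverage`. The query itself (matched by `query_id`) is always
#' retained.
#'
#' @param hits a [hit_table()].
#' @param cfg a [selection_config()].
#' @param query_id id of the query row, exempt from filtering.
#' @return the filtered hit table.
#' @export
filter_hits <- function(hits, cfg = selection_config(), query_id = NULL) {
  keep <- hits$identity_to_query >= cfg$min_identity &
    hits$identity_to_query <= cfg$max_identity &
    hits$coverage_of_query >= cfg$min_coverage
  if (!is.null(query_id)) keep <- keep | hits$subject_id == query_id
  hits[keep, , drop = FALSE]
}

# Pairwise identity used for redundancy clustering: global alignment with
# match +1 / mismatch 0 / gap -1, identity = matches / min(ungapped lengths)
# (CD-HIT-style short-sequence normalization).
pair_identity <- function(s1, s2) {
  ab <- sort(unique(c(strsplit(s1, "")[[1L]], strsplit(s2, "")[[1L]])))
  sub <- matrix(0L, length(ab), length(ab), dimnames = list(ab, ab))
  diag(sub) <- 1L
  al <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                      substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(al) / min(nchar(s1), nchar(s2))
}

# Cheap upper bound on pair_identity from character compositions: the number
# of aligned matches can never exceed the shared composition. Used to skip
# hopeless alignments during clustering.
composition_bound <- function(counts1, counts2, len1, len2) {
  sum(pmin(counts1, counts2)) / min(len1, len2)
}

char_counts <- function(s, alphabet) {
  table(factor(strsplit(s, "", fixed = TRUE)[[1L]], levels = alphabet))
}

#' Greedy redundancy clustering
#'
#' Scans hits in their (sorted) input order. Each hit joins the first
#' existing cluster whose representative it matches at or above
#' `redundancy_identity` (global-alignment identity normalized by the
#' shorter ungapped length); otherwise it founds a new cluster. Because the
#' scan order is the canonical E-value order, the representative of every
#' cluster is its lowest-E-value member and output is deterministic.
#'
#' @param hits_sorted a [hit_table()] already ordered by [sort_hits()].
#' @param redundancy_identity identity threshold (fraction).
#' @return list of clusters; each has `representative` (subject id) and
#'   `members` (character vector of subject ids, representative first).
#' @export
cluster_redundant <- function(hits_sorted, redundancy_identity = 0.95) {
  n <- nrow(hits_sorted)
  if (n == 0L) return(list())
  seqs <- hits_sorted$sequence
  lens <- nchar(seqs)
  ab <- sort(unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)))
  counts <- t(vapply(seqs, char_counts, numeric(length(ab)), alphabet = ab,
                     USE.NAMES = FALSE))
  chars <- strsplit(seqs, "", fixed = TRUE)

  rep_idx <- integer(0)           # indices of cluster representatives
  rep_counts <- matrix(0, 0L, length(ab))
  assign <- integer(n)            # cluster id per hit
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(rep_idx)) {
      # composition upper bound against all representatives at once; only
      # candidates that could reach the threshold are aligned
      shared <- rep_counts
      exceeds <- sweep(shared, 2L, counts[i, ], ">")
      shared[exceeds] <- rep(counts[i, ], each = nrow(shared))[exceeds]
      bound <- rowSums(shared) / pmin(lens[rep_idx], lens[i])
      for (ci in which(bound >= redundancy_identity)) {
        r <- rep_idx[ci]
        # exact-length fast path: positional identity is a lower bound on
        # the alignment identity, so >= threshold means join w/o aligning
        ident <- NA_real_
        if (lens[i] == lens[r]) {
          ham <- sum(chars[[i]] == chars[[r]]) / lens[i]
          if (ham >= redundancy_identity) ident <- ham
        }
        if (is.na(ident)) ident <- pair_identity(seqs[i], seqs[r])
        if (ident >= redundancy_identity) {
          assign[i] <- ci
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      rep_counts <- rbind(rep_counts, counts[i, ])
      assign[i] <- length(rep_idx)
    }
  }
  lapply(seq_along(rep_idx), function(ci) {
    members <- hits_sorted$subject_id[assign == ci]
    list(representative = hits_sorted$subject_id[rep_idx[ci]],
         members = members)
  })
}

#' Select representatives from clusters
#'
#' If there are at most `n` clusters, all representatives are returned.
#' Otherwise `n` are sampled at evenly spaced indices
#' `floor(i * m / n), i = 0..n-1` from the E-value-ordered representative
#' list, preserving diversity along the similarity gradient rather than
#' keeping only the closest hits. The query is always included: if its
#' cluster was not sampled, it replaces the selected representative nearest
#' to its ordered position.
#'
#' @param clusters output of [cluster_redundant()].
#' @param hits_sorted the sorted hit table the clusters were built from.
#' @param query_id subject id of the query.
#' @param n target number of representatives.
#' @return [hit_table()] rows of the selected representatives, in E-value
#'   order; exactly `min(n, length(clusters))` rows.
#' @export
select_representatives <- function(clusters, hits_sorted, query_id,
                                   n = 150L) {
  reps <- vapply(clusters, `[[`, character(1L), "representative")
  m <- length(reps)
  if (m <= n) {
    sel <- seq_len(m)
  } else {
    sel <- floor((0:(n - 1L)) * m / n) + 1L
    # the query's cluster must survive selection
    qcl <- which(vapply(clusters, function(cl) query_id %in% cl$members,
                        logical(1L)))
    if (length(qcl) == 1L && !(qcl %in% sel)) {
      swap <- which.min(abs(sel - qcl))
      sel[swap] <- qcl
      sel <- sort(sel)
    }
  }
  out <- hits_sorted[match(reps[sel], hits_sorted$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enforce homologue-count policy
#'
#' Errors when fewer than `min_homologues` sequences (query included)
#' remain; warns when the count is below `warn_below` (too little
#' diversity for an informative analysis) or above `warn_above`
#' (diminishing returns at high computational cost).
#'
#' @param selected a [hit_table()] (or anything with `nrow`).
#' @param cfg a [selection_config()].
#' @return `selected`, unchanged.
#' @export
enforce_counts <- function(selected, cfg = selection_config()) {
  k <- nrow(selected)
  if (k < cfg$min_homologues)
    evog_stop("evograde_too_few_homologues_error",
              "only %d sequences (including the query); at least %d required",
              k, cfg$min_homologues)
  if (k < cfg$warn_below)
    evog_warn("only %d homologues; analyses with fewer than %d are not recommended",
              k, cfg$warn_below)
  if (k > cfg$warn_above)
    evog_warn("%d homologues exceed the recommended maximum of %d",
              k, cfg$warn_above)
  selected
}

#' Full homologue selection stage
#'
#' Convenience wrapper: sort, filter, cluster, select, and enforce counts.
#'
#' @param hits a [hit_table()] including the query row.
#' @param query_id subject id of the query.
#' @param cfg a [selection_config()].
#' @return [hit_table()] of selected representatives (query included).
#' @export
select_homologues <- function(hits, query_id, cfg = selection_config()) {
  hits <- sort_hits(hits)
  hits <- filter_hits(hits, cfg, query_id = query_id)
  clusters <- cluster_redundant(hits, cfg$redundancy_identity)
  sel <- select_representatives(clusters, hits, query_id,
                                n = cfg$n_representatives)
  enforce_counts(sel, cfg)
}
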