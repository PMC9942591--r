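#' @name seq_io
#' @title Alignment input/output and the query coordinate system
#' @description Readers and helpers for multiple sequence alignments:
#'   FASTA/Clustal parsing, alphabet detection, residue normalization, and
#'   the map from ungapped query positions to alignment columns.
NULL

.PROTEIN_STATES <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                     "F","P","S","T","W","Y","V")
.NUC_STATES <- c("A","C","G","T")

#' Construct an alignment object
#'
#' An `evo_msa` holds equal-length sequences as a character matrix (one row
#' per record, one column per alignment site), the identifier of the query
#' record, and the detected alphabet.
#'
#' @param seqs named character vector of aligned sequences (equal length;
#'   names are record ids, unique and non-empty).
#' @param query_id id of the query record; must be present in `names(seqs)`.
#' @param alphabet `"protein"`, `"nucleotide"`, or `NULL` to auto-detect.
#' @return An object of class `evo_msa` with elements `mat` (character
#'   matrix, rownames = ids), `query_id`, `alphabet`, `n_sites`.
#' @export
new_alignment <- function(seqs, query_id, alphabet = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    evog_stop("evograde_parse_error", "all sequences must carry non-empty ids")
  if (anyDuplicated(ids))
    evog_stop("evograde_parse_error", "duplicate sequence id: %s",
              ids[duplicated(ids)][1L])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    evog_stop("evograde_unequal_length_error",
              "alignment records differ in length (%s)",
              paste(unique(lens), collapse = ", "))
  if (length(seqs) < 2L)
    evog_stop("evograde_too_few_homologues_error",
              "an alignment needs at least 2 records")
  if (lens[1L] < 1L)
    evog_stop("evograde_parse_error", "alignment has zero columns")
  if (!query_id %in% ids)
    evog_stop("evograde_query_missing_error",
              "query '%s' is not among the alignment records", query_id)

  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (is.null(alphabet)) {
    alphabet <- detect_alphabet(seqs)
  } else {
    alphabet <- match.arg(alphabet, c("protein", "nucleotide"))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  mat <- normalize_residues(mat, alphabet)
  structure(
    list(mat = mat, query_id = query_id, alphabet = alphabet,
         n_sites = ncol(mat)),
    class = "evo_msa"
  )
}

# Map ambiguity codes to missing data and (for nucleotides) U to T, so the
# likelihood machinery only ever sees model states, '-', or 'X'/'N'.
normalize_residues <- function(mat, alphabet) {
  if (alphabet == "nucleotide") {
    mat[mat == "U"] <- "T"
    mat[!(mat %in% c(.NUC_STATES, "-"))] <- "N"
  } else {
    mat[!(mat %in% c(.PROTEIN_STATES, "-"))] <- "X"
  }
  mat
}

#' @export
print.evo_msa <- function(x, ...) {
  cat(sprintf("evo_msa: %d sequences x %d sites (%s), query '%s'\n",
              nrow(x$mat), x$n_sites, x$alphabet, x$query_id))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments, upper-cases residues, normalizes `.`
#' gaps to `-`, maps ambiguity codes to missing data, and auto-detects the
#' alphabet unless overridden.
#'
#' @param path file path.
#' @param query_id id of the query sequence (must be present in the file).
#' @param format `"fasta"` or `"clustal"`.
#' @param alphabet optional override, `"protein"` or `"nucleotide"`.
#' @return An [new_alignment()] object.
#' @export
read_alignment <- function(path, query_id, format = c("fasta", "clustal"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    evog_stop("evograde_parse_error", "file not found: %s", path)
  seqs <- tryCatch({
    if (format == "fasta") {
      ss <- Biostrings::readBStringSet(path)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    } else {
      ss <- Biostrings::unmasked(
        Biostrings::readAAMultipleAlignment(path, format = "clustal"))
      setNames(as.character(ss), names(ss))
    }
  }, error = function(e) {
    evog_stop("evograde_parse_error", "could not parse %s as %s: %s",
              path, format, conditionMessage(e))
  })
  if (length(seqs) == 0L)
    evog_stop("evograde_parse_error", "no sequences in %s", path)
  new_alignment(seqs, query_id = query_id, alphabet = alphabet)
}

#' Write an alignment as FASTA
#'
#' @param aln an `evo_msa`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Detect the alphabet of a sequence set
#'
#' Classifies sequences as nucleotide when at least 85% of the non-gap,
#' non-X characters are A, C, G, T, or U; otherwise protein. Case- and
#' order-insensitive.
#'
#' @param seqs character vector of sequences (may contain gaps).
#' @param threshold nucleotide fraction required to call nucleotide.
#' @return `"protein"` or `"nucleotide"`.
#' @export
detect_alphabet <- function(seqs, threshold = 0.85) {
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  chars <- chars[!chars %in% c("-", ".", "X")]
  if (length(chars) == 0L)
    evog_stop("evograde_empty_alignment_error",
              "no informative characters to detect an alphabet from")
  frac <- mean(chars %in% c("A", "C", "G", "T", "U"))
  if (frac >= threshold) "nucleotide" else "protein"
}

#' Map query positions to alignment columns
#'
#' Returns, for each ungapped position of the query (1-based), the alignment
#' column (1-based) that holds it.
#'
#' @param aln an `evo_msa`.
#' @return integer vector; strictly increasing, one entry per non-gap
#'   query character.
#' @export
build_query_map <- function(aln) {
  q <- aln$mat[aln$query_id, ]
  which(q != "-")
}

#' Ungapped query sequence
#'
#' @param aln an `evo_msa`.
#' @return single string: the query with gap characters removed.
#' @export
query_sequence <- function(aln) {
  q <- aln$mat[aln$query_id, ]
  paste(q[q != "-"], collapse = "")
}

# Integer encoding of an alignment against the model states: entries are
# indices into the state vector, NA for gaps/X/N (missing data).
encode_alignment <- function(aln, states) {
  m <- match(aln$mat, states)
  dim(m) <- dim(aln$mat)
  rownames(m) <- rownames(aln$mat)
  m
}
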