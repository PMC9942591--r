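#' @name cli_pipeline
#' @title End-to-end pipeline orchestration
#' @description Runs the full analysis from either a ready-made alignment
#'   or a homologue hit table: selection, tree building or ingestion,
#'   gamma-shape fitting, posterior rates, grading, and optional structure
#'   mapping. Every stage logs its parameters and counts; results are
#'   deterministic given the configuration and seed. A companion verb
#'   re-runs the analysis on a user-chosen subtree.
NULL

#' Pipeline configuration
#'
#' Exactly one input mode must be active: `msa` (a ready alignment
#' containing the query) or `hits` + `sequences` + `query_id` (a search
#' result table to be filtered, clustered, aligned externally or supplied
#' pre-aligned). Optional inputs: a Newick tree over the alignment taxa
#' and a structure for grade mapping.
#'
#' @param msa path to an aligned FASTA/Clustal file (MSA mode).
#' @param msa_format `"fasta"` or `"clustal"`.
#' @param query_id id of the query sequence (required).
#' @param hits,sequences hit-table mode inputs (see [read_hits()]).
#' @param hits_format hit-table layout for [read_hits()].
#' @param query_length ungapped query length (BLAST tabular coverage).
#' @param tree optional Newick path; when absent a neighbor-joining tree
#'   is built from model-corrected distances.
#' @param structure optional PDB/mmCIF path.
#' @param chain chain to map the query onto (default: first chain).
#' @param alphabet optional `"protein"`/`"nucleotide"` override.
#' @param selection a [selection_config()].
#' @param K number of discrete-gamma categories.
#' @param ci_level credible level for the per-site intervals.
#' @param scale color scale, `"standard"` or `"color_blind"`.
#' @param aligner optional external aligner executable (e.g. `"mafft"`)
#'   for hit-table mode when hit sequences are unaligned.
#' @param out_dir output directory.
#' @param seed integer seed (stage determinism).
#' @return list of class `run_config`.
#' @export
run_config <- function(msa = NULL, msa_format = "fasta", query_id,
                       hits = NULL, sequences = NULL, hits_format = "auto",
                       query_length = NULL, tree = NULL, structure = NULL,
                       chain = NULL, alphabet = NULL,
                       selection = selection_config(), K = 16L,
                       ci_level = 0.95, scale = "standard", aligner = NULL,
                       out_dir = tempfile("evograde_run_"), seed = 1L) {
  msa_mode <- !is.null(msa)
  hit_mode <- !is.null(hits)
  if (msa_mode == hit_mode)
    evog_stop("evograde_config_error",
              "exactly one input mode: either 'msa' or 'hits' + 'sequences'")
  if (hit_mode && is.null(sequences))
    evog_stop("evograde_config_error",
              "hit-table mode needs a 'sequences' FASTA")
  structure(list(msa = msa, msa_format = msa_format, query_id = query_id,
                 hits = hits, sequences = sequences,
                 hits_format = hits_format, query_length = query_length,
                 tree = tree, structure = structure, chain = chain,
                 alphabet = alphabet, selection = selection,
                 K = as.integer(K), ci_level = ci_level, scale = scale,
                 aligner = aligner, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

log_stage <- function(log, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  c(log, line)
}

#' Align representatives with an external aligner
#'
#' Writes the unaligned sequences to a temporary FASTA, invokes the
#' configured aligner executable (`<aligner> <in.fasta>` writing FASTA to
#' stdout, the MAFFT/MUSCLE convention), and parses the result back. This
#' step is entirely optional: MSA-mode runs never need it, and hit-table
#' runs whose hit sequences are already aligned (equal lengths with gaps)
#' skip it.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param query_id query id, forwarded to the alignment object.
#' @param aligner executable name or path.
#' @param alphabet optional alphabet override.
#' @return an `evo_msa`.
#' @export
align_with_external <- function(seqs, query_id, aligner = "mafft",
                                alphabet = NULL) {
  exe <- Sys.which(aligner)
  if (!nzchar(exe))
    evog_stop("evograde_external_tool_error",
              "aligner '%s' not found on PATH; supply a pre-aligned MSA instead",
              aligner)
  inf <- tempfile(fileext = ".fasta")
  outf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), inf)
  args <- if (grepl("mafft", basename(aligner))) c("--auto", "--quiet", inf)
          else inf
  status <- system2(exe, args, stdout = outf, stderr = FALSE)
  if (status != 0L || !file.exists(outf))
    evog_stop("evograde_external_tool_error",
              "aligner '%s' failed with status %d", aligner, status)
  read_alignment(outf, query_id = query_id, format = "fasta",
                 alphabet = alphabet)
}

#' Run the full pipeline
#'
#' Stages: homologue selection (hit-table mode only), alignment ingestion,
#' tree building or ingestion, gamma-shape estimation, posterior rates,
#' nine-grade binning, and optional structure mapping with script export.
#' Outputs written to `config$out_dir`: `msa.fasta`, `tree.nwk`,
#' `rates.tsv`, `grades.tsv`, `grades.json`, `run.log`, and, when a
#' structure is supplied, `graded.<ext>` plus `coloring.pml` /
#' `coloring.cxc`.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `alignment`, `tree`, `alpha`,
#'   `rates`, `grades`, `structure` (or NULL), `grade_maps` (or NULL),
#'   `config`, `files`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  set.seed(config$seed)

  # --- input stage -------------------------------------------------------
  if (!is.null(config$msa)) {
    log <- log_stage(log, "input: alignment %s (%s)", config$msa,
                     config$msa_format)
    aln <- read_alignment(config$msa, query_id = config$query_id,
                          format = config$msa_format,
                          alphabet = config$alphabet)
  } else {
    log <- log_stage(log, "input: hit table %s", config$hits)
    hits <- read_hits(config$hits, config$sequences,
                      format = config$hits_format,
                      query_length = config$query_length)
    log <- log_stage(log, "selection: %d hits in", nrow(hits))
    sel <- select_homologues(hits, config$query_id, config$selection)
    log <- log_stage(log, "selection: %d representatives out", nrow(sel))
    seqs <- setNames(sel$sequence, sel$subject_id)
    gap_free <- !grepl("-", seqs, fixed = TRUE)
    if (length(unique(nchar(seqs))) == 1L && !all(gap_free)) {
      # already aligned (equal lengths, gaps present)
      aln <- new_alignment(seqs, query_id = config$query_id,
                           alphabet = config$alphabet)
    } else if (length(unique(nchar(seqs))) == 1L && is.null(config$aligner)) {
      # equal-length gapless set: usable as a trivial alignment
      aln <- new_alignment(seqs, query_id = config$query_id,
                           alphabet = config$alphabet)
    } else {
      log <- log_stage(log, "alignment: external aligner '%s'",
                       config$aligner %||% "mafft")
      aln <- align_with_external(seqs, config$query_id,
                                 aligner = config$aligner %||% "mafft",
                                 alphabet = config$alphabet)
    }
  }
  enforce_counts(aln$mat, config$selection)
  log <- log_stage(log, "alignment: %d sequences x %d sites (%s)",
                   nrow(aln$mat), aln$n_sites, aln$alphabet)

  # --- tree stage --------------------------------------------------------
  if (!is.null(config$tree)) {
    log <- log_stage(log, "tree: reading %s", config$tree)
    tree <- read_newick(config$tree, aln)
  } else {
    log <- log_stage(log, "tree: neighbor joining on corrected distances")
    tree <- build_nj(pairwise_distances(aln))
  }

  # --- rates stage -------------------------------------------------------
  model <- build_model(aln$alphabet)
  alpha <- estimate_alpha(aln, tree, model, K = config$K)
  log <- log_stage(log, "rates: fitted gamma shape alpha = %.4f (K = %d)",
                   alpha, config$K)
  gamma <- discretize_gamma(alpha, config$K)
  rates <- posterior_rates(aln, tree, model, gamma,
                           ci_level = config$ci_level)
  grades <- grade_sites(rates, aln, scale = config$scale)
  log <- log_stage(log, "grading: %d query positions, %d flagged unreliable",
                   nrow(grades), sum(!grades$reliable))

  files <- list(
    msa = file.path(config$out_dir, "msa.fasta"),
    tree = file.path(config$out_dir, "tree.nwk"),
    rates = file.path(config$out_dir, "rates.tsv"),
    grades_tsv = file.path(config$out_dir, "grades.tsv"),
    grades_json = file.path(config$out_dir, "grades.json"),
    log = file.path(config$out_dir, "run.log"))
  write_alignment(aln, files$msa)
  write_newick(tree, files$tree)
  write_rates_tsv(rates, aln, files$rates)
  write_grades(grades, files$grades_tsv, files$grades_json)

  # --- structure stage ---------------------------------------------------
  struct <- NULL
  grade_maps <- NULL
  if (!is.null(config$structure)) {
    struct <- parse_structure(config$structure)
    chain <- config$chain %||% names(struct$chains)[1L]
    log <- log_stage(log, "structure: %s, mapping chain %s",
                     config$structure, chain)
    mapping <- map_query_to_chain(query_sequence(aln),
                                  chain_sequence(struct, chain),
                                  alphabet = aln$alphabet)
    log <- log_stage(log, "structure: query/chain identity %.3f",
                     mapping$identity)
    gm <- chain_grade_map(struct, chain, grades, mapping)
    grade_maps <- propagate_identical_chains(struct, chain, gm)
    log <- log_stage(log, "structure: grades on %d chain(s)",
                     length(grade_maps))
    ext <- if (struct$format == "pdb") "pdb" else "cif"
    files$graded_structure <- file.path(config$out_dir,
                                        paste0("graded.", ext))
    write_graded_structure(struct, grade_maps, files$graded_structure)
    script_paths <- emit_coloring_scripts(
      grade_maps, paste0("graded.", ext),
      file.path(config$out_dir, "coloring"), scale = config$scale)
    files$pml <- script_paths[1L]
    files$cxc <- script_paths[2L]
  }

  writeLines(log, files$log)
  structure(list(alignment = aln, tree = tree, alpha = alpha,
                 rates = rates, grades = grades, structure = struct,
                 grade_maps = grade_maps, config = config, files = files),
            class = "run_result")
}

#' Re-run the pipeline on a subtree
#'
#' Extracts the clade defined by `leaves` (with the query inside) from a
#' previous run's tree, restricts the alignment to those taxa, and re-runs
#' every downstream stage: shape fitting, posterior rates, and grading are
#' all recomputed on the subfamily alone. Useful for detecting functional
#' regions specific to a subfamily.
#'
#' @param result a `run_result` from [run_pipeline()].
#' @param leaves character vector of leaf names defining the clade.
#' @param out_dir output directory for the re-run.
#' @return a new `run_result`.
#' @export
run_subtree <- function(result, leaves,
                        out_dir = file.path(result$config$out_dir,
                                            "subtree")) {
  sub <- extract_subtree(result$tree, leaves, result$alignment,
                         min_homologues = result$config$selection$min_homologues)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msa_path <- file.path(out_dir, "input_msa.fasta")
  tree_path <- file.path(out_dir, "input_tree.nwk")
  write_alignment(sub$alignment, msa_path)
  write_newick(sub$tree, tree_path)
  cfg <- result$config
  cfg$msa <- msa_path
  cfg$msa_format <- "fasta"
  cfg$hits <- NULL
  cfg$sequences <- NULL
  cfg$tree <- tree_path
  cfg$out_dir <- out_dir
  run_pipeline(cfg)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "run_result: %d seqs x %d sites (%s), alpha = %.3f, %d query positions graded\n",
    nrow(x$alignment$mat), x$alignment$n_sites, x$alignment$alphabet,
    x$alpha, nrow(x$grades)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
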