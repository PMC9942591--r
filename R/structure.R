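#' @name structure_mapping
#' @title Structure parsing and conservation-grade mapping
#' @description Parses PDB and mmCIF coordinate files into a common chain
#'   model (including HETATM-flagged modified polymer residues such as
#'   selenomethionine), aligns the query onto a chain, writes grades into
#'   the temperature-factor column, propagates grades across identical
#'   chains of homo-oligomers, and emits PyMOL/ChimeraX coloring scripts.
NULL

.RES3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # nucleic acids (ribo and deoxy)
  A = "A", C = "C", G = "G", U = "U", I = "X",
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "X")

# Modified / non-standard polymer residues (HETATM records) mapped to the
# parent one-letter code; editable via options(evograde.modres = ...).
.MODRES <- c(
  MSE = "M", FME = "M", CXM = "M",
  SEC = "C", CSO = "C", CSD = "C", CME = "C", OCS = "C", CSX = "C",
  SMC = "C", SCH = "C",
  PYL = "K", MLY = "K", M3L = "K", ALY = "K", KCX = "K", MLZ = "K",
  LLP = "K",
  PTR = "Y", TYS = "Y", NIY = "Y",
  SEP = "S", SAC = "S", DHA = "S",
  TPO = "T",
  HYP = "P",
  HIC = "H", NEP = "H",
  PCA = "E", CGU = "E",
  DAH = "F",
  AIB = "A", ABA = "A",
  TRQ = "W", TRW = "W",
  UNK = "X",
  # modified nucleotides
  `5MC` = "C", OMC = "C", PSU = "U", H2U = "U", `4SU` = "U", `5MU` = "U",
  `1MA` = "A", `7MG` = "G", OMG = "G", `2MG` = "G", M2G = "G")

.WATERS <- c("HOH", "DOD", "WAT")

res_one_letter <- function(name3) {
  modres <- getOption("evograde.modres", .MODRES)
  out <- unname(.RES3TO1[name3])
  use_mod <- is.na(out)
  out[use_mod] <- unname(modres[name3[use_mod]])
  out[is.na(out)] <- "X"
  out
}

detect_structure_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(data_|_atom_site\\.|loop_)", head_lines))) "mmcif" else "pdb"
}

#' Parse a PDB or mmCIF structure
#'
#' Both formats yield the same chain model: for every chain, the ordered
#' polymer residues with author numbering, insertion codes, record kind
#' (ATOM/HETATM), and one-letter codes (HETATM-flagged modified residues
#' are translated through the shipped modified-residue table). Waters and
#' non-polymer HETATM groups (ligands, ions) are excluded from chain
#' sequences but preserved in the raw atom records for file write-through.
#' Where a residue has alternate locations, the highest-occupancy altloc
#' is kept.
#'
#' @param path structure file path.
#' @param format `"auto"` (extension, then content sniffing), `"pdb"`, or
#'   `"mmcif"`.
#' @return list of class `evo_structure`: `chains` (named list of
#'   residue data.frames: `resno`, `icode`, `name3`, `record_kind`,
#'   `one_letter`), `atom` (full atom table), `lines` (raw file lines),
#'   `format`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    evog_stop("evograde_parse_error", "structure file not found: %s", path)
  if (format == "auto") format <- detect_structure_format(path)
  obj <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                           verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) evog_stop("evograde_parse_error",
                                  "could not parse %s as %s: %s",
                                  path, format, conditionMessage(e)))
  atom <- obj$atom
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "

  # highest-occupancy altloc per (chain, residue, atom name)
  if (!all(is.na(atom$alt))) {
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    ord <- order(atom$chain, atom$resno, atom$insert, atom$elety, -occ)
    a2 <- atom[ord, ]
    dup <- duplicated(a2[, c("chain", "resno", "insert", "elety")])
    atom <- a2[!dup, ]
    atom <- atom[order(as.integer(rownames(atom))), ]
  }

  res <- unique(atom[, c("chain", "resno", "insert", "resid", "type")])
  has_ca <- with(atom, paste(chain, resno, insert)) %in%
    with(atom[atom$elety %in% c("CA", "C1'", "C1*"), ],
         paste(chain, resno, insert))
  names(has_ca) <- with(atom, paste(chain, resno, insert))
  polymer <- !(res$resid %in% .WATERS) &
    (res$resid %in% names(.RES3TO1) |
       res$resid %in% names(getOption("evograde.modres", .MODRES)) |
       has_ca[with(res, paste(chain, resno, insert))])
  res <- res[polymer, , drop = FALSE]
  if (nrow(res) == 0L)
    evog_stop("evograde_empty_structure_error",
              "no polymer residues found in %s", path)

  chains <- lapply(split(res, res$chain), function(r) {
    r <- r[order(r$resno, r$insert), , drop = FALSE]
    data.frame(resno = r$resno, icode = r$insert, name3 = r$resid,
               record_kind = r$type, one_letter = res_one_letter(r$resid),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(chains = chains, atom = atom,
                 lines = readLines(path, warn = FALSE), format = format,
                 path = path),
            class = "evo_structure")
}

#' @export
print.evo_structure <- function(x, ...) {
  cat(sprintf("evo_structure (%s): %d chain(s): %s\n", x$format,
              length(x$chains),
              paste(sprintf("%s (%d res)", names(x$chains),
                            vapply(x$chains, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' Includes HETATM-flagged modified residues via the modified-residue
#' table; unmapped residue names become `X`.
#'
#' @param model an `evo_structure`.
#' @param chain_id chain identifier.
#' @return single string.
#' @export
chain_sequence <- function(model, chain_id) {
  if (!chain_id %in% names(model$chains))
    evog_stop("evograde_unknown_chain_error",
              "no chain '%s' in structure (have: %s)", chain_id,
              paste(names(model$chains), collapse = ", "))
  paste(model$chains[[chain_id]]$one_letter, collapse = "")
}

#' Align the query sequence onto a structure chain
#'
#' Global alignment (proteins: BLOSUM62, gap open 10 / extend 0.5;
#' nucleotides: match 2 / mismatch -1, same gap costs). The mapping pairs
#' aligned non-gap positions of the two sequences; identity is computed
#' over aligned columns. An identity below 0.60 raises an error (the chain
#' is not the query's molecule); below 0.95 a warning is emitted.
#'
#' @param query_seq ungapped query string.
#' @param chain_seq chain one-letter string (see [chain_sequence()]).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return list with `map` (data.frame `query_pos`, `chain_pos`) and
#'   `identity`.
#' @export
map_query_to_chain <- function(query_seq, chain_seq,
                               alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  stopifnot(nzchar(query_seq), nzchar(chain_seq))
  if (alphabet == "protein") {
    sub <- "BLOSUM62"
  } else {
    ab <- sort(unique(c(strsplit(query_seq, "")[[1L]],
                        strsplit(chain_seq, "")[[1L]])))
    sub <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
    diag(sub) <- 2
  }
  al <- Biostrings::pairwiseAlignment(query_seq, chain_seq, type = "global",
                                      substitutionMatrix = sub,
                                      gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  ca <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  qpos <- cumsum(qa != "-")
  cpos <- cumsum(ca != "-")
  both <- qa != "-" & ca != "-"
  if (!any(both))
    evog_stop("evograde_mapping_error",
              "query and chain sequences do not align")
  identity <- sum(qa[both] == ca[both]) / sum(both)
  if (identity < 0.60)
    evog_stop("evograde_mapping_error",
              "query/chain identity %.2f < 0.60; not the same molecule",
              identity)
  if (identity < 0.95)
    evog_warn("query/chain identity %.2f below 0.95; check the chain choice",
              identity)
  list(map = data.frame(query_pos = qpos[both], chain_pos = cpos[both]),
       identity = identity)
}

#' Per-chain grade assignment for one chain
#'
#' Combines a grade table with a query-to-chain mapping into a
#' chain grade map: one row per chain residue carrying its grade (NA where
#' unmapped).
#'
#' @param model an `evo_structure`.
#' @param chain_id the chain the query was mapped to.
#' @param grades a `grade_table` (see [grade_sites()]).
#' @param mapping result of [map_query_to_chain()] for that chain.
#' @return data.frame: `chain_id`, `resno`, `icode`, `grade`.
#' @export
chain_grade_map <- function(model, chain_id, grades, mapping) {
  res <- model$chains[[chain_id]]
  g <- rep(NA_integer_, nrow(res))
  hit <- match(mapping$map$query_pos, grades$query_position)
  ok <- !is.na(hit)
  g[mapping$map$chain_pos[ok]] <- grades$grade[hit[ok]]
  data.frame(chain_id = chain_id, resno = res$resno, icode = res$icode,
             grade = g, stringsAsFactors = FALSE)
}

#' Propagate grades across identical chains
#'
#' Every chain whose one-letter sequence is byte-identical to the graded
#' chain's receives the same per-position grades (the homo-oligomer case);
#' non-identical chains are untouched. Idempotent and independent of chain
#' order.
#'
#' @param model an `evo_structure`.
#' @param graded_chain_id chain the grades were computed for.
#' @param grade_map output of [chain_grade_map()] for that chain.
#' @return list of per-chain grade maps (the graded chain first).
#' @export
propagate_identical_chains <- function(model, graded_chain_id, grade_map) {
  ref_seq <- chain_sequence(model, graded_chain_id)
  others <- setdiff(names(model$chains), graded_chain_id)
  maps <- list(grade_map)
  for (ch in others) {
    if (identical(chain_sequence(model, ch), ref_seq)) {
      res <- model$chains[[ch]]
      maps[[length(maps) + 1L]] <-
        data.frame(chain_id = ch, resno = res$resno, icode = res$icode,
                   grade = grade_map$grade, stringsAsFactors = FALSE)
    }
  }
  maps
}

# grade lookup environment keyed by "chain|resno|icode"
grade_env <- function(grade_maps) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (gm in grade_maps) {
    ok <- !is.na(gm$grade)
    keys <- sprintf("%s|%d|%s", gm$chain_id, gm$resno[ok],
                    trimws(gm$icode[ok]))
    for (i in seq_along(keys)) assign(keys[i], gm$grade[ok][i], envir = env)
  }
  env
}

#' Write grades into the temperature-factor column
#'
#' Produces a copy of the input structure file in which the temperature
#' factor (B-factor) of every atom in a mapped residue equals its
#' conservation grade; atoms of unmapped residues (ligands, waters,
#' ungraded chains) get 0.00. Everything else in the file is preserved.
#' PDB output writes `%6.2f` into columns 61-66; mmCIF output replaces the
#' `B_iso_or_equiv` field of each `atom_site` row.
#'
#' @param model an `evo_structure`.
#' @param grade_maps list of chain grade maps (see
#'   [propagate_identical_chains()]).
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
write_graded_structure <- function(model, grade_maps, out_path) {
  env <- grade_env(grade_maps)
  if (length(ls(env)) == 0L)
    evog_stop("evograde_mapping_error", "no mapped residues to write")
  lines <- model$lines
  out <- if (model$format == "pdb") {
    rewrite_pdb_bfactors(lines, env)
  } else {
    rewrite_mmcif_bfactors(lines, env)
  }
  writeLines(out, out_path)
  invisible(out_path)
}

rewrite_pdb_bfactors <- function(lines, env) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 66L) ln <- formatC(ln, width = -66L)
    key <- sprintf("%s|%d|%s",
                   substr(ln, 22L, 22L),
                   as.integer(substr(ln, 23L, 26L)),
                   trimws(substr(ln, 27L, 27L)))
    g <- if (exists(key, envir = env, inherits = FALSE))
      get(key, envir = env) else 0
    substr(ln, 61L, 66L) <- sprintf("%6.2f", g)
    lines[i] <- ln
  }
  lines
}

rewrite_mmcif_bfactors <- function(lines, env) {
  fields <- grep("^_atom_site\\.", lines)
  if (!length(fields))
    evog_stop("evograde_parse_error", "no _atom_site loop in mmCIF input")
  field_names <- sub("^_atom_site\\.", "", trimws(lines[fields]))
  b_idx <- match("B_iso_or_equiv", field_names)
  chain_idx <- match("auth_asym_id", field_names)
  if (is.na(chain_idx)) chain_idx <- match("label_asym_id", field_names)
  seq_idx <- match("auth_seq_id", field_names)
  if (is.na(seq_idx)) seq_idx <- match("label_seq_id", field_names)
  ins_idx <- match("pdbx_PDB_ins_code", field_names)
  if (is.na(b_idx) || is.na(chain_idx) || is.na(seq_idx))
    evog_stop("evograde_parse_error",
              "atom_site loop lacks B_iso_or_equiv/asym_id/seq_id fields")

  i <- max(fields) + 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|loop_|_|data_)", ln) || !nzchar(trimws(ln))) break
    toks <- regmatches(ln, gregexpr("\\S+", ln))[[1L]]
    pos <- gregexpr("\\S+", ln)[[1L]]
    if (length(toks) >= b_idx) {
      ins <- if (!is.na(ins_idx)) toks[ins_idx] else "?"
      if (ins %in% c("?", ".")) ins <- ""
      key <- sprintf("%s|%d|%s", toks[chain_idx],
                     suppressWarnings(as.integer(toks[seq_idx])), ins)
      g <- if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env) else 0
      new_tok <- sprintf("%.2f", g)
      start <- pos[b_idx]
      end <- start + attr(pos, "match.length")[b_idx] - 1L
      lines[i] <- paste0(substr(ln, 1L, start - 1L), new_tok,
                         substr(ln, end + 1L, nchar(ln)))
    }
    i <- i + 1L
  }
  lines
}

#' Emit PyMOL and ChimeraX coloring scripts
#'
#' Plain-text command scripts (`.pml` and `.cxc`) that load the graded
#' structure file (by relative path), define the nine-grade color scale,
#' and color every mapped residue by its grade. An empty grade map yields
#' a no-op script with an explanatory header.
#'
#' @param grade_maps list of chain grade maps.
#' @param structure_file relative path of the graded structure file, as
#'   referenced from the scripts.
#' @param out_prefix path prefix for the two scripts (`<prefix>.pml`,
#'   `<prefix>.cxc`).
#' @param scale color scale (see [colorize()]).
#' @return character vector of the two script paths, invisibly.
#' @export
emit_coloring_scripts <- function(grade_maps, structure_file, out_prefix,
                                  scale = c("standard", "color_blind")) {
  scale <- match.arg(scale)
  tab <- if (scale == "standard") .COLORS_STANDARD else .COLORS_BLIND
  all_maps <- do.call(rbind, grade_maps)
  all_maps <- all_maps[!is.na(all_maps$grade), , drop = FALSE]

  pml <- c("# PyMOL coloring script: residues colored by conservation grade",
           sprintf("# scale: %s (grade 1 = variable ... 9 = conserved)", scale))
  cxc <- c("# ChimeraX coloring script: residues colored by conservation grade",
           sprintf("# scale: %s (grade 1 = variable ... 9 = conserved)", scale))
  if (nrow(all_maps) > 0L) {
    pml <- c(pml, sprintf("load %s, graded", structure_file),
             "hide everything, graded", "show cartoon, graded",
             "color gray70, graded")
    cxc <- c(cxc, sprintf("open %s", structure_file), "color gray(70)")
    for (g in sort(unique(all_maps$grade))) {
      rgb <- tab[g, ]
      pml <- c(pml, sprintf("set_color grade_%d, [%.4f, %.4f, %.4f]",
                            g, rgb[1L] / 255, rgb[2L] / 255, rgb[3L] / 255))
      sel_parts <- character(0)
      cxc_specs <- character(0)
      for (ch in unique(all_maps$chain_id[all_maps$grade == g])) {
        resi <- all_maps$resno[all_maps$grade == g & all_maps$chain_id == ch]
        sel_parts <- c(sel_parts,
                       sprintf("(chain %s and resi %s)", ch,
                               paste(resi, collapse = "+")))
        cxc_specs <- c(cxc_specs,
                       sprintf("/%s:%s", ch, paste(resi, collapse = ",")))
      }
      pml <- c(pml,
               sprintf("select sel_grade_%d, graded and (%s)", g,
                       paste(sel_parts, collapse = " or ")),
               sprintf("color grade_%d, sel_grade_%d", g, g))
      cxc <- c(cxc, sprintf("color %s rgb(%d,%d,%d)",
                            paste(cxc_specs, collapse = ""),
                            rgb[1L], rgb[2L], rgb[3L]))
    }
    pml <- c(pml, "deselect")
  } else {
    pml <- c(pml, "# no graded residues")
    cxc <- c(cxc, "# no graded residues")
  }
  paths <- paste0(out_prefix, c(".pml", ".cxc"))
  writeLines(pml, paths[1L])
  writeLines(cxc, paths[2L])
  invisible(paths)
}
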