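# Shared fixtures and independent oracles, all built in code at test time.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

# Brute-force site likelihood by exhaustive enumeration of internal-node
# states; independent of the pruning implementation. Missing leaves ('-',
# 'X', 'N') marginalize to 1 by skipping their edge factor.
bf_site_loglik <- function(tree, column, model, r = 1) {
  ntip <- length(tree$tip.label)
  k <- length(model$states)
  nn <- tree$Nnode
  obs <- match(toupper(column[tree$tip.label]), model$states)
  Plist <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, r * tree$edge.length[e]))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tot <- 0
  for (ci in seq_len(nrow(combos))) {
    st <- integer(ntip + nn)
    st[ntip + seq_len(nn)] <- combos[ci, ]
    st[seq_len(ntip)] <- obs
    p <- model$pi[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      child <- tree$edge[e, 2L]
      if (child <= ntip && is.na(st[child])) next  # missing leaf sums to 1
      p <- p * Plist[[e]][st[tree$edge[e, 1L]], st[child]]
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# Synthetic homologue hit table: a base sequence mutated to target
# identities, one cluster per hit at the default redundancy threshold.
make_synthetic_hits <- function(n, L = 120, seed = 99,
                                id_range = c(0.40, 0.90)) {
  set.seed(seed)
  base <- sample(AA20, L, replace = TRUE)
  ids <- c("query", sprintf("h%04d", seq_len(n - 1L)))
  u <- c(1, runif(n - 1L, id_range[1L], id_range[2L]))
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    if (i > 1L) {
      nm <- round((1 - u[i]) * L)
      pos <- sample(L, nm)
      s[pos] <- sample(AA20, nm, replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  hit_table(ids, c(0, 10^-(300 * (u[-1L] - 0.35))), u, rep(1, n), seqs)
}

# --- structure fixtures --------------------------------------------------

pdb_atom_line <- function(record, serial, name, resn, chain, resno,
                          x = 1, y = 2, z = 3, occ = 1, b = 0,
                          elem = substr(trimws(name), 1L, 1L),
                          alt = " ", icode = " ") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resn, chain, resno, icode,
          x, y, z, occ, b, elem)
}

# homo-dimer (chains A and B, sequence AGMKL with a selenomethionine),
# a divergent chain C (AGS), a zinc ligand, and a water
test_structure_residues <- function() {
  list(
    A = data.frame(resn = c("ALA", "GLY", "MSE", "LYS", "LEU"),
                   resno = 1:5,
                   record = c("ATOM", "ATOM", "HETATM", "ATOM", "ATOM")),
    B = data.frame(resn = c("ALA", "GLY", "MSE", "LYS", "LEU"),
                   resno = 1:5,
                   record = c("ATOM", "ATOM", "HETATM", "ATOM", "ATOM")),
    C = data.frame(resn = c("ALA", "GLY", "SER"),
                   resno = 1:3,
                   record = c("ATOM", "ATOM", "ATOM")))
}

write_test_pdb <- function(path) {
  res <- test_structure_residues()
  lines <- c("HEADER    SYNTHETIC TEST STRUCTURE                XXXX")
  serial <- 0L
  for (ch in names(res)) {
    r <- res[[ch]]
    for (i in seq_len(nrow(r))) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(r$record[i], serial, at, r$resn[i],
                                        ch, r$resno[i],
                                        x = serial, y = serial + 0.5,
                                        z = serial + 0.25, b = 20))
      }
    }
  }
  serial <- serial + 1L
  lines <- c(lines, pdb_atom_line("HETATM", serial, "ZN", "ZN", "A", 100L,
                                  b = 30, elem = "ZN"))
  serial <- serial + 1L
  lines <- c(lines, pdb_atom_line("HETATM", serial, "O", "HOH", "A", 201L,
                                  b = 40, elem = "O"))
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  path
}

write_test_cif <- function(path) {
  res <- test_structure_residues()
  hdr <- c("data_synthetic_test",
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- character(0)
  serial <- 0L
  cif_row <- function(record, serial, elem, at, resn, chain, resno, b) {
    sprintf("%-6s %-4d %-2s %-3s . %-3s %s 1 %-3d ? %8.3f %8.3f %8.3f 1.00 %6.2f ? %-3d %-3s %s %-3s 1",
            record, serial, elem, at, resn, chain, resno,
            serial + 0.0, serial + 0.5, serial + 0.25, b, resno, resn,
            chain, at)
  }
  for (ch in names(res)) {
    r <- res[[ch]]
    for (i in seq_len(nrow(r))) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1L
        rows <- c(rows, cif_row(r$record[i], serial, substr(at, 1L, 1L),
                                at, r$resn[i], ch, r$resno[i], 20))
      }
    }
  }
  serial <- serial + 1L
  rows <- c(rows, cif_row("HETATM", serial, "ZN", "ZN", "ZN", "A", 100L, 30))
  serial <- serial + 1L
  rows <- c(rows, cif_row("HETATM", serial, "O", "O", "HOH", "A", 201L, 40))
  writeLines(c(hdr, rows, "#"), path)
  path
}

# grade table stub covering query positions 1..n
stub_grades <- function(grades) {
  structure(data.frame(query_position = seq_along(grades),
                       residue = rep("A", length(grades)),
                       site = seq_along(grades),
                       score = 0, grade = as.integer(grades),
                       ci_grade_low = as.integer(grades),
                       ci_grade_high = as.integer(grades),
                       reliable = TRUE, color = "#FFFFFF",
                       stringsAsFactors = FALSE),
            class = c("grade_table", "data.frame"))
}
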