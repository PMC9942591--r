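test_that("PDB and mmCIF parses of equivalent content agree", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_test_pdb(pdb)
  write_test_cif(cif)
  sp <- parse_structure(pdb)
  sc <- parse_structure(cif)
  expect_identical(sp$format, "pdb")
  expect_identical(sc$format, "mmcif")
  expect_identical(names(sp$chains), names(sc$chains))
  for (ch in names(sp$chains)) {
    a <- sp$chains[[ch]][, c("resno", "name3", "record_kind", "one_letter")]
    b <- sc$chains[[ch]][, c("resno", "name3", "record_kind", "one_letter")]
    expect_identical(a, b)
  }
  # waters and the zinc ligand are excluded from polymer chains
  expect_identical(nrow(sp$chains[["A"]]), 5L)
})

test_that("chain sequences include HETATM-flagged modified residues", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  s <- parse_structure(pdb)
  expect_identical(chain_sequence(s, "A"), "AGMKL")   # MSE -> M
  expect_identical(chain_sequence(s, "C"), "AGS")
  expect_error(chain_sequence(s, "Z"), class = "evograde_unknown_chain_error")
  # unknown residue names fall back to X
  expect_identical(evograde:::res_one_letter(c("ALA", "UNK", "QQQ", "PTR")),
                   c("A", "X", "X", "Y"))
})

test_that("a water-only file is rejected as empty", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line("HETATM", 1, "O", "HOH", "A", 1),
               pdb_atom_line("HETATM", 2, "O", "HOH", "A", 2), "END"), pdb)
  expect_error(parse_structure(pdb), class = "evograde_empty_structure_error")
})

test_that("query-to-chain mapping handles offsets and dissimilarity", {
  q <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  m1 <- map_query_to_chain(q, q)
  expect_equal(m1$identity, 1)
  expect_identical(m1$map$query_pos, m1$map$chain_pos)
  # expression-tag cleavage: chain missing the first five residues
  m2 <- map_query_to_chain(q, substr(q, 6, nchar(q)))
  expect_equal(m2$identity, 1)
  expect_identical(m2$map$query_pos, m2$map$chain_pos + 5L)
  # a diverged but homologous chain warns
  qc <- strsplit(q, "")[[1]]
  qc[seq(1, 30, by = 4)] <- "A"
  expect_warning(map_query_to_chain(q, paste(qc, collapse = "")), "identity")
  # unrelated sequence errors
  expect_error(
    suppressWarnings(map_query_to_chain(q, strrep("WC", 20))),
    class = "evograde_mapping_error")
})

test_that("grades propagate across byte-identical chains only", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  s <- parse_structure(pdb)
  grades <- stub_grades(c(9L, 7L, 5L, 3L, 1L))
  mapping <- map_query_to_chain("AGMKL", chain_sequence(s, "A"))
  gm <- chain_grade_map(s, "A", grades, mapping)
  maps <- propagate_identical_chains(s, "A", gm)
  expect_identical(vapply(maps, function(m) m$chain_id[1], ""), c("A", "B"))
  expect_identical(maps[[2]]$grade, gm$grade)
  # propagation is idempotent: regrading from B gives the same pair
  maps2 <- propagate_identical_chains(s, "B", maps[[2]])
  expect_setequal(vapply(maps2, function(m) m$chain_id[1], ""), c("A", "B"))
  # chain C differs -> untouched
  expect_false("C" %in% vapply(maps, function(m) m$chain_id[1], ""))
})

test_that("grades written to B-factor columns round-trip exactly", {
  for (fmt in c("pdb", "cif")) {
    src <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "pdb") write_test_pdb(src) else write_test_cif(src)
    s <- parse_structure(src)
    grades <- stub_grades(c(9L, 7L, 5L, 3L, 1L))
    mapping <- map_query_to_chain("AGMKL", chain_sequence(s, "A"))
    gm <- chain_grade_map(s, "A", grades, mapping)
    maps <- propagate_identical_chains(s, "A", gm)
    out <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graded_structure(s, maps, out)
    back <- parse_structure(out)
    atoms <- back$atom
    for (i in seq_len(5)) {
      for (ch in c("A", "B")) {
        b <- atoms$b[atoms$chain == ch & atoms$resno == i]
        expect_equal(unname(b), rep(gm$grade[i], length(b)))
      }
    }
    # unmapped ligand/water atoms carry 0.00
    expect_equal(unique(atoms$b[atoms$resno %in% c(100, 201)]), 0)
    # chain C was not graded
    expect_equal(unique(atoms$b[atoms$chain == "C"]), 0)
    # content preserved outside the B-factor field
    expect_identical(back$chains, s$chains)
  }
})

test_that("highest-occupancy altloc wins", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line("ATOM", 1, "N", "ALA", "A", 1),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 1, occ = 0.3, alt = "A",
                  x = 1),
    pdb_atom_line("ATOM", 3, "CA", "ALA", "A", 1, occ = 0.7, alt = "B",
                  x = 9),
    pdb_atom_line("ATOM", 4, "C", "ALA", "A", 1),
    pdb_atom_line("ATOM", 5, "N", "GLY", "A", 2),
    pdb_atom_line("ATOM", 6, "CA", "GLY", "A", 2),
    pdb_atom_line("ATOM", 7, "C", "GLY", "A", 2),
    "END"), pdb)
  s <- parse_structure(pdb)
  ca <- s$atom[s$atom$elety == "CA" & s$atom$resno == 1, ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$o, 0.7)
})

test_that("coloring scripts cover every present grade in both dialects", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  s <- parse_structure(pdb)
  grades <- stub_grades(c(9L, 7L, 5L, 3L, 1L))
  mapping <- map_query_to_chain("AGMKL", chain_sequence(s, "A"))
  maps <- propagate_identical_chains(s, "A",
                                     chain_grade_map(s, "A", grades, mapping))
  prefix <- withr::local_tempfile()
  paths <- emit_coloring_scripts(maps, "graded.pdb", prefix)
  pml <- readLines(paths[1])
  cxc <- readLines(paths[2])
  for (g in c(1, 3, 5, 7, 9)) {
    expect_true(any(grepl(sprintf("set_color grade_%d", g), pml)))
    expect_true(any(grepl(sprintf("color grade_%d", g), pml)))
  }
  expect_length(grep("^color /", cxc), 5L)
  expect_true(any(grepl("load graded.pdb", pml)))
  # color-blind scale swaps the RGB table
  paths_cb <- emit_coloring_scripts(maps, "graded.pdb",
                                    paste0(prefix, "_cb"),
                                    scale = "color_blind")
  expect_false(identical(readLines(paths[1]), readLines(paths_cb[1])))
  # empty grade map -> no-op script with a header
  empty <- list(data.frame(chain_id = character(0), resno = integer(0),
                           icode = character(0), grade = integer(0)))
  p0 <- emit_coloring_scripts(empty, "graded.pdb", paste0(prefix, "_0"))
  expect_true(any(grepl("no graded residues", readLines(p0[1]))))
})
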