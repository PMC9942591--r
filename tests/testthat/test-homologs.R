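test_that("hits sort by E-value with lexicographic id tie-break", {
  h <- hit_table(c("c", "B", "A"), c(1e-3, 1e-50, 1e-10),
                 c(0.5, 0.6, 0.7), c(1, 1, 1),
                 c("MKLV", "MKLV", "MKLV"))
  expect_identical(sort_hits(h)$subject_id, c("B", "A", "c"))
  tie <- hit_table(c("B", "A"), c(1e-5, 1e-5), c(0.5, 0.5), c(1, 1),
                   c("MKLV", "MKLV"))
  expect_identical(sort_hits(tie)$subject_id, c("A", "B"))
  empty <- hit_table(character(0), numeric(0), numeric(0), numeric(0),
                     character(0))
  expect_identical(nrow(sort_hits(empty)), 0L)
})

test_that("similarity-bound filtering keeps in-range hits and the query", {
  h <- hit_table(c("q", "lo", "hi", "a", "b", "shallow"),
                 c(0, 1, 2, 3, 4, 5),
                 c(1.00, 0.30, 0.97, 0.40, 0.50, 0.96),
                 c(1, 1, 1, 1, 1, 0.3),
                 rep("MKLV", 6))
  kept <- filter_hits(h, selection_config(), query_id = "q")
  expect_identical(kept$subject_id, c("q", "a", "b"))
  # identities {0.40, 0.50, 0.96} with full coverage -> 2 retained
  h2 <- h[h$subject_id %in% c("a", "b", "hi"), ]
  expect_identical(nrow(filter_hits(h2, selection_config())), 2L)
})

test_that("greedy clustering groups by identity to the representative", {
  base <- strrep("AR", 50)                      # 100 columns
  one_mm <- paste0("G", substr(base, 2, 100))   # identity 0.99
  half <- paste0(strrep("GG", 25), substr(base, 51, 100))  # identity ~0.5
  h <- sort_hits(hit_table(c("s", "s1", "sHalf"), c(1e-30, 1e-20, 1e-10),
                           c(0.9, 0.9, 0.5), c(1, 1, 1),
                           c(base, one_mm, half)))
  cl <- cluster_redundant(h, 0.95)
  expect_length(cl, 2L)
  expect_identical(cl[[1]]$representative, "s")
  expect_setequal(cl[[1]]$members, c("s", "s1"))
  expect_identical(cl[[2]]$members, "sHalf")
})

test_that("identical sequences collapse to one cluster, distinct stay apart", {
  same <- hit_table(sprintf("s%d", 1:5), (1:5) * 1e-10, rep(0.9, 5),
                    rep(1, 5), rep(strrep("MKLVVA", 20), 5))
  cl <- cluster_redundant(sort_hits(same), 0.95)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 5L)
  set.seed(3)
  distinct <- hit_table(sprintf("d%d", 1:3), (1:3) * 1e-5, rep(0.5, 3),
                        rep(1, 3),
                        vapply(1:3, function(i)
                          paste(sample(AA20, 80, TRUE), collapse = ""), ""))
  expect_length(cluster_redundant(sort_hits(distinct), 0.95), 3L)
})

test_that("every member matches its own representative at the threshold", {
  h <- sort_hits(make_synthetic_hits(60, L = 80, seed = 4,
                                     id_range = c(0.85, 0.999)))
  cl <- cluster_redundant(h, 0.95)
  for (c1 in cl) {
    rep_seq <- h$sequence[h$subject_id == c1$representative]
    for (m in c1$members) {
      m_seq <- h$sequence[h$subject_id == m]
      ident <- sum(strsplit(rep_seq, "")[[1]] == strsplit(m_seq, "")[[1]]) /
        nchar(rep_seq)
      al <- Biostrings::pairwiseAlignment(rep_seq, m_seq, type = "global")
      expect_gte(max(ident, Biostrings::nmatch(al) / nchar(rep_seq)), 0.95)
    }
  }
  # representatives carry the smallest E-value of their cluster
  for (c1 in cl) {
    evs <- h$e_value[match(c1$members, h$subject_id)]
    expect_equal(h$e_value[h$subject_id == c1$representative], min(evs))
  }
})

test_that("representative selection strides evenly and keeps the query", {
  h <- sort_hits(make_synthetic_hits(10, L = 60, seed = 8))
  cl <- cluster_redundant(h, 0.95)
  expect_length(cl, 10L)
  sel <- select_representatives(cl, h, "query", n = 5L)
  # stride indices floor(i*10/5) = 0,2,4,6,8 (1-based: 1,3,5,7,9)
  reps <- vapply(cl, `[[`, "", "representative")
  expect_identical(sel$subject_id, reps[c(1, 3, 5, 7, 9)])
  expect_true("query" %in% sel$subject_id)
  # fewer clusters than target: all returned
  sel_all <- select_representatives(cl, h, "query", n = 150L)
  expect_identical(nrow(sel_all), 10L)
})

test_that("selection size is min(n, #clusters) and query always survives", {
  h <- sort_hits(make_synthetic_hits(40, L = 60, seed = 12))
  cl <- cluster_redundant(h, 0.95)
  for (n in c(3L, 10L, 39L, 80L)) {
    sel <- select_representatives(cl, h, "query", n = n)
    expect_identical(nrow(sel), min(n, length(cl)))
    expect_true("query" %in% sel$subject_id)
  }
})

test_that("count policy: error below 5, warnings below 50 and above 300", {
  few <- make_synthetic_hits(4)
  expect_error(enforce_counts(few, selection_config()),
               class = "evograde_too_few_homologues_error")
  expect_warning(enforce_counts(make_synthetic_hits(30), selection_config()),
                 "not recommended")
  expect_warning(
    enforce_counts(make_synthetic_hits(301, L = 30), selection_config()),
    "exceed")
  expect_silent(enforce_counts(data.frame(x = 1:150), selection_config()))
})

test_that("selection output is identical for any input order of hits", {
  h <- make_synthetic_hits(120, L = 60, seed = 21)
  sel1 <- suppressWarnings(select_homologues(h, "query"))
  set.seed(1)
  h2 <- h[sample(nrow(h)), ]
  rownames(h2) <- NULL
  sel2 <- suppressWarnings(select_homologues(h2, "query"))
  rownames(sel1) <- rownames(sel2) <- NULL
  expect_identical(sel1, sel2)
})

test_that("hit tables read from BLAST tabular and generic TSV layouts", {
  seq_f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">h1", "MKLVWAAG", ">h2", "MKLVWAAR"), seq_f)
  tab_f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q\th1\t90.0\t8\t1\t0\t1\t8\t1\t8\t1e-30\t50.1",
               "q\th2\t45.0\t8\t4\t0\t1\t4\t1\t4\t1e-5\t20.2"), tab_f)
  h <- read_hits(tab_f, seq_f, query_length = 8)
  expect_equal(h$identity_to_query, c(0.90, 0.45))
  expect_equal(h$coverage_of_query, c(1, 0.5))
  writeLines(c("h1\t1e-30\t90\t100", "h2\t1e-5\t45\t50"), tab_f)
  g <- read_hits(tab_f, seq_f, format = "tsv")
  expect_equal(g$identity_to_query, c(0.90, 0.45))
  expect_equal(g$coverage_of_query, c(1, 0.5))
  # id-only tables (missing sequences) are rejected
  writeLines(c("h1\t1e-30\t90\t100", "h9\t1e-5\t45\t50"), tab_f)
  expect_error(read_hits(tab_f, seq_f, format = "tsv"),
               class = "evograde_missing_sequence_error")
})
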