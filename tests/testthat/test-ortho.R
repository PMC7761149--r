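# Protein alignment, residue/column maps, window matching, classes 0-4.

test_that("the editing score matrix treats '*' and 'X' as specified", {
  m <- editing_score_matrix()
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  lo <- min(e$BLOSUM62)
  not_x <- setdiff(colnames(m), "X")
  expect_true(all(m["*", not_x] == lo))
  expect_true(all(m[not_x, "*"] == lo))
  expect_true(all(m["X", ] == 0))   # X scores 0 against anything, even '*'
  expect_true(all(m[, "X"] == 0))
  expect_equal(m["W", "W"], e$BLOSUM62["W", "W"])
})

test_that("identical sequences align gap-free with the diagonal score", {
  m <- editing_score_matrix()
  a <- align_global("MKVLW", "MKVLW")
  expect_equal(a$aligned_query, "MKVLW")
  expect_equal(a$aligned_ref, "MKVLW")
  expect_equal(a$score, sum(diag(m[strsplit("MKVLW", "")[[1]],
                                   strsplit("MKVLW", "")[[1]]])))
})

test_that("alignment is optimal and degapping reproduces the inputs", {
  m <- editing_score_matrix()
  a <- align_global("MKV", "MV")
  expect_equal(a$score, exhaustive_align_score("MKV", "MV", m))
  expect_equal(gsub("-", "", a$aligned_query), "MKV")
  expect_equal(gsub("-", "", a$aligned_ref), "MV")
  expect_equal(nchar(a$aligned_query), nchar(a$aligned_ref))
  # score symmetry
  expect_equal(align_global("MKV", "MV")$score, align_global("MV", "MKV")$score)
  expect_error(align_global("", "MV"), "empty")
})

test_that("alignment equals the exhaustive oracle on short random pairs", {
  m <- editing_score_matrix()
  alphabet <- c("A", "R", "N", "D")
  withr::with_seed(21L, {
    for (rep in 1:12) {
      a <- paste(sample(alphabet, sample(2:6, 1L), replace = TRUE), collapse = "")
      b <- paste(sample(alphabet, sample(2:6, 1L), replace = TRUE), collapse = "")
      got <- align_global(a, b)
      expect_equal(got$score, exhaustive_align_score(a, b, m),
                   info = paste(a, b))
      # the emitted alignment really has the reported score
      expect_equal(score_alignment(got$aligned_query, got$aligned_ref, m),
                   got$score, info = paste(a, b))
    }
  })
})

test_that("column_of and residue_at are mutually inverse", {
  aln <- structure(list(aligned_query = "M-KV", aligned_ref = "MLKV", score = 0),
                   class = "pairwise_alignment")
  expect_equal(column_of(aln, "query", 2L), 3L)  # the 'K'
  expect_equal(residue_at(aln, "query", 2L), NA_integer_)
  for (p in 1:3) expect_equal(residue_at(aln, "query", column_of(aln, "query", p)), p)
  for (p in 1:4) expect_equal(residue_at(aln, "ref", column_of(aln, "ref", p)), p)
  expect_error(column_of(aln, "query", 4L), "out of range")

  nogap <- align_global("MKVL", "MKVL")
  for (p in 1:4) expect_equal(column_of(nogap, "query", p), p)
})

test_that("classification covers the full truth table exactly", {
  # brute force over (query synonymous) x (ref synonymous) x (pre-match) x
  # (post-match), constructing residues from scratch
  for (q_syn in c(TRUE, FALSE)) for (r_syn in c(TRUE, FALSE)) {
    for (pre_match in c(TRUE, FALSE)) for (post_match in c(TRUE, FALSE)) {
      q_pre <- "K"
      q_post <- if (q_syn) "K" else "R"
      r_pre <- if (pre_match) q_pre else "S"
      r_post <- if (post_match) q_post else "E"
      if (r_syn && r_pre != r_post) next  # unconstructible combination
      if (!r_syn && r_pre == r_post) next
      got <- classify_conservation(q_pre, q_post, q_syn, r_pre, r_post, r_syn)
      want <- if (q_syn && r_syn) 0L
              else if (pre_match && post_match) 1L
              else if (!pre_match && post_match) 2L
              else if (pre_match && !post_match) 3L
              else 4L
      expect_equal(got, want,
                   info = sprintf("qsyn=%s rsyn=%s pre=%s post=%s",
                                  q_syn, r_syn, pre_match, post_match))
    }
  }
  # spec'd spot checks
  expect_equal(classify_conservation("K", "R", FALSE, "K", "R", FALSE), 1L)
  expect_equal(classify_conservation("N", "D", FALSE, "S", "D", FALSE), 2L)
  expect_equal(classify_conservation("K", "R", FALSE, "K", "E", FALSE), 3L)
  expect_equal(classify_conservation("Q", "R", FALSE, "H", "K", FALSE), 4L)
  expect_equal(classify_conservation("A", "A", TRUE, "G", "G", TRUE), 0L)
})

match_case <- function(site_pos, windows = c(0, 1, 5, Inf)) {
  prot <- strrep("K", 20L)
  hits <- data.frame(event_id = "s1|100", scaffold = "s1", pos = 100L,
                     ref = "A", alt = "G", transcript_id = "q1", gene_id = "gq",
                     tx_strand = "+", cds_pos = 28L, codon_pos = 1L, aa_pos = 10L,
                     ref_codon = "AAA", edited_codon = "GAA", ref_aa = "K",
                     edited_aa = "E", synonymous = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(ref_gene_id = "gr", ref_isoform_id = "r1",
                      aa_pos = site_pos, pre_aa = "K", post_aa = "E",
                      source_tag = "", stringsAsFactors = FALSE)
  pairs <- data.frame(query_gene_id = "gq", ref_gene_id = "gr",
                      stringsAsFactors = FALSE)
  match_events(hits, sites, pairs, c(q1 = prot), c(r1 = prot), windows = windows)
}

test_that("window matching emits one call per site within each window", {
  # distance 0: present at every window
  calls <- match_case(10L)
  expect_equal(sort(calls$window), c(0, 1, 5, Inf))
  expect_true(all(calls$aligned_distance == 0))
  expect_true(all(calls$cls == 1L))
  # distance 3: excluded from windows 0 and 1, kept at 5 and Inf
  calls <- match_case(13L)
  expect_equal(sort(calls$window), c(5, Inf))
  # distance 8: only the infinite window accepts it
  calls <- match_case(18L)
  expect_equal(calls$window, Inf)
  expect_equal(calls$aligned_distance, 8)
})

test_that("several reference sites within the window all produce calls", {
  calls <- match_case(c(9L, 10L, 11L), windows = 1)
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$ref_aa_pos, c(9L, 10L, 11L))
})

test_that("class counts deduplicate by event and keep window nesting", {
  calls <- rbind(
    data.frame(event_id = "e1", window = 0, cls = 1L),
    data.frame(event_id = "e1", window = 0, cls = 3L),   # second isoform
    data.frame(event_id = "e2", window = 0, cls = 4L),
    data.frame(event_id = "e1", window = 5, cls = 1L),
    data.frame(event_id = "e1", window = 5, cls = 3L),
    data.frame(event_id = "e2", window = 5, cls = 4L),
    data.frame(event_id = "e3", window = 5, cls = 2L))
  tab <- class_count_table(calls)
  w0 <- tab[tab$window == 0, ]
  expect_equal(w0$class_1, 1L)
  expect_equal(w0$class_3, 1L)
  expect_equal(w0$total, 2L)   # e1 counted once despite two classes
  expect_true(all(diff(tab$total) >= 0L))

  empty <- class_count_table(data.frame(event_id = character(),
                                        window = numeric(), cls = integer()),
                             windows = c(0, 1))
  expect_true(all(empty$total == 0L))
})

test_that("conservation calls nest across windows on the fixture", {
  run <- default_run()
  calls <- run$calls
  ws <- sort(unique(calls$window))
  key <- function(w) unique(paste(calls$event_id, calls$ref_isoform_id,
                                  calls$ref_aa_pos)[calls$window == w])
  for (i in seq_along(ws)[-1L]) {
    expect_true(all(key(ws[i - 1L]) %in% key(ws[i])))
  }
  expect_true(all(diff(run$counts$total) >= 0L))
})
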