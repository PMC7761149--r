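# Nussinov folding, dot-bracket import, and the dsRNA/nick curation rule.

test_that("folding finds the obvious hairpin and respects min_loop", {
  ss <- fold_nussinov("GGGAAAACCC")
  expect_equal(ss$dotbracket, "(((....)))")
  expect_equal(nrow(ss$pairs), 3L)
  expect_valid_structure(ss)

  ss <- fold_nussinov("AAAA")
  expect_equal(ss$dotbracket, "....")
  expect_equal(nrow(ss$pairs), 0L)

  # GC pair possible only if loop >= min_loop: "GAAAC" has loop 3
  expect_equal(nrow(fold_nussinov("GAAAC")$pairs), 1L)
  expect_equal(nrow(fold_nussinov("GAAC")$pairs), 0L)
  expect_equal(nrow(fold_nussinov("GAAC", min_loop = 2L)$pairs), 1L)

  expect_error(fold_nussinov("ACGB"), "invalid character")
  expect_error(fold_nussinov(""), "empty")
})

test_that("DNA input is accepted and G.U wobble is switchable", {
  expect_equal(fold_nussinov("GGGAAAACCC")$dotbracket,
               fold_nussinov("GGGAAAACCC", allow_gu = FALSE)$dotbracket)
  # GU-only stem folds only with wobble enabled
  expect_gt(nrow(fold_nussinov("GGGAAAAUUU")$pairs), 0L)
  expect_equal(fold_nussinov("GGGAAAATTT")$sequence, "GGGAAAAUUU")
})

test_that("DP pair count equals brute-force enumeration on short sequences", {
  withr::with_seed(31L, {
    for (rep in 1:25) {
      n <- sample(4:12, 1L)
      s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
      gu <- rep %% 2L == 0L
      ss <- fold_nussinov(s, allow_gu = gu)
      expect_equal(nrow(ss$pairs), bf_max_pairs(s, allow_gu = gu),
                   info = paste(s, "gu:", gu))
      expect_valid_structure(ss)
    }
  })
})

test_that("pair count is invariant under reverse complementation", {
  # holds for Watson-Crick pairs: (i, j) maps to (n+1-j, n+1-i); a G.U wobble
  # pair maps to A-C, which does not pair, so the check disables wobble
  withr::with_seed(32L, {
    for (rep in 1:10) {
      s <- paste(sample(c("A", "C", "G", "U"), 12L, replace = TRUE), collapse = "")
      rc <- paste(rev(chartr("ACGU", "UGCA", strsplit(s, "")[[1L]])), collapse = "")
      expect_equal(nrow(fold_nussinov(s, allow_gu = FALSE)$pairs),
                   nrow(fold_nussinov(rc, allow_gu = FALSE)$pairs),
                   info = s)
    }
  })
})

test_that("dot-bracket import validates balance and length", {
  ss <- secondary_structure("GGGAAAACCC", "(((....)))")
  expect_equal(ss$pairs, fold_nussinov("GGGAAAACCC")$pairs)
  expect_error(secondary_structure("GGGA", "((("), "length")
  expect_error(secondary_structure("GGGA", "(().."), "length")
  expect_error(secondary_structure("GGGAA", "(()))"), "unbalanced")
  expect_error(secondary_structure("GGGAA", "((().."), "length|unbalanced")
  expect_error(secondary_structure("GGGAA", "((x))"), "may only contain")

  path <- tempfile()
  write_dotbracket(ss, path, id = "hairpin")
  back <- read_dotbracket(path)
  expect_equal(back$dotbracket, ss$dotbracket)
  expect_equal(back$sequence, ss$sequence)
})

test_that("the dsRNA/nick rule follows the pairing pattern only", {
  #             1234567890123
  db <- "((.((....))))"
  ss <- secondary_structure(strrep("A", 13L), db)
  expect_true(is_dsRNA_context(ss, 3L))    # nick: both neighbors paired
  expect_false(is_dsRNA_context(ss, 6L))   # loop: right neighbor unpaired
  for (p in which(strsplit(db, "")[[1L]] != ".")) {
    expect_true(is_dsRNA_context(ss, p))   # any paired base
  }
  # terminal unpaired base
  ss2 <- secondary_structure(strrep("A", 12L), ".(((....))).")
  expect_false(is_dsRNA_context(ss2, 1L))
  expect_false(is_dsRNA_context(ss2, 12L))
  expect_error(is_dsRNA_context(ss2, 13L), "out of range")

  # verdicts are independent of sequence content
  ss3 <- secondary_structure(strrep("C", 13L), db)
  for (p in 1:13) expect_equal(is_dsRNA_context(ss, p), is_dsRNA_context(ss3, p))
})

hairpin_candidates <- function(pos, scaffold = "s1") {
  list(events = data.frame(event_id = paste0(scaffold, "|", pos),
                           scaffold = scaffold, pos = pos, ref = "A", alt = "G",
                           samples = "Gut", n_samples = 1L, synonymous = FALSE,
                           stringsAsFactors = FALSE),
       hits = data.frame(event_id = paste0(scaffold, "|", pos), scaffold = scaffold,
                         pos = pos, ref = "A", alt = "G", transcript_id = "t1",
                         gene_id = "g1", tx_strand = "+", stringsAsFactors = FALSE))
}

test_that("curation detects a planted inverted repeat around the edit", {
  # 60-nt gene: left arm (15 nt ending at the edit A), 4-nt loop, right arm
  withr::with_seed(41L, {
    left <- c(sample(c("A", "C", "G", "T"), 14L, replace = TRUE), "A")
    loop <- c("C", "A", "A", "C")
    right <- rev(chartr("ACGT", "TGCA", left))
    tail <- sample(c("A", "C", "G", "T"), 26L, replace = TRUE)
  })
  g <- c(s1 = paste(c(left, loop, right, tail), collapse = ""))
  tms <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 60))))
  cur <- curate_events(hairpin_candidates(15L), tms, g)
  expect_true(cur$in_dsRNA)
  expect_equal(cur$structure_source, "internal")
})

test_that("an edit at an unpaired terminus is not in dsRNA context", {
  g <- c(s1 = paste0("A", strrep("C", 59L)))  # nothing can pair
  tms <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 60))))
  cur <- curate_events(hairpin_candidates(1L), tms, g)
  expect_false(cur$in_dsRNA)
})

test_that("imported structures must match the pre-mRNA and drive the verdict", {
  g <- c(s1 = paste0("GGG", "AAAA", "CCC", strrep("A", 20L)))
  tms <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 30))))
  cand <- hairpin_candidates(2L)
  internal <- curate_events(cand, tms, g)
  pre <- substr(g[["s1"]], 1L, 30L)
  db <- fold_nussinov(pre)$dotbracket
  imported <- curate_events(cand, tms, g, structures = list(t1 = db))
  expect_equal(imported$in_dsRNA, internal$in_dsRNA)
  expect_equal(imported$structure_source, "imported")
  expect_error(curate_events(cand, tms, g, structures = list(t1 = "((....))")),
               "length")
})

test_that("long pre-mRNAs are folded in a window centered on the edit", {
  # pairing partner sits 12 nt away; a 31-nt window still contains it
  withr::with_seed(42L, {
    left <- c(sample(c("A", "C", "G", "T"), 14L, replace = TRUE), "A")
    right <- rev(chartr("ACGT", "TGCA", left))
    g <- c(s1 = paste(c(left, "CAAC", right, sample(c("A", "C", "G", "T"), 166L,
                                                    replace = TRUE)),
                      collapse = ""))
  })
  tms <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 198))))
  cur <- curate_events(hairpin_candidates(15L), tms, g, fold_window = 40L)
  expect_true(cur$in_dsRNA)
})
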