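# SAM parsing, CIGAR walking, and threshold-based SNV calling.

test_that("CIGAR operations consume reference and query as specified", {
  genome <- c(s1 = "ACGTACGTAC")

  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 1L, "6M", "ACGTAC"),
                                c(s1 = 10L)))
  p <- build_pileup(sam, genome)
  expect_equal(p$pos, 1:6)
  expect_equal(p$depth, rep(1L, 6L))

  # insertion contributes to no column
  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 1L, "2M1I3M", "ACGGTA"),
                                c(s1 = 10L)))
  p <- build_pileup(sam, genome)
  expect_equal(p$pos, 1:5)
  expect_equal(sum(p$depth), 5L)

  # deletion leaves empty columns under the read
  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 1L, "2M2D2M", "ACAC"),
                                c(s1 = 10L)))
  p <- build_pileup(sam, genome)
  expect_equal(p$pos, c(1L, 2L, 5L, 6L))

  # N (intron skip) behaves like D for the pileup
  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 1L, "3M4N3M", "ACGTAC"),
                                c(s1 = 10L)))
  p <- build_pileup(sam, genome)
  expect_equal(p$pos, c(1:3, 8:10))

  # soft clip consumes query only
  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 3L, "2S3M", "TTGTA"),
                                c(s1 = 10L)))
  p <- build_pileup(sam, genome)
  expect_equal(p$pos, 3:5)
  expect_equal(p$G[1L], 1L)

  sam <- read_sam(write_tmp_sam(sam_line("bad", "s1", 1L, "5Q", "ACGTA"),
                                c(s1 = 10L)))
  expect_error(build_pileup(sam, genome), "bad")
})

test_that("unmapped, secondary and supplementary records are skipped", {
  genome <- c(s1 = "ACGTACGTAC")
  lines <- c(sam_line("r1", "s1", 1L, "4M", "ACGT"),
             sam_line("r2", "s1", 1L, "4M", "ACGT", flag = 4L),
             sam_line("r3", "s1", 1L, "4M", "ACGT", flag = 256L),
             sam_line("r4", "s1", 1L, "4M", "ACGT", flag = 2048L))
  p <- build_pileup(read_sam(write_tmp_sam(lines, c(s1 = 10L))), genome)
  expect_equal(p$depth, rep(1L, 4L))
})

test_that("pileup matches the naive per-base walker on random read sets", {
  for (seed in c(101L, 202L, 303L, 404L)) {
    case <- random_sam_case(seed)
    sam <- read_sam(case$sam_path)
    got <- build_pileup(sam, case$genome)
    want <- naive_pileup(sam, case$genome)
    expect_equal(got, want, info = paste("seed", seed))
    # conservation: counted bases == reference-consuming ACGT bases
    expect_equal(sum(got$A + got$C + got$G + got$T), sum(want$depth))
  }
})

test_that("call_snvs applies the depth cut-off and alt thresholds", {
  genome <- c(s1 = strrep("A", 30L))
  mk_pile <- function(pos, A, C, G, T) {
    data.frame(scaffold = "s1", pos = pos, A = A, C = C, G = G, T = T,
               depth = A + C + G + T, stringsAsFactors = FALSE)
  }
  # depth 9, alt 9: below the depth cut-off of 10
  expect_equal(nrow(call_snvs(mk_pile(1L, 0L, 0L, 9L, 0L), genome)), 0L)
  # depth 10, {A:7, G:3}: called, alt_count 3
  res <- call_snvs(mk_pile(2L, 7L, 0L, 3L, 0L), genome, sample_id = "Gut")
  expect_equal(nrow(res), 1L)
  expect_equal(res$ref, "A")
  expect_equal(res$alt, "G")
  expect_equal(res$alt_count, 3L)
  expect_equal(res$sample_id, "Gut")
  # depth 50, {A:49, G:1}: below min_alt_reads
  expect_equal(nrow(call_snvs(mk_pile(3L, 49L, 0L, 1L, 0L), genome)), 0L)
  # depth 20, {A:18, G:2}: 2 reads but fraction 0.1 exactly -> called
  expect_equal(nrow(call_snvs(mk_pile(4L, 18L, 0L, 2L, 0L), genome)), 1L)
  # N reference base skipped
  gn <- c(s1 = paste0(strrep("A", 4L), "N", strrep("A", 25L)))
  expect_equal(nrow(call_snvs(mk_pile(5L, 0L, 0L, 12L, 0L), gn)), 0L)
})

test_that("genomic SNP calling disables the depth cut-off", {
  genome <- c(s1 = strrep("A", 10L))
  pile <- data.frame(scaffold = "s1", pos = c(1L, 2L, 3L),
                     A = c(1L, 5L, 5L), C = 0L, G = c(2L, 0L, 5L), T = 0L,
                     depth = c(3L, 5L, 10L), stringsAsFactors = FALSE)
  snps <- call_genomic_snps(pile, genome)
  # depth 3 called (no cut-off), homozygous-reference not, 50/50 called
  expect_equal(snps$pos, c(1L, 3L))
  expect_equal(snps$key, c("s1:1:G", "s1:3:G"))
})

test_that("raising any caller threshold never adds calls", {
  genome <- c(s1 = paste(rep("A", 40L), collapse = ""))
  withr::with_seed(99L, {
    counts <- matrix(rpois(160L, 4L), ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    pile <- data.frame(scaffold = "s1", pos = 1:40, counts,
                       depth = rowSums(counts), stringsAsFactors = FALSE)
  })
  base <- caller_params(min_depth = 5L, min_alt_reads = 1L, min_alt_fraction = 0.05)
  base_calls <- call_snvs(pile, genome, base)
  harder <- list(caller_params(min_depth = 10L, min_alt_reads = 1L, min_alt_fraction = 0.05),
                 caller_params(min_depth = 5L, min_alt_reads = 3L, min_alt_fraction = 0.05),
                 caller_params(min_depth = 5L, min_alt_reads = 1L, min_alt_fraction = 0.3))
  for (p in harder) {
    calls <- call_snvs(pile, genome, p)
    expect_true(all(snv_keys <- paste(calls$pos, calls$alt) %in%
                      paste(base_calls$pos, base_calls$alt)))
  }
})

test_that("base-quality filtering drops low-quality bases before counting", {
  genome <- c(s1 = "AAAA")
  qual <- paste0("I", "#", "I", "I")  # position 2 is Q2
  sam <- read_sam(write_tmp_sam(sam_line("r1", "s1", 1L, "4M", "GGGG", qual = qual),
                                c(s1 = 4L)))
  p <- build_pileup(sam, genome, min_base_quality = 20L)
  expect_equal(p$pos, c(1L, 3L, 4L))
  p0 <- build_pileup(sam, genome)
  expect_equal(p0$pos, 1:4)
})
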