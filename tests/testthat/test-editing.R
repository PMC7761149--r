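# Editing-type filtering, SNP subtraction, consequences, sample merging.

mk_snv <- function(scaffold, pos, ref, alt, sample_id = "Gut",
                   depth = 20L, alt_count = 10L) {
  data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_count = alt_count, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

two_strand_transcripts <- function() {
  list(
    tp = transcript_model("tp", "gp", "s1", "+", rbind(c(1, 30))),
    tm = transcript_model("tm", "gm", "s1", "-", rbind(c(41, 70))))
}

test_that("only strand-compatible A-to-I transitions are kept", {
  tms <- two_strand_transcripts()
  snvs <- rbind(mk_snv("s1", 5L, "A", "G"),    # + CDS, kept
                mk_snv("s1", 50L, "T", "C"),   # - CDS, kept
                mk_snv("s1", 6L, "G", "A"),    # wrong transition
                mk_snv("s1", 7L, "T", "C"),    # T>C but + strand CDS
                mk_snv("s1", 51L, "A", "G"),   # A>G but - strand CDS
                mk_snv("s1", 35L, "A", "G"))   # intergenic
  hits <- filter_editing_type(snvs, tms)
  expect_equal(hits$pos, c(5L, 50L))
  expect_equal(hits$transcript_id, c("tp", "tm"))
})

test_that("SNVs overlapping both strands keep only matching transcripts", {
  tms <- list(
    tp = transcript_model("tp", "gp", "s1", "+", rbind(c(1, 30))),
    tm = transcript_model("tm", "gm", "s1", "-", rbind(c(10, 39))))
  hits <- filter_editing_type(mk_snv("s1", 15L, "A", "G"), tms)
  expect_equal(hits$transcript_id, "tp")
  hits <- filter_editing_type(mk_snv("s1", 15L, "T", "C"), tms)
  expect_equal(hits$transcript_id, "tm")
})

test_that("SNP subtraction matches position AND allele", {
  cand <- rbind(mk_snv("s1", 100L, "A", "G"), mk_snv("s1", 200L, "A", "G"))
  snp_same <- data.frame(scaffold = "s1", pos = 100L, alt = "G")
  snp_other <- data.frame(scaffold = "s1", pos = 100L, alt = "T")
  expect_equal(subtract_genomic(cand, snp_same)$pos, 200L)
  expect_equal(subtract_genomic(cand, snp_other)$pos, c(100L, 200L))
  expect_equal(subtract_genomic(cand, cand[0L, ]), cand)
})

test_that("subtracting a union equals sequential subtraction", {
  withr::with_seed(5L, {
    cand <- do.call(rbind, lapply(1:20, function(i) {
      mk_snv("s1", sample.int(500L, 1L), "A", "G")
    }))
    s1 <- data.frame(scaffold = "s1", pos = sample.int(500L, 8L), alt = "G")
    s2 <- data.frame(scaffold = "s1", pos = sample.int(500L, 8L), alt = "G")
  })
  expect_equal(subtract_genomic(cand, rbind(s1, s2)),
               subtract_genomic(subtract_genomic(cand, s1), s2))
})

test_that("consequences substitute G on the transcript strand", {
  # + strand: codons AAA CAA GCA; edits at specific codon positions
  g <- c(s1 = "AAACAAGCA")
  tm <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 9))))
  hits <- filter_editing_type(rbind(
    mk_snv("s1", 2L, "A", "G"),   # AAA -> AGA, K->R
    mk_snv("s1", 5L, "A", "G"),   # CAA -> CGA, Q->R
    mk_snv("s1", 9L, "A", "G")),  # GCA -> GCG, synonymous A
    tm)
  ann <- annotate_consequence(hits, tm, g)
  expect_equal(ann$ref_aa, c("K", "Q", "A"))
  expect_equal(ann$edited_aa, c("R", "R", "A"))
  expect_equal(ann$synonymous, c(FALSE, FALSE, TRUE))
  expect_equal(ann$edited_codon, c("AGA", "CGA", "GCG"))
})

test_that("edited stops are retained as readthrough events", {
  g <- c(s1 = "ATGTAG")  # M *
  tm <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 6))))
  ann <- annotate_consequence(filter_editing_type(mk_snv("s1", 5L, "A", "G"), tm),
                              tm, g)
  expect_equal(ann$ref_aa, "*")
  expect_equal(ann$edited_aa, "W")   # TAG -> TGG
  expect_false(ann$synonymous)
})

test_that("minus-strand consequences complement the genomic transition", {
  # genomic TTTCAT, revcomp ATGAAA: genomic T>C at pos 2 = transcript A>G
  g <- c(s1 = "TTTCAT")
  tm <- list(t1 = transcript_model("t1", "g1", "s1", "-", rbind(c(1, 6))))
  ann <- annotate_consequence(filter_editing_type(mk_snv("s1", 2L, "T", "C"), tm),
                              tm, g)
  expect_equal(ann$ref_codon, "AAA")
  expect_equal(ann$codon_pos, 2L)
  expect_equal(ann$edited_codon, "AGA")
  expect_equal(ann$ref_aa, "K")
  expect_equal(ann$edited_aa, "R")
})

test_that("isoform hits with N in the codon are dropped with a warning", {
  g <- c(s1 = "AANCAA")
  tm <- list(t1 = transcript_model("t1", "g1", "s1", "+", rbind(c(1, 6))))
  expect_warning(
    ann <- annotate_consequence(filter_editing_type(mk_snv("s1", 2L, "A", "G"), tm),
                                tm, g),
    "N in codon")
  expect_equal(nrow(ann), 0L)
})

annotated_hit <- function(scaffold, pos, sample_id, alt = "G") {
  data.frame(scaffold = scaffold, pos = pos, ref = "A", alt = alt,
             depth = 20L, alt_count = 10L, sample_id = sample_id,
             transcript_id = "t1", gene_id = "g1", tx_strand = "+",
             cds_pos = pos, codon_pos = 1L, aa_pos = (pos - 1L) %/% 3L + 1L,
             ref_codon = "AAA", edited_codon = "GAA", ref_aa = "K",
             edited_aa = "E", synonymous = FALSE, stringsAsFactors = FALSE)
}

test_that("merge_samples unions sample sets per (scaffold, pos, alt)", {
  hits <- rbind(annotated_hit("s1", 10L, "Cirri"),
                annotated_hit("s1", 10L, "Embr8h"),
                annotated_hit("s1", 20L, "Gut"))
  cand <- merge_samples(hits)
  expect_equal(nrow(cand$events), 2L)
  ev <- cand$events[cand$events$pos == 10L, ]
  expect_equal(ev$samples, "Cirri;Embr8h")
  expect_equal(ev$n_samples, 2L)
  expect_equal(ev$event_id, "s1|10")

  nine <- do.call(rbind, lapply(
    c("Cirri", "Embr8h", "Embr10h", "Epidermis", "FemGonads", "Gills", "Gut",
      "Hepatic", "MaleGonads"),
    function(s) annotated_hit("s1", 30L, s)))
  expect_equal(merge_samples(nine)$events$n_samples, 9L)

  single <- annotated_hit("s1", 40L, "Gut")
  expect_equal(merge_samples(single)$events$samples, "Gut")
})

test_that("different alt alleles at one position stay separate events", {
  hits <- rbind(annotated_hit("s1", 10L, "Gut", alt = "G"),
                annotated_hit("s1", 10L, "Gills", alt = "C"))
  cand <- merge_samples(hits)
  expect_equal(nrow(cand$events), 2L)
  expect_equal(sort(cand$events$alt), c("C", "G"))
  expect_equal(unique(cand$events$event_id), "s1|10")
})

test_that("planted edits are recovered and planted SNPs are removed", {
  fx <- small_fixture()
  genome <- read_genome(fx$files$genome)
  tms <- read_annotation(fx$files$annotation)
  res <- find_editing_candidates(genome, tms,
                                 rna_sams = fx$files$rna_sams,
                                 dna_sams = fx$files$dna_sam)
  got <- paste(res$candidates$events$scaffold, res$candidates$events$pos,
               res$candidates$events$alt, sep = ":")
  expect_true(all(truth_event_ids(fx$truth, "edit") %in% got))
  expect_false(any(truth_event_ids(fx$truth, "snp") %in% got))
  # every emitted event satisfies the transition/strand invariant
  h <- res$candidates$hits
  expect_true(all((h$ref == "A" & h$alt == "G" & h$tx_strand == "+") |
                  (h$ref == "T" & h$alt == "C" & h$tx_strand == "-")))
})
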