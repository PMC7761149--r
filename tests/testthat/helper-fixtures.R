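# Shared in-code fixtures. The generated bundles are memoized per session so
# several test files can reuse them without re-simulating.

.oe_cache <- new.env(parent = emptyenv())

# Small, fast bundle for module-level tests.
small_fixture <- function() {
  if (is.null(.oe_cache$small)) {
    .oe_cache$small <- generate_fixture(
      fixture_spec(seed = 7L, n_scaffolds = 2L, scaffold_len = 6000L,
                   n_genes = 6L, rna_depth = 20, dna_depth = 12,
                   seq_error_rate = 0, n_planted_edits = 12L,
                   n_planted_snps = 12L),
      file.path(tempdir(), "oe_small_fixture"))
  }
  .oe_cache$small
}

# Reference study conditions: seed 42, 20 genes, RNA depth 30, no sequencing
# errors, 50 planted edits and 50 planted SNPs.
default_fixture <- function() {
  if (is.null(.oe_cache$default)) {
    .oe_cache$default <- generate_fixture(
      fixture_spec(seed = 42L, n_genes = 20L, rna_depth = 30,
                   seq_error_rate = 0, n_planted_edits = 50L,
                   n_planted_snps = 50L),
      file.path(tempdir(), "oe_default_fixture"))
  }
  .oe_cache$default
}

fixture_config <- function(fx, out_dir, ...) {
  validate_config(list(
    genome = fx$files$genome, annotation = fx$files$annotation,
    sample_sheet = fx$files$sample_sheet,
    homolog_pairs = fx$files$homolog_pairs,
    ref_sites = fx$files$ref_sites, ref_proteome = fx$files$ref_proteome,
    out_dir = out_dir, seed = fx$spec$seed, ...))
}

# Full pipeline over the default fixture, memoized.
default_run <- function() {
  if (is.null(.oe_cache$default_run)) {
    fx <- default_fixture()
    cfg <- fixture_config(fx, file.path(tempdir(), "oe_default_run"))
    .oe_cache$default_run <- suppressMessages(run_pipeline(cfg))
  }
  .oe_cache$default_run
}

truth_event_ids <- function(truth, kind = "edit") {
  t <- truth[truth$kind == kind, , drop = FALSE]
  paste(t$scaffold, t$pos, t$alt, sep = ":")
}

# Write a throwaway FASTA / GFF3 / SAM for hand-built cases.
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]]))),
             path)
  path
}

write_tmp_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

sam_line <- function(qname, rname, pos, cigar, seq, flag = 0L, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq, qual, sep = "\t")
}

write_tmp_sam <- function(lines, scaffold_lens) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lens), scaffold_lens))
  writeLines(c(hdr, lines), path)
  path
}

# Random SAM records over a random genome, for pileup property tests.
random_sam_case <- function(seed, n_reads = 30L, glen = 80L) {
  withr::with_seed(seed, {
    genome <- c(s1 = paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                           collapse = ""))
    recs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      pos <- sample.int(glen - 30L, 1L)
      ops <- character(0L)
      qlen <- 0L
      rlen <- 0L
      n_ops <- sample(1:4, 1L)
      for (k in seq_len(n_ops)) {
        op <- if (k %% 2L == 1L) "M" else sample(c("I", "D", "N", "S", "M"), 1L)
        len <- sample(1:6, 1L)
        ops <- c(ops, paste0(len, op))
        if (op %in% c("M", "I", "S")) qlen <- qlen + len
        if (op %in% c("M", "D", "N")) rlen <- rlen + len
      }
      if (pos + rlen > glen) next
      seq <- paste(sample(c("A", "C", "G", "T", "N"), qlen, replace = TRUE,
                          prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
      recs[i] <- sam_line(paste0("r", i), "s1", pos, paste(ops, collapse = ""), seq)
    }
    recs <- recs[nzchar(recs)]
    list(genome = genome, sam_path = write_tmp_sam(recs, c(s1 = glen)))
  })
}
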