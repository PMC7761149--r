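## From SNVs to editing candidates: strand-aware transition filter, genomic
## SNP subtraction, per-isoform amino-acid consequence, cross-sample merge.

#' Keep SNVs matching the A-to-I editing signature inside coding regions
#'
#' Inosine reads as guanosine, so an editing event appears as A-to-G on the
#' genomic forward strand when the transcript is on `+`, and as T-to-C when
#' the transcript is on `-`. An SNV is kept once per overlapping CDS whose
#' strand matches its transition; all other transitions are dropped. An SNV
#' overlapping CDS of both strands is kept only with the strand-compatible
#' transcripts.
#'
#' @param snvs Data.frame from [call_snvs()] (possibly several samples bound
#'   together).
#' @param transcripts Named list of [transcript_model()] objects.
#' @return Data.frame of candidate hits: the SNV columns plus
#'   `transcript_id`, `gene_id`, `tx_strand` — one row per (SNV, transcript).
#' @export
filter_editing_type <- function(snvs, transcripts) {
  empty <- cbind(empty_snvs(),
                 data.frame(transcript_id = character(), gene_id = character(),
                            tx_strand = character(), stringsAsFactors = FALSE))
  if (!nrow(snvs) || !length(transcripts)) return(empty)
  segs <- do.call(rbind, lapply(transcripts, function(tm) {
    data.frame(scaffold = tm$scaffold_id,
               start = tm$segments[, 1L], end = tm$segments[, 2L],
               transcript_id = tm$transcript_id, gene_id = tm$gene_id,
               tx_strand = tm$strand, stringsAsFactors = FALSE)
  }))
  gr_seg <- GenomicRanges::GRanges(segs$scaffold,
                                   IRanges::IRanges(segs$start, segs$end))
  gr_snv <- GenomicRanges::GRanges(snvs$scaffold,
                                   IRanges::IRanges(snvs$pos, snvs$pos))
  ov <- GenomicRanges::findOverlaps(gr_snv, gr_seg, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  hits <- cbind(snvs[qh, , drop = FALSE],
                segs[sh, c("transcript_id", "gene_id", "tx_strand"), drop = FALSE])
  keep <- (hits$ref == "A" & hits$alt == "G" & hits$tx_strand == "+") |
          (hits$ref == "T" & hits$alt == "C" & hits$tx_strand == "-")
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Remove candidates confirmed as genomic SNPs
#'
#' A candidate is removed iff a genomic SNP exists at the same scaffold and
#' position with the same alternative allele; a genomic variant with a
#' different allele at that position is a different variant and does not
#' remove it.
#'
#' @param candidates Data.frame with `scaffold`, `pos`, `alt` columns.
#' @param snp_set Data.frame from [call_genomic_snps()] (or any data.frame
#'   with `scaffold`, `pos`, `alt`).
#' @return `candidates` with confirmed-SNP rows removed.
#' @export
subtract_genomic <- function(candidates, snp_set) {
  if (!nrow(candidates) || is.null(snp_set) || !nrow(snp_set)) return(candidates)
  skeys <- if (!is.null(snp_set$key)) snp_set$key else snv_key(snp_set)
  out <- candidates[!snv_key(candidates) %in% skeys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate per-isoform amino-acid consequences of candidate edits
#'
#' For each (candidate, transcript) hit, builds the codon context, substitutes
#' the transcript-strand edited base (always `G`: A-to-G on `+`, and the
#' complement of the genomic T-to-C on `-`), and translates both codons. Stop
#' codons render as `*` and may change to an amino acid (readthrough).
#' Isoform hits whose codon contains `N` are dropped with a warning.
#'
#' @param hits Data.frame from [filter_editing_type()] (after
#'   [subtract_genomic()]).
#' @param transcripts Named list of `transcript_model` objects.
#' @param genome Named `DNAStringSet` or character vector.
#' @return `hits` with added columns `cds_pos`, `codon_pos`, `aa_pos`,
#'   `ref_codon`, `edited_codon`, `ref_aa`, `edited_aa`, `synonymous`.
#' @export
annotate_consequence <- function(hits, transcripts, genome) {
  empty_cols <- data.frame(cds_pos = integer(), codon_pos = integer(),
                           aa_pos = integer(), ref_codon = character(),
                           edited_codon = character(), ref_aa = character(),
                           edited_aa = character(), synonymous = logical(),
                           stringsAsFactors = FALSE)
  if (!nrow(hits)) return(cbind(hits, empty_cols))
  out <- vector("list", nrow(hits))
  dropped <- character(0L)
  for (tid in unique(hits$transcript_id)) {
    tm <- transcripts[[tid]]
    if (is.null(tm)) stop("unknown transcript in hits: ", tid)
    positions <- transcript_cds_positions(tm)
    cds <- spliced_cds(tm, genome)
    rows <- which(hits$transcript_id == tid)
    for (i in rows) {
      ctx <- genomic_to_codon(tm, genome, hits$pos[i], cds = cds, positions = positions)
      if (is.null(ctx)) next  # e.g. phase-trimmed or partial-codon base
      if (grepl("N", ctx$codon, fixed = TRUE)) {
        dropped <- c(dropped, paste0(hits$scaffold[i], "|", hits$pos[i], "@", tid))
        next
      }
      edited_codon <- ctx$codon
      substr(edited_codon, ctx$codon_pos, ctx$codon_pos) <- "G"
      out[[i]] <- cbind(
        hits[i, , drop = FALSE],
        data.frame(cds_pos = ctx$cds_pos, codon_pos = ctx$codon_pos,
                   aa_pos = ctx$aa_pos, ref_codon = ctx$codon,
                   edited_codon = edited_codon, ref_aa = ctx$ref_aa,
                   edited_aa = codon_aa(edited_codon),
                   synonymous = ctx$ref_aa == codon_aa(edited_codon),
                   stringsAsFactors = FALSE))
    }
  }
  if (length(dropped)) {
    warning("dropped isoform hit(s) with N in codon: ", paste(dropped, collapse = ", "))
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(cbind(hits[0L, , drop = FALSE], empty_cols))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge per-sample candidate hits into a unique event set
#'
#' Candidates identical in (scaffold, pos, alt) are merged into one event
#' whose sample set is the union of the samples they were seen in; different
#' alternative alleles at the same position remain separate events. Event ids
#' render as `"scaffold|pos"`.
#'
#' @param hits Data.frame from [annotate_consequence()] carrying `sample_id`
#'   (several samples may be bound together, or pass a list of per-sample
#'   data.frames).
#' @return An object of class `editing_candidates`: a list with
#'   \describe{
#'     \item{events}{one row per unique event: `event_id`, `scaffold`, `pos`,
#'       `ref`, `alt`, `samples` (`;`-joined, sorted), `n_samples`,
#'       `synonymous` (TRUE iff synonymous in every hit isoform).}
#'     \item{hits}{one row per (event, isoform): consequence columns.}
#'   }
#' @export
merge_samples <- function(hits) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) {
    return(structure(list(
      events = data.frame(event_id = character(), scaffold = character(),
                          pos = integer(), ref = character(), alt = character(),
                          samples = character(), n_samples = integer(),
                          synonymous = logical(), stringsAsFactors = FALSE),
      hits = data.frame(event_id = character(), scaffold = character(),
                        pos = integer(), ref = character(), alt = character(),
                        transcript_id = character(), gene_id = character(),
                        tx_strand = character(), cds_pos = integer(),
                        codon_pos = integer(), aa_pos = integer(),
                        ref_codon = character(), edited_codon = character(),
                        ref_aa = character(), edited_aa = character(),
                        synonymous = logical(), stringsAsFactors = FALSE)),
      class = "editing_candidates"))
  }
  key <- snv_key(hits)
  samples <- vapply(split(hits$sample_id, key),
                    function(s) paste(sort(unique(s)), collapse = ";"), "")
  syn_all <- vapply(split(hits$synonymous, key), all, logical(1L))
  first <- hits[!duplicated(key), , drop = FALSE]
  fkey <- snv_key(first)
  events <- data.frame(
    event_id = paste0(first$scaffold, "|", first$pos),
    scaffold = first$scaffold, pos = first$pos,
    ref = first$ref, alt = first$alt,
    samples = unname(samples[fkey]),
    n_samples = lengths(strsplit(unname(samples[fkey]), ";", fixed = TRUE)),
    synonymous = unname(syn_all[fkey]),
    stringsAsFactors = FALSE)
  events <- events[order(events$scaffold, events$pos, events$alt), , drop = FALSE]
  rownames(events) <- NULL

  hcols <- c("scaffold", "pos", "ref", "alt", "transcript_id", "gene_id",
             "tx_strand", "cds_pos", "codon_pos", "aa_pos", "ref_codon",
             "edited_codon", "ref_aa", "edited_aa", "synonymous")
  h <- unique(hits[, hcols])
  h <- cbind(data.frame(event_id = paste0(h$scaffold, "|", h$pos),
                        stringsAsFactors = FALSE), h)
  h <- h[order(h$scaffold, h$pos, h$alt, h$transcript_id), , drop = FALSE]
  rownames(h) <- NULL
  structure(list(events = events, hits = h), class = "editing_candidates")
}

#' @export
print.editing_candidates <- function(x, ...) {
  cat(sprintf("<editing_candidates> %d unique event(s) across %d isoform hit(s), %d gene(s)\n",
              nrow(x$events), nrow(x$hits), length(unique(x$hits$gene_id))))
  invisible(x)
}

#' Run the candidate-discovery stage end to end
#'
#' Convenience driver: genomic pileup and SNP calls from DNA alignments, then
#' per-sample RNA pileups, SNV calls, editing-type filtering, SNP subtraction
#' and consequence annotation, merged into a unique event set.
#'
#' @param genome Named `DNAStringSet` from [read_genome()].
#' @param transcripts Named list from [read_annotation()].
#' @param rna_sams Named character vector of per-sample SAM paths (names are
#'   sample ids).
#' @param dna_sams Character vector of genomic-read SAM paths (may be empty:
#'   no SNP subtraction).
#' @param params [caller_params()] used for RNA calls; genomic calls reuse it
#'   with the depth cut-off disabled.
#' @return List with `candidates` (an `editing_candidates` object), `snps`
#'   (genomic SNP data.frame) and `n_snvs` (per-sample raw SNV counts).
#' @export
find_editing_candidates <- function(genome, transcripts, rna_sams, dna_sams = character(0L),
                                    params = caller_params()) {
  snps <- NULL
  if (length(dna_sams)) {
    dna <- do.call(rbind, lapply(dna_sams, read_sam))
    dpile <- build_pileup(dna, genome, min_base_quality = params$min_base_quality)
    snps <- call_genomic_snps(dpile, genome, params)
  }
  if (is.null(names(rna_sams)) || any(!nzchar(names(rna_sams)))) {
    stop("rna_sams must be a named vector (names are sample ids)")
  }
  n_snvs <- integer(length(rna_sams))
  names(n_snvs) <- names(rna_sams)
  per_sample <- vector("list", length(rna_sams))
  for (i in seq_along(rna_sams)) {
    sid <- names(rna_sams)[i]
    pile <- build_pileup(read_sam(rna_sams[[i]]), genome,
                         min_base_quality = params$min_base_quality)
    snvs <- call_snvs(pile, genome, params, sample_id = sid)
    n_snvs[i] <- nrow(snvs)
    hits <- filter_editing_type(snvs, transcripts)
    hits <- subtract_genomic(hits, snps)
    per_sample[[i]] <- annotate_consequence(hits, transcripts, genome)
  }
  list(candidates = merge_samples(per_sample), snps = snps, n_snvs = n_snvs)
}
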