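## Reference data: genome FASTA, GFF3 CDS models, spliced CDS extraction,
## translation, and genomic <-> codon coordinate conversion.
## All coordinates are 1-based inclusive (GFF3/VCF convention).

#' Read a genome FASTA into a named DNAStringSet
#'
#' Sequences are upper-cased and restricted to the alphabet A/C/G/T/N.
#' Scaffold ids are the first whitespace-delimited token of each FASTA header
#' and must be unique.
#'
#' @param fasta_source Path to a (multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per scaffold.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' as.character(read_genome(fa))
#' @export
read_genome <- function(fasta_source) {
  if (!file.exists(fasta_source)) {
    stop("genome FASTA not found: ", fasta_source)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) == 0L) {
    stop("empty FASTA: ", fasta_source)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s) in ", fasta_source, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("zero-length scaffold(s): ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  }
  af <- Biostrings::alphabetFrequency(seqs)
  extra <- af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE]
  bad <- rowSums(extra) > 0
  if (any(bad)) {
    stop("non-ACGTN characters in scaffold(s): ", paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Construct a transcript model
#'
#' A transcript model is the strand-aware CDS geometry of one isoform: an
#' ordered set of non-overlapping genomic CDS segments on one scaffold, plus
#' the GFF3 phase of the 5'-most segment (bases to trim before the first
#' complete codon).
#'
#' @param transcript_id,gene_id,scaffold_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param segments Two-column matrix of 1-based inclusive `(start, end)`
#'   genomic intervals; rows are sorted by genomic start.
#' @param phase Integer 0-2; bases trimmed from the 5' end of the spliced CDS.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, scaffold_id, strand,
                             segments, phase = 0L) {
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  segments <- segments[order(segments[, 1L]), , drop = FALSE]
  if (!strand %in% c("+", "-")) {
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  }
  if (any(segments[, 2L] < segments[, 1L])) {
    stop("transcript ", transcript_id, ": segment end before start")
  }
  if (nrow(segments) > 1L &&
      any(segments[-1L, 1L] <= segments[-nrow(segments), 2L])) {
    stop("transcript ", transcript_id, ": overlapping CDS segments")
  }
  phase <- as.integer(phase)
  if (is.na(phase) || phase < 0L || phase > 2L) {
    stop("transcript ", transcript_id, ": phase must be 0, 1 or 2")
  }
  total <- sum(segments[, 2L] - segments[, 1L] + 1L)
  if (total - phase < 3L) {
    stop("transcript ", transcript_id, ": CDS shorter than one codon after phase trimming")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         scaffold_id = scaffold_id, strand = strand,
         segments = segments, phase = phase),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s strand %s, %d CDS segment(s), %d bp, phase %d\n",
              x$transcript_id, x$gene_id, x$scaffold_id,
              paste0(min(x$segments[, 1L]), "-", max(x$segments[, 2L])),
              x$strand, nrow(x$segments),
              sum(x$segments[, 2L] - x$segments[, 1L] + 1L), x$phase))
  invisible(x)
}

first_parent <- function(p) {
  # rtracklayer stores Parent as a CharacterList
  vapply(p, function(x) if (length(x)) as.character(x[[1L]]) else NA_character_,
         character(1L))
}

#' Read transcript models from a GFF3 annotation
#'
#' CDS features are grouped by their `Parent` attribute into one
#' [transcript_model()] each. Gene ids are resolved through `mRNA`/`transcript`
#' parent rows when present, otherwise the transcript id is reused. `mRNA`
#' rows without CDS children are skipped with a warning. CDS rows of one
#' transcript spread over several scaffolds or strands are an error.
#'
#' @param gff3_source Path to a GFF3 file with CDS features.
#' @return A named list of `transcript_model` objects.
#' @export
read_annotation <- function(gff3_source) {
  if (!file.exists(gff3_source)) {
    stop("annotation GFF3 not found: ", gff3_source)
  }
  gr <- rtracklayer::import(gff3_source, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)

  tx2gene <- character(0L)
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  if (length(tx_rows)) {
    tid <- as.character(meta$ID[tx_rows])
    gid <- first_parent(meta$Parent[tx_rows])
    tx2gene <- stats::setNames(ifelse(is.na(gid), tid, gid), tid)
  }

  cds_idx <- which(type == "CDS")
  if (!length(cds_idx)) {
    warning("no CDS features in ", gff3_source)
    return(stats::setNames(list(), character(0L)))
  }
  cds <- gr[cds_idx]
  parent <- first_parent(S4Vectors::mcols(cds)$Parent)
  if (anyNA(parent)) {
    stop("CDS feature(s) without a Parent attribute in ", gff3_source)
  }

  models <- lapply(split(seq_along(cds), parent), function(ii) {
    tid <- parent[ii[1L]]
    sc <- unique(as.character(GenomicRanges::seqnames(cds)[ii]))
    if (length(sc) != 1L) {
      stop("transcript ", tid, ": CDS segments on multiple scaffolds (",
           paste(sc, collapse = ", "), ")")
    }
    st <- unique(as.character(GenomicRanges::strand(cds)[ii]))
    if (length(st) != 1L || !st %in% c("+", "-")) {
      stop("transcript ", tid, ": CDS segments on mixed or undefined strand")
    }
    seg <- cbind(GenomicRanges::start(cds)[ii], GenomicRanges::end(cds)[ii])
    ord <- order(seg[, 1L])
    seg <- seg[ord, , drop = FALSE]
    ph <- S4Vectors::mcols(cds)$phase
    ph <- if (is.null(ph)) rep(NA_integer_, length(cds)) else as.integer(ph)
    ph <- ph[ii][ord]
    # phase of the 5'-most segment in transcript orientation
    phase <- if (st == "+") ph[1L] else ph[length(ph)]
    if (is.na(phase)) phase <- 0L
    gid <- if (tid %in% names(tx2gene)) tx2gene[[tid]] else tid
    transcript_model(tid, gid, sc, st, seg, phase)
  })

  orphans <- setdiff(names(tx2gene), names(models))
  if (length(orphans)) {
    warning("skipped transcript(s) without CDS: ", paste(orphans, collapse = ", "))
  }
  models
}

scaffold_string <- function(genome, scaffold_id) {
  if (is.character(genome)) {
    if (!scaffold_id %in% names(genome)) {
      stop("scaffold not in genome: ", scaffold_id)
    }
    return(genome[[scaffold_id]])
  }
  if (!scaffold_id %in% names(genome)) {
    stop("scaffold not in genome: ", scaffold_id)
  }
  as.character(genome[[scaffold_id]])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Genomic CDS positions of a transcript, in transcript (5' to 3') order
#'
#' Returns the genomic coordinates of every spliced-CDS base after phase
#' trimming. Index `i` of the result is the genomic position of base `i` of
#' [spliced_cds()].
#'
#' @param tm A `transcript_model`.
#' @return Integer vector of 1-based genomic positions.
#' @export
transcript_cds_positions <- function(tm) {
  seg <- tm$segments
  pos <- unlist(lapply(seq_len(nrow(seg)), function(i) seg[i, 1L]:seg[i, 2L]),
                use.names = FALSE)
  if (tm$strand == "-") pos <- rev(pos)
  if (tm$phase > 0L) pos <- pos[-seq_len(tm$phase)]
  pos
}

#' Extract the spliced coding sequence of a transcript
#'
#' Concatenates the CDS segments in transcript order, reverse-complements on
#' the minus strand, and trims `phase` bases from the 5' end.
#'
#' @param tm A `transcript_model`.
#' @param genome A named `DNAStringSet` (or named character vector) holding
#'   `tm$scaffold_id`.
#' @return The spliced CDS as a plain character string.
#' @export
spliced_cds <- function(tm, genome) {
  s <- scaffold_string(genome, tm$scaffold_id)
  if (max(tm$segments[, 2L]) > nchar(s)) {
    stop("transcript ", tm$transcript_id, ": CDS segment exceeds scaffold length")
  }
  cds <- paste(substring(s, tm$segments[, 1L], tm$segments[, 2L]), collapse = "")
  if (tm$strand == "-") cds <- revcomp(cds)
  if (tm$phase > 0L) cds <- substr(cds, tm$phase + 1L, nchar(cds))
  cds
}

codon_aa <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Translate a coding DNA sequence
#'
#' Standard genetic code; stop codons render as `*` and internal stops are
#' retained (an edited stop is still analyzable). Codons containing `N`
#' translate to `X`. A trailing partial codon is dropped with a warning.
#'
#' @param cds DNA string over A/C/G/T/N, length >= 3.
#' @return Protein string, length `floor(nchar(cds) / 3)`.
#' @examples
#' translate_cds("ATGAAATAA") # "MK*"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop("non-ACGTN base in coding sequence")
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon")
  r <- n %% 3L
  if (r != 0L) {
    warning("trailing partial codon (", r, " base(s)) ignored")
    n <- n - r
    cds <- substr(cds, 1L, n)
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(Biostrings::GENETIC_CODE[codons]))
  paste(aa, collapse = "")
}

#' Codon context of a genomic position within a transcript
#'
#' Maps a genomic position to its spliced-CDS coordinate, codon and encoded
#' residue, honoring strand: on minus-strand transcripts the reported codon
#' base is the complement of the genomic base.
#'
#' @param tm A `transcript_model`.
#' @param genome Genome container as in [spliced_cds()].
#' @param genomic_pos 1-based genomic position.
#' @param cds,positions Optional precomputed [spliced_cds()] /
#'   [transcript_cds_positions()] results, for repeated calls.
#' @return `NULL` when the position is outside the (phase-trimmed) CDS, else a
#'   list of class `codon_context` with fields `cds_pos` (1-based position in
#'   the spliced CDS), `codon`, `codon_pos` (1-3), `aa_pos` (1-based) and
#'   `ref_aa` (single letter, `*` for stop, `X` for N-containing codons).
#' @export
genomic_to_codon <- function(tm, genome, genomic_pos, cds = NULL, positions = NULL) {
  if (is.null(positions)) positions <- transcript_cds_positions(tm)
  i <- match(genomic_pos, positions)
  if (is.na(i)) return(NULL)
  if (is.null(cds)) cds <- spliced_cds(tm, genome)
  aa_pos <- (i - 1L) %/% 3L + 1L
  codon <- substr(cds, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
  if (nchar(codon) < 3L) return(NULL)  # trailing partial codon
  structure(
    list(cds_pos = i, codon = codon, codon_pos = (i - 1L) %% 3L + 1L,
         aa_pos = aa_pos, ref_aa = codon_aa(codon)),
    class = "codon_context"
  )
}
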