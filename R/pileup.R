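## Per-position base counts from SAM alignments and threshold-based SNV calls.
## The CIGAR walker is deliberately explicit and fully specified so that calls
## are reproducible; it is cross-checked in the tests against an independent
## per-base oracle.

SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_SECONDARY <- 0x100L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

#' Read alignment records from a SAM file
#'
#' Parses the eleven mandatory SAM columns; header lines are skipped. No flag
#' filtering happens here — [build_pileup()] skips unmapped, secondary and
#' supplementary records.
#'
#' @param path Path to a SAM file.
#' @return A data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(nf < 11L)[1L], " of ", path)
  }
  data.frame(
    qname = vapply(f, `[[`, "", 1L),
    flag = as.integer(vapply(f, `[[`, "", 2L)),
    rname = vapply(f, `[[`, "", 3L),
    pos = as.integer(vapply(f, `[[`, "", 4L)),
    mapq = as.integer(vapply(f, `[[`, "", 5L)),
    cigar = vapply(f, `[[`, "", 6L),
    seq = vapply(f, `[[`, "", 10L),
    qual = vapply(f, `[[`, "", 11L),
    stringsAsFactors = FALSE
  )
}

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

parse_cigar <- function(cigar, qname = "?") {
  tokens <- regmatches(cigar, gregexpr("[0-9]+|[^0-9]", cigar))[[1L]]
  n <- length(tokens)
  if (n == 0L || n %% 2L != 0L || paste(tokens, collapse = "") != cigar) {
    stop("malformed CIGAR '", cigar, "' in read ", qname)
  }
  lens <- suppressWarnings(as.integer(tokens[seq(1L, n, by = 2L)]))
  ops <- tokens[seq(2L, n, by = 2L)]
  if (anyNA(lens) || !all(ops %in% CIGAR_OPS)) {
    stop("unknown CIGAR operation in '", cigar, "' of read ", qname)
  }
  list(lens = lens, ops = ops)
}

BASE_IDX <- local({
  v <- integer(256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

#' Build a per-position base-count pileup from SAM records
#'
#' Walks each read's CIGAR: `M`, `=` and `X` consume reference and query and
#' contribute bases to their columns; `I` and `S` consume query only; `D` and
#' `N` consume reference only and contribute nothing; `H`/`P` consume neither.
#' Unmapped, secondary and supplementary records are skipped, as are non-ACGT
#' read bases. Columns with depth 0 are omitted.
#'
#' @param sam Data.frame from [read_sam()] (or with the same columns).
#' @param genome Named `DNAStringSet` or named character vector; every mapped
#'   `rname` must be one of its scaffolds.
#' @param region Optional `list(scaffold =, start =, end =)` restriction.
#' @param min_base_quality Minimum Phred base quality (0 = off); bases below
#'   it are dropped before counting when the record carries qualities.
#' @return Data.frame with columns `scaffold`, `pos`, `A`, `C`, `G`, `T`,
#'   `depth` (`depth` is the row sum of the four base counts).
#' @export
build_pileup <- function(sam, genome, region = NULL, min_base_quality = 0L) {
  glens <- if (is.character(genome)) nchar(genome) else {
    stats::setNames(Biostrings::width(genome), names(genome))
  }
  keep <- bitwAnd(sam$flag,
                  bitwOr(SAM_FLAG_UNMAPPED,
                         bitwOr(SAM_FLAG_SECONDARY, SAM_FLAG_SUPPLEMENTARY))) == 0L
  sam <- sam[keep & sam$rname != "*", , drop = FALSE]
  scaffolds <- unique(sam$rname)
  missing <- setdiff(scaffolds, names(glens))
  if (length(missing)) {
    stop("SAM records refer to scaffold(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(region)) {
    scaffolds <- intersect(scaffolds, region$scaffold)
    sam <- sam[sam$rname %in% scaffolds, , drop = FALSE]
  }
  counts <- lapply(scaffolds, function(sc) {
    matrix(0L, nrow = 4L, ncol = glens[[sc]],
           dimnames = list(c("A", "C", "G", "T"), NULL))
  })
  names(counts) <- scaffolds
  min_bq <- as.integer(min_base_quality)

  for (i in seq_len(nrow(sam))) {
    if (sam$cigar[i] == "*") next
    cg <- parse_cigar(sam$cigar[i], sam$qname[i])
    sc <- sam$rname[i]
    mat <- counts[[sc]]
    rpos <- sam$pos[i]
    qpos <- 1L
    bases <- utf8ToInt(sam$seq[i])
    quals <- if (min_bq > 0L && sam$qual[i] != "*") utf8ToInt(sam$qual[i]) - 33L else NULL
    for (k in seq_along(cg$ops)) {
      op <- cg$ops[k]
      len <- cg$lens[k]
      if (op %in% c("M", "=", "X")) {
        qi <- qpos:(qpos + len - 1L)
        ri <- rpos:(rpos + len - 1L)
        idx <- BASE_IDX[bases[qi]]
        ok <- idx > 0L & ri <= ncol(mat) & ri >= 1L
        if (!is.null(quals)) ok <- ok & quals[qi] >= min_bq
        if (any(ok)) {
          cells <- cbind(idx[ok], ri[ok])
          mat[cells] <- mat[cells] + 1L
        }
        rpos <- rpos + len
        qpos <- qpos + len
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      }
      # H and P consume neither
    }
    counts[[sc]] <- mat
  }

  out <- lapply(scaffolds, function(sc) {
    mat <- counts[[sc]]
    depth <- colSums(mat)
    pos <- which(depth > 0L)
    if (!length(pos)) return(NULL)
    data.frame(scaffold = sc, pos = pos,
               A = mat[1L, pos], C = mat[2L, pos],
               G = mat[3L, pos], T = mat[4L, pos],
               depth = as.integer(depth[pos]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(), T = integer(),
                      depth = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(region) && nrow(out)) {
    out <- out[out$pos >= region$start & out$pos <= region$end, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' SNV caller thresholds
#'
#' `min_depth` defaults to 10, the depth cut-off applied to RNA-derived
#' calls; genomic SNP calling disables it (see [call_genomic_snps()]).
#' `min_alt_reads` and `min_alt_fraction` pin down the otherwise unstated
#' calling criteria so results are reproducible.
#'
#' @param min_depth Minimum total depth at a site (default 10).
#' @param min_alt_reads Minimum reads supporting the alternative base
#'   (default 2).
#' @param min_alt_fraction Minimum alternative-base fraction of depth
#'   (default 0.1).
#' @param min_base_quality Minimum Phred base quality applied at the pileup
#'   stage (default 0 = off).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_depth = 10L, min_alt_reads = 2L,
                          min_alt_fraction = 0.1, min_base_quality = 0L) {
  p <- list(min_depth = as.integer(min_depth),
            min_alt_reads = as.integer(min_alt_reads),
            min_alt_fraction = as.numeric(min_alt_fraction),
            min_base_quality = as.integer(min_base_quality))
  if (anyNA(unlist(p)) || any(unlist(p) < 0)) {
    stop("caller parameters must be non-negative")
  }
  if (p$min_alt_fraction > 1) stop("min_alt_fraction must be in [0, 1]")
  structure(p, class = "caller_params")
}

empty_snvs <- function() {
  data.frame(scaffold = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), alt_count = integer(),
             sample_id = character(), stringsAsFactors = FALSE)
}

#' Call single-nucleotide variants from a pileup
#'
#' A site yields one record per alternative base with
#' `alt_count >= min_alt_reads`, `alt_count / depth >= min_alt_fraction` and
#' `depth >= min_depth`. Sites where the genome base is `N` are skipped.
#'
#' @param pileup Data.frame from [build_pileup()].
#' @param genome Named `DNAStringSet` or named character vector.
#' @param params A [caller_params()] object.
#' @param sample_id Label (tissue or stage) stored with each call.
#' @return Data.frame with columns `scaffold`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `sample_id`.
#' @export
call_snvs <- function(pileup, genome, params = caller_params(), sample_id = "sample") {
  stopifnot(inherits(params, "caller_params"))
  if (!nrow(pileup)) return(empty_snvs())
  out <- vector("list", length(unique(pileup$scaffold)))
  names(out) <- unique(pileup$scaffold)
  for (sc in names(out)) {
    p <- pileup[pileup$scaffold == sc, , drop = FALSE]
    s <- scaffold_string(genome, sc)
    ref <- substring(s, p$pos, p$pos)
    rows <- list()
    for (alt in c("A", "C", "G", "T")) {
      cnt <- p[[alt]]
      ok <- ref != alt & ref != "N" &
        cnt >= params$min_alt_reads &
        cnt / p$depth >= params$min_alt_fraction &
        p$depth >= params$min_depth
      if (any(ok)) {
        rows[[alt]] <- data.frame(
          scaffold = sc, pos = p$pos[ok], ref = ref[ok], alt = alt,
          depth = p$depth[ok], alt_count = cnt[ok], sample_id = sample_id,
          stringsAsFactors = FALSE)
      }
    }
    out[[sc]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_snvs())
  res <- res[order(res$scaffold, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call genomic SNPs (no depth cut-off)
#'
#' Identical logic to [call_snvs()] but with the depth cut-off disabled
#' (`min_depth = 1`): genomic reads confirm a polymorphism at any depth. The
#' result carries a `key` column (`scaffold:pos:alt`) for fast membership
#' tests in [subtract_genomic()].
#'
#' @inheritParams call_snvs
#' @return Data.frame as [call_snvs()] plus a `key` column.
#' @export
call_genomic_snps <- function(pileup, genome, params = caller_params()) {
  params$min_depth <- 1L
  res <- call_snvs(pileup, genome, params, sample_id = "genomic")
  res$key <- snv_key(res)
  res
}

snv_key <- function(x) paste(x$scaffold, x$pos, x$alt, sep = ":")

#' Write SNV or candidate records as a minimal VCF 4.2
#'
#' @param snvs Data.frame with `scaffold`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count` and optionally `sample_id` / `samples` columns.
#' @param path Output file.
#' @param extra_info Optional character vector (same length as `nrow(snvs)`)
#'   appended to the INFO field.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, extra_info = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=orthoedit",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternative allele read count\">",
    "##INFO=<ID=SAMPLE,Number=.,Type=String,Description=\"Sample label(s)\">",
    "##INFO=<ID=EDIT_AA,Number=.,Type=String,Description=\"Per-isoform amino-acid change transcript:ref>edited\">",
    "##INFO=<ID=SYN,Number=0,Type=Flag,Description=\"Synonymous in every hit isoform\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0L)
  if (nrow(snvs)) {
    sample_lab <- if (!is.null(snvs$samples)) snvs$samples else snvs$sample_id
    info <- sprintf("DP=%d;AD=%d;SAMPLE=%s", snvs$depth, snvs$alt_count,
                    gsub(";", ",", sample_lab))
    if (!is.null(extra_info)) info <- paste0(info, ";", extra_info)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    snvs$scaffold, snvs$pos,
                    paste0(snvs$scaffold, "|", snvs$pos),
                    snvs$ref, snvs$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
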