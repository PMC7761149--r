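## dsRNA context of edited positions: maximum-base-pairing fold of the
## pre-mRNA (Nussinov DP, Rcpp kernel), dot-bracket import, and the
## paired-or-nick rule. ADAR enzymes act on double-stranded RNA, so an edit
## in an unpaired context is suspect.

partner_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  db[partner > seq_along(partner)] <- "("
  db[partner > 0L & partner < seq_along(partner)] <- ")"
  paste(db, collapse = "")
}

partner_to_pairs <- function(partner) {
  i <- which(partner > seq_along(partner))
  cbind(i = i, j = partner[i])
}

new_secondary_structure <- function(sequence, partner) {
  structure(
    list(sequence = sequence, dotbracket = partner_to_dotbracket(partner),
         pairs = partner_to_pairs(partner), partner = as.integer(partner)),
    class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pair(s)\n",
              nchar(x$sequence), nrow(x$pairs)))
  if (nchar(x$sequence) <= 120L) {
    cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  }
  invisible(x)
}

#' Fold an RNA sequence by maximum base pairing (Nussinov)
#'
#' Maximizes the number of Watson-Crick (plus, optionally, G·U wobble) base
#' pairs subject to hairpin loops of at least `min_loop` unpaired bases,
#' using the standard Nussinov dynamic program with a deterministic
#' traceback. `T` is converted to `U` on input.
#'
#' This is a topological, not thermodynamic, fold: use [secondary_structure()]
#' to import a dot-bracket string from any external folder instead.
#'
#' @param seq RNA (or DNA) string over A/C/G/U/T.
#' @param min_loop Minimum unpaired bases in a hairpin loop (default 3); no
#'   pair `(i, j)` with `j - i - 1 < min_loop` is formed.
#' @param allow_gu Allow G·U wobble pairs (default TRUE).
#' @return An object of class `secondary_structure` with fields `sequence`,
#'   `dotbracket`, `pairs` (two-column 1-based matrix) and `partner`
#'   (1-based partner table, 0 = unpaired).
#' @examples
#' fold_nussinov("GGGAAAACCC")$dotbracket # "(((....)))"
#' @export
fold_nussinov <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  s <- chartr("Tt", "Uu", toupper(seq))
  if (!nchar(s)) stop("cannot fold an empty sequence")
  if (grepl("[^ACGU]", s)) stop("invalid character in RNA sequence")
  partner <- nussinov_pairs_cpp(s, as.integer(min_loop), isTRUE(allow_gu))
  new_secondary_structure(s, partner)
}

#' Build a secondary structure from an imported dot-bracket string
#'
#' @param sequence RNA/DNA string.
#' @param dotbracket Matching Vienna-style dot-bracket string (same length,
#'   balanced parentheses).
#' @return A `secondary_structure` object.
#' @export
secondary_structure <- function(sequence, dotbracket) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  if (nchar(dotbracket) != nchar(s)) {
    stop("dot-bracket length (", nchar(dotbracket),
         ") differs from sequence length (", nchar(s), ")")
  }
  ch <- strsplit(dotbracket, "")[[1L]]
  if (any(!ch %in% c("(", ")", "."))) {
    stop("dot-bracket may only contain '(', ')' and '.'")
  }
  partner <- integer(length(ch))
  open <- integer(0L)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket: unmatched '('")
  new_secondary_structure(s, partner)
}

#' Read a Vienna-style dot-bracket file
#'
#' Plain-text format: an optional `>` header line, a sequence line, then a
#' structure line (any trailing energy annotation after whitespace is
#' ignored).
#'
#' @param path File path.
#' @return A `secondary_structure` object.
#' @export
read_dotbracket <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], ">")) lines <- lines[-1L]
  if (length(lines) < 2L) stop("dot-bracket file needs a sequence and a structure line: ", path)
  secondary_structure(lines[1L], sub("\\s.*$", "", lines[2L]))
}

#' Write a secondary structure as a Vienna-style dot-bracket file
#'
#' @param ss A `secondary_structure`.
#' @param path Output path.
#' @param id Optional header id.
#' @export
write_dotbracket <- function(ss, path, id = NULL) {
  lines <- c(if (!is.null(id)) paste0(">", id), ss$sequence, ss$dotbracket)
  writeLines(lines, path)
  invisible(path)
}

#' Is a position in a double-stranded context (paired, or a one-base nick)?
#'
#' TRUE iff the base is paired, or it is unpaired with both neighbors present
#' and paired (a "nick": a single-nucleotide single-stranded stretch flanked
#' by dsRNA). Terminal unpaired bases are FALSE. The verdict depends only on
#' the pairing pattern, never on sequence content.
#'
#' @param ss A `secondary_structure`.
#' @param pos 1-based position.
#' @return Logical flag.
#' @export
is_dsRNA_context <- function(ss, pos) {
  n <- length(ss$partner)
  if (pos < 1L || pos > n) stop("position ", pos, " out of range 1..", n)
  if (ss$partner[pos] > 0L) return(TRUE)
  pos > 1L && pos < n && ss$partner[pos - 1L] > 0L && ss$partner[pos + 1L] > 0L
}

premrna_span <- function(tm) {
  c(min(tm$segments[, 1L]), max(tm$segments[, 2L]))
}

#' Curate candidate events for dsRNA context on the folded pre-mRNA
#'
#' For each event and each isoform it hits, extracts the pre-mRNA
#' strand-aware (the genomic footprint of the CDS segments, introns
#' included), locates the edited base in pre-mRNA coordinates, folds with
#' [fold_nussinov()] (or uses an imported dot-bracket), and applies
#' [is_dsRNA_context()]. A multi-isoform event is curated OK iff the context
#' holds in at least one isoform.
#'
#' Pre-mRNAs longer than `fold_window` are folded in a window of that length
#' centered on the edited base (cubic DP cost, and structure predictions are
#' length-dependent anyway).
#'
#' @param candidates An `editing_candidates` object (or a list with `events`
#'   and `hits` data.frames).
#' @param transcripts,genome Reference data.
#' @param fold_window Maximum folded length in nt (default 2000).
#' @param min_loop,allow_gu Passed to [fold_nussinov()].
#' @param structures Optional named list (by transcript id) of imported
#'   dot-bracket strings for the full pre-mRNA; their length must equal the
#'   pre-mRNA length.
#' @param event_ids Optional subset of event ids to curate (default: all).
#' @return Data.frame with columns `event_id`, `in_dsRNA` (logical) and
#'   `structure_source` (`"internal"` or `"imported"`).
#' @export
curate_events <- function(candidates, transcripts, genome, fold_window = 2000L,
                          min_loop = 3L, allow_gu = TRUE, structures = NULL,
                          event_ids = NULL) {
  events <- candidates$events
  hits <- candidates$hits
  if (!is.null(event_ids)) {
    events <- events[events$event_id %in% event_ids, , drop = FALSE]
  }
  if (!nrow(events)) {
    return(data.frame(event_id = character(), in_dsRNA = logical(),
                      structure_source = character(), stringsAsFactors = FALSE))
  }
  fold_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(events))
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    tids <- unique(hits$transcript_id[hits$event_id == ev$event_id &
                                      hits$alt == ev$alt])
    in_ds <- FALSE
    src <- "internal"
    for (tid in tids) {
      tm <- transcripts[[tid]]
      span <- premrna_span(tm)
      len <- span[2L] - span[1L] + 1L
      ppos <- if (tm$strand == "+") ev$pos - span[1L] + 1L else span[2L] - ev$pos + 1L
      if (ppos < 1L || ppos > len) next
      imported <- if (!is.null(structures)) structures[[tid]] else NULL
      if (!is.null(imported)) {
        pre <- substr(scaffold_string(genome, tm$scaffold_id), span[1L], span[2L])
        if (tm$strand == "-") pre <- revcomp(pre)
        if (nchar(imported) != len) {
          stop("imported dot-bracket for ", tid, " has length ",
               nchar(imported), ", pre-mRNA has ", len)
        }
        ss <- secondary_structure(pre, imported)
        fpos <- ppos
        src <- "imported"
      } else {
        # fold a window centered on the edit when the pre-mRNA is long
        ws <- 1L
        we <- len
        if (len > fold_window) {
          half <- fold_window %/% 2L
          ws <- max(1L, ppos - half)
          we <- min(len, ws + fold_window - 1L)
          ws <- max(1L, we - fold_window + 1L)
        }
        key <- paste(tid, ws, we, sep = "\r")
        ss <- fold_cache[[key]]
        if (is.null(ss)) {
          pre <- substr(scaffold_string(genome, tm$scaffold_id), span[1L], span[2L])
          if (tm$strand == "-") pre <- revcomp(pre)
          ss <- fold_nussinov(substr(pre, ws, we), min_loop = min_loop,
                              allow_gu = allow_gu)
          fold_cache[[key]] <- ss
        }
        fpos <- ppos - ws + 1L
      }
      if (is_dsRNA_context(ss, fpos)) {
        in_ds <- TRUE
        break
      }
    }
    out[[e]] <- data.frame(event_id = ev$event_id, in_dsRNA = in_ds,
                           structure_source = src, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
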