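## Orthology-window conservation: global protein alignment of query isoforms
## to reference-species homolog isoforms, projection of known edited residues,
## window-of-homology matching, conservation classes 0-4.

#' Substitution matrix for editing-aware protein alignment
#'
#' BLOSUM62 with two adjustments so translated CDS can be aligned as-is:
#' `*` (stop) participates as an ordinary symbol scoring the matrix minimum
#' against everything (edited stops are analyzable, e.g. readthrough events),
#' and `X` (untranslatable codon) scores 0 against anything.
#'
#' @return A square numeric substitution matrix.
#' @export
editing_score_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  lo <- min(m)
  m["*", ] <- lo
  m[, "*"] <- lo
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Optimal global (Needleman-Wunsch/Gotoh) protein alignment
#'
#' Affine-gap global alignment via [Biostrings::pairwiseAlignment()]. Gap
#' penalties follow the BLAST convention (opening 11, extension 1 per
#' residue).
#'
#' @param query,ref Non-empty protein strings (may contain `*` and `X`).
#' @param substitution_matrix Substitution matrix; default
#'   [editing_score_matrix()].
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `pairwise_alignment`: list with
#'   `aligned_query`, `aligned_ref` (equal-length gapped strings; degapping
#'   reproduces the inputs) and `score`.
#' @export
align_global <- function(query, ref, substitution_matrix = editing_score_matrix(),
                         gap_open = 11, gap_extend = 1) {
  if (!nchar(query) || !nchar(ref)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  structure(
    list(aligned_query = as.character(Biostrings::alignedPattern(pa)),
         aligned_ref = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "\n")
  cat(" query:", x$aligned_query, "\n")
  cat(" ref:  ", x$aligned_ref, "\n")
  invisible(x)
}

aln_chars <- function(aln, which = c("query", "ref")) {
  which <- match.arg(which)
  strsplit(if (which == "query") aln$aligned_query else aln$aligned_ref, "")[[1L]]
}

#' Alignment column holding a given residue
#'
#' @param aln A `pairwise_alignment`.
#' @param which `"query"` or `"ref"`.
#' @param residue_pos 1-based residue index in the ungapped sequence.
#' @return 1-based alignment-column index.
#' @seealso [residue_at()] for the inverse.
#' @export
column_of <- function(aln, which = c("query", "ref"), residue_pos) {
  ch <- aln_chars(aln, which)
  nongap <- which(ch != "-")
  if (residue_pos < 1L || residue_pos > length(nongap)) {
    stop("residue position ", residue_pos, " out of range (sequence has ",
         length(nongap), " residues)")
  }
  nongap[residue_pos]
}

#' Residue index at a given alignment column
#'
#' @inheritParams column_of
#' @param column 1-based alignment-column index.
#' @return 1-based residue index, or `NA` when the column holds a gap.
#' @export
residue_at <- function(aln, which = c("query", "ref"), column) {
  ch <- aln_chars(aln, which)
  if (column < 1L || column > length(ch)) stop("column ", column, " out of range")
  if (ch[column] == "-") return(NA_integer_)
  sum(ch[seq_len(column)] != "-")
}

#' Conservation class of a (query event, reference site) pair
#'
#' Class 0: the editing is synonymous in both species. Otherwise, with
#' pre-match = (query pre-edit residue == reference pre-edit residue) and
#' post-match = (query edited residue == reference edited residue):
#' class 1 = both match, class 2 = only post matches, class 3 = only pre
#' matches, class 4 = neither matches.
#'
#' All arguments are vectorized.
#'
#' @param query_pre_aa,query_post_aa,ref_pre_aa,ref_post_aa Single letters
#'   (including `*`).
#' @param query_synonymous,ref_synonymous Logical flags.
#' @return Integer class in `0:4`.
#' @export
classify_conservation <- function(query_pre_aa, query_post_aa, query_synonymous,
                                  ref_pre_aa, ref_post_aa, ref_synonymous) {
  pre <- query_pre_aa == ref_pre_aa
  post <- query_post_aa == ref_post_aa
  ifelse(query_synonymous & ref_synonymous, 0L,
         ifelse(pre & post, 1L,
                ifelse(!pre & post, 2L,
                       ifelse(pre & !post, 3L, 4L))))
}

#' Read a homologous-gene pair table
#'
#' Two-column TSV: query gene id, reference gene id (many-to-many allowed).
#'
#' @param path TSV path (with or without a header line).
#' @return Data.frame with columns `query_gene_id`, `ref_gene_id`.
#' @export
read_homolog_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("query_gene_id", "ref_gene_id") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("homolog pair table needs two columns: ", path)
    names(df)[1:2] <- c("query_gene_id", "ref_gene_id")
  }
  unique(df[, c("query_gene_id", "ref_gene_id")])
}

#' Read a reference-species editing-site table
#'
#' TSV with columns `ref_gene_id`, `ref_isoform_id`, `aa_pos`, `pre_aa`,
#' `post_aa` and optionally `source_tag`. A row with `pre_aa == post_aa`
#' flags a synonymous reference event.
#'
#' @param path TSV path.
#' @return Data.frame of reference edit sites.
#' @export
read_ref_sites <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("ref_gene_id", "ref_isoform_id", "aa_pos", "pre_aa", "post_aa")
  if (!all(need %in% names(df))) {
    stop("reference site table must have columns ",
         paste(need, collapse = ", "), ": ", path)
  }
  if (is.null(df$source_tag)) df$source_tag <- ""
  df$aa_pos <- as.integer(df$aa_pos)
  df
}

#' Read a reference proteome FASTA
#'
#' @param path FASTA of reference-species isoform protein sequences; record
#'   ids (first header token) are isoform ids and must be unique.
#' @return Named character vector of protein sequences.
#' @export
read_ref_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate isoform id(s) in ", path)
  stats::setNames(as.character(seqs), ids)
}

empty_calls <- function() {
  data.frame(event_id = character(), query_isoform_id = character(),
             query_gene_id = character(), ref_isoform_id = character(),
             ref_gene_id = character(), ref_aa_pos = integer(),
             query_pre_aa = character(), query_post_aa = character(),
             query_synonymous = logical(), ref_pre_aa = character(),
             ref_post_aa = character(), ref_synonymous = logical(),
             aligned_distance = numeric(), window = numeric(), cls = integer(),
             stringsAsFactors = FALSE)
}

#' Match candidate events against reference editing sites within windows
#'
#' For every (event isoform, reference isoform) pair joined through a homolog
#' pair, computes the aligned distance between the query's edited residue and
#' each known edited residue of the reference isoform, and emits one
#' conservation call per reference site whose distance is within the window.
#' When several reference sites fall inside a window, all are emitted
#' (deduplication happens in [class_count_table()]). A query residue whose
#' alignment column falls in a terminal overhang of the reference (aligned to
#' nothing) yields no call.
#'
#' @param hits Candidate isoform hits (the `hits` element of an
#'   `editing_candidates` object).
#' @param ref_sites Data.frame from [read_ref_sites()].
#' @param pairs Data.frame from [read_homolog_pairs()].
#' @param query_proteins,ref_proteins Named character vectors of protein
#'   sequences (query keyed by transcript id, reference by isoform id).
#' @param windows Numeric vector of window sizes; `Inf` accepts any distance.
#' @param distance_metric `"column"` (absolute difference of alignment-column
#'   indices, gaps counted — the default, strictest reading) or `"residue"`
#'   (difference in reference-residue coordinates, gap columns not counted).
#' @param substitution_matrix,gap_open,gap_extend Passed to [align_global()].
#' @return Data.frame of conservation calls (one row per site, per window it
#'   falls into), with columns including `event_id`, `aligned_distance`,
#'   `window` and `cls`.
#' @export
match_events <- function(hits, ref_sites, pairs, query_proteins, ref_proteins,
                         windows = c(0, 1, 5, Inf),
                         distance_metric = c("column", "residue"),
                         substitution_matrix = editing_score_matrix(),
                         gap_open = 11, gap_extend = 1) {
  distance_metric <- match.arg(distance_metric)
  if (!nrow(hits) || !nrow(ref_sites) || !nrow(pairs)) return(empty_calls())
  windows <- sort(unique(as.numeric(windows)))
  iso2gene <- unique(ref_sites[, c("ref_isoform_id", "ref_gene_id")])
  aln_cache <- new.env(parent = emptyenv())
  rows <- list()
  n <- 0L
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    ref_genes <- pairs$ref_gene_id[pairs$query_gene_id == h$gene_id]
    if (!length(ref_genes)) next
    isoforms <- iso2gene$ref_isoform_id[iso2gene$ref_gene_id %in% ref_genes]
    for (riso in isoforms) {
      qp <- query_proteins[[h$transcript_id]]
      rp <- ref_proteins[[riso]]
      if (is.null(qp) || is.null(rp)) {
        stop("missing protein sequence for ",
             if (is.null(qp)) h$transcript_id else riso)
      }
      key <- paste(h$transcript_id, riso, sep = "\r")
      aln <- if (!is.null(aln_cache[[key]])) aln_cache[[key]] else {
        a <- align_global(qp, rp, substitution_matrix, gap_open, gap_extend)
        aln_cache[[key]] <- a
        a
      }
      if (h$aa_pos > nchar(qp)) next  # edit beyond translated length
      qcol <- column_of(aln, "query", h$aa_pos)
      rch <- aln_chars(aln, "ref")
      rspan <- range(which(rch != "-"))
      if (qcol < rspan[1L] || qcol > rspan[2L]) {
        message("event ", h$event_id, " isoform ", h$transcript_id,
                ": edited residue in terminal overhang vs ", riso, "; no call")
        next
      }
      sites <- ref_sites[ref_sites$ref_isoform_id == riso, , drop = FALSE]
      for (j in seq_len(nrow(sites))) {
        s <- sites[j, ]
        if (s$aa_pos > nchar(rp)) next
        d <- if (distance_metric == "column") {
          abs(qcol - column_of(aln, "ref", s$aa_pos))
        } else {
          # reference-residue coordinate of the query column vs the site
          abs(sum(rch[seq_len(qcol)] != "-") - s$aa_pos)
        }
        ws <- windows[windows >= d]
        if (!length(ws)) next
        cls <- classify_conservation(h$ref_aa, h$edited_aa, h$synonymous,
                                     s$pre_aa, s$post_aa, s$pre_aa == s$post_aa)
        for (w in ws) {
          n <- n + 1L
          rows[[n]] <- data.frame(
            event_id = h$event_id, query_isoform_id = h$transcript_id,
            query_gene_id = h$gene_id, ref_isoform_id = riso,
            ref_gene_id = s$ref_gene_id, ref_aa_pos = s$aa_pos,
            query_pre_aa = h$ref_aa, query_post_aa = h$edited_aa,
            query_synonymous = h$synonymous, ref_pre_aa = s$pre_aa,
            ref_post_aa = s$post_aa, ref_synonymous = s$pre_aa == s$post_aa,
            aligned_distance = d, window = w, cls = cls,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!n) return(empty_calls())
  res <- do.call(rbind, rows)
  res <- res[order(res$window, res$event_id, res$query_isoform_id,
                   res$ref_isoform_id, res$ref_aa_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-window, per-class counts of distinct events
#'
#' For each (window, class) cell: the number of distinct event ids having at
#' least one call of that class at that window. The per-window total counts
#' distinct events with any call at that window; since one event can belong
#' to several classes through different isoforms, totals need not equal the
#' row sums.
#'
#' @param calls Data.frame from [match_events()].
#' @param windows Windows to tabulate (default: those present in `calls`).
#' @return Data.frame with one row per window: `window`, `class_0` ...
#'   `class_4`, `total`.
#' @export
class_count_table <- function(calls, windows = NULL) {
  if (is.null(windows)) windows <- sort(unique(calls$window))
  if (!length(windows)) windows <- c(0, 1, 5, Inf)
  out <- lapply(windows, function(w) {
    cw <- calls[calls$window == w, , drop = FALSE]
    counts <- vapply(0:4, function(k) {
      length(unique(cw$event_id[cw$cls == k]))
    }, integer(1L))
    data.frame(window = w, class_0 = counts[1L], class_1 = counts[2L],
               class_2 = counts[3L], class_3 = counts[4L], class_4 = counts[5L],
               total = length(unique(cw$event_id)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the conservation stage on an editing-candidate set
#'
#' Translates the spliced CDS of every isoform carrying a candidate and calls
#' [match_events()] against the reference sites.
#'
#' @param candidates An `editing_candidates` object.
#' @param transcripts,genome Reference data as elsewhere.
#' @param pairs,ref_sites,ref_proteins See [match_events()].
#' @param windows,distance_metric,substitution_matrix,gap_open,gap_extend
#'   See [match_events()].
#' @return List with `calls` and `counts` (a [class_count_table()]).
#' @export
conserve_events <- function(candidates, transcripts, genome, pairs, ref_sites,
                            ref_proteins, windows = c(0, 1, 5, Inf),
                            distance_metric = c("column", "residue"),
                            substitution_matrix = editing_score_matrix(),
                            gap_open = 11, gap_extend = 1) {
  tids <- unique(candidates$hits$transcript_id)
  query_proteins <- vapply(tids, function(tid) {
    translate_cds(spliced_cds(transcripts[[tid]], genome))
  }, character(1L))
  calls <- match_events(candidates$hits, ref_sites, pairs, query_proteins,
                        ref_proteins, windows = windows,
                        distance_metric = match.arg(distance_metric),
                        substitution_matrix = substitution_matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
  list(calls = calls, counts = class_count_table(calls, sort(unique(as.numeric(windows)))))
}
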