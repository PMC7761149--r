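## Summaries and report files: tissue/stage specificity counts, headline
## statistics, and the on-disk report bundle.

#' Restrict event sample sets to one sample class
#'
#' Intersects each event's sample set with the samples of the given class
#' (tissues or stages) and drops events left with no sample, so that
#' [tissue_specific_counts()] can be run per class over the same merged
#' event store.
#'
#' @param candidates An `editing_candidates` object.
#' @param sample_sheet Data.frame with `sample_id` and `class` columns.
#' @param sample_class `"tissue"` or `"stage"`.
#' @return An `editing_candidates` object with restricted sample sets.
#' @export
restrict_to_sample_class <- function(candidates, sample_sheet,
                                     sample_class = c("tissue", "stage")) {
  sample_class <- match.arg(sample_class)
  keep_samples <- sample_sheet$sample_id[sample_sheet$class == sample_class]
  ev <- candidates$events
  sets <- lapply(strsplit(ev$samples, ";", fixed = TRUE), intersect, keep_samples)
  ev$samples <- vapply(sets, paste, character(1L), collapse = ";")
  ev$n_samples <- lengths(sets)
  ev <- ev[ev$n_samples > 0L, , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev,
                 hits = candidates$hits[candidates$hits$event_id %in% ev$event_id, ,
                                        drop = FALSE]),
            class = "editing_candidates")
}

#' Per-sample counts of sample-specific events (accumulative convention)
#'
#' Keeps events present in at most `max_sharing` samples and lets each kept
#' event contribute 1 to the count of every sample it appears in (so an event
#' shared by two tissues counts once for each). The input events must carry
#' samples of a single class; mixing tissues and stages is an error — use
#' [restrict_to_sample_class()] first.
#'
#' @param candidates An `editing_candidates` object (events with `samples`).
#' @param sample_sheet Data.frame with `sample_id`, `class` columns; used to
#'   validate the class and to report zero counts for unobserved samples.
#' @param sample_class `"tissue"` or `"stage"`.
#' @param max_sharing Maximum number of samples an event may appear in
#'   (default 2: "specific to one or two samples").
#' @return Data.frame with columns `sample_id`, `count`, `max_sharing`.
#' @export
tissue_specific_counts <- function(candidates, sample_sheet,
                                   sample_class = c("tissue", "stage"),
                                   max_sharing = 2L) {
  sample_class <- match.arg(sample_class)
  cls_samples <- sample_sheet$sample_id[sample_sheet$class == sample_class]
  other <- sample_sheet$sample_id[!sample_sheet$class %in% c(sample_class, "genomic")]
  sets <- strsplit(candidates$events$samples, ";", fixed = TRUE)
  if (any(vapply(sets, function(s) any(s %in% other), logical(1L)))) {
    stop("events carry samples of mixed classes; restrict_to_sample_class() first")
  }
  keep <- lengths(sets) >= 1L & lengths(sets) <= max_sharing
  tab <- table(factor(unlist(sets[keep]), levels = cls_samples))
  data.frame(sample_id = cls_samples, count = as.integer(tab),
             max_sharing = as.integer(max_sharing), stringsAsFactors = FALSE)
}

#' Headline summary arithmetic
#'
#' The printed-precision conventions of the pipeline summary: mean events per
#' locus to 2 decimals, synonymous fraction as a percent rounded to the
#' nearest integer.
#'
#' @param n_events,n_loci_with_events,n_synonymous Counts.
#' @return List with `n_events`, `n_loci_with_events`,
#'   `mean_events_per_locus`, `synonymous_fraction` (integer percent).
#' @export
editing_summary <- function(n_events, n_loci_with_events, n_synonymous) {
  if (n_events == 0L) {
    return(list(n_events = 0L, n_loci_with_events = 0L,
                mean_events_per_locus = 0, synonymous_fraction = 0))
  }
  if (n_loci_with_events == 0L) {
    stop("events present but no loci with events")
  }
  list(n_events = as.integer(n_events),
       n_loci_with_events = as.integer(n_loci_with_events),
       mean_events_per_locus = round(n_events / n_loci_with_events, 2L),
       synonymous_fraction = as.integer(round(100 * n_synonymous / n_events)))
}

#' Summary statistics of an editing-candidate set
#'
#' Counts unique events and the coding loci (genes) harboring them, the mean
#' number of events per such locus (2 decimals), and the fraction of
#' synonymous events as an integer percent. An event counts as synonymous
#' iff it is synonymous in every isoform it hits.
#'
#' @param candidates An `editing_candidates` object.
#' @param total_coding_loci Optional total number of annotated coding loci,
#'   echoed back for context.
#' @return List as [editing_summary()] plus `total_coding_loci`.
#' @export
summary_stats <- function(candidates, total_coding_loci = NULL) {
  ev <- candidates$events
  res <- editing_summary(
    n_events = nrow(ev),
    n_loci_with_events = length(unique(candidates$hits$gene_id)),
    n_synonymous = sum(ev$synonymous))
  res$total_coding_loci <- total_coding_loci
  res
}

fmt_window <- function(w) ifelse(is.infinite(w), "Inf", format(w, trim = TRUE))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the report bundle of a pipeline run
#'
#' Emits the candidate events (TSV + VCF), per-isoform hits, conservation
#' calls and the window-by-class count table, the curated event list
#' (columns `SNV_Coordinates`, `Tissues`, query/reference gene ids,
#' `AA_Change`, `Variant_in_dsRNA` with values OK/NO), per-window
#' sample-specificity counts, and a JSON run manifest recording config, seed
#' and package version. All outputs are deterministic functions of the run
#' state, so re-running with the same seed and config reproduces them byte
#' for byte.
#'
#' @param run Pipeline state: a list with elements `candidates`, `snps`,
#'   `calls`, `counts`, `curation`, `sample_sheet`, and optionally `config`
#'   and `seed`.
#' @param out_dir Output directory (created if missing).
#' @return Named list of written file paths (also stored in
#'   `manifest.json`), invisibly.
#' @export
write_report_bundle <- function(run, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- list()
  cand <- run$candidates
  ev <- cand$events

  files$candidates_tsv <- write_tsv(ev, file.path(out_dir, "candidates.tsv"))
  files$candidate_hits_tsv <- write_tsv(cand$hits, file.path(out_dir, "candidate_hits.tsv"))
  aa_info <- if (nrow(ev)) {
    vapply(seq_len(nrow(ev)), function(i) {
      h <- cand$hits[cand$hits$event_id == ev$event_id[i] & cand$hits$alt == ev$alt[i], ]
      paste0("EDIT_AA=", paste0(h$transcript_id, ":", h$ref_aa, ">", h$edited_aa,
                                collapse = ","),
             if (ev$synonymous[i]) ";SYN" else "")
    }, character(1L))
  } else NULL
  vcf_df <- ev
  if (nrow(vcf_df)) {
    vcf_df$depth <- 0L
    vcf_df$alt_count <- 0L
  } else {
    vcf_df$depth <- integer(0L)
    vcf_df$alt_count <- integer(0L)
  }
  files$candidates_vcf <- file.path(out_dir, "candidates.vcf")
  write_snv_vcf(vcf_df, files$candidates_vcf, extra_info = aa_info)

  calls <- run$calls
  if (!is.null(calls)) {
    out_calls <- calls
    out_calls$window <- fmt_window(out_calls$window)
    files$conservation_calls_tsv <-
      write_tsv(out_calls, file.path(out_dir, "conservation_calls.tsv"))
  }
  counts <- run$counts
  if (!is.null(counts)) {
    out_counts <- counts
    out_counts$window <- fmt_window(out_counts$window)
    files$class_counts_tsv <- write_tsv(out_counts, file.path(out_dir, "class_counts.tsv"))
  }

  if (!is.null(run$curation)) {
    cur <- run$curation
    curated <- merge(cur, ev, by = "event_id", all.x = TRUE)
    gene_of <- function(eid) {
      g <- unique(cand$hits$gene_id[cand$hits$event_id == eid])
      paste(g, collapse = ";")
    }
    ref_gene_of <- function(eid) {
      if (is.null(calls)) return("")
      paste(unique(calls$ref_gene_id[calls$event_id == eid]), collapse = ";")
    }
    aa_change_of <- function(eid) {
      h <- cand$hits[cand$hits$event_id == eid, ]
      paste(unique(paste0(h$ref_aa, "->", h$edited_aa)), collapse = ";")
    }
    table2 <- data.frame(
      SNV_Coordinates = curated$event_id,
      Tissues = curated$samples,
      Query_Gene = vapply(curated$event_id, gene_of, character(1L)),
      Ref_Gene = vapply(curated$event_id, ref_gene_of, character(1L)),
      AA_Change = vapply(curated$event_id, aa_change_of, character(1L)),
      Variant_in_dsRNA = ifelse(curated$in_dsRNA, "OK", "NO"),
      stringsAsFactors = FALSE)
    files$curated_events_tsv <- write_tsv(table2, file.path(out_dir, "curated_events.tsv"))
  }

  sheet <- run$sample_sheet
  if (!is.null(sheet)) {
    for (cls in intersect(c("tissue", "stage"), unique(sheet$class))) {
      restricted <- restrict_to_sample_class(cand, sheet, cls)
      spec_all <- tissue_specific_counts(restricted, sheet, cls)
      files[[paste0("specificity_", cls, "_tsv")]] <-
        write_tsv(spec_all, file.path(out_dir, paste0("specificity_", cls, ".tsv")))
      if (!is.null(calls) && nrow(calls)) {
        per_w <- lapply(sort(unique(calls$window)), function(w) {
          ids <- unique(calls$event_id[calls$window == w])
          sub <- restricted
          sub$events <- sub$events[sub$events$event_id %in% ids, , drop = FALSE]
          cbind(window = fmt_window(w), tissue_specific_counts(sub, sheet, cls))
        })
        files[[paste0("specificity_", cls, "_by_window_tsv")]] <-
          write_tsv(do.call(rbind, per_w),
                    file.path(out_dir, paste0("specificity_", cls, "_by_window.tsv")))
      }
    }
  }

  if (!is.null(run$snps)) {
    files$snps_tsv <- write_tsv(run$snps, file.path(out_dir, "genomic_snps.tsv"))
  }

  manifest <- list(
    tool = "orthoedit",
    version = as.character(utils::packageVersion("orthoedit")),
    seed = run$seed,
    config = run$config,
    n_events = nrow(ev),
    files = lapply(files, basename))
  files$manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest_json, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(files)
}
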