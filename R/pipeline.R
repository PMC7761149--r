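## Declarative run configuration and the staged pipeline driver:
## candidates -> conserve -> curate -> report.

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a list. Fills defaults (depth cut-off 10,
#' windows 0/1/5/Inf, fold window 2000 nt), resolves paths and reports every
#' missing input at once.
#'
#' @param cfg Path to a YAML config or a named list. Mandatory keys:
#'   `genome`, `annotation`, `sample_sheet`, `homolog_pairs`, `ref_sites`,
#'   `ref_proteome`. Optional: `caller` (list, see [caller_params()]),
#'   `windows` (numeric vector or `"0,1,5,inf"` string), `fold` (list with
#'   `fold_window`, `min_loop`, `allow_gu`), `distance_metric`,
#'   `curate_window`, `curate_class`, `out_dir`, `seed`.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")

  problems <- character(0L)
  mandatory <- c("genome", "annotation", "sample_sheet", "homolog_pairs",
                 "ref_sites", "ref_proteome")
  for (key in mandatory) {
    if (is.null(cfg[[key]])) {
      problems <- c(problems, paste0("missing mandatory path: ", key))
    } else if (!file.exists(cfg[[key]])) {
      problems <- c(problems, paste0(key, " does not exist: ", cfg[[key]]))
    }
  }

  caller_defaults <- list(min_depth = 10L, min_alt_reads = 2L,
                          min_alt_fraction = 0.1, min_base_quality = 0L)
  caller <- utils::modifyList(caller_defaults, as.list(cfg$caller))
  params <- tryCatch(do.call(caller_params, caller), error = function(e) {
    problems <<- c(problems, conditionMessage(e))
    NULL
  })

  windows <- cfg$windows
  if (is.null(windows)) windows <- c(0, 1, 5, Inf)
  if (is.character(windows)) {
    windows <- unlist(strsplit(windows, ",", fixed = TRUE))
    windows <- vapply(trimws(windows), function(w) {
      if (tolower(w) %in% c("inf", "infinite")) Inf else suppressWarnings(as.numeric(w))
    }, numeric(1L))
  }
  windows <- as.numeric(windows)
  if (anyNA(windows) || any(windows < 0)) {
    problems <- c(problems, "windows must be non-negative numbers or 'inf'")
  }

  fold_defaults <- list(fold_window = 2000L, min_loop = 3L, allow_gu = TRUE)
  fold <- utils::modifyList(fold_defaults, as.list(cfg$fold))

  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }

  structure(list(
    genome = normalizePath(cfg$genome),
    annotation = normalizePath(cfg$annotation),
    sample_sheet = normalizePath(cfg$sample_sheet),
    homolog_pairs = normalizePath(cfg$homolog_pairs),
    ref_sites = normalizePath(cfg$ref_sites),
    ref_proteome = normalizePath(cfg$ref_proteome),
    caller = params,
    windows = sort(unique(windows)),
    fold = fold,
    distance_metric = if (is.null(cfg$distance_metric)) "column" else cfg$distance_metric,
    curate_window = if (is.null(cfg$curate_window)) 0 else as.numeric(cfg$curate_window),
    curate_class = if (is.null(cfg$curate_class)) 1L else as.integer(cfg$curate_class),
    out_dir = if (is.null(cfg$out_dir)) "orthoedit_out" else cfg$out_dir,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  ), class = "run_config")
}

read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "sam")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  }
  bad <- !sheet$class %in% c("tissue", "stage", "genomic")
  if (any(bad)) {
    stop("sample sheet class must be tissue, stage or genomic; got: ",
         paste(unique(sheet$class[bad]), collapse = ", "))
  }
  # relative SAM paths resolve against the sheet's own directory
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$sam)
  sheet$sam[rel] <- file.path(dirname(path), sheet$sam[rel])
  missing <- !file.exists(sheet$sam)
  if (any(missing)) {
    stop("sample sheet SAM file(s) not found: ",
         paste(sheet$sam[missing], collapse = ", "))
  }
  sheet
}

#' Run the full pipeline from a validated configuration
#'
#' Stages: candidate discovery (pileup, SNV calls, editing filter, SNP
#' subtraction, consequence annotation), conservation (alignment + window
#' matching), dsRNA curation of the selected window/class, and the report
#' bundle. Each stage's result is cached under `out_dir/cache/` and reused
#' on a resumed run with unchanged inputs.
#'
#' @param cfg A `run_config` from [validate_config()] (a list or YAML path is
#'   validated on the fly).
#' @param dry_run Print the stage plan and write nothing.
#' @param resume Reuse cached stage results when present (default FALSE).
#' @return Invisibly, the run state: `candidates`, `snps`, `calls`, `counts`,
#'   `curation`, `summary`, `files`, `config`.
#' @export
run_pipeline <- function(cfg, dry_run = FALSE, resume = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  stages <- c("candidates", "conserve", "curate", "report")
  if (dry_run) {
    cat("orthoedit run plan:\n")
    cat(paste0("  ", seq_along(stages), ". ", stages, collapse = "\n"), "\n")
    cat("out_dir:", cfg$out_dir, "(nothing written: dry run)\n")
    return(invisible(stages))
  }
  dir.create(file.path(cfg$out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)
  cache_path <- function(stage) file.path(cfg$out_dir, "cache", paste0(stage, ".rds"))
  with_cache <- function(stage, expr) {
    cp <- cache_path(stage)
    if (resume && file.exists(cp)) {
      message("stage ", stage, ": reusing cached result")
      return(readRDS(cp))
    }
    message("stage ", stage, ": running")
    res <- force(expr)
    saveRDS(res, cp)
    res
  }

  genome <- read_genome(cfg$genome)
  transcripts <- read_annotation(cfg$annotation)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  rna <- sheet[sheet$class %in% c("tissue", "stage"), , drop = FALSE]
  dna <- sheet$sam[sheet$class == "genomic"]

  stage1 <- with_cache("candidates", {
    find_editing_candidates(genome, transcripts,
                            rna_sams = stats::setNames(rna$sam, rna$sample_id),
                            dna_sams = dna, params = cfg$caller)
  })

  stage2 <- with_cache("conserve", {
    conserve_events(stage1$candidates, transcripts, genome,
                    pairs = read_homolog_pairs(cfg$homolog_pairs),
                    ref_sites = read_ref_sites(cfg$ref_sites),
                    ref_proteins = read_ref_proteome(cfg$ref_proteome),
                    windows = cfg$windows,
                    distance_metric = cfg$distance_metric)
  })

  stage3 <- with_cache("curate", {
    calls <- stage2$calls
    ids <- unique(calls$event_id[calls$window == cfg$curate_window &
                                 calls$cls == cfg$curate_class])
    curate_events(stage1$candidates, transcripts, genome,
                  fold_window = cfg$fold$fold_window,
                  min_loop = cfg$fold$min_loop, allow_gu = cfg$fold$allow_gu,
                  event_ids = ids)
  })

  cfg_json <- unclass(cfg)
  cfg_json$windows <- fmt_window(cfg_json$windows)  # Inf is not valid JSON
  cfg_json$caller <- unclass(cfg_json$caller)
  run <- list(candidates = stage1$candidates, snps = stage1$snps,
              calls = stage2$calls, counts = stage2$counts,
              curation = stage3, sample_sheet = sheet,
              config = cfg_json, seed = cfg$seed)
  run$summary <- summary_stats(stage1$candidates,
                               total_coding_loci = length(unique(
                                 vapply(transcripts, `[[`, "", "gene_id"))))
  run$files <- write_report_bundle(run, cfg$out_dir)
  run$config <- cfg
  invisible(run)
}
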