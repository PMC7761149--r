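## Seeded synthetic inputs with planted truth: genome, GFF3 annotation,
## per-sample RNA-seq SAM (spliced reads with N CIGAR ops), genomic-read SAM,
## reference proteome + editing sites, homolog pairs, and a truth table, so
## every pipeline stage is testable without external data.

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]

#' Specification of a synthetic fixture
#'
#' Defaults are the package's reference study conditions: 20 two-to-three-exon
#' genes on 4 scaffolds, RNA depth 30x over spliced transcripts, genomic
#' depth 15x, 50 planted editing events (per-read Bernoulli at editing level
#' 0.5, exercising the alt-fraction thresholds) and 50 planted homozygous
#' SNPs that mimic the A-to-G editing signature.
#'
#' @param seed Integer RNG seed; the whole fixture is a deterministic
#'   function of it.
#' @param n_scaffolds,scaffold_len Genome shape.
#' @param n_genes,isoforms_per_gene Gene models (isoform 2, when requested,
#'   drops the last exon).
#' @param rna_depth,dna_depth Approximate per-base read depths.
#' @param read_len Read length (nt).
#' @param seq_error_rate Per-base uniform substitution error rate.
#' @param n_planted_edits,n_planted_snps Planted item counts.
#' @param editing_level Per-read probability that an edited site reads as G.
#' @param fraction_conserved_sites Fraction of planted edits that also get a
#'   matching reference-species editing site.
#' @param planted_class_mix Named proportions over conservation classes
#'   `"0"`..`"4"` for the planted reference sites (class 0 is only reachable
#'   by synonymous query events, so the realized mix is conditioned on each
#'   edit's synonymy).
#' @param hairpin_fraction Fraction of edits embedded in a planted inverted
#'   repeat (dsRNA-positive truth).
#' @param unstructured_fraction Fraction of edits embedded in a pairing-free
#'   A/C-only context (dsRNA-negative truth within a 121-nt fold window).
#' @param tissues,stages Sample labels of the two sample classes.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_scaffolds = 4L, scaffold_len = 12000L,
                         n_genes = 20L, isoforms_per_gene = 1L,
                         rna_depth = 30, dna_depth = 15, read_len = 60L,
                         seq_error_rate = 0.001,
                         n_planted_edits = 50L, n_planted_snps = 50L,
                         editing_level = 0.5, fraction_conserved_sites = 0.6,
                         planted_class_mix = c("0" = 0.1, "1" = 0.3, "2" = 0.2,
                                               "3" = 0.2, "4" = 0.2),
                         hairpin_fraction = 0.2, unstructured_fraction = 0.2,
                         tissues = c("Gut", "Gills", "MaleGonads", "NeuralTube"),
                         stages = c("Embr8h", "Embr15h")) {
  sp <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
             scaffold_len = as.integer(scaffold_len), n_genes = as.integer(n_genes),
             isoforms_per_gene = as.integer(isoforms_per_gene),
             rna_depth = rna_depth, dna_depth = dna_depth,
             read_len = as.integer(read_len), seq_error_rate = seq_error_rate,
             n_planted_edits = as.integer(n_planted_edits),
             n_planted_snps = as.integer(n_planted_snps),
             editing_level = editing_level,
             fraction_conserved_sites = fraction_conserved_sites,
             planted_class_mix = planted_class_mix,
             hairpin_fraction = hairpin_fraction,
             unstructured_fraction = unstructured_fraction,
             tissues = tissues, stages = stages)
  stopifnot(sp$n_scaffolds >= 1L, sp$scaffold_len >= 1000L, sp$n_genes >= 1L,
            sp$isoforms_per_gene >= 1L, sp$rna_depth >= 1, sp$dna_depth >= 1,
            sp$read_len >= 20L, sp$seq_error_rate >= 0, sp$seq_error_rate < 1,
            sp$n_planted_edits >= 0L, sp$n_planted_snps >= 0L,
            sp$editing_level > 0, sp$editing_level <= 1,
            sp$fraction_conserved_sites >= 0, sp$fraction_conserved_sites <= 1,
            sp$hairpin_fraction + sp$unstructured_fraction <= 1)
  if (abs(sum(sp$planted_class_mix) - 1) > 1e-8) {
    stop("planted_class_mix proportions must sum to 1")
  }
  structure(sp, class = "fixture_spec")
}

#' Plant a conserved reference editing site for a query event
#'
#' Mutates a reference protein (initially a copy/homolog of the query) and
#' emits a reference edit-site record such that the (query event, reference
#' site) pair classifies as `target_class` at aligned distance
#' `window_offset`, assuming a gapless alignment of the two proteins.
#'
#' @param ref_protein Reference protein as a character vector of single
#'   letters (or a single string).
#' @param q_pos 1-based residue position of the query event.
#' @param q_pre,q_post Query pre-/post-edit residues.
#' @param q_syn Is the query event synonymous?
#' @param target_class Desired conservation class in `0:4`.
#' @param window_offset Desired aligned distance (>= 0). The site is placed
#'   at `q_pos + window_offset` when that fits in the protein, else at
#'   `q_pos - window_offset`.
#' @return List with `ref_protein` (modified letters), `site` (data.frame
#'   row: `aa_pos`, `pre_aa`, `post_aa`), `expected_class` and
#'   `expected_distance`.
#' @export
plant_conserved_site <- function(ref_protein, q_pos, q_pre, q_post, q_syn,
                                 target_class, window_offset = 0L) {
  if (length(ref_protein) == 1L && nchar(ref_protein) > 1L) {
    ref_protein <- strsplit(ref_protein, "")[[1L]]
  }
  if (!target_class %in% 0:4) stop("target_class must be in 0..4")
  if (window_offset < 0L) stop("window_offset must be >= 0")
  r_pos <- q_pos + window_offset
  if (r_pos > length(ref_protein)) r_pos <- q_pos - window_offset
  if (r_pos < 1L || r_pos > length(ref_protein)) {
    stop("window_offset places the site outside the reference protein")
  }
  pick_other <- function(exclude) {
    pool <- setdiff(AA20, exclude)
    pool[sample.int(length(pool), 1L)]
  }
  if (target_class == 0L) {
    if (!q_syn) stop("class 0 requires a synonymous query event")
    r_pre <- r_post <- ref_protein[r_pos]
  } else if (target_class == 1L) {
    if (q_syn) stop("class 1 requires a non-synonymous query event")
    r_pre <- q_pre
    r_post <- q_post
  } else if (target_class == 2L) {
    r_pre <- pick_other(c(q_pre, q_post))
    r_post <- q_post
  } else if (target_class == 3L) {
    r_pre <- q_pre
    r_post <- pick_other(c(q_post, q_pre))
  } else {
    r_pre <- pick_other(q_pre)
    r_post <- pick_other(c(q_post, r_pre))
  }
  ref_protein[r_pos] <- r_pre
  list(ref_protein = ref_protein,
       site = data.frame(aa_pos = r_pos, pre_aa = r_pre, post_aa = r_post,
                         stringsAsFactors = FALSE),
       expected_class = as.integer(target_class),
       expected_distance = abs(r_pos - q_pos))
}

wrap_fasta <- function(s, width = 70L) {
  starts <- seq.int(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

cigar_from_gpos <- function(gpos) {
  d <- diff(gpos)
  cig <- ""
  run <- 1L
  for (k in seq_along(d)) {
    if (d[k] == 1L) {
      run <- run + 1L
    } else {
      cig <- paste0(cig, run, "M", d[k] - 1L, "N")
      run <- 1L
    }
  }
  paste0(cig, run, "M")
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes a genome FASTA, GFF3 annotation, per-sample RNA-seq SAM files
#' (spliced reads with `N` CIGAR operations across introns), a genomic-read
#' SAM, a reference proteome, homolog-pair and reference edit-site tables, a
#' sample sheet and a truth table to `out_dir`. Deterministic given
#' `spec$seed`.
#'
#' Planted edits sit on transcript-strand adenosines inside the CDS (at least
#' 25 CDS bases from either end, so tiled reads cover them at full depth);
#' planted SNPs share that signature but appear homozygous in the genomic
#' reads and in every RNA read. A fraction of edits is embedded in a perfect
#' inverted repeat (dsRNA-positive) or in an A/C-only context that cannot
#' base-pair locally (dsRNA-negative within a 121-nt fold window).
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `files` (named paths), `truth` (the truth
#'   data.frame), and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_fixture_impl(spec, out_dir))
}

generate_fixture_impl <- function(spec, out_dir) {
  scaffolds <- sprintf("Sc%04d", seq_len(spec$n_scaffolds))
  genome_chars <- lapply(scaffolds, function(sc) {
    sample(DNA_BASES, spec$scaffold_len, replace = TRUE)
  })
  names(genome_chars) <- scaffolds

  ## ---- gene models ----------------------------------------------------
  cursors <- stats::setNames(rep(200L, spec$n_scaffolds), scaffolds)
  genes <- list()
  transcripts <- list()
  for (g in seq_len(spec$n_genes)) {
    sc <- scaffolds[(g - 1L) %% spec$n_scaffolds + 1L]
    n_exons <- sample(2:3, 1L)
    exon_lens <- 3L * sample(30:60, n_exons, replace = TRUE)
    intron_lens <- if (n_exons > 1L) sample(60:150, n_exons - 1L, replace = TRUE) else integer(0L)
    span <- sum(exon_lens) + sum(intron_lens)
    start <- cursors[[sc]]
    if (start + span > spec$scaffold_len - 200L) {
      stop("planted genes exceed available scaffold space; increase scaffold_len")
    }
    cursors[[sc]] <- start + span + sample(100:200, 1L)
    strand <- sample(c("+", "-"), 1L)
    seg <- matrix(0L, nrow = n_exons, ncol = 2L)
    p <- start
    for (e in seq_len(n_exons)) {
      seg[e, ] <- c(p, p + exon_lens[e] - 1L)
      p <- p + exon_lens[e] + if (e < n_exons) intron_lens[e] else 0L
    }
    gid <- sprintf("BL%05d", g)
    tid <- paste0(gid, "_T1")
    tms <- list(transcript_model(tid, gid, sc, strand, seg, 0L))
    if (spec$isoforms_per_gene > 1L && n_exons > 1L) {
      # shorter isoform: drop the 3'-most exon (each exon is a codon multiple)
      seg2 <- if (strand == "+") seg[-n_exons, , drop = FALSE] else seg[-1L, , drop = FALSE]
      tms <- c(tms, list(transcript_model(paste0(gid, "_T2"), gid, sc, strand, seg2, 0L)))
    }
    genes[[gid]] <- list(gene_id = gid, scaffold = sc, strand = strand,
                         segments = seg, span = c(start, p - 1L))
    for (tm in tms) transcripts[[tm$transcript_id]] <- tm
  }

  ## ---- plantable positions -------------------------------------------
  # keep plants far enough from transcript ends that tiled reads reach the
  # depth cut-off there: end depth ~ margin / step + 1 with step = len/depth
  rna_step0 <- max(1L, as.integer(round(spec$read_len / spec$rna_depth)))
  margin <- max(25L, 10L * rna_step0)
  pool <- do.call(rbind, lapply(genes, function(gn) {
    tm <- transcripts[[paste0(gn$gene_id, "_T1")]]
    pos_t <- transcript_cds_positions(tm)
    L <- length(pos_t)
    idx <- seq.int(margin + 1L, L - margin)
    gp <- pos_t[idx]
    base <- genome_chars[[gn$scaffold]][gp]
    want <- if (gn$strand == "+") "A" else "T"
    gp <- gp[base == want]
    if (!length(gp)) return(NULL)
    data.frame(gene_id = gn$gene_id, scaffold = gn$scaffold,
               strand = gn$strand, pos = gp, stringsAsFactors = FALSE)
  }))
  n_items <- spec$n_planted_edits + spec$n_planted_snps
  if (is.null(pool) || nrow(pool) < n_items) {
    stop("planted items exceed available CDS adenosine positions (",
         if (is.null(pool)) 0L else nrow(pool), " < ", n_items, ")")
  }
  picked <- pool[sample.int(nrow(pool), n_items), , drop = FALSE]
  edits <- picked[seq_len(spec$n_planted_edits), , drop = FALSE]
  snps <- picked[spec$n_planted_edits + seq_len(spec$n_planted_snps), , drop = FALSE]

  ## ---- structure-context surgery -------------------------------------
  # hairpin: write revcomp(15-nt arm ending at the edit) 4 nt downstream;
  # unstructured: overwrite +/-60 nt of the pre-mRNA with A/C only (no
  # Watson-Crick or wobble pair exists within an A/C alphabet).
  premrna_coord <- function(gn, gpos) {
    if (gn$strand == "+") gpos - gn$span[1L] + 1L else gn$span[2L] - gpos + 1L
  }
  premrna_get <- function(gn, t1, t2) {
    if (gn$strand == "+") {
      genome_chars[[gn$scaffold]][(gn$span[1L] + t1 - 1L):(gn$span[1L] + t2 - 1L)]
    } else {
      unname(COMPLEMENT[genome_chars[[gn$scaffold]][(gn$span[2L] - t1 + 1L):(gn$span[2L] - t2 + 1L)]])
    }
  }
  premrna_set <- function(gn, t1, t2, chars) {
    if (gn$strand == "+") {
      genome_chars[[gn$scaffold]][(gn$span[1L] + t1 - 1L):(gn$span[1L] + t2 - 1L)] <<- chars
    } else {
      genome_chars[[gn$scaffold]][(gn$span[2L] - t1 + 1L):(gn$span[2L] - t2 + 1L)] <<- unname(COMPLEMENT[chars])
    }
  }

  context <- rep("ambient", nrow(edits))
  n_hp <- round(spec$hairpin_fraction * nrow(edits))
  n_un <- round(spec$unstructured_fraction * nrow(edits))
  if (nrow(edits) && (n_hp > 0L || n_un > 0L)) {
    # every planted base (plus its codon) is reserved; a surgery window may
    # not touch any reserved interval but its own
    reserved <- data.frame(scaffold = picked$scaffold,
                           lo = picked$pos - 12L, hi = picked$pos + 12L,
                           stringsAsFactors = FALSE)
    clear_of_reserved <- function(sc, lo, hi, own_pos) {
      r <- reserved[reserved$scaffold == sc & !(reserved$lo == own_pos - 12L &
                                                reserved$hi == own_pos + 12L), ]
      !any(r$lo <= hi & r$hi >= lo)
    }
    reserve <- function(sc, lo, hi) {
      reserved[nrow(reserved) + 1L, ] <<- list(sc, lo, hi)
    }
    fits <- function(i, flank) {
      gn <- genes[[edits$gene_id[i]]]
      t <- premrna_coord(gn, edits$pos[i])
      len <- gn$span[2L] - gn$span[1L] + 1L
      t - flank >= 1L && t + flank <= len &&
        clear_of_reserved(edits$scaffold[i], edits$pos[i] - flank,
                          edits$pos[i] + flank, edits$pos[i])
    }
    for (i in sample(seq_len(nrow(edits)))) {
      if (sum(context == "hairpin") < n_hp && fits(i, 19L)) {
        context[i] <- "hairpin"
        reserve(edits$scaffold[i], edits$pos[i] - 19L, edits$pos[i] + 19L)
      } else if (sum(context == "unstructured") < n_un && fits(i, 61L)) {
        context[i] <- "unstructured"
        reserve(edits$scaffold[i], edits$pos[i] - 61L, edits$pos[i] + 61L)
      }
    }
    for (i in which(context == "hairpin")) {
      gn <- genes[[edits$gene_id[i]]]
      t <- premrna_coord(gn, edits$pos[i])
      arm <- premrna_get(gn, t - 14L, t)           # 15 nt ending at the edit A
      rc <- unname(COMPLEMENT[rev(arm)])
      premrna_set(gn, t + 4L, t + 18L, rc)         # 3-nt loop, then the arm's complement
    }
    for (i in which(context == "unstructured")) {
      gn <- genes[[edits$gene_id[i]]]
      t <- premrna_coord(gn, edits$pos[i])
      filler <- sample(c("A", "C"), 121L, replace = TRUE)
      filler[61L] <- "A"                           # the edit base itself
      premrna_set(gn, t - 60L, t + 60L, filler)
    }
  }
  edits$context <- if (nrow(edits)) context else character(0L)

  ## ---- per-edit sample sets and alleles -------------------------------
  all_samples <- c(spec$tissues, spec$stages)
  edits$samples <- vapply(seq_len(nrow(edits)), function(i) {
    k <- sample.int(3L, 1L, prob = c(0.5, 0.35, 0.15))
    paste(sort(sample(all_samples, min(k, length(all_samples)))), collapse = ";")
  }, character(1L))
  edits$alt <- ifelse(edits$strand == "+", "G", "C")  # genomic-space alt
  snps$alt <- ifelse(snps$strand == "+", "G", "C")

  ## ---- consequences (reference genome view) ---------------------------
  consequence_of <- function(df) {
    pre <- post <- syn <- rep(NA_character_, nrow(df))
    aa_pos <- rep(NA_integer_, nrow(df))
    for (i in seq_len(nrow(df))) {
      tm <- transcripts[[paste0(df$gene_id[i], "_T1")]]
      ctx <- genomic_to_codon(tm, genome_chars_str(), df$pos[i])
      if (is.null(ctx)) next
      edited <- ctx$codon
      substr(edited, ctx$codon_pos, ctx$codon_pos) <- "G"
      pre[i] <- ctx$ref_aa
      post[i] <- codon_aa(edited)
      syn[i] <- as.character(pre[i] == post[i])
      aa_pos[i] <- ctx$aa_pos
    }
    df$pre_aa <- pre
    df$post_aa <- post
    df$synonymous <- as.logical(syn)
    df$aa_pos <- aa_pos
    df
  }
  genome_chars_str <- function() {
    vapply(genome_chars, paste, character(1L), collapse = "")
  }
  edits <- consequence_of(edits)
  snps <- consequence_of(snps)

  ## ---- reference-species homologs, proteomes and edit sites -----------
  genome_str <- genome_chars_str()
  gene_nums <- stats::setNames(seq_along(genes), names(genes))
  ref_gene_of <- function(gid) sprintf("HS%03d", gene_nums[[gid]])
  ref_proteins <- lapply(names(genes), function(gid) {
    strsplit(translate_cds(spliced_cds(transcripts[[paste0(gid, "_T1")]], genome_str)),
             "")[[1L]]
  })
  names(ref_proteins) <- names(genes)

  edits$conserved <- if (nrow(edits)) {
    stats::runif(nrow(edits)) < spec$fraction_conserved_sites
  } else logical(0L)
  ne <- nrow(edits)
  edits$target_class <- rep(NA_integer_, ne)
  edits$window_offset <- rep(NA_integer_, ne)
  edits$ref_gene_id <- rep(NA_character_, ne)
  edits$ref_isoform_id <- rep(NA_character_, ne)
  edits$ref_aa_pos <- rep(NA_integer_, ne)
  edits$ref_pre_aa <- rep(NA_character_, ne)
  edits$ref_post_aa <- rep(NA_character_, ne)
  sites <- list()
  used_ref_pos <- list()
  mix <- spec$planted_class_mix
  for (i in which(edits$conserved)) {
    if (is.na(edits$aa_pos[i]) || edits$pre_aa[i] == "X") {
      edits$conserved[i] <- FALSE
      next
    }
    gid <- edits$gene_id[i]
    cls <- if (isTRUE(edits$synonymous[i])) 0L else {
      p <- mix[c("1", "2", "3", "4")]
      as.integer(sample(1:4, 1L, prob = p / sum(p)))
    }
    offset <- sample(c(0L, 0L, 0L, 1L, 3L, 6L), 1L)
    plant <- NULL
    for (off_try in unique(c(offset, 0L))) {
      r_try <- edits$aa_pos[i] + off_try
      if (r_try > length(ref_proteins[[gid]])) r_try <- edits$aa_pos[i] - off_try
      if (r_try %in% used_ref_pos[[gid]]) next
      plant <- plant_conserved_site(ref_proteins[[gid]], edits$aa_pos[i],
                                    edits$pre_aa[i], edits$post_aa[i],
                                    isTRUE(edits$synonymous[i]), cls, off_try)
      offset <- off_try
      break
    }
    if (is.null(plant)) {
      edits$conserved[i] <- FALSE
      next
    }
    ref_proteins[[gid]] <- plant$ref_protein
    used_ref_pos[[gid]] <- c(used_ref_pos[[gid]], plant$site$aa_pos)
    edits$target_class[i] <- plant$expected_class
    edits$window_offset[i] <- plant$expected_distance
    edits$ref_gene_id[i] <- ref_gene_of(gid)
    edits$ref_isoform_id[i] <- paste0(ref_gene_of(gid), "_P1")
    edits$ref_aa_pos[i] <- plant$site$aa_pos
    edits$ref_pre_aa[i] <- plant$site$pre_aa
    edits$ref_post_aa[i] <- plant$site$post_aa
    sites[[length(sites) + 1L]] <- data.frame(
      ref_gene_id = ref_gene_of(gid), ref_isoform_id = paste0(ref_gene_of(gid), "_P1"),
      aa_pos = plant$site$aa_pos, pre_aa = plant$site$pre_aa,
      post_aa = plant$site$post_aa, source_tag = "planted",
      stringsAsFactors = FALSE)
  }
  ref_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(ref_gene_id = character(), ref_isoform_id = character(),
               aa_pos = integer(), pre_aa = character(), post_aa = character(),
               source_tag = character(), stringsAsFactors = FALSE)

  ## ---- reads -----------------------------------------------------------
  snp_alt <- stats::setNames(snps$alt, paste(snps$scaffold, snps$pos))
  edit_alt <- stats::setNames(edits$alt, paste(edits$scaffold, edits$pos))
  edit_samples <- stats::setNames(strsplit(edits$samples, ";", fixed = TRUE),
                                  paste(edits$scaffold, edits$pos))

  add_errors <- function(bases) {
    if (spec$seq_error_rate <= 0) return(bases)
    err <- which(stats::runif(length(bases)) < spec$seq_error_rate)
    for (k in err) bases[k] <- sample(setdiff(DNA_BASES, bases[k]), 1L)
    bases
  }

  sam_header <- c("@HD\tVN:1.6\tSO:unsorted",
                  sprintf("@SQ\tSN:%s\tLN:%d", scaffolds, spec$scaffold_len))
  qual_str <- strrep("I", spec$read_len)

  rna_step <- max(1L, as.integer(round(spec$read_len / spec$rna_depth)))
  write_rna_sam <- function(sample_id, path) {
    recs <- character(0L)
    for (tid in names(transcripts)) {
      tm <- transcripts[[tid]]
      seg <- tm$segments
      pos_g <- unlist(lapply(seq_len(nrow(seg)), function(e) seg[e, 1L]:seg[e, 2L]),
                      use.names = FALSE)  # ascending genomic order
      L <- length(pos_g)
      if (L < spec$read_len) next
      starts <- seq.int(1L, L - spec$read_len + 1L, by = rna_step)
      key_all <- paste(tm$scaffold_id, pos_g)
      base_all <- genome_chars[[tm$scaffold_id]][pos_g]
      snp_hit <- !is.na(snp_alt[key_all])
      base_all[snp_hit] <- snp_alt[key_all[snp_hit]]
      edit_hit <- which(!is.na(edit_alt[key_all]) &
                          vapply(key_all, function(k) {
                            s <- edit_samples[[k]]
                            !is.null(s) && sample_id %in% s
                          }, logical(1L)))
      for (s0 in starts) {
        idx <- s0:(s0 + spec$read_len - 1L)
        bases <- base_all[idx]
        eh <- intersect(edit_hit, idx)
        if (length(eh)) {
          on <- eh[stats::runif(length(eh)) < spec$editing_level]
          bases[match(on, idx)] <- edit_alt[key_all[on]]
        }
        bases <- add_errors(bases)
        recs <- c(recs, paste(
          sprintf("r_%s_%s_%d", sample_id, tid, s0), 0L, tm$scaffold_id,
          pos_g[s0], 60L, cigar_from_gpos(pos_g[idx]), "*", 0L, 0L,
          paste(bases, collapse = ""), qual_str, sep = "\t"))
      }
    }
    writeLines(c(sam_header, recs), path)
    path
  }

  dna_step <- max(1L, as.integer(round(spec$read_len / spec$dna_depth)))
  write_dna_sam <- function(path) {
    recs <- character(0L)
    for (sc in scaffolds) {
      chars <- genome_chars[[sc]]
      keys <- paste(sc, seq_along(chars))
      hit <- !is.na(snp_alt[keys])
      chars[hit] <- snp_alt[keys[hit]]
      starts <- seq.int(1L, spec$scaffold_len - spec$read_len + 1L, by = dna_step)
      for (s0 in starts) {
        bases <- add_errors(chars[s0:(s0 + spec$read_len - 1L)])
        recs <- c(recs, paste(
          sprintf("d_%s_%d", sc, s0), 0L, sc, s0, 60L,
          paste0(spec$read_len, "M"), "*", 0L, 0L,
          paste(bases, collapse = ""), qual_str, sep = "\t"))
      }
    }
    writeLines(c(sam_header, recs), path)
    path
  }

  ## ---- write bundle ----------------------------------------------------
  files <- list()
  files$genome <- file.path(out_dir, "genome.fa")
  fa <- unlist(lapply(scaffolds, function(sc) {
    c(paste0(">", sc), wrap_fasta(paste(genome_chars[[sc]], collapse = "")))
  }))
  writeLines(fa, files$genome)

  files$annotation <- file.path(out_dir, "annotation.gff3")
  gff <- c("##gff-version 3")
  for (gid in names(genes)) {
    gn <- genes[[gid]]
    gff <- c(gff, sprintf("%s\torthoedit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          gn$scaffold, gn$span[1L], gn$span[2L], gn$strand, gid))
    for (tid in names(transcripts)) {
      tm <- transcripts[[tid]]
      if (tm$gene_id != gid) next
      gff <- c(gff, sprintf("%s\torthoedit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            tm$scaffold_id, min(tm$segments[, 1L]),
                            max(tm$segments[, 2L]), tm$strand, tid, gid))
      for (e in seq_len(nrow(tm$segments))) {
        gff <- c(gff, sprintf("%s\torthoedit\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s-%d;Parent=%s",
                              tm$scaffold_id, tm$segments[e, 1L], tm$segments[e, 2L],
                              tm$strand, tid, e, tid))
      }
    }
  }
  writeLines(gff, files$annotation)

  files$dna_sam <- write_dna_sam(file.path(out_dir, "dna.sam"))
  rna_paths <- character(0L)
  for (sid in all_samples) {
    p <- write_rna_sam(sid, file.path(out_dir, paste0("rna_", sid, ".sam")))
    rna_paths[sid] <- p
  }
  files$rna_sams <- rna_paths

  files$ref_proteome <- file.path(out_dir, "ref_proteome.fa")
  fa <- unlist(lapply(names(genes), function(gid) {
    c(paste0(">", ref_gene_of(gid), "_P1"),
      wrap_fasta(paste(ref_proteins[[gid]], collapse = "")))
  }))
  writeLines(fa, files$ref_proteome)

  files$homolog_pairs <- file.path(out_dir, "homolog_pairs.tsv")
  utils::write.table(
    data.frame(query_gene_id = names(genes),
               ref_gene_id = vapply(names(genes), ref_gene_of, character(1L))),
    files$homolog_pairs, sep = "\t", quote = FALSE, row.names = FALSE)

  files$ref_sites <- file.path(out_dir, "ref_sites.tsv")
  utils::write.table(ref_sites, files$ref_sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files$sample_sheet <- file.path(out_dir, "sample_sheet.tsv")
  # SAM paths are relative to the sheet so the bundle is relocatable (and
  # byte-identical across output directories); read_sample_sheet resolves them
  sheet <- data.frame(
    sample_id = c(all_samples, "genomic"),
    class = c(rep("tissue", length(spec$tissues)),
              rep("stage", length(spec$stages)), "genomic"),
    sam = basename(c(unname(rna_paths), files$dna_sam)),
    stringsAsFactors = FALSE)
  utils::write.table(sheet, files$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- rbind(
    if (nrow(edits)) cbind(data.frame(kind = "edit", stringsAsFactors = FALSE),
                           edits, expected_in_dsRNA = ifelse(
                             edits$context == "hairpin", TRUE,
                             ifelse(edits$context == "unstructured", FALSE, NA))),
    if (nrow(snps)) {
      s <- snps
      s$context <- "ambient"
      s$samples <- ""
      s$conserved <- FALSE
      s$target_class <- NA_integer_
      s$window_offset <- NA_integer_
      s$ref_gene_id <- NA_character_
      s$ref_isoform_id <- NA_character_
      s$ref_aa_pos <- NA_integer_
      s$ref_pre_aa <- NA_character_
      s$ref_post_aa <- NA_character_
      cbind(data.frame(kind = "snp", stringsAsFactors = FALSE), s,
            expected_in_dsRNA = NA)
    })
  if (!is.null(truth) && nrow(truth)) {
    truth$ref <- ifelse(truth$strand == "+", "A", "T")
    truth <- truth[order(truth$kind, truth$scaffold, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(
      kind = character(), gene_id = character(), scaffold = character(),
      strand = character(), pos = integer(), context = character(),
      samples = character(), alt = character(), pre_aa = character(),
      post_aa = character(), synonymous = logical(), aa_pos = integer(),
      conserved = logical(), target_class = integer(), window_offset = integer(),
      ref_gene_id = character(), ref_isoform_id = character(),
      ref_aa_pos = integer(), ref_pre_aa = character(),
      ref_post_aa = character(), expected_in_dsRNA = logical(),
      ref = character(), stringsAsFactors = FALSE)
  }
  files$truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(files = files, truth = truth, spec = spec))
}
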