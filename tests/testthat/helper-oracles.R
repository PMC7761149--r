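# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimized paths on small inputs.

# Per-read, per-base pileup walker (no vectorization, no shared code with
# build_pileup beyond the SAM data.frame shape).
naive_pileup <- function(sam, genome) {
  acc <- new.env(parent = emptyenv())
  bump <- function(sc, pos, base) {
    key <- paste(sc, pos)
    cur <- acc[[key]]
    if (is.null(cur)) cur <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    cur[base] <- cur[base] + 1L
    acc[[key]] <- cur
  }
  for (i in seq_len(nrow(sam))) {
    if (bitwAnd(sam$flag[i], 0x4L + 0x100L + 0x800L) != 0L) next
    if (sam$cigar[i] == "*" || sam$rname[i] == "*") next
    toks <- regmatches(sam$cigar[i], gregexpr("[0-9]+[A-Z=]", sam$cigar[i]))[[1L]]
    rpos <- sam$pos[i]
    qpos <- 1L
    for (tok in toks) {
      len <- as.integer(sub("[A-Z=]$", "", tok))
      op <- sub("^[0-9]+", "", tok)
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          b <- substr(sam$seq[i], qpos, qpos)
          if (b %in% c("A", "C", "G", "T")) bump(sam$rname[i], rpos, b)
          rpos <- rpos + 1L
          qpos <- qpos + 1L
        }
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(scaffold = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  df <- data.frame(scaffold = parts[, 1L], pos = as.integer(parts[, 2L]),
                   t(vapply(keys, function(k) acc[[k]], integer(4L))),
                   stringsAsFactors = FALSE)
  names(df)[3:6] <- c("A", "C", "G", "T")
  df$depth <- df$A + df$C + df$G + df$T
  df <- df[order(df$scaffold, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive global affine-gap alignment: recursively enumerates every
# alignment and returns the maximum score (gap of length L costs
# open + extend * L, matching the pairwiseAlignment convention).
exhaustive_align_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {
      cost <- gap_extend + if (identical(last, "A")) 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, "A"))
    }
    if (j <= length(bv)) {
      cost <- gap_extend + if (identical(last, "B")) 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, "B"))
    }
    best
  }
  rec(1L, 1L, "none")
}

# Re-score a gapped alignment from its strings (affine gaps), to confirm the
# reported score is consistent with the emitted alignment.
score_alignment <- function(aq, ar, mat, gap_open = 11, gap_extend = 1) {
  q <- strsplit(aq, "")[[1L]]
  r <- strsplit(ar, "")[[1L]]
  s <- 0
  in_gap <- ""
  for (k in seq_along(q)) {
    if (q[k] == "-" || r[k] == "-") {
      side <- if (q[k] == "-") "q" else "r"
      s <- s - gap_extend - if (identical(in_gap, side)) 0 else gap_open
      in_gap <- side
    } else {
      s <- s + mat[q[k], r[k]]
      in_gap <- ""
    }
  }
  s
}

# Brute-force maximum non-crossing base pairing: recursion over explicit
# position sets (first available base unpaired, or paired with each
# admissible partner, splitting inside/outside).
bf_max_pairs <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  can <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "CG", "GC") || (allow_gu && p %in% c("GU", "UG"))
  }
  rec <- function(idx) {
    if (length(idx) < 2L) return(0L)
    i <- idx[1L]
    best <- rec(idx[-1L])
    for (j in idx[-1L]) {
      if (j - i - 1L >= min_loop && can(ch[i], ch[j])) {
        inside <- idx[idx > i & idx < j]
        outside <- idx[idx > j]
        best <- max(best, 1L + rec(inside) + rec(outside))
      }
    }
    best
  }
  rec(seq_along(ch))
}

# Validity check of a secondary structure object against its own invariants.
expect_valid_structure <- function(ss, min_loop = 3L) {
  n <- nchar(ss$sequence)
  expect_equal(nchar(ss$dotbracket), n)
  p <- ss$partner
  paired <- which(p > 0L)
  expect_true(all(p[p[paired]] == paired))      # involution
  if (nrow(ss$pairs)) {
    expect_true(all(ss$pairs[, 2L] - ss$pairs[, 1L] - 1L >= min_loop))
  }
}
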