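#' Default alignment scoring parameters
#'
#' ONT-tolerant defaults for amplicon-scale alignment: match +2, mismatch
#' -4, two-piece gaps — a gap of length k costs
#' `min(4 + 2k, 24 + k)`, the long-gap piece keeping large inserts (e.g. a
#' 143 bp synthetic intron) contiguous instead of fragmenting through
#' chance micro-matches — and an adaptive band of `2 * expected_indel + 32`
#' diagonals that widens automatically until the optimum is stable.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (short-gap
#'   piece).
#' @param gap_open2,gap_extend2 Long-gap piece; with the defaults the long
#'   piece takes over for gaps beyond 20 nt.
#' @param expected_indel Expected net indel length (sets the initial band).
#' @return A list of parameters.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_open = -4,
                         gap_extend = -2, gap_open2 = -24,
                         gap_extend2 = -1, expected_indel = 0L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, gap_open2 = gap_open2,
       gap_extend2 = gap_extend2,
       band = as.integer(2L * expected_indel + 32L))
}

#' Align a read to an amplicon (end-free affine-gap)
#'
#' Banded "glocal" alignment: the reference flanks are free and unaligned
#' read ends become soft clips. The band widens automatically (doubling)
#' until the optimal path no longer touches the band edge and the score is
#' stable, so the result equals the unbanded optimum. Indels are left-aligned
#' to their canonical leftmost position and ops are normalised (merged runs,
#' no leading/trailing I or D).
#'
#' @param read_seq Read sequence (or a one-row data frame from
#'   [simulate_reads()]).
#' @param amp An [amplicon()] (or a plain reference string).
#' @param params Scoring parameters from [align_params()].
#' @param read_id,quality Read metadata; quality is a Phred+33 string (used
#'   by the pileup's base-quality filter).
#' @param try_both_strands Also align the reverse complement and keep the
#'   better strand (default `TRUE`).
#' @return An `aligned_read`: `read_id`, `amplicon_id`, `ref_start`
#'   (0-based), `ops` (data frame `op` in M/I/D/S and `len`), `score`,
#'   `strand`, `map_conf`, `sequence` and `quality` in aligned orientation.
#' @export
align_read <- function(read_seq, amp, params = align_params(),
                       read_id = "read", quality = NULL,
                       try_both_strands = TRUE) {
  if (is.data.frame(read_seq)) {
    read_id <- read_seq$read_id[1]
    quality <- read_seq$quality[1]
    read_seq <- read_seq$sequence[1]
  }
  if (is.character(amp)) amp <- amplicon("ref", amp)
  if (!nzchar(read_seq)) stop("empty read")
  strands <- if (try_both_strands) c("+", "-") else "+"
  best <- NULL
  for (st in strands) {
    q <- if (st == "+") read_seq else revcomp(read_seq)
    res <- .align_banded(q, amp$sequence, params)
    if (is.null(best) || res$score > best$score) {
      best <- res; best$strand <- st; best$query <- q
    }
  }
  qual <- quality
  if (!is.null(qual) && best$strand == "-")
    qual <- paste(rev(seq_chars(qual)), collapse = "")
  ops <- data.frame(op = best$op, len = as.integer(best$len),
                    stringsAsFactors = FALSE)
  norm <- normalize_ops(ops, best$ref_start, best$query, amp$sequence)
  structure(list(read_id = read_id, amplicon_id = amp$id,
                 ref_start = norm$ref_start, ops = norm$ops,
                 score = best$score, strand = best$strand, map_conf = 60L,
                 sequence = best$query, quality = qual),
            class = "aligned_read")
}

# banded DP with automatic widening until the optimum is stable
.align_banded <- function(query, ref, params) {
  band <- max(1L, params$band)
  full_band <- nchar(query) + nchar(ref)
  last_score <- NULL
  repeat {
    res <- .align_glocal_cpp(query, ref, params$match, params$mismatch,
                             -params$gap_open, -params$gap_extend,
                             -params$gap_open2, -params$gap_extend2, band)
    if (!isTRUE(res$ok)) stop("alignment failed")
    stable <- !res$touched_boundary &&
      (!is.null(last_score) && res$score == last_score)
    if (band >= full_band ||
        (!res$touched_boundary && is.null(last_score)) || stable)
      return(res)
    last_score <- if (res$touched_boundary) NULL else res$score
    band <- min(full_band, band * 2L)
  }
}

# merge runs, convert terminal insertions to soft clips, drop terminal
# deletions into ref_start / ref span, left-align interior indels
normalize_ops <- function(ops, ref_start, query, ref) {
  ops <- merge_ops(ops)
  # terminal D: not an alignment statement, fold into the free flank
  while (nrow(ops) && ops$op[1] == "D") {
    ref_start <- ref_start + ops$len[1]; ops <- ops[-1, , drop = FALSE]
  }
  while (nrow(ops) && ops$op[nrow(ops)] == "D")
    ops <- ops[-nrow(ops), , drop = FALSE]
  # terminal I -> S
  if (nrow(ops) && ops$op[1] == "I") ops$op[1] <- "S"
  if (nrow(ops) && ops$op[nrow(ops)] == "I") ops$op[nrow(ops)] <- "S"
  la <- left_align_indels(ops, ref_start, query, ref)
  ops <- merge_ops(la$ops); ref_start <- la$ref_start
  # left-alignment may have exposed a new terminal D
  first_real <- if (nrow(ops) && ops$op[1] == "S") 2L else 1L
  while (nrow(ops) >= first_real && ops$op[first_real] == "D") {
    ref_start <- ref_start + ops$len[first_real]
    ops <- ops[-first_real, , drop = FALSE]
  }
  last_real <- if (nrow(ops) && ops$op[nrow(ops)] == "S") nrow(ops) - 1L
               else nrow(ops)
  while (last_real >= 1L && ops$op[last_real] == "D") {
    ops <- ops[-last_real, , drop = FALSE]
    last_real <- last_real - 1L
  }
  rownames(ops) <- NULL
  list(ops = ops, ref_start = ref_start)
}

merge_ops <- function(ops) {
  if (nrow(ops) < 2L) return(ops)
  keep <- c(TRUE, ops$op[-1] != ops$op[-nrow(ops)])
  grp <- cumsum(keep)
  data.frame(op = ops$op[keep],
             len = as.integer(tapply(ops$len, grp, sum)),
             stringsAsFactors = FALSE)
}

# Shift interior I/D runs to their leftmost equivalent position (canonical
# VCF-style left alignment) so pileup and window-overlap logic see canonical
# coordinates. A deletion of ref[r, r+len) flanked by M ops shifts left one
# base when ref[r-1] == ref[r+len-1]; an insertion of read[q, q+len) shifts
# left when read[q-1] == read[q+len-1]. Shifting swaps one aligned base from
# the preceding M to the following M and leaves the aligned sequences
# unchanged.
left_align_indels <- function(ops, ref_start, query, ref) {
  refc <- seq_chars(ref); qc <- seq_chars(query)
  repeat {
    moved <- FALSE
    qpos <- 0L; rpos <- ref_start   # 0-based, consumed so far
    k <- 1L
    while (k <= nrow(ops)) {
      op <- ops$op[k]; len <- ops$len[k]
      shiftable <- (op == "D" || op == "I") &&
        k > 1L && k < nrow(ops) &&
        ops$op[k - 1L] == "M" && ops$op[k + 1L] == "M"
      if (shiftable) {
        while (ops$len[k - 1L] > 0L) {
          can <- if (op == "D") refc[rpos] == refc[rpos + len]
                 else qc[qpos] == qc[qpos + len]
          if (!isTRUE(can)) break
          ops$len[k - 1L] <- ops$len[k - 1L] - 1L
          ops$len[k + 1L] <- ops$len[k + 1L] + 1L
          rpos <- rpos - 1L; qpos <- qpos - 1L
          moved <- TRUE
        }
      }
      if (op %in% c("M", "S", "I")) qpos <- qpos + len
      if (op %in% c("M", "D")) rpos <- rpos + len
      k <- k + 1L
    }
    ops <- ops[ops$len > 0L, , drop = FALSE]
    ops <- merge_ops(ops)
    if (!moved) break
  }
  list(ops = ops, ref_start = ref_start)
}
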