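#' Assign a read to the best-matching amplicon of a pool
#'
#' Aligns the read to every amplicon (both strands) and keeps the best
#' scorer. The mapping confidence is derived from the score margin:
#' `map_conf = min(60, c * (best - second_best))` with `c = 6`; with a
#' single amplicon the assignment is unambiguous and `map_conf = 60`.
#' Identical amplicons therefore force `map_conf = 0`. The result is
#' invariant to the order of the amplicon list.
#'
#' @param read_seq Read sequence (or one-row data frame from
#'   [simulate_reads()]).
#' @param amps List of [amplicon()] objects.
#' @param params Scoring parameters from [align_params()].
#' @param score_floor Minimum acceptable base-level support — the score of
#'   the aligned (M) columns alone, ignoring gap costs, so reads carrying a
#'   long legitimate insert are not rejected for their gap penalty. Below it
#'   the read is unassigned (`NULL`, counted by callers).
#' @param conf_scale Margin-to-confidence factor `c` (default 6).
#' @return An `aligned_read` for the winning amplicon with `map_conf` set,
#'   or `NULL` when all reads fall below `score_floor`.
#' @export
assign_amplicon <- function(read_seq, amps, params = align_params(),
                            score_floor = 20, conf_scale = 6) {
  stopifnot(length(amps) >= 1L)
  alns <- lapply(amps, function(a)
    align_read(read_seq, a, params = params))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  ord <- order(scores, decreasing = TRUE)
  best <- alns[[ord[1]]]
  amp_best <- amps[[ord[1]]]
  if (alignment_support(best, amp_best$sequence, params) < score_floor)
    return(NULL)
  margin <- if (length(scores) == 1L) Inf
            else scores[ord[1]] - scores[ord[2]]
  best$map_conf <- as.integer(min(60, floor(conf_scale * margin)))
  best
}

# score of the aligned columns only (gap costs excluded): evidence that the
# read derives from this amplicon even when it carries a large indel
alignment_support <- function(al, ref, params = align_params()) {
  rpos <- al$ref_start; qpos <- 0L
  refc <- seq_chars(ref); qc <- seq_chars(al$sequence)
  s <- 0
  for (k in seq_len(nrow(al$ops))) {
    op <- al$ops$op[k]; len <- al$ops$len[k]
    if (op == "M") {
      eq <- qc[qpos + seq_len(len)] == refc[rpos + seq_len(len)]
      s <- s + sum(eq) * params$match + sum(!eq) * params$mismatch
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") rpos <- rpos + len
    else qpos <- qpos + len
  }
  s
}

ops_to_cigar <- function(ops) {
  if (!nrow(ops)) return("*")
  paste0(ops$len, ops$op, collapse = "")
}

cigar_to_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  m <- gregexpr("\\d+[MIDSH=X]", cigar)[[1]]
  if (m[1] < 0 || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDSH=X]", cigar))[[1]]
  op <- substring(toks, nchar(toks), nchar(toks))
  op[op %in% c("=", "X")] <- "M"
  data.frame(op = op, len = as.integer(sub("[MIDSH=X]$", "", toks)),
             stringsAsFactors = FALSE)
}

# query length implied by the ops (query-consuming ops)
ops_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S")])
# reference span implied by the ops
ops_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

#' Write aligned reads as a SAM file
#'
#' Emits `@HD`/`@SQ` headers from the amplicon pool and one record per
#' aligned read (FLAG 0 or 16 by strand, 1-based POS, MAPQ from `map_conf`,
#' CIGAR from the ops). SEQ/QUAL are written in the aligned (reference)
#' orientation, as SAM requires.
#'
#' @param alns List of `aligned_read` objects.
#' @param amps List of [amplicon()] objects (the pool; provides `@SQ`).
#' @param path Output path.
#' @export
write_sam <- function(alns, amps, path) {
  if (inherits(amps, "amplicon")) amps <- list(amps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (a in amps)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", a$id, nchar(a$sequence)), con)
  for (al in alns) {
    flag <- if (identical(al$strand, "-")) 16L else 0L
    qual <- if (is.null(al$quality) || !nzchar(al$quality)) "*" else al$quality
    writeLines(paste(al$read_id, flag, al$amplicon_id, al$ref_start + 1L,
                     al$map_conf, ops_to_cigar(al$ops), "*", 0L, 0L,
                     al$sequence, qual, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM file into aligned reads
#'
#' Imports MAPQ into `map_conf` and CIGAR into ops, so output from an
#' external aligner (e.g. minimap2 with the map-ont preset) can substitute
#' for the native aligner. Unmapped records (FLAG 0x4 or CIGAR `*`) are
#' skipped and counted.
#'
#' @param path SAM path.
#' @return List of `aligned_read` objects; the number of skipped unmapped
#'   records is attached as attribute `n_unmapped`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  out <- list()
  n_unmapped <- 0L
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed SAM record at line ",
           which(!startsWith(lines, "@"))[k])
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L || f[6] == "*") {
      n_unmapped <- n_unmapped + 1L
      next
    }
    ops <- cigar_to_ops(f[6])
    if (ops_query_len(ops) != nchar(f[10]) && f[10] != "*")
      stop("CIGAR/SEQ length mismatch at line ",
           which(!startsWith(lines, "@"))[k])
    out[[length(out) + 1L]] <- structure(list(
      read_id = f[1], amplicon_id = f[3],
      ref_start = as.integer(f[4]) - 1L, ops = ops, score = NA_real_,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      map_conf = as.integer(f[5]), sequence = f[10],
      quality = if (f[11] == "*") NULL else f[11]), class = "aligned_read")
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read> %s -> %s:%d(%s) %s mapq %d\n",
              x$read_id, x$amplicon_id, x$ref_start, x$strand,
              ops_to_cigar(x$ops), x$map_conf))
  invisible(x)
}

#' Align a set of reads against an amplicon pool
#'
#' Convenience wrapper: [assign_amplicon()] for every read of a FASTQ data
#' frame. Unassigned reads are dropped and counted.
#'
#' @param reads Data frame from [simulate_reads()] / [read_fastq()].
#' @param amps List of [amplicon()] objects.
#' @param params Scoring parameters.
#' @return List of `aligned_read`, attribute `n_unassigned`.
#' @export
align_reads <- function(reads, amps, params = align_params()) {
  if (inherits(amps, "amplicon")) amps <- list(amps)
  out <- list()
  n_un <- 0L
  for (i in seq_len(nrow(reads))) {
    al <- assign_amplicon(reads[i, , drop = FALSE], amps, params = params)
    if (is.null(al)) n_un <- n_un + 1L else out[[length(out) + 1L]] <- al
  }
  attr(out, "n_unassigned") <- n_un
  out
}
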