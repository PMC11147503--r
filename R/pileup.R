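#' Quality thresholds for pileup counting
#'
#' Defaults mirror the variant-calling criteria used throughout the
#' package: base quality >= 16, mapping quality >= 10, depth capped at
#' 10,000 reads (first-come order).
#'
#' @param min_base_quality Minimum Phred base quality for a call (16).
#' @param min_map_quality Minimum mapping quality for a read (10).
#' @param max_depth Depth cap per amplicon (10,000).
#' @return A `quality_thresholds` list.
#' @export
quality_thresholds <- function(min_base_quality = 16L, min_map_quality = 10L,
                               max_depth = 10000L) {
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_map_quality = as.integer(min_map_quality),
                 max_depth = as.integer(max_depth)),
            class = "quality_thresholds")
}

phred_values <- function(qual_string) utf8ToInt(qual_string) - 33L

#' Per-site pileup of aligned reads
#'
#' Produces per-position high-quality tallies of reference bases,
#' substitution alleles, deletions, and insertions. Reads below the mapping
#' quality threshold are excluded entirely; base calls below the base
#' quality threshold are excluded at that site only. Deletions are counted
#' once at their (left-aligned) anchor position with their span recorded,
#' and additionally tracked as span coverage across every deleted position;
#' insertions are keyed by inserted sequence and anchored after the
#' preceding reference base (VCF convention). Reads beyond the depth cap
#' are dropped in input order (count attached as attribute `n_depth_capped`).
#'
#' @param alns List of `aligned_read` objects on one amplicon.
#' @param amp The [amplicon()] they align to.
#' @param thresholds A [quality_thresholds()].
#' @return A `site_pileup`: list with `amplicon_id`, vectors/matrices
#'   `depth_hq`, `ref_count`, `subs` (4 x L, rows A/C/G/T),
#'   `del_span_cover`, and event maps `dels` (named counts `"pos:span"`),
#'   `ins` (named counts `"pos:seq"`, insertion after position `pos - 1`).
#' @export
pileup <- function(alns, amp, thresholds = quality_thresholds()) {
  stopifnot(inherits(amp, "amplicon"))
  L <- nchar(amp$sequence)
  refc <- seq_chars(amp$sequence)
  bases <- c("A", "C", "G", "T")
  ref_count <- integer(L)
  subs <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  depth_hq <- integer(L)
  del_span_cover <- integer(L)
  dels <- new.env(parent = emptyenv())
  ins <- new.env(parent = emptyenv())
  bump <- function(env, key) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0L) + 1L,
           envir = env)
  }
  n_used <- 0L
  n_capped <- 0L
  for (al in alns) {
    if (!identical(al$amplicon_id, amp$id))
      stop("alignment references amplicon '", al$amplicon_id,
           "', not '", amp$id, "'")
    if (al$map_conf < thresholds$min_map_quality) next
    if (n_used >= thresholds$max_depth) { n_capped <- n_capped + 1L; next }
    n_used <- n_used + 1L
    q <- if (is.null(al$quality)) NULL else phred_values(al$quality)
    rpos <- al$ref_start   # 0-based next reference position
    qpos <- 0L             # 0-based next query position
    for (k in seq_len(nrow(al$ops))) {
      op <- al$ops$op[k]; len <- al$ops$len[k]
      if (op == "S") {
        qpos <- qpos + len
      } else if (op == "M") {
        if (rpos + len > L) stop("alignment extends past reference end")
        rr <- seq.int(rpos + 1L, rpos + len)          # 1-based ref index
        qq <- seq.int(qpos + 1L, qpos + len)
        calls <- substring(al$sequence, qq, qq)
        ok <- if (is.null(q)) rep(TRUE, len) else
          q[qq] >= thresholds$min_base_quality
        ok <- ok & calls %in% bases
        if (any(ok)) {
          is_ref <- calls[ok] == refc[rr[ok]]
          depth_hq[rr[ok]] <- depth_hq[rr[ok]] + 1L
          hit_ref <- rr[ok][is_ref]
          if (length(hit_ref)) {
            tab <- tabulate(hit_ref, nbins = L)
            ref_count <- ref_count + tab
          }
          mis <- which(ok)[!is_ref]
          for (idx in mis)
            subs[calls[idx], rr[idx]] <- subs[calls[idx], rr[idx]] + 1L
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        if (rpos + len > L) stop("alignment extends past reference end")
        bump(dels, sprintf("%d:%d", rpos, len))
        span <- seq.int(rpos + 1L, rpos + len)
        del_span_cover[span] <- del_span_cover[span] + 1L
        rpos <- rpos + len
      } else if (op == "I") {
        seq_ins <- substring(al$sequence, qpos + 1L, qpos + len)
        bump(ins, sprintf("%d:%s", rpos - 1L, seq_ins))
        qpos <- qpos + len
      } else stop("unknown op: ", op)
    }
  }
  out <- structure(list(
    amplicon_id = amp$id, length = L,
    depth_hq = depth_hq, ref_count = ref_count, subs = subs,
    del_span_cover = del_span_cover,
    dels = unlist(as.list(dels)), ins = unlist(as.list(ins)),
    thresholds = thresholds, n_reads_used = n_used), class = "site_pileup")
  attr(out, "n_depth_capped") <- n_capped
  if (is.null(out$dels)) out$dels <- setNames(integer(0), character(0))
  if (is.null(out$ins)) out$ins <- setNames(integer(0), character(0))
  out
}

# parse "pos:span" / "pos:seq" keyed counts into data frames
del_events <- function(pp) {
  if (!length(pp$dels))
    return(data.frame(pos = integer(0), span = integer(0),
                      count = integer(0)))
  parts <- strsplit(names(pp$dels), ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(parts, `[`, character(1), 1)),
             span = as.integer(vapply(parts, `[`, character(1), 2)),
             count = as.integer(pp$dels), stringsAsFactors = FALSE)
}

ins_events <- function(pp) {
  if (!length(pp$ins))
    return(data.frame(after_pos = integer(0), seq = character(0),
                      count = integer(0)))
  keys <- names(pp$ins)
  pos <- as.integer(sub(":.*$", "", keys))
  data.frame(after_pos = pos, seq = sub("^-?\\d+:", "", keys),
             count = as.integer(pp$ins), stringsAsFactors = FALSE)
}

#' Write a site pileup as TSV
#'
#' One row per reference position with 1-based coordinates; deletion and
#' insertion events are rendered as semicolon-separated `span:count` /
#' `seq:count` lists anchored at their row. Deterministic ordering;
#' round-trips through [read_site_tsv()].
#'
#' @param pp A `site_pileup`.
#' @param path Output path.
#' @export
write_site_tsv <- function(pp, path) {
  L <- pp$length
  de <- del_events(pp); ie <- ins_events(pp)
  del_col <- character(L); ins_col <- character(L)
  for (p in unique(de$pos)) {
    sel <- de[de$pos == p, , drop = FALSE]
    sel <- sel[order(sel$span), , drop = FALSE]
    del_col[p + 1L] <- paste(sprintf("%d:%d", sel$span, sel$count),
                             collapse = ";")
  }
  for (p in unique(ie$after_pos)) {
    sel <- ie[ie$after_pos == p, , drop = FALSE]
    sel <- sel[order(sel$seq), , drop = FALSE]
    if (p + 1L >= 1L && p + 1L <= L)
      ins_col[p + 1L] <- paste(sprintf("%s:%d", sel$seq, sel$count),
                               collapse = ";")
  }
  df <- data.frame(
    amplicon = pp$amplicon_id, pos_1based = seq_len(L),
    depth_hq = pp$depth_hq, ref_count = pp$ref_count,
    sub_A = pp$subs["A", ], sub_C = pp$subs["C", ],
    sub_G = pp$subs["G", ], sub_T = pp$subs["T", ],
    del_events = del_col, del_span_cover = pp$del_span_cover,
    ins_events = ins_col, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-pileup TSV back into a `site_pileup`
#'
#' @param path TSV path written by [write_site_tsv()].
#' @return A `site_pileup` (event maps reconstructed; thresholds unknown).
#' @export
read_site_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(del_events = "character",
                                  ins_events = "character"))
  L <- nrow(df)
  subs <- rbind(A = df$sub_A, C = df$sub_C, G = df$sub_G, T = df$sub_T)
  dels <- integer(0); dnames <- character(0)
  ins <- integer(0); inames <- character(0)
  for (i in seq_len(L)) {
    if (nzchar(df$del_events[i])) {
      for (tok in strsplit(df$del_events[i], ";", fixed = TRUE)[[1]]) {
        sp <- strsplit(tok, ":", fixed = TRUE)[[1]]
        dels <- c(dels, as.integer(sp[2]))
        dnames <- c(dnames, sprintf("%d:%s", i - 1L, sp[1]))
      }
    }
    if (nzchar(df$ins_events[i])) {
      for (tok in strsplit(df$ins_events[i], ";", fixed = TRUE)[[1]]) {
        sp <- strsplit(tok, ":", fixed = TRUE)[[1]]
        ins <- c(ins, as.integer(sp[2]))
        inames <- c(inames, sprintf("%d:%s", i - 1L, sp[1]))
      }
    }
  }
  structure(list(
    amplicon_id = df$amplicon[1], length = L,
    depth_hq = df$depth_hq, ref_count = df$ref_count, subs = subs,
    del_span_cover = df$del_span_cover,
    dels = setNames(dels, dnames), ins = setNames(ins, inames),
    thresholds = NULL, n_reads_used = NA_integer_), class = "site_pileup")
}
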