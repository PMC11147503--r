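#' Target window on an amplicon
#'
#' Default window is the located guide's spacer plus PAM (the smallest
#' interval consistent with scoring variants that overlap the predicted cut
#' site), with optional symmetric padding.
#'
#' @param guide A `guide_target`, or `NULL` if `window` is given directly.
#' @param window Explicit 0-based half-open interval `c(start, end)`.
#' @param pad Padding in nt added to each side (default 0).
#' @param target_id Label.
#' @return A `target_window`.
#' @export
target_window <- function(guide = NULL, window = NULL, pad = 0L,
                          target_id = NULL) {
  if (is.null(window)) {
    stopifnot(inherits(guide, "guide_target"))
    window <- guide$target_window
    if (is.null(target_id)) target_id <- guide$guide_id
    amplicon_id <- guide$amplicon_id
    cut_index <- guide$cut_index
  } else {
    amplicon_id <- if (!is.null(guide)) guide$amplicon_id else NA_character_
    cut_index <- if (!is.null(guide)) guide$cut_index else NA_integer_
    if (is.null(target_id)) target_id <- "target"
  }
  window <- c(max(0L, window[1] - pad), window[2] + pad)
  stopifnot(window[2] > window[1])
  structure(list(target_id = target_id, amplicon_id = amplicon_id,
                 window = as.integer(window),
                 cut_index = cut_index), class = "target_window")
}

#' Filtered per-target variant summary
#'
#' Computes, for one target window, the percentage of reads supporting
#' substitutions, deletions, or insertions, and the fully-reference
#' percentage. Substitutions and insertions are counted when their site
#' lies in the window; deletions are counted when their span intersects the
#' window — i.e. deletions starting in or extending into the target site,
#' including anchors upstream of it. Only variants supported by at least
#' `min_reads` reads and making up at least `min_frac` of total reads are
#' counted. Under the single-variant-per-read assumption the
#' fully-reference percentage is 100 minus the sum of all passing variant
#' percentages (clipped at 0 with a warning if multi-variant reads push the
#' sum past 100).
#'
#' @param pp A `site_pileup` covering the window (whole-amplicon pileups
#'   always do).
#' @param tw A [target_window()].
#' @param min_reads Minimum supporting reads per variant (default 3).
#' @param min_frac Minimum fraction of total reads per variant
#'   (default 0.001, i.e. 0.1%).
#' @param total_reads Window-covering, quality-passing read count; default
#'   is the maximum of `depth_hq + del_span_cover` over the window.
#' @return A `target_site_summary`: `target_id`, `total_reads`, `pct_sub`,
#'   `pct_del`, `pct_ins`, `pct_ref`, and `passing_variants` (data frame
#'   `type`, `site` 0-based, `allele`, `reads`, `pct`). With
#'   `total_reads == 0` the summary is flagged empty and percentages are
#'   `NA`.
#' @export
summarize_target <- function(pp, tw, min_reads = 3L, min_frac = 0.001,
                             total_reads = NULL) {
  stopifnot(inherits(pp, "site_pileup"), inherits(tw, "target_window"))
  w <- tw$window
  if (w[2] > pp$length) stop("target window exceeds amplicon length")
  idx <- seq.int(w[1] + 1L, w[2])          # 1-based rows in window
  if (is.null(total_reads))
    total_reads <- max(pp$depth_hq[idx] + pp$del_span_cover[idx], 0L)
  if (total_reads == 0L) {
    return(structure(list(target_id = tw$target_id, total_reads = 0L,
                          pct_sub = NA_real_, pct_del = NA_real_,
                          pct_ins = NA_real_, pct_ref = NA_real_,
                          empty = TRUE,
                          passing_variants = data.frame()),
                     class = "target_site_summary"))
  }
  vars <- list()
  add <- function(type, site, allele, reads) {
    pct <- reads / total_reads * 100
    if (reads >= min_reads && reads / total_reads >= min_frac)
      vars[[length(vars) + 1L]] <<- data.frame(
        type = type, site = site, allele = allele, reads = reads,
        pct = pct, stringsAsFactors = FALSE)
  }
  # substitutions: per distinct alternate allele at an in-window site
  for (b in rownames(pp$subs)) {
    cnt <- pp$subs[b, idx]
    for (k in which(cnt > 0L))
      add("sub", w[1] + k - 1L, b, cnt[k])
  }
  # deletions: span intersects the window
  de <- del_events(pp)
  if (nrow(de)) {
    hits <- de$pos < w[2] & (de$pos + de$span) > w[1]
    for (k in which(hits))
      add("del", de$pos[k], sprintf("del%d", de$span[k]), de$count[k])
  }
  # insertions: anchored inside the window
  ie <- ins_events(pp)
  if (nrow(ie)) {
    hits <- ie$after_pos >= w[1] & ie$after_pos < w[2]
    for (k in which(hits))
      add("ins", ie$after_pos[k], ie$seq[k], ie$count[k])
  }
  pv <- if (length(vars)) do.call(rbind, vars)
        else data.frame(type = character(0), site = integer(0),
                        allele = character(0), reads = integer(0),
                        pct = numeric(0))
  pct_sub <- sum(pv$pct[pv$type == "sub"])
  pct_del <- sum(pv$pct[pv$type == "del"])
  pct_ins <- sum(pv$pct[pv$type == "ins"])
  pct_ref <- 100 - (pct_sub + pct_del + pct_ins)
  if (pct_ref < 0) {
    warning("variant percentages exceed 100 (multi-variant reads); ",
            "fully-reference percentage clipped to 0")
    pct_ref <- 0
  }
  structure(list(target_id = tw$target_id,
                 total_reads = as.integer(total_reads),
                 pct_sub = pct_sub, pct_del = pct_del, pct_ins = pct_ins,
                 pct_ref = pct_ref, empty = FALSE,
                 passing_variants = pv), class = "target_site_summary")
}

#' @export
print.target_site_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("<target_site_summary> %s: no covering reads\n", x$target_id))
    return(invisible(x))
  }
  cat(sprintf(
    "<target_site_summary> %s: n=%d ref %.2f%% sub %.2f%% del %.2f%% ins %.2f%% (%d passing variants)\n",
    x$target_id, x$total_reads, x$pct_ref, x$pct_sub, x$pct_del, x$pct_ins,
    nrow(x$passing_variants)))
  invisible(x)
}

#' Paired comparison of target summaries between conditions
#'
#' Two-sided paired t-tests per target (and per metric) between two
#' conditions, with Benjamini-Hochberg correction across the whole family
#' tested in one invocation. Pairs with zero variance and zero difference
#' give p = 1 by convention.
#'
#' @param df Long-format data frame with columns `target`, `sample`,
#'   `condition`, and one column per metric value (default metric
#'   `pct_ref`).
#' @param conditions Character vector of the two condition labels to
#'   compare (default: the two levels present).
#' @param metrics Metric column(s) to test (default `"pct_ref"`).
#' @return Data frame `target`, `metric`, `mean_diff`, `t`, `df`, `p`, `q`.
#' @export
compare_conditions <- function(df, conditions = NULL, metrics = "pct_ref") {
  stopifnot(all(c("target", "sample", "condition") %in% names(df)))
  if (is.null(conditions)) conditions <- unique(df$condition)
  if (length(conditions) != 2L)
    stop("exactly two conditions required; got ",
         paste(conditions, collapse = ", "))
  out <- list()
  for (tg in unique(df$target)) {
    for (m in metrics) {
      a <- df[df$target == tg & df$condition == conditions[1],
              c("sample", m)]
      b <- df[df$target == tg & df$condition == conditions[2],
              c("sample", m)]
      merged <- merge(a, b, by = "sample", suffixes = c(".a", ".b"))
      missing <- setdiff(union(a$sample, b$sample), merged$sample)
      if (length(missing))
        stop("unpaired sample(s) for target ", tg, ": ",
             paste(missing, collapse = ", "))
      if (nrow(merged) < 2L)
        stop("need >= 2 complete pairs per target; target ", tg,
             " has ", nrow(merged))
      d <- merged[[paste0(m, ".a")]] - merged[[paste0(m, ".b")]]
      if (all(d == 0)) {
        tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
      } else {
        ht <- t.test(d)
        tt <- list(statistic = unname(ht$statistic),
                   parameter = unname(ht$parameter), p.value = ht$p.value)
      }
      out[[length(out) + 1L]] <- data.frame(
        target = tg, metric = m, mean_diff = mean(d),
        t = tt$statistic, df = tt$parameter, p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- p.adjust(res$p, method = "BH")
  res
}
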