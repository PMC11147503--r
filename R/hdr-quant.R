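# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Classify a single aligned read by editing outcome
#'
#' Labels follow the precedence `NHEJ_indel > HDR_complete > HDR_partial >
#' WT`: any indel overlapping the NHEJ window (cut site +/- `window_pad`)
#' marks the read NHEJ regardless of donor bases; otherwise a read carrying
#' the donor base at every edit position is a complete HDR conversion, at
#' some (but not all) positions a partial conversion, and at none wild
#' type. Reads that do not fully cover the window and all edit positions —
#' or whose donor-position base calls fall below the base-quality
#' threshold, leaving no countable position — are ambiguous.
#'
#' @param al An `aligned_read` on the target amplicon.
#' @param guide The `guide_target` (provides the cut site).
#' @param donor An anchored `donor_spec` (see [anchor_donor()]).
#' @param window_pad Half-width of the NHEJ window around the cut
#'   (default 4 nt).
#' @param min_base_quality Base-quality threshold for donor-position calls
#'   (default 16).
#' @return A `read_classification`: `read_id`, `label`, `evidence` (list
#'   with `donor_matched`, `donor_total`, `indel_in_window`).
#' @export
classify_read <- function(al, guide, donor, window_pad = 4L,
                          min_base_quality = 16L) {
  stopifnot(inherits(al, "aligned_read"), inherits(guide, "guide_target"),
            inherits(donor, "donor_spec"))
  if (is.null(donor$anchor)) stop("donor is not anchored; call anchor_donor()")
  cut <- guide$cut_index
  win <- c(cut - window_pad, cut + window_pad)   # between-base indices
  edit_pos <- donor$edits$amp_pos                # 0-based amplicon positions
  ref_span <- c(al$ref_start, al$ref_start + ops_ref_span(al$ops))
  need <- c(win[1], win[2], if (length(edit_pos)) c(min(edit_pos),
                                                    max(edit_pos) + 1L))
  covered <- ref_span[1] <= min(need) && ref_span[2] >= max(need)
  mk <- function(label, matched = NA_integer_, total = NA_integer_,
                 indel = NA) {
    structure(list(read_id = al$read_id, label = label,
                   evidence = list(donor_matched = matched,
                                   donor_total = total,
                                   indel_in_window = indel)),
              class = "read_classification")
  }
  if (!covered) return(mk("ambiguous"))
  # walk ops: indel overlap with the window + base calls at edit positions
  indel_in_window <- FALSE
  calls <- setNames(rep(NA_character_, length(edit_pos)),
                    as.character(edit_pos))
  quals <- setNames(rep(NA_integer_, length(edit_pos)),
                    as.character(edit_pos))
  q <- if (is.null(al$quality)) NULL else phred_values(al$quality)
  rpos <- al$ref_start; qpos <- 0L
  for (k in seq_len(nrow(al$ops))) {
    op <- al$ops$op[k]; len <- al$ops$len[k]
    if (op == "S") qpos <- qpos + len
    else if (op == "M") {
      hit <- edit_pos[edit_pos >= rpos & edit_pos < rpos + len]
      for (p in hit) {
        qi <- qpos + (p - rpos) + 1L
        calls[as.character(p)] <- substring(al$sequence, qi, qi)
        quals[as.character(p)] <- if (is.null(q)) 41L else q[qi]
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      if (rpos < win[2] && rpos + len > win[1]) indel_in_window <- TRUE
      rpos <- rpos + len
    } else if (op == "I") {
      if (rpos >= win[1] && rpos <= win[2]) indel_in_window <- TRUE
      qpos <- qpos + len
    }
  }
  if (indel_in_window) return(mk("NHEJ_indel", indel = TRUE))
  donor_base <- donor$edits$donor_base
  ref_base <- donor$edits$ref_base
  if (donor$anchor$strand == "-") {
    donor_base <- vapply(donor_base, revcomp, character(1),
                         USE.NAMES = FALSE)
    ref_base <- vapply(ref_base, revcomp, character(1), USE.NAMES = FALSE)
  }
  # informative votes only: calls matching neither the donor nor the
  # reference allele are sequencing noise and are uncounted, like
  # low-quality calls
  usable <- !is.na(calls) & quals >= min_base_quality &
    (calls == donor_base | calls == ref_base)
  if (length(edit_pos) && !any(usable))
    return(mk("ambiguous", indel = FALSE))
  matched <- sum(calls[usable] == donor_base[usable])
  total <- sum(usable)
  label <- if (length(edit_pos) == 0L) "WT"
           else if (matched == total) "HDR_complete"
           else if (matched >= 1L) "HDR_partial"
           else "WT"
  mk(label, matched = matched, total = total, indel = FALSE)
}

#' Quantify editing outcomes over a set of alignments (sequence mode)
#'
#' Classifies every read with [classify_read()] and reports label fractions
#' over the non-ambiguous reads, with Wilson 95% confidence intervals; the
#' ambiguous fraction is reported separately.
#'
#' @param alns List of `aligned_read` on the target amplicon.
#' @param guide `guide_target`.
#' @param donor Anchored `donor_spec`.
#' @param window_pad,min_base_quality Passed to [classify_read()].
#' @return An `editing_quant`: `mode = "sequence"`, `n_total`,
#'   `n_classified`, `n_per_label`, `fractions`, `ci` (2-row matrix), and
#'   `ambiguous_fraction`.
#' @export
quantify_editing <- function(alns, guide, donor, window_pad = 4L,
                             min_base_quality = 16L) {
  labels <- vapply(alns, function(al)
    classify_read(al, guide, donor, window_pad, min_base_quality)$label,
    character(1))
  lev <- c("WT", "HDR_complete", "HDR_partial", "NHEJ_indel")
  n_amb <- sum(labels == "ambiguous")
  n_cls <- length(labels) - n_amb
  if (n_cls == 0L) stop("zero classifiable reads")
  counts <- table(factor(labels[labels != "ambiguous"], levels = lev))
  fr <- as.numeric(counts) / n_cls
  ci <- vapply(as.integer(counts), function(x) wilson_ci(x, n_cls),
               numeric(2))
  colnames(ci) <- lev
  structure(list(mode = "sequence", n_total = length(labels),
                 n_classified = n_cls,
                 n_per_label = setNames(as.integer(counts), lev),
                 fractions = setNames(fr, lev), ci = ci,
                 ambiguous_fraction = n_amb / length(labels)),
            class = "editing_quant")
}

#' @export
print.editing_quant <- function(x, ...) {
  cat(sprintf("<editing_quant mode=%s> n=%d classified=%d\n", x$mode,
              x$n_total, x$n_classified))
  for (l in names(x$fractions))
    cat(sprintf("  %-13s %6.2f%%  [%5.2f, %5.2f]\n", l,
                100 * x$fractions[l], 100 * x$ci[1, l], 100 * x$ci[2, l]))
  cat(sprintf("  ambiguous     %6.2f%%\n", 100 * x$ambiguous_fraction))
  invisible(x)
}

#' Restriction-digest (RFLP) quantification of donor integration
#'
#' The edited allele gains a restriction site (e.g. BspEI, `TCCGGA`) absent
#' from the wild type, so the cut fraction measures integration. Two input
#' forms:
#' \itemize{
#'   \item molecules/reads: fraction of sequences containing the intact
#'     recognition site (site on either strand);
#'   \item gel band masses: `cut_fraction = sum(mass of cut bands) / sum(all
#'     band masses)` — mass-weighting equals the molar fraction because
#'     cutting conserves mass.
#' }
#'
#' @param reads Character vector of read/molecule sequences (or data frame
#'   with a `sequence` column), or `NULL` when using `bands`.
#' @param enzyme_site Recognition sequence (default BspEI `TCCGGA`).
#' @param wt_sequence Wild-type amplicon sequence; if supplied, the assay is
#'   validated: an error is raised when the site is already present in WT.
#' @param bands Data frame with columns `length`, `mass`, and logical `cut`
#'   (or `uncut_length` given instead).
#' @param uncut_length If `bands` has no `cut` column, bands with `length`
#'   different from `uncut_length` are treated as cut fragments.
#' @return List: `cut_fraction`, `n` (reads mode), `ci` (Wilson 95%, reads
#'   mode).
#' @export
digest_quantify <- function(reads = NULL, enzyme_site = "TCCGGA",
                            wt_sequence = NULL, bands = NULL,
                            uncut_length = NULL) {
  enzyme_site <- toupper(enzyme_site)
  if (!is.null(wt_sequence)) {
    wt <- toupper(wt_sequence)
    if (grepl(enzyme_site, wt, fixed = TRUE) ||
        grepl(revcomp(enzyme_site), wt, fixed = TRUE))
      stop("recognition site present in the wild-type allele: ",
           "digest assay invalid")
  }
  if (!is.null(bands)) {
    stopifnot(all(c("length", "mass") %in% names(bands)))
    cut <- if ("cut" %in% names(bands)) bands$cut
           else if (!is.null(uncut_length)) bands$length != uncut_length
           else stop("bands need a 'cut' column or an uncut_length")
    tot <- sum(bands$mass)
    if (tot <= 0) stop("total band mass must be positive")
    return(list(cut_fraction = sum(bands$mass[cut]) / tot, n = NA_integer_,
                ci = c(NA_real_, NA_real_)))
  }
  if (is.data.frame(reads)) reads <- reads$sequence
  if (is.null(reads) || !length(reads)) stop("no reads and no bands given")
  reads <- toupper(reads)
  hit <- grepl(enzyme_site, reads, fixed = TRUE) |
    grepl(revcomp(enzyme_site), reads, fixed = TRUE)
  list(cut_fraction = mean(hit), n = length(reads),
       ci = wilson_ci(sum(hit), length(hit)))
}

#' Size-shift quantification of insert integration
#'
#' Integration of a known insert (e.g. a 143 bp synthetic intron) is scored
#' from reads whose total inserted length overlapping the cut window lies
#' within `expected_insert_len * (1 +/- tol)` — the read-level analogue of
#' a gel size shift, tolerant of sequencing-error indels that fragment the
#' insert boundary. The integrated fraction is reported over
#' window-covering reads with a Wilson 95% CI.
#'
#' @param alns List of `aligned_read`.
#' @param guide `guide_target` (provides the cut site).
#' @param expected_insert_len Expected insert length in bp (default 143).
#' @param tol Relative length tolerance (default 0.1).
#' @param window_pad Half-width of the cut window (default 10 nt).
#' @return List: `integrated_fraction`, `n_covering`, `n_integrated`, `ci`.
#' @export
size_shift_quantify <- function(alns, guide, expected_insert_len = 143L,
                                tol = 0.1, window_pad = 10L) {
  stopifnot(expected_insert_len > 0)
  cut <- guide$cut_index
  win <- c(cut - window_pad, cut + window_pad)
  lo <- expected_insert_len * (1 - tol)
  hi <- expected_insert_len * (1 + tol)
  n_cov <- 0L; n_int <- 0L
  for (al in alns) {
    ref_span <- c(al$ref_start, al$ref_start + ops_ref_span(al$ops))
    if (!(ref_span[1] <= win[1] && ref_span[2] >= win[2])) next
    n_cov <- n_cov + 1L
    rpos <- al$ref_start
    ins_in_win <- 0L
    for (k in seq_len(nrow(al$ops))) {
      op <- al$ops$op[k]; len <- al$ops$len[k]
      if (op == "I" && rpos >= win[1] && rpos <= win[2])
        ins_in_win <- ins_in_win + len
      if (op %in% c("M", "D")) rpos <- rpos + len
    }
    if (ins_in_win >= lo && ins_in_win <= hi)
      n_int <- n_int + 1L
  }
  list(integrated_fraction = if (n_cov) n_int / n_cov else NA_real_,
       n_covering = n_cov, n_integrated = n_int,
       ci = wilson_ci(n_int, n_cov))
}
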