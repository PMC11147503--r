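#' Locate a guide (spacer + PAM) on an amplicon
#'
#' Exact search for the spacer on both strands of the amplicon, optionally
#' requiring the PAM pattern (IUPAC, default `NGG` for SpCas9) immediately
#' PAM-proximal to the spacer on the guide strand. All coordinates are
#' 0-based half-open on the + strand of the amplicon.
#'
#' @param amp An [amplicon()].
#' @param spacer Spacer sequence (>= 10 nt; 20 nt is the SpCas9 convention,
#'   21 nt guides are equally supported).
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @param require_pam If `TRUE` (default) only spacer hits with an adjacent
#'   PAM match are returned.
#' @param guide_id Identifier for the guide.
#' @param window_pad Extra padding (nt) added to each side of the target
#'   window beyond spacer plus PAM (default 0).
#' @return A `guide_target` (fields `spacer_interval`, `pam_interval`,
#'   `cut_index`, `target_window`, `strand`, ...), or `NULL` when there is no
#'   hit. Multiple hits raise an error listing the positions.
#' @export
locate_guide <- function(amp, spacer, pam_pattern = "NGG",
                         require_pam = TRUE, guide_id = "guide",
                         window_pad = 0L) {
  stopifnot(inherits(amp, "amplicon"))
  spacer <- toupper(spacer)
  if (nchar(spacer) < 10L) stop("spacer must be at least 10 nt")
  if (!nzchar(amp$sequence)) stop("empty amplicon")
  L <- nchar(spacer)
  P <- nchar(pam_pattern)
  ref <- amp$sequence
  n <- nchar(ref)
  hits <- list()
  find_all <- function(pattern, subject) {
    out <- integer(0); from <- 1L
    repeat {
      i <- regexpr(pattern, substring(subject, from), fixed = TRUE)
      if (i < 0) break
      out <- c(out, from + i - 1L)
      from <- from + i
    }
    out - 1L   # 0-based
  }
  pam_ok <- function(bases) {
    length(bases) == P && !anyNA(bases) &&
      all(iupac_match(bases, seq_chars(pam_pattern)))
  }
  refc <- seq_chars(ref)
  # + strand: spacer at [s, s+L), PAM at [s+L, s+L+P)
  for (s in find_all(spacer, ref)) {
    pam_iv <- c(s + L, s + L + P)
    ok_pam <- pam_iv[2] <= n && pam_ok(refc[(pam_iv[1] + 1L):pam_iv[2]])
    if (!require_pam || ok_pam)
      hits[[length(hits) + 1L]] <- list(strand = "+", s = s, pam = pam_iv,
                                        pam_present = ok_pam)
  }
  # - strand: rc(spacer) at [s, s+L) on +; PAM occupies [s-P, s) on +,
  # read as rc on the guide strand
  for (s in find_all(revcomp(spacer), ref)) {
    pam_iv <- c(s - P, s)
    ok_pam <- pam_iv[1] >= 0 &&
      pam_ok(seq_chars(revcomp(paste(refc[(pam_iv[1] + 1L):pam_iv[2]],
                                     collapse = ""))))
    if (!require_pam || ok_pam)
      hits[[length(hits) + 1L]] <- list(strand = "-", s = s, pam = pam_iv,
                                        pam_present = ok_pam)
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L)
    stop("ambiguous guide target: hits at ",
         paste(vapply(hits, function(h)
           sprintf("%s:%d", h$strand, h$s), character(1)), collapse = ", "))
  h <- hits[[1]]
  spacer_iv <- c(h$s, h$s + L)
  win <- range(c(spacer_iv, pmax(0L, pmin(n, h$pam))))
  win <- c(max(0L, win[1] - window_pad), min(n, win[2] + window_pad))
  g <- structure(list(
    guide_id = guide_id, spacer = spacer, pam_pattern = pam_pattern,
    amplicon_id = amp$id, strand = h$strand,
    spacer_interval = as.integer(spacer_iv),
    pam_interval = as.integer(h$pam),
    pam_present = h$pam_present,
    target_window = as.integer(win)
  ), class = "guide_target")
  g$cut_index <- cut_site(g)
  g
}

#' Predicted Cas9 cut position for a located guide
#'
#' SpCas9 makes a blunt cut 3 nt 5' of the PAM. The returned value is a
#' between-base index on the + strand of the amplicon (the cut falls between
#' bases `cut_index - 1` and `cut_index`, 0-based), and is invariant under
#' reverse-complementing the amplicon and relocating the guide.
#'
#' @param guide A `guide_target`.
#' @param offset Distance of the blunt cut from the PAM-proximal spacer
#'   boundary (default 3).
#' @return Integer between-base index.
#' @export
cut_site <- function(guide, offset = 3L) {
  stopifnot(inherits(guide, "guide_target"))
  if (guide$strand == "+") guide$spacer_interval[2] - offset
  else guide$spacer_interval[1] + offset
}

#' @export
print.guide_target <- function(x, ...) {
  cat(sprintf(
    "<guide_target> %s on %s(%s): spacer [%d,%d), PAM [%d,%d)%s, cut %d\n",
    x$guide_id, x$amplicon_id, x$strand,
    x$spacer_interval[1], x$spacer_interval[2],
    x$pam_interval[1], x$pam_interval[2],
    if (x$pam_present) "" else " [PAM absent]", x$cut_index))
  invisible(x)
}
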