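#' Parse an annotated ssODN donor string
#'
#' Donors are written in a compact vendor-style notation: lowercase letters
#' match the reference, UPPERCASE letters are edited bases, and `*` marks a
#' phosphorothioate bond between the two flanking bases. For example
#' `"t*g*gac...cag*g*t"` is a donor with two phosphorothioate bonds at each
#' end.
#'
#' @param donor_string The annotated donor string.
#' @param donor_id Identifier for the donor (default `"donor"`).
#' @param strand Strand of the donor relative to its amplicon (`"+"` or
#'   `"-"`); recorded, not interpreted, until the donor is anchored.
#' @return A `donor_spec` with fields:
#'   \describe{
#'     \item{full_sequence}{the upper-cased sequence,}
#'     \item{edits}{data frame of point edits (`donor_pos` 0-based,
#'       `donor_base`, `ref_base` = `NA` until anchored, `class` =
#'       `"unknown"` until anchored),}
#'     \item{pt_bonds}{0-based inter-base bond indices (bond `i` sits between
#'       bases `i` and `i+1`).}
#'   }
#' [render_donor()] reproduces the input string byte-identically.
#' @export
#' @examples
#' d <- parse_donor("t*g*gacGGa*c")
#' d$edits
parse_donor <- function(donor_string, donor_id = "donor", strand = "+") {
  stopifnot(is.character(donor_string), length(donor_string) == 1L)
  ch <- seq_chars(donor_string)
  bad <- which(!ch %in% c(seq_chars("acgtACGT"), "*"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at offset %d in donor string",
                 ch[bad[1]], bad[1] - 1L))
  star <- ch == "*"
  if (any(star)) {
    w <- which(star)
    if (w[1] == 1L || w[length(w)] == length(ch))
      stop("'*' may not be the first or last character of a donor string")
    if (any(diff(w) == 1L))
      stop("adjacent '*' characters are not allowed in a donor string")
  }
  letters_only <- ch[!star]
  # a '*' after the k-th letter marks the bond between letters k and k+1;
  # 0-based bond index k-1
  n_letters_before <- cumsum(!star)
  pt_bonds <- n_letters_before[star] - 1L
  upper <- which(letters_only %in% seq_chars("ACGT")) - 1L
  edits <- data.frame(
    donor_pos = upper,
    donor_base = letters_only[upper + 1L],
    ref_base = rep(NA_character_, length(upper)),
    class = rep("unknown", length(upper)),
    stringsAsFactors = FALSE
  )
  structure(list(donor_id = donor_id, strand = strand,
                 full_sequence = toupper(paste(letters_only, collapse = "")),
                 arm5 = NULL, arm3 = NULL,
                 edits = edits, pt_bonds = as.integer(pt_bonds)),
            class = "donor_spec")
}

#' Render a donor back to annotated-string notation
#'
#' Inverse of [parse_donor()]: lowercase reference-matching bases, uppercase
#' edits, `*` at phosphorothioate bonds.
#'
#' @param donor A `donor_spec`.
#' @return A single string.
#' @export
render_donor <- function(donor) {
  stopifnot(inherits(donor, "donor_spec"))
  ch <- seq_chars(tolower(donor$full_sequence))
  if (nrow(donor$edits))
    ch[donor$edits$donor_pos + 1L] <- toupper(ch[donor$edits$donor_pos + 1L])
  n <- length(ch)
  out <- character(0)
  bonds <- donor$pt_bonds
  for (i in seq_len(n)) {
    out <- c(out, ch[i])
    if ((i - 1L) %in% bonds) out <- c(out, "*")
  }
  paste(out, collapse = "")
}

#' @export
print.donor_spec <- function(x, ...) {
  cat(sprintf("<donor_spec> %s: %d nt, %d edits, %d PT bonds, strand %s\n",
              x$donor_id, nchar(x$full_sequence), nrow(x$edits),
              length(x$pt_bonds), x$strand))
  invisible(x)
}

#' Read donors from a two-column TSV (donor_id, annotated string)
#'
#' @param path TSV path with columns `donor_id` and `donor_string` (no
#'   header required if exactly two columns).
#' @return Named list of `donor_spec`.
#' @export
read_donor_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (identical(tolower(df[1, 1]), "donor_id")) df <- df[-1, , drop = FALSE]
  out <- lapply(seq_len(nrow(df)), function(i)
    parse_donor(df[i, 2], donor_id = df[i, 1]))
  names(out) <- df[[1]]
  out
}

#' Anchor a donor to an amplicon reference
#'
#' Locates the donor on the amplicon by requiring every reference-matching
#' (lowercase-derived) donor position to match exactly, on either strand; the
#' anchor must be unique. Reference bases are then filled into the edits and,
#' when a guide (and optionally a coding context) is supplied, edit classes
#' are assigned: inside the PAM interval and PAM-breaking ->
#' `"pam_disrupting"`; inside the spacer and synonymous -> `"spacer_silent"`;
#' otherwise `"payload"`.
#'
#' @param donor A `donor_spec`.
#' @param amp An [amplicon()].
#' @param guide Optional `guide_target` used for class assignment.
#' @param ctx Optional [coding_context()] used to test synonymy.
#' @return The donor with `anchor` (list: `start` on the + strand, `strand`),
#'   `ref_base` filled, and classes assigned where determinable.
#' @export
anchor_donor <- function(donor, amp, guide = NULL, ctx = NULL) {
  stopifnot(inherits(donor, "donor_spec"), inherits(amp, "amplicon"))
  dseq <- donor$full_sequence
  n <- nchar(dseq)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") dseq else revcomp(dseq)
    qe <- if (strand == "+") donor$edits$donor_pos
          else (n - 1L) - donor$edits$donor_pos
    qc <- seq_chars(q)
    ref <- seq_chars(amp$sequence)
    keep <- setdiff(seq_len(n) - 1L, qe)   # positions that must match
    if (nchar(amp$sequence) < n) next
    for (off in 0:(nchar(amp$sequence) - n)) {
      if (all(qc[keep + 1L] == ref[off + keep + 1L]))
        hits[[length(hits) + 1L]] <- list(start = off, strand = strand)
    }
  }
  if (length(hits) == 0L) stop("donor arms do not anchor to amplicon '",
                               amp$id, "'")
  if (length(hits) > 1L) stop("donor anchors at multiple sites (",
                              length(hits), "); anchoring is ambiguous")
  anc <- hits[[1]]
  donor$anchor <- list(amplicon_id = amp$id, start = anc$start,
                       strand = anc$strand)
  ref <- seq_chars(amp$sequence)
  ed <- donor$edits
  if (nrow(ed)) {
    # amplicon + strand position of each donor edit
    amp_pos <- if (anc$strand == "+") anc$start + ed$donor_pos
               else anc$start + (n - 1L) - ed$donor_pos
    ref_plus <- ref[amp_pos + 1L]
    ed$ref_base <- if (anc$strand == "+") ref_plus
                   else vapply(ref_plus, revcomp, character(1), USE.NAMES = FALSE)
    ed$amp_pos <- amp_pos
    same <- ed$ref_base == ed$donor_base
    if (any(same))
      warning("donor edit position(s) identical to reference: ",
              paste(ed$donor_pos[same], collapse = ", "))
    ed$class <- classify_edits(ed, amp_pos, guide, ctx, amp, donor, anc)
  }
  donor$edits <- ed
  donor
}

# assign edit classes once amplicon positions are known
classify_edits <- function(ed, amp_pos, guide, ctx, amp, donor, anc) {
  cls <- rep("payload", nrow(ed))
  if (is.null(guide)) return(rep("unknown", nrow(ed)))
  in_pam <- amp_pos >= guide$pam_interval[1] & amp_pos < guide$pam_interval[2]
  in_spacer <- amp_pos >= guide$spacer_interval[1] &
    amp_pos < guide$spacer_interval[2]
  cls[in_pam] <- "pam_disrupting"
  if (!is.null(ctx)) {
    for (i in which(in_spacer & !in_pam)) {
      base_plus <- if (anc$strand == "+") ed$donor_base[i]
                   else revcomp(ed$donor_base[i])
      if (is_synonymous(ctx, amp, amp_pos[i], base_plus))
        cls[i] <- "spacer_silent"
    }
  }
  cls
}

#' Derive the edited (HDR) allele of an amplicon from an anchored donor
#'
#' @param amp An [amplicon()].
#' @param donor An anchored `donor_spec` (see [anchor_donor()]).
#' @return The edited allele sequence (+ strand of the amplicon).
#' @export
apply_donor <- function(amp, donor) {
  stopifnot(inherits(donor, "donor_spec"))
  if (is.null(donor$anchor)) stop("donor is not anchored; call anchor_donor()")
  ch <- seq_chars(amp$sequence)
  ed <- donor$edits
  if (nrow(ed)) {
    base_plus <- if (donor$anchor$strand == "+") ed$donor_base
                 else vapply(ed$donor_base, revcomp, character(1),
                             USE.NAMES = FALSE)
    ch[ed$amp_pos + 1L] <- base_plus
  }
  paste(ch, collapse = "")
}
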