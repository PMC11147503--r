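#' Enumerate synonymous single-nucleotide substitutions in a region
#'
#' Candidates are single-base substitutions within `region` whose codon is
#' synonymous with wild type. The list is sorted by codon-usage distance
#' `|usage(WT codon) - usage(alt codon)|` ascending — operationalising the
#' selection of "codons with equivalent frequency to wild-type" — with ties
#' broken by proximity to `prefer_near` (typically the PAM boundary) when
#' given, else by descending position.
#'
#' @param ctx A [coding_context()].
#' @param amp The [amplicon()].
#' @param region 0-based half-open interval `c(start, end)` on the amplicon.
#' @param prefer_near Optional amplicon position used for tie-breaking.
#' @return Data frame with columns `amp_pos`, `ref_base`, `alt_base` (both on
#'   the + strand), `wt_codon`, `alt_codon`, `usage_distance`. Empty when the
#'   region is entirely non-coding.
#' @export
enumerate_silent_substitutions <- function(ctx, amp, region,
                                           prefer_near = NULL) {
  stopifnot(inherits(ctx, "coding_context"), inherits(amp, "amplicon"),
            length(region) == 2L, region[2] > region[1])
  refc <- seq_chars(amp$sequence)
  out <- list()
  for (pos in seq.int(region[1], region[2] - 1L)) {
    cd <- codon_at(ctx, amp, pos)
    if (is.null(cd)) next
    ref_plus <- refc[pos + 1L]
    for (alt in setdiff(c("A", "C", "G", "T"), ref_plus)) {
      b <- if (ctx$coding_strand == "+") alt else revcomp(alt)
      alt_codon <- cd$codon
      substr(alt_codon, cd$within + 1L, cd$within + 1L) <- b
      if (!identical(unname(GENETIC_CODE_STD[alt_codon]),
                     unname(GENETIC_CODE_STD[cd$codon]))) next
      u_wt <- codon_usage_of(ctx, cd$codon)
      u_alt <- codon_usage_of(ctx, alt_codon)
      d <- if (is.na(u_wt) || is.na(u_alt)) Inf else abs(u_wt - u_alt)
      out[[length(out) + 1L]] <- data.frame(
        amp_pos = pos, ref_base = ref_plus, alt_base = alt,
        wt_codon = cd$codon, alt_codon = alt_codon, usage_distance = d,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(amp_pos = integer(0), ref_base = character(0),
                      alt_base = character(0), wt_codon = character(0),
                      alt_codon = character(0), usage_distance = numeric(0)))
  df <- do.call(rbind, out)
  tie <- if (is.null(prefer_near)) -df$amp_pos else abs(df$amp_pos - prefer_near)
  df[order(df$usage_distance, tie), , drop = FALSE]
}

#' Design an ssODN HDR donor
#'
#' Builds a donor spanning `[cut - arm_len5, cut + arm_len3)` around the
#' guide's cut site carrying (i) the requested payload substitutions, (ii)
#' optionally a PAM-disrupting mutation (silent where the PAM is coding and a
#' synonymous option exists), and (iii) exactly `n_spacer_silent` synonymous
#' substitutions in the PAM-proximal `spacer_region` nucleotides of the
#' spacer — the design that breaks residual protospacer recognition after
#' repair.
#'
#' @param amp The [amplicon()].
#' @param guide A located `guide_target` on `amp`.
#' @param ctx [coding_context()] (required when silent edits are requested).
#' @param payload_edits Data frame with columns `amp_pos` (0-based, + strand)
#'   and `alt_base`, or `NULL`.
#' @param mutate_pam Disrupt the NGG PAM (default `TRUE`).
#' @param n_spacer_silent Number of silent spacer mutations (default 0).
#' @param spacer_region PAM-proximal window length in nt considered for
#'   silent spacer mutations (default 10, the seed region).
#' @param arm_len5,arm_len3 Homology arm lengths in nt (>= 20; default 45).
#' @param pt_bonds_per_end Phosphorothioate bonds at each donor end
#'   (default 2).
#' @param donor_strand `"+"`, `"-"`, or `"auto"` (auto = amplicon + strand).
#' @param allow_nonsilent Permit a non-synonymous PAM mutation when no silent
#'   option exists (default `FALSE`: error instead).
#' @param donor_id Donor identifier.
#' @return An anchored `donor_spec`.
#' @export
design_ssodn <- function(amp, guide, ctx = NULL, payload_edits = NULL,
                         mutate_pam = TRUE, n_spacer_silent = 0L,
                         spacer_region = 10L, arm_len5 = 45L, arm_len3 = 45L,
                         pt_bonds_per_end = 2L, donor_strand = "auto",
                         allow_nonsilent = FALSE, donor_id = "designed_donor") {
  stopifnot(inherits(amp, "amplicon"), inherits(guide, "guide_target"),
            arm_len5 >= 20L, arm_len3 >= 20L, n_spacer_silent >= 0L)
  cut <- guide$cut_index
  span <- c(max(0L, cut - arm_len5), min(nchar(amp$sequence), cut + arm_len3))
  edits <- data.frame(amp_pos = integer(0), alt_base = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  add_edit <- function(pos, base, class) {
    if (pos %in% edits$amp_pos)
      stop("conflicting edits at amplicon position ", pos)
    rbind(edits, data.frame(amp_pos = as.integer(pos), alt_base = base,
                            class = class, stringsAsFactors = FALSE))
  }
  if (!is.null(payload_edits) && nrow(payload_edits)) {
    if (any(payload_edits$amp_pos < span[1] | payload_edits$amp_pos >= span[2]))
      stop("payload edit outside the donor span [", span[1], ",", span[2], ")")
    for (i in seq_len(nrow(payload_edits)))
      edits <- add_edit(payload_edits$amp_pos[i],
                        toupper(payload_edits$alt_base[i]), "payload")
  }
  refc <- seq_chars(amp$sequence)
  edited_chars <- function() {
    ch <- refc
    if (nrow(edits)) ch[edits$amp_pos + 1L] <- edits$alt_base
    ch
  }
  pam_on_guide_strand <- function(ch) {
    iv <- guide$pam_interval
    s <- paste(ch[(iv[1] + 1L):iv[2]], collapse = "")
    if (guide$strand == "+") s else revcomp(s)
  }
  # PAM-proximal spacer window (amplicon + coordinates)
  sp <- guide$spacer_interval
  reg_len <- min(spacer_region, sp[2] - sp[1])
  seed_iv <- if (guide$strand == "+") c(sp[2] - reg_len, sp[2])
             else c(sp[1], sp[1] + reg_len)
  pam_boundary <- if (guide$strand == "+") sp[2] else sp[1] - 1L

  if (mutate_pam) {
    pam_now <- pam_on_guide_strand(edited_chars())
    if (grepl("GG$", pam_now)) {
      # the two guide-strand G positions, in amplicon + coordinates
      gg_amp <- if (guide$strand == "+") c(guide$pam_interval[1] + 1L,
                                           guide$pam_interval[1] + 2L)
                else c(guide$pam_interval[1], guide$pam_interval[1] + 1L)
      chosen <- NULL
      if (!is.null(ctx)) {
        for (p in gg_amp) {
          if (p %in% edits$amp_pos) next
          cand <- enumerate_silent_substitutions(ctx, amp, c(p, p + 1L))
          # must change the guide-strand G to a non-G
          if (nrow(cand)) {
            keep <- vapply(seq_len(nrow(cand)), function(i) {
              b <- if (guide$strand == "+") cand$alt_base[i]
                   else revcomp(cand$alt_base[i])
              b != "G"
            }, logical(1))
            cand <- cand[keep, , drop = FALSE]
          }
          if (nrow(cand) && (is.null(chosen) ||
                             cand$usage_distance[1] < chosen$usage_distance))
            chosen <- list(pos = p, base = cand$alt_base[1],
                           usage_distance = cand$usage_distance[1])
        }
      }
      if (!is.null(chosen)) {
        edits <- add_edit(chosen$pos, chosen$base, "pam_disrupting")
      } else {
        cd_any <- !is.null(ctx) &&
          any(vapply(gg_amp, function(p) !is.null(codon_at(ctx, amp, p)),
                     logical(1)))
        if (cd_any && !allow_nonsilent)
          stop("no synonymous PAM-disrupting substitution exists; ",
               "rerun with allow_nonsilent = TRUE to permit a coding change")
        # non-coding PAM (or explicitly allowed): transversion of the first G
        p <- gg_amp[1]
        b_guide <- "C"
        b_plus <- if (guide$strand == "+") b_guide else revcomp(b_guide)
        edits <- add_edit(p, b_plus, "pam_disrupting")
      }
    } # payload already destroyed the PAM: nothing to add
  }

  if (n_spacer_silent > 0L) {
    if (is.null(ctx)) stop("silent spacer mutations require a coding_context")
    cand <- enumerate_silent_substitutions(ctx, amp, seed_iv,
                                           prefer_near = pam_boundary)
    cand <- cand[!cand$amp_pos %in% edits$amp_pos, , drop = FALSE]
    cand <- cand[!duplicated(cand$amp_pos), , drop = FALSE]
    if (nrow(cand) < n_spacer_silent)
      stop("only ", nrow(cand), " silent spacer substitution site(s) ",
           "available; ", n_spacer_silent, " requested")
    for (i in seq_len(n_spacer_silent))
      edits <- add_edit(cand$amp_pos[i], cand$alt_base[i], "spacer_silent")
  }

  # assemble the donor on the requested strand
  strand <- if (donor_strand == "auto") "+" else donor_strand
  ch <- edited_chars()[(span[1] + 1L):span[2]]
  pos_in_donor_plus <- edits$amp_pos - span[1]
  donor_len <- span[2] - span[1]
  if (strand == "-") {
    ch <- seq_chars(revcomp(paste(ch, collapse = "")))
    pos_in_donor <- donor_len - 1L - pos_in_donor_plus
  } else pos_in_donor <- pos_in_donor_plus
  full <- paste(ch, collapse = "")
  pt <- integer(0)
  if (pt_bonds_per_end > 0L)
    pt <- sort(unique(c(seq_len(pt_bonds_per_end) - 1L,
                        donor_len - 1L - seq_len(pt_bonds_per_end))))
  ord <- order(pos_in_donor)
  donor <- structure(list(
    donor_id = donor_id, strand = strand, full_sequence = full,
    arm5 = NULL, arm3 = NULL,
    edits = data.frame(
      donor_pos = as.integer(pos_in_donor[ord]),
      donor_base = if (strand == "+") edits$alt_base[ord]
                   else vapply(edits$alt_base[ord], revcomp, character(1),
                               USE.NAMES = FALSE),
      ref_base = rep(NA_character_, length(ord)),
      class = edits$class[ord],
      stringsAsFactors = FALSE),
    pt_bonds = as.integer(pt)), class = "donor_spec")
  anchored <- anchor_donor(donor, amp, guide = guide, ctx = ctx)
  anchored$edits$class <- donor$edits$class   # keep design-time classes
  anchored
}

#' Validate a donor against its amplicon, guide, and restriction enzymes
#'
#' Reconstructs the edited allele and reports whether a perfect
#' spacer-plus-PAM protospasser match survives on either strand, whether
#' silent-classed edits preserve the translation, restriction sites gained
#' and lost per enzyme (e.g. BspEI `TCCGGA` for RFLP quantification), and the
#' mismatch count versus the reference.
#'
#' @param donor A `donor_spec` (anchored, or anchorable to `amp`).
#' @param guide The `guide_target`.
#' @param amp The [amplicon()].
#' @param ctx Optional [coding_context()] for translation checks.
#' @param enzymes Named character vector of recognition sites, e.g.
#'   `c(BspEI = "TCCGGA")`.
#' @return A list report: `residual_protospacer`, `translation_preserved`
#'   (`NA` without a context or silent edits), `sites_gained`, `sites_lost`
#'   (named integer vectors), `mismatches`.
#' @export
validate_donor <- function(donor, guide, amp, ctx = NULL,
                           enzymes = c(BspEI = "TCCGGA")) {
  stopifnot(inherits(donor, "donor_spec"))
  if (is.null(donor$anchor)) donor <- anchor_donor(donor, amp, guide, ctx)
  allele <- apply_donor(amp, donor)
  # perfect protospacer (spacer + PAM-pattern match) on either strand?
  residual <- protospacer_present(allele, guide)
  translation_ok <- NA
  if (!is.null(ctx) && any(donor$edits$class == "spacer_silent")) {
    translation_ok <- all(vapply(which(donor$edits$class == "spacer_silent"),
      function(i) {
        pos <- donor$edits$amp_pos[i]
        b <- if (donor$anchor$strand == "+") donor$edits$donor_base[i]
             else revcomp(donor$edits$donor_base[i])
        is_synonymous(ctx, amp, pos, b)
      }, logical(1)))
  }
  count_sites <- function(seqs, site) {
    tot <- 0L
    for (s in unique(c(site, revcomp(site))))
      tot <- tot + length(gregexpr(s, seqs, fixed = TRUE)[[1]][
        gregexpr(s, seqs, fixed = TRUE)[[1]] > 0])
    tot
  }
  gained <- lost <- setNames(integer(length(enzymes)), names(enzymes))
  for (e in seq_along(enzymes)) {
    n_wt <- count_sites(amp$sequence, toupper(enzymes[e]))
    n_ed <- count_sites(allele, toupper(enzymes[e]))
    gained[e] <- max(0L, n_ed - n_wt)
    lost[e] <- max(0L, n_wt - n_ed)
  }
  mism <- sum(seq_chars(allele) != seq_chars(amp$sequence))
  list(residual_protospacer = residual,
       translation_preserved = translation_ok,
       sites_gained = gained, sites_lost = lost,
       mismatches = mism, edited_allele = allele)
}

# does a perfect spacer + PAM match survive anywhere in `seqs`?
protospacer_present <- function(seqs, guide) {
  hit <- function(subject) {
    L <- nchar(guide$spacer); P <- nchar(guide$pam_pattern)
    from <- 1L
    repeat {
      i <- regexpr(guide$spacer, substring(subject, from), fixed = TRUE)
      if (i < 0) return(FALSE)
      s <- from + i - 1L
      pam <- substring(subject, s + L, s + L + P - 1L)
      if (nchar(pam) == P &&
          all(iupac_match(seq_chars(pam), seq_chars(guide$pam_pattern))))
        return(TRUE)
      from <- s + 1L
    }
  }
  hit(seqs) || hit(revcomp(seqs))
}
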