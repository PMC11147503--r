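GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Human codon usage, relative frequency within each amino-acid family
# (GenBank-derived table as distributed by the Kazusa codon usage database).
HUMAN_CODON_USAGE <- c(
  TTT = 0.46, TTC = 0.54,
  TTA = 0.08, TTG = 0.13, CTT = 0.13, CTC = 0.20, CTA = 0.07, CTG = 0.40,
  ATT = 0.36, ATC = 0.47, ATA = 0.17, ATG = 1.00,
  GTT = 0.18, GTC = 0.24, GTA = 0.12, GTG = 0.46,
  TCT = 0.19, TCC = 0.22, TCA = 0.15, TCG = 0.05, AGT = 0.15, AGC = 0.24,
  CCT = 0.29, CCC = 0.32, CCA = 0.28, CCG = 0.11,
  ACT = 0.25, ACC = 0.36, ACA = 0.28, ACG = 0.11,
  GCT = 0.27, GCC = 0.40, GCA = 0.23, GCG = 0.11,
  TAT = 0.44, TAC = 0.56,
  CAT = 0.42, CAC = 0.58, CAA = 0.27, CAG = 0.73,
  AAT = 0.47, AAC = 0.53, AAA = 0.43, AAG = 0.57,
  GAT = 0.46, GAC = 0.54, GAA = 0.42, GAG = 0.58,
  TGT = 0.46, TGC = 0.54, TGG = 1.00,
  CGT = 0.08, CGC = 0.18, CGA = 0.11, CGG = 0.20, AGA = 0.21, AGG = 0.21,
  GGT = 0.16, GGC = 0.34, GGA = 0.25, GGG = 0.25,
  TAA = 0.30, TAG = 0.24, TGA = 0.47
)

#' Translate a DNA sequence with the standard genetic code
#'
#' @param seq DNA string; length must be a multiple of 3.
#' @return Single-letter amino acid string (`*` = stop).
#' @export
translate_dna <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- GENETIC_CODE_STD[codons]
  if (anyNA(aa)) stop("untranslatable codon: ",
                      codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

#' The bundled human codon usage table
#'
#' Relative synonymous codon usage: frequencies sum to 1 within each
#' amino-acid family (renormalised on load to absorb rounding in the
#' published two-decimal values).
#'
#' @return Data frame with columns `codon`, `aa`, `rel_freq`.
#' @export
human_codon_usage <- function() {
  df <- data.frame(codon = names(HUMAN_CODON_USAGE),
                   aa = unname(GENETIC_CODE_STD[names(HUMAN_CODON_USAGE)]),
                   rel_freq = unname(HUMAN_CODON_USAGE),
                   stringsAsFactors = FALSE)
  for (a in unique(df$aa)) {
    i <- df$aa == a
    df$rel_freq[i] <- df$rel_freq[i] / sum(df$rel_freq[i])
  }
  df
}

#' Coding context for an amplicon
#'
#' Describes where the coding sequence lies on an amplicon so that synonymy
#' of candidate substitutions can be evaluated.
#'
#' @param amplicon_id Amplicon the context refers to.
#' @param cds_intervals Matrix or list of 0-based half-open `[start, end)`
#'   intervals (in amplicon + strand coordinates, ordered 5'->3' on the
#'   coding strand for multi-exon contexts).
#' @param coding_strand `"+"` or `"-"`.
#' @param frame_offset 0-2: number of bases of the first interval that
#'   complete an upstream codon and are skipped before the first full codon.
#' @param codon_usage Codon usage data frame as from [human_codon_usage()]
#'   (the default); frequencies are renormalised per amino-acid family.
#' @return A `coding_context`.
#' @export
coding_context <- function(amplicon_id, cds_intervals, coding_strand = "+",
                           frame_offset = 0L,
                           codon_usage = human_codon_usage()) {
  if (is.list(cds_intervals))
    cds_intervals <- do.call(rbind, lapply(cds_intervals, as.integer))
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2)
  stopifnot(all(cds_intervals[, 2] > cds_intervals[, 1]),
            coding_strand %in% c("+", "-"), frame_offset %in% 0:2)
  stopifnot(all(c("codon", "aa", "rel_freq") %in% names(codon_usage)))
  for (a in unique(codon_usage$aa)) {
    i <- codon_usage$aa == a
    codon_usage$rel_freq[i] <- codon_usage$rel_freq[i] /
      sum(codon_usage$rel_freq[i])
  }
  structure(list(amplicon_id = amplicon_id, cds_intervals = cds_intervals,
                 coding_strand = coding_strand,
                 frame_offset = as.integer(frame_offset),
                 codon_usage = codon_usage),
            class = "coding_context")
}

# map each CDS amplicon position (+ strand, 0-based) to its index along the
# coding strand (0-based, after frame_offset trimming); returns a data.frame
cds_position_map <- function(ctx) {
  pos <- unlist(lapply(seq_len(nrow(ctx$cds_intervals)), function(i)
    seq.int(ctx$cds_intervals[i, 1], ctx$cds_intervals[i, 2] - 1L)))
  pos <- sort(unique(pos))
  ord <- if (ctx$coding_strand == "+") pos else rev(pos)
  idx <- seq_along(ord) - 1L - ctx$frame_offset
  keep <- idx >= 0L
  data.frame(amp_pos = ord[keep], cds_idx = idx[keep])
}

# the codon (amplicon + strand context translated to coding strand) that
# contains amplicon position `pos`; returns NULL when pos is non-coding or
# its codon is incomplete within the amplicon
codon_at <- function(ctx, amp, pos) {
  map <- cds_position_map(ctx)
  row <- match(pos, map$amp_pos)
  if (is.na(row)) return(NULL)
  ci <- map$cds_idx[row] %/% 3L
  within <- map$cds_idx[row] %% 3L
  members <- map$amp_pos[match(ci * 3L + 0:2, map$cds_idx)]
  if (anyNA(members)) return(NULL)
  bases <- seq_chars(amp$sequence)[members + 1L]
  if (ctx$coding_strand == "-")
    bases <- vapply(bases, revcomp, character(1), USE.NAMES = FALSE)
  list(codon = paste(bases, collapse = ""), codon_index = ci,
       within = within, amp_positions = members)
}

# would substituting `new_base_plus` (given on the + strand) at amplicon
# position `pos` leave the encoded amino acid unchanged?
is_synonymous <- function(ctx, amp, pos, new_base_plus) {
  cd <- codon_at(ctx, amp, pos)
  if (is.null(cd)) return(FALSE)
  b <- if (ctx$coding_strand == "+") toupper(new_base_plus)
       else revcomp(toupper(new_base_plus))
  alt <- cd$codon
  substr(alt, cd$within + 1L, cd$within + 1L) <- b
  identical(unname(GENETIC_CODE_STD[alt]), unname(GENETIC_CODE_STD[cd$codon]))
}

codon_usage_of <- function(ctx, codon) {
  i <- match(codon, ctx$codon_usage$codon)
  if (is.na(i)) return(NA_real_)
  ctx$codon_usage$rel_freq[i]
}
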