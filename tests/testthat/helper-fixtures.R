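# Published SRSF2 ssODN donor strings (vendor notation: lowercase =
# reference, UPPERCASE = edited base, * = phosphorothioate bond).
SRSF2_SPACER <- "CGGCTGTGGTGTGAGTCCGG"

DONOR_STRINGS <- c(
  silent = "t*g*gacggccgcgagctgcgggtgcaaatggcgcgctacggccgcccTccAgaTtcacaccacagccgccggggaccgccaccccgcag*g*t",
  p95h = "t*g*gacggccgcgagctgcgggtgcaaatggcgcgctacggccgccATccggactcacaccacagccgccggggaccgccaccccgcag*g*t",
  long = "TtcacgacaagcgcgacgctgaggacgctatggaTgccatggacggggccgtgctggacggccgcgagctgcgggtgcaaatggcgcgctacggccgccATccggactcacaccacagccgccggggaccgccaccccgcaggtacgggggcggtggctacggacgccggagccgcaggtaaacggggctgaggggaccg",
  p95h_silent = "t*g*gacggccgcgagctgcgggtgcaaatggcgcgctacggccgccATccAgaTtcacaccacagccgccggggaccgccaccccgcag*g*t"
)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Synthetic in-frame coding locus with the SRSF2 spacer + TGG PAM embedded
# on the + strand; deterministic for a given seed. Frame starts at 0 so the
# whole 120-nt amplicon is CDS.
coding_locus <- function(seed = 3) {
  set.seed(seed)
  left <- rand_dna(48)
  right <- rand_dna(49)
  amp <- amplicon("locus", paste0(left, SRSF2_SPACER, "TGG", right))
  guide <- locate_guide(amp, SRSF2_SPACER)
  ctx <- coding_context("locus", rbind(c(0L, 120L)), "+", 0L)
  list(amp = amp, guide = guide, ctx = ctx)
}

# minimal hand-built aligned_read for pileup-level tests
mk_aln <- function(read_id, amp_id, ref_start, ops, seq, qual = NULL,
                   map_conf = 60L, strand = "+") {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Phred 40
  structure(list(read_id = read_id, amplicon_id = amp_id,
                 ref_start = as.integer(ref_start),
                 ops = data.frame(op = ops$op, len = as.integer(ops$len),
                                  stringsAsFactors = FALSE),
                 score = NA_real_, strand = strand,
                 map_conf = as.integer(map_conf),
                 sequence = seq, quality = qual),
            class = "aligned_read")
}

phred_string <- function(q, n) strrep(intToUtf8(q + 33L), n)
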