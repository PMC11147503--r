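test_that("read classification follows the outcome precedence", {
  fx <- coding_locus()
  don <- design_ssodn(fx$amp, fx$guide, fx$ctx, mutate_pam = TRUE,
                      n_spacer_silent = 2, allow_nonsilent = TRUE)
  hdr <- make_allele(fx$amp, don, "hdr")

  al_hdr <- align_read(hdr$sequence, fx$amp, read_id = "hdr")
  expect_equal(classify_read(al_hdr, fx$guide, don)$label, "HDR_complete")

  al_wt <- align_read(fx$amp$sequence, fx$amp, read_id = "wt")
  expect_equal(classify_read(al_wt, fx$guide, don)$label, "WT")

  nhej <- make_allele(fx$amp, list(list(type = "del",
                                        start = fx$guide$cut_index - 2L,
                                        end = fx$guide$cut_index + 3L)))
  al_nhej <- align_read(nhej$sequence, fx$amp, read_id = "nhej")
  expect_equal(classify_read(al_nhej, fx$guide, don)$label, "NHEJ_indel")

  # 2 of 3 donor bases (third reverted) with no indel -> partial
  ch <- strsplit(hdr$sequence, "")[[1]]
  rev1 <- don$edits$amp_pos[1]
  ch[rev1 + 1L] <- substring(fx$amp$sequence, rev1 + 1L, rev1 + 1L)
  al_part <- align_read(paste(ch, collapse = ""), fx$amp, read_id = "part")
  cls <- classify_read(al_part, fx$guide, don)
  expect_equal(cls$label, "HDR_partial")
  expect_equal(cls$evidence$donor_matched, 2L)
  expect_equal(cls$evidence$donor_total, 3L)

  # NHEJ takes precedence even when all donor bases are present
  hdr_del <- make_allele(fx$amp, don)
  hd <- strsplit(hdr_del$sequence, "")[[1]]
  hd <- hd[-(fx$guide$cut_index + 1L)]        # 1-nt del at the cut
  al_both <- align_read(paste(hd, collapse = ""), fx$amp, read_id = "both")
  expect_equal(classify_read(al_both, fx$guide, don)$label, "NHEJ_indel")

  # a read not covering the window is ambiguous
  al_short <- align_read(substring(fx$amp$sequence, 1, 30), fx$amp,
                         read_id = "short")
  expect_equal(classify_read(al_short, fx$guide, don)$label, "ambiguous")

  # low-quality donor-position calls force ambiguity
  qual <- rep(40L, nchar(hdr$sequence))
  qual[don$edits$amp_pos + 1L] <- 10L
  al_lowq <- align_read(data.frame(read_id = "lowq",
                                   sequence = hdr$sequence,
                                   quality = intToUtf8(qual + 33L)), fx$amp)
  expect_equal(classify_read(al_lowq, fx$guide, don)$label, "ambiguous")
})

test_that("sequence-mode quantification recovers the simulated mixture", {
  fx <- coding_locus()
  don <- design_ssodn(fx$amp, fx$guide, fx$ctx, mutate_pam = TRUE,
                      n_spacer_silent = 2, allow_nonsilent = TRUE)
  hdr <- make_allele(fx$amp, don, "hdr")
  mix <- list(list(allele_id = "hdr", sequence = hdr$sequence,
                   fraction = 0.94),
              list(allele_id = "wt", sequence = fx$amp$sequence,
                   fraction = 0.06))
  rd <- simulate_reads(mix, 600, perfect_reads(), seed = 51)
  alns <- align_reads(rd, fx$amp)
  q <- quantify_editing(alns, fx$guide, don)
  truth <- mean(rd$true_allele == "hdr")
  expect_equal(unname(q$fractions["HDR_complete"]), truth)
  expect_equal(q$ambiguous_fraction, 0)
  # per-read agreement with the truth labels at zero error
  labels <- vapply(alns, function(al)
    classify_read(al, fx$guide, don)$label, character(1))
  ids <- vapply(alns, `[[`, character(1), "read_id")
  truth_lab <- ifelse(rd$true_allele[match(ids, rd$read_id)] == "hdr",
                      "HDR_complete", "WT")
  expect_equal(labels, truth_lab)

  # all-WT mixture: nothing but WT
  rd0 <- simulate_reads(list(list(allele_id = "wt",
                                  sequence = fx$amp$sequence,
                                  fraction = 1)), 100, perfect_reads(),
                        seed = 52)
  q0 <- quantify_editing(align_reads(rd0, fx$amp), fx$guide, don)
  expect_equal(unname(q0$fractions["HDR_complete"]), 0)
  expect_equal(unname(q0$fractions["NHEJ_indel"]), 0)
  expect_equal(unname(q0$fractions["WT"]), 1)
})

test_that("estimates are invariant to read order and strand", {
  fx <- coding_locus()
  don <- design_ssodn(fx$amp, fx$guide, fx$ctx, mutate_pam = FALSE,
                      n_spacer_silent = 2)
  hdr <- make_allele(fx$amp, don, "hdr")
  mix <- list(list(allele_id = "hdr", sequence = hdr$sequence,
                   fraction = 0.5),
              list(allele_id = "wt", sequence = fx$amp$sequence,
                   fraction = 0.5))
  rd <- simulate_reads(mix, 80, error_model(), seed = 53)
  alns <- align_reads(rd, fx$amp)
  q1 <- quantify_editing(alns, fx$guide, don)
  q2 <- quantify_editing(rev(alns), fx$guide, don)
  expect_equal(q1$fractions, q2$fractions)
  # reverse-complement every read: identical outcome
  rd_rc <- rd
  rd_rc$sequence <- vapply(rd$sequence, revcomp, character(1),
                           USE.NAMES = FALSE)
  rd_rc$quality <- vapply(rd$quality, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  q3 <- quantify_editing(align_reads(rd_rc, fx$amp), fx$guide, don)
  expect_equal(q1$fractions, q3$fractions)
})

test_that("digest quantification handles bands and molecules", {
  # gel mode: mass-weighted cut fraction
  bands <- data.frame(length = c(90, 50, 40), mass = c(30, 35, 35),
                      cut = c(FALSE, TRUE, TRUE))
  expect_equal(digest_quantify(bands = bands)$cut_fraction, 0.7)
  bands0 <- data.frame(length = c(90, 50, 40), mass = c(0, 60, 40))
  expect_equal(digest_quantify(bands = bands0,
                               uncut_length = 90)$cut_fraction, 1)

  # molecule mode with assay validation
  fx <- coding_locus()
  wt <- fx$amp$sequence
  expect_false(grepl("TCCGGA", wt, fixed = TRUE))
  edited <- paste0(substring(wt, 1, fx$guide$cut_index), "TCCGGA",
                   substring(wt, fx$guide$cut_index + 7, nchar(wt)))
  mix <- list(list(allele_id = "edited", sequence = edited, fraction = 0.5),
              list(allele_id = "wt", sequence = wt, fraction = 0.5))
  rd <- simulate_reads(mix, 2000, perfect_reads(), seed = 54)
  dq <- digest_quantify(rd, wt_sequence = wt)
  truth <- mean(rd$true_allele == "edited")
  expect_equal(dq$cut_fraction, truth)

  # invalid assay: site already in WT
  expect_error(digest_quantify(rd, wt_sequence = edited), "invalid")
})

test_that("digest and sequence modes agree on the same simulated mixture", {
  # a locus whose payload edit both converts the codon and creates the
  # BspEI site: WT carries TCCGTA just 3' of the PAM; the payload T->G
  # substitution turns it into TCCGGA
  set.seed(59)
  left <- rand_dna(45)
  right <- rand_dna(40)
  wt_seq <- paste0(left, SRSF2_SPACER, "TGG", "TCCGTA", right)
  if (grepl("TCCGGA", wt_seq, fixed = TRUE) ||
      grepl("TCCGGA", revcomp(wt_seq), fixed = TRUE))
    wt_seq <- sub("TCCGGA", "TACGGA", wt_seq)   # scrub chance sites
  amp <- amplicon("rflp", wt_seq)
  g <- locate_guide(amp, SRSF2_SPACER)
  site_pos <- 45L + 20L + 3L + 4L               # the T of TCCGTA, 0-based
  payload <- data.frame(amp_pos = site_pos, alt_base = "G")
  don <- design_ssodn(amp, g, ctx = NULL, payload_edits = payload,
                      mutate_pam = FALSE, n_spacer_silent = 0,
                      arm_len5 = 45, arm_len3 = 40)
  rep <- validate_donor(don, g, amp)
  expect_equal(unname(rep$sites_gained["BspEI"]), 1L)
  hdr <- make_allele(amp, don, "hdr")
  mix <- list(list(allele_id = "hdr", sequence = hdr$sequence,
                   fraction = 0.3),
              list(allele_id = "wt", sequence = amp$sequence,
                   fraction = 0.7))
  rd <- simulate_reads(mix, 1200, error_model(sub_rate = 0.003,
                                              ins_rate = 0, del_rate = 0),
                       seed = 55)
  dq <- digest_quantify(rd, wt_sequence = amp$sequence)
  alns <- align_reads(rd, amp)
  sq <- quantify_editing(alns, g, don)
  truth <- mean(rd$true_allele == "hdr")
  sigma3 <- 3 * sqrt(truth * (1 - truth) / 1200)
  expect_lt(abs(dq$cut_fraction - truth), sigma3)
  expect_lt(abs(unname(sq$fractions["HDR_complete"]) - truth), sigma3)
  expect_lt(abs(dq$cut_fraction - unname(sq$fractions["HDR_complete"])),
            sigma3)
})

test_that("size-shift quantification detects the expected insert length", {
  fx <- coding_locus()
  intron <- rand_dna(143)
  ia <- make_allele(fx$amp, list(list(type = "ins",
                                      pos = fx$guide$cut_index,
                                      seq = intron)), "intron")
  mix1 <- list(list(allele_id = "intron", sequence = ia$sequence,
                    fraction = 1))
  rd <- simulate_reads(mix1, 40, perfect_reads(), seed = 56)
  alns <- align_reads(rd, fx$amp, align_params(expected_indel = 143))
  ss <- size_shift_quantify(alns, fx$guide)
  expect_equal(ss$integrated_fraction, 1)

  # an insert of the wrong size (100 when expecting 143 +/- 10%) scores 0
  ia100 <- make_allele(fx$amp, list(list(type = "ins",
                                         pos = fx$guide$cut_index,
                                         seq = rand_dna(100))), "i100")
  rd100 <- simulate_reads(list(list(allele_id = "i100",
                                    sequence = ia100$sequence,
                                    fraction = 1)), 30, perfect_reads(),
                          seed = 57)
  alns100 <- align_reads(rd100, fx$amp, align_params(expected_indel = 100))
  ss100 <- size_shift_quantify(alns100, fx$guide)
  expect_equal(ss100$integrated_fraction, 0)

  # 20% intron mixture under nanopore-like errors within binomial 3 sigma
  mix2 <- list(list(allele_id = "wt", sequence = fx$amp$sequence,
                    fraction = 0.8),
               list(allele_id = "intron", sequence = ia$sequence,
                    fraction = 0.2))
  rd2 <- simulate_reads(mix2, 2000, error_model(), seed = 58)
  alns2 <- align_reads(rd2, fx$amp, align_params(expected_indel = 143))
  ss2 <- size_shift_quantify(alns2, fx$guide)
  truth <- mean(rd2$true_allele == "intron")
  expect_lt(abs(ss2$integrated_fraction - truth),
            3 * sqrt(truth * (1 - truth) / 2000))
})
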