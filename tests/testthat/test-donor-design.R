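test_that("silent substitution enumeration preserves translation", {
  fx <- coding_locus()
  cds <- fx$ctx
  win <- c(fx$guide$spacer_interval[2] - 10L, fx$guide$spacer_interval[2])
  cand <- enumerate_silent_substitutions(cds, fx$amp, win)
  expect_gt(nrow(cand), 0)
  wt_prot <- translate_dna(fx$amp$sequence)
  for (i in seq_len(nrow(cand))) {
    ch <- strsplit(fx$amp$sequence, "")[[1]]
    ch[cand$amp_pos[i] + 1L] <- cand$alt_base[i]
    expect_identical(translate_dna(paste(ch, collapse = "")), wt_prot)
  }
  # sorted by usage distance ascending
  expect_true(all(diff(cand$usage_distance) >= 0))
})

test_that("single-codon amino acids yield no silent candidates", {
  # ATG (Met) and TGG (Trp) have no synonyms
  amp <- amplicon("met", "ATGTGGATGTGG")
  ctx <- coding_context("met", rbind(c(0L, 12L)), "+", 0L)
  cand <- enumerate_silent_substitutions(ctx, amp, c(0L, 12L))
  expect_equal(nrow(cand), 0L)
})

test_that("non-coding regions give an empty candidate list", {
  amp <- amplicon("nc", rand_dna(60))
  ctx <- coding_context("nc", rbind(c(0L, 30L)), "+", 0L)
  cand <- enumerate_silent_substitutions(ctx, amp, c(40L, 55L))
  expect_equal(nrow(cand), 0L)
})

test_that("leucine wobble candidates include the near-usage synonym", {
  # CTG (Leu, usage .40) at a known position: CTC (.20) must be offered
  amp <- amplicon("leu", paste0("ATG", "CTG", "AAA"))
  ctx <- coding_context("leu", rbind(c(0L, 9L)), "+", 0L)
  cand <- enumerate_silent_substitutions(ctx, amp, c(3L, 6L))
  expect_true("CTC" %in% cand$alt_codon)
  ctc <- cand[cand$alt_codon == "CTC", ]
  expect_equal(ctc$usage_distance,
               abs(0.40 - 0.20) / 1.01 * 1,  # family renormalised by 1.01
               tolerance = 1e-6)
})

test_that("designed donors satisfy the mismatch-count identity", {
  fx <- coding_locus()
  for (n_sil in 0:2) {
    don <- design_ssodn(fx$amp, fx$guide, fx$ctx, mutate_pam = FALSE,
                        n_spacer_silent = n_sil)
    rep <- validate_donor(don, fx$guide, fx$amp, fx$ctx)
    expect_equal(rep$mismatches, n_sil)
    if (n_sil > 0) {
      expect_true(all(don$edits$class == "spacer_silent"))
      expect_identical(translate_dna(rep$edited_allele),
                       translate_dna(fx$amp$sequence))
      expect_false(rep$residual_protospacer)
      expect_false(oracle_protospacer_scan(rep$edited_allele, SRSF2_SPACER))
    } else {
      # identity donor: reference window, protospacer intact
      expect_equal(don$full_sequence,
                   substring(fx$amp$sequence,
                             fx$guide$cut_index - 45 + 1,
                             fx$guide$cut_index + 45))
      expect_true(rep$residual_protospacer)
    }
  }
})

test_that("payload + PAM + silent design removes the protospacer", {
  fx <- coding_locus()
  # payload inside the spacer, clear of the PAM, so the PAM edit is separate
  payload <- data.frame(amp_pos = fx$guide$cut_index - 6L, alt_base = "A")
  ref_base <- substring(fx$amp$sequence, payload$amp_pos + 1,
                        payload$amp_pos + 1)
  if (ref_base == "A") payload$alt_base <- "G"
  don <- design_ssodn(fx$amp, fx$guide, fx$ctx, payload_edits = payload,
                      mutate_pam = TRUE, n_spacer_silent = 2,
                      allow_nonsilent = TRUE)
  rep <- validate_donor(don, fx$guide, fx$amp, fx$ctx)
  expect_gte(rep$mismatches, 3)
  expect_equal(rep$mismatches, 1L + 1L + 2L)  # payload + pam + silent
  expect_false(rep$residual_protospacer)
  expect_false(oracle_protospacer_scan(rep$edited_allele, SRSF2_SPACER))
  expect_setequal(unique(don$edits$class),
                  c("payload", "pam_disrupting", "spacer_silent"))
})

test_that("silent-only PAM disruption errors without a synonymous option", {
  # force a Trp (TGG) codon exactly on the PAM: no synonymous escape
  set.seed(11)
  left <- rand_dna(48)                       # spacer ends at 68; PAM 68..70
  right <- rand_dna(49)
  amp <- amplicon("trp", paste0(left, SRSF2_SPACER, "TGG", right))
  ctx <- coding_context("trp", rbind(c(0L, 120L)), "+", 2L)
  g <- locate_guide(amp, SRSF2_SPACER)
  # depending on frame the GG may or may not admit a silent change; request
  # silent-only and accept either a silent design or the explanatory error
  res <- tryCatch(
    design_ssodn(amp, g, ctx, mutate_pam = TRUE, n_spacer_silent = 0),
    error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "allow_nonsilent")
  } else {
    expect_true(all(res$edits$class == "pam_disrupting"))
  }
})

test_that("the printed P95H donor (and only it) gains one BspEI site", {
  # anchor both published donors to a reconstructed wild-type window:
  # each donor is reference (lowercase) where the other is edited, except
  # the shared position, recoverable from the silent donor's context
  d_sil <- parse_donor(DONOR_STRINGS["silent"], "silent")
  d_p95 <- parse_donor(DONOR_STRINGS["p95h"], "p95h")
  wt <- strsplit(d_p95$full_sequence, "")[[1]]
  # revert P95H payload positions using the silent donor (lowercase there)
  sil <- strsplit(d_sil$full_sequence, "")[[1]]
  for (pos in d_p95$edits$donor_pos) {
    if (!(pos %in% d_sil$edits$donor_pos)) wt[pos + 1L] <- sil[pos + 1L]
  }
  # position 46 is uppercase (edited) in both printed donors, so its true
  # reference base is not derivable from print; substitute a non-edited
  # base (C) to build a synthetic wild-type stand-in without the site
  shared <- intersect(d_p95$edits$donor_pos, d_sil$edits$donor_pos)
  expect_equal(shared, 46L)
  wt[shared + 1L] <- "C"
  wt_amp <- amplicon("srsf2_synthetic_wt", paste(wt, collapse = ""))
  g <- locate_guide(wt_amp, SRSF2_SPACER, require_pam = FALSE)
  rep_p95 <- validate_donor(d_p95, g, wt_amp)
  rep_sil <- validate_donor(d_sil, g, wt_amp)
  expect_equal(unname(rep_p95$sites_gained["BspEI"]), 1L)
  expect_equal(unname(rep_sil$sites_gained["BspEI"]), 0L)
  # direct string facts from the printed sequences
  expect_true(grepl("TCCGGA", d_p95$full_sequence, fixed = TRUE))
  expect_false(grepl("TCCGGA", d_sil$full_sequence, fixed = TRUE))
})

test_that("anchoring fills reference bases and honours both strands", {
  fx <- coding_locus()
  don <- design_ssodn(fx$amp, fx$guide, fx$ctx, mutate_pam = FALSE,
                      n_spacer_silent = 2)
  expect_true(all(!is.na(don$edits$ref_base)))
  expect_true(all(don$edits$ref_base != don$edits$donor_base))

  # re-anchor the same donor to the reverse-complemented amplicon
  rc_amp <- amplicon("rc", revcomp(fx$amp$sequence))
  d2 <- parse_donor(render_donor(don), "same")
  anc <- anchor_donor(d2, rc_amp)
  expect_equal(anc$anchor$strand, "-")
  expect_setequal(paste(anc$edits$ref_base, anc$edits$donor_base),
                  paste(don$edits$ref_base, don$edits$donor_base))

  # a pure reference substring anchors with zero edits
  plain <- parse_donor(tolower(substring(fx$amp$sequence, 21, 80)))
  anc2 <- anchor_donor(plain, fx$amp)
  expect_equal(nrow(anc2$edits), 0L)
  expect_equal(anc2$anchor$start, 20L)

  # zero or multiple anchor sites are errors
  expect_error(anchor_donor(parse_donor("acgtacgtacgtacgtacgt"),
                            amplicon("x", rand_dna(30))), "anchor")
})

test_that("zero-edit donors validate as inert", {
  fx <- coding_locus()
  plain <- parse_donor(tolower(substring(fx$amp$sequence, 31, 100)))
  rep <- validate_donor(plain, fx$guide, fx$amp, fx$ctx)
  expect_true(rep$residual_protospacer)
  expect_equal(rep$mismatches, 0L)
  expect_equal(sum(rep$sites_gained), 0L)
  expect_equal(sum(rep$sites_lost), 0L)
})
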