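test_that("exact substrings align as a single match run", {
  set.seed(5)
  ref <- rand_dna(200)
  amp <- amplicon("a", ref)
  al <- align_read(substring(ref, 11, 90), amp)
  expect_equal(al$ref_start, 10L)
  expect_equal(al$ops, data.frame(op = "M", len = 80L))
  expect_equal(al$strand, "+")
})

test_that("a 143-nt insertion is kept as a single contiguous I op", {
  set.seed(6)
  ref <- rand_dna(200)
  amp <- amplicon("a", ref)
  read <- paste0(substring(ref, 1, 100), rand_dna(143),
                 substring(ref, 101, 200))
  al <- align_read(read, amp, align_params(expected_indel = 143))
  ii <- al$ops[al$ops$op == "I", ]
  expect_equal(nrow(ii), 1L)
  expect_equal(ii$len, 143L)
})

test_that("banded score equals the exhaustive DP oracle on random pairs", {
  set.seed(8)
  p <- align_params()
  for (i in 1:60) {
    read <- rand_dna(sample(5:40, 1))
    ref <- rand_dna(sample(5:40, 1))
    al <- align_read(read, amplicon("r", ref), p,
                     try_both_strands = FALSE)
    expect_equal(al$score, oracle_glocal_score(read, ref),
                 info = sprintf("pair %d", i))
  }
})

test_that("indels are left-aligned in homopolymer context", {
  # reference has a 6-A homopolymer; a deletion anywhere inside it must be
  # reported at the leftmost position
  ref <- paste0("CGTCG", strrep("A", 6), "GTCGT")
  amp <- amplicon("hp", ref)
  read <- paste0("CGTCG", strrep("A", 4), "GTCGT")   # 2-A deletion
  al <- align_read(read, amp)
  dd <- which(al$ops$op == "D")
  expect_equal(length(dd), 1L)
  rpos <- al$ref_start + sum(al$ops$len[seq_len(dd - 1)][
    al$ops$op[seq_len(dd - 1)] %in% c("M", "D")])
  expect_equal(rpos, 5L)   # leftmost A of the run
  expect_equal(al$ops$len[dd], 2L)

  # insertion into the run likewise anchors leftmost
  read2 <- paste0("CGTCG", strrep("A", 8), "GTCGT")
  al2 <- align_read(read2, amp)
  ii <- which(al2$ops$op == "I")
  expect_equal(length(ii), 1L)
  rpos2 <- al2$ref_start + sum(al2$ops$len[seq_len(ii - 1)][
    al2$ops$op[seq_len(ii - 1)] %in% c("M", "D")])
  expect_equal(rpos2, 5L)
})

test_that("ops bookkeeping matches read length and reference span", {
  set.seed(12)
  amp <- amplicon("a", rand_dna(150))
  mix <- list(list(allele_id = "wt", sequence = amp$sequence, fraction = 1))
  rd <- simulate_reads(mix, 30, error_model(sub_rate = 0.02,
                                            ins_rate = 0.01,
                                            del_rate = 0.01), seed = 4)
  for (i in seq_len(nrow(rd))) {
    al <- align_read(rd[i, , drop = FALSE], amp)
    qlen <- sum(al$ops$len[al$ops$op %in% c("M", "I", "S")])
    expect_equal(qlen, nchar(rd$sequence[i]))
    rspan <- sum(al$ops$len[al$ops$op %in% c("M", "D")])
    expect_lte(al$ref_start + rspan, 150L)
    # ops never begin/end with I or D after normalisation
    expect_false(al$ops$op[1] %in% c("I", "D"))
    expect_false(al$ops$op[nrow(al$ops)] %in% c("I", "D"))
  }
})

test_that("amplicon assignment recovers the source locus", {
  set.seed(13)
  amps <- list(amplicon("a1", rand_dna(120)),
               amplicon("a2", rand_dna(120)),
               amplicon("a3", rand_dna(120)))
  for (src in 1:3) {
    mix <- list(list(allele_id = amps[[src]]$id,
                     sequence = amps[[src]]$sequence, fraction = 1))
    rd <- simulate_reads(mix, 5, error_model(), seed = src)
    for (i in seq_len(nrow(rd))) {
      al <- assign_amplicon(rd[i, , drop = FALSE], amps)
      expect_equal(al$amplicon_id, amps[[src]]$id)
      expect_equal(al$map_conf, 60L)
    }
  }
  # permutation invariance
  rd <- simulate_reads(list(list(allele_id = "a2",
                                 sequence = amps[[2]]$sequence,
                                 fraction = 1)), 1, perfect_reads(), seed = 5)
  a_fwd <- assign_amplicon(rd[1, , drop = FALSE], amps)
  a_rev <- assign_amplicon(rd[1, , drop = FALSE], rev(amps))
  expect_equal(a_fwd$amplicon_id, a_rev$amplicon_id)
  expect_equal(a_fwd$map_conf, a_rev$map_conf)

  # a read of N's is unassignable
  rn <- data.frame(read_id = "n", comment = "", sequence = strrep("N", 100),
                   quality = strrep("I", 100), true_allele = "")
  expect_null(assign_amplicon(rn, amps))

  # duplicated amplicons force ambiguity
  dup <- list(amps[[1]], amplicon("copy", amps[[1]]$sequence))
  rd1 <- simulate_reads(list(list(allele_id = "a1",
                                  sequence = amps[[1]]$sequence,
                                  fraction = 1)), 1, perfect_reads(),
                        seed = 6)
  al_dup <- assign_amplicon(rd1[1, , drop = FALSE], dup)
  expect_equal(al_dup$map_conf, 0L)
})

test_that("reverse-strand reads are located and flagged", {
  set.seed(14)
  amp <- amplicon("a", rand_dna(150))
  rc_read <- revcomp(substring(amp$sequence, 21, 140))
  al <- align_read(rc_read, amp)
  expect_equal(al$strand, "-")
  expect_equal(al$ref_start, 20L)
  expect_equal(al$ops, data.frame(op = "M", len = 120L))
})

test_that("SAM round-trips preserve positions, CIGARs and MAPQ", {
  set.seed(15)
  amp <- amplicon("locus1", rand_dna(140))
  mix <- list(list(allele_id = "wt", sequence = amp$sequence, fraction = 1))
  rd <- simulate_reads(mix, 20, error_model(sub_rate = 0.02,
                                            ins_rate = 0.01,
                                            del_rate = 0.01), seed = 16)
  alns <- align_reads(rd, amp)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(alns, amp, path)
  back <- read_sam(path)
  expect_equal(length(back), length(alns))
  for (i in seq_along(alns)) {
    expect_equal(back[[i]]$ref_start, alns[[i]]$ref_start)
    expect_equal(back[[i]]$ops, alns[[i]]$ops)
    expect_equal(back[[i]]$map_conf, alns[[i]]$map_conf)
    expect_equal(back[[i]]$sequence, alns[[i]]$sequence)
  }
})

test_that("SAM parsing honours MAPQ, CIGAR and unmapped records", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:amp\tLN:100",
    paste("r1", 0, "amp", 1, 10, "5S90M", "*", 0, 0, strrep("A", 95),
          strrep("I", 95), sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII", sep = "\t")
  ), path)
  reads <- read_sam(path)
  expect_equal(length(reads), 1L)
  expect_equal(attr(reads, "n_unmapped"), 1L)
  expect_equal(reads[[1]]$map_conf, 10L)
  expect_equal(reads[[1]]$ops,
               data.frame(op = c("S", "M"), len = c(5L, 90L)))
  # malformed CIGAR is an error with a line number
  writeLines(c("@SQ\tSN:amp\tLN:100",
               paste("r1", 0, "amp", 1, 10, "5Q90M", "*", 0, 0, "A", "I",
                     sep = "\t")), path)
  expect_error(read_sam(path), "CIGAR")
})
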