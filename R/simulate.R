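#' Nanopore-like sequencing error model
#'
#' Per-base independent substitutions; insertion/deletion events with
#' geometric lengths; the deletion rate is multiplied inside homopolymer
#' runs of length >= 3 to caricature nanopore behaviour. Base qualities are
#' drawn from a clipped normal and emitted as Phred+33.
#'
#' @param sub_rate,ins_rate,del_rate Per-base event rates in `[0, 1)`.
#' @param indel_length Geometric parameter: extra length beyond 1 is
#'   `rgeom(prob = indel_length)` (default 0.5, mean length 2).
#' @param homopolymer_del_multiplier Deletion-rate multiplier inside
#'   homopolymers >= 3 nt (>= 1; default 3).
#' @param quality_mean,quality_sd Emitted Phred quality distribution for
#'   correctly called bases (clipped to `[2, 41]`).
#' @param quality_mean_error Mean Phred quality of substituted and inserted
#'   bases (default 10): basecallers assign lower confidence to errors,
#'   which is what makes downstream base-quality filtering informative.
#' @return An `error_model`.
#' @export
error_model <- function(sub_rate = 0.01, ins_rate = 0.0025,
                        del_rate = 0.005, indel_length = 0.5,
                        homopolymer_del_multiplier = 3,
                        quality_mean = 20, quality_sd = 5,
                        quality_mean_error = 10) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, homopolymer_del_multiplier >= 1,
            indel_length > 0, indel_length <= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, indel_length = indel_length,
                 homopolymer_del_multiplier = homopolymer_del_multiplier,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 quality_mean_error = quality_mean_error),
            class = "error_model")
}

#' Error-free model (all rates zero)
#' @export
#' @rdname error_model
perfect_reads <- function() {
  error_model(sub_rate = 0, ins_rate = 0, del_rate = 0,
              quality_mean = 40, quality_sd = 0)
}

#' Construct an allele sequence from an amplicon
#'
#' Applies a list of modifications — substitutions, insertions, deletions —
#' with positions given on the *unmodified* amplicon (0-based; insertions at
#' between-base indices), or substitutes the edits of an anchored donor to
#' produce the HDR allele.
#'
#' @param amp An [amplicon()].
#' @param modifications Either an anchored `donor_spec` or a list of
#'   modifications: `list(type = "sub", pos =, base =)`,
#'   `list(type = "ins", pos =, seq =)` (inserted before 0-based position
#'   `pos`), `list(type = "del", start =, end =)` (half-open interval).
#' @param allele_id Label for the allele.
#' @return A list with `allele_id` and `sequence`.
#' @export
make_allele <- function(amp, modifications = list(), allele_id = "allele") {
  stopifnot(inherits(amp, "amplicon"))
  if (inherits(modifications, "donor_spec"))
    return(list(allele_id = allele_id,
                sequence = apply_donor(amp, modifications)))
  n <- nchar(amp$sequence)
  spans <- lapply(modifications, function(m) {
    switch(m$type,
      sub = c(m$pos, m$pos + 1L),
      del = c(m$start, m$end),
      ins = c(m$pos, m$pos),
      stop("unknown modification type: ", m$type))
  })
  for (s in spans)
    if (s[1] < 0 || s[2] > n) stop("modification out of amplicon bounds")
  solid <- spans[vapply(spans, function(s) s[2] > s[1], logical(1))]
  if (length(solid) > 1L) {
    o <- order(vapply(solid, `[`, numeric(1), 1))
    so <- solid[o]
    for (i in seq_len(length(so) - 1L))
      if (so[[i + 1L]][1] < so[[i]][2]) stop("overlapping modifications")
  }
  ch <- seq_chars(amp$sequence)
  pieces <- as.list(ch)          # one slot per reference base
  pre <- vector("list", n + 1L)  # insertions before each position
  for (m in modifications) {
    if (m$type == "sub") pieces[[m$pos + 1L]] <- toupper(m$base)
    else if (m$type == "del")
      for (p in seq.int(m$start, m$end - 1L)) pieces[[p + 1L]] <- ""
    else pre[[m$pos + 1L]] <- paste0(pre[[m$pos + 1L]], toupper(m$seq))
  }
  out <- character(0)
  for (i in seq_len(n)) {
    if (!is.null(pre[[i]])) out <- c(out, pre[[i]])
    out <- c(out, pieces[[i]])
  }
  if (!is.null(pre[[n + 1L]])) out <- c(out, pre[[n + 1L]])
  list(allele_id = allele_id, sequence = paste(out, collapse = ""))
}

# identify positions lying in homopolymer runs >= min_run
homopolymer_mask <- function(chars, min_run = 3L) {
  r <- rle(chars)
  rep(r$lengths >= min_run, r$lengths)
}

# apply the error model to one sequence; returns the read string plus a
# per-emitted-base error flag (TRUE for substituted or inserted bases),
# which drives the error-aware quality emission
corrupt_sequence <- function(seq, err) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n == 0L) return(list(seq = "", is_err = logical(0)))
  bases <- c("A", "C", "G", "T")
  is_err <- logical(n)
  # substitutions
  hit <- runif(n) < err$sub_rate
  if (any(hit)) {
    for (i in which(hit)) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    is_err[hit] <- TRUE
  }
  # deletions (homopolymer-aware)
  del_p <- rep(err$del_rate, n)
  if (err$del_rate > 0) {
    hp <- homopolymer_mask(seq_chars(seq))
    del_p[hp] <- pmin(0.5, del_p[hp] * err$homopolymer_del_multiplier)
  }
  keep <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    if (keep[i] && runif(1) < del_p[i]) {
      len <- 1L + rgeom(1L, err$indel_length)
      keep[seq.int(i, min(n, i + len - 1L))] <- FALSE
      i <- i + len
    } else i <- i + 1L
  }
  # insertions (after surviving bases)
  out <- ch
  flags <- as.list(is_err)
  out[!keep] <- ""
  flags[!keep] <- list(logical(0))
  if (err$ins_rate > 0) {
    ins_at <- which(runif(n) < err$ins_rate)
    for (i in ins_at) {
      len <- 1L + rgeom(1L, err$indel_length)
      out[i] <- paste0(out[i], paste(sample(bases, len, replace = TRUE),
                                     collapse = ""))
      flags[[i]] <- c(flags[[i]], rep(TRUE, len))
    }
  }
  list(seq = paste(out, collapse = ""), is_err = unlist(flags))
}

#' Simulate amplicon reads from an allele mixture
#'
#' Allele identities are drawn multinomially from the mixture fractions and
#' each read is passed through the error model. Output is reproducible:
#' identical `(mixture, n_reads, err, seed)` give byte-identical FASTQ. The
#' true allele of each read is recorded in the FASTQ comment (after the
#' first whitespace), where downstream tools ignore it.
#'
#' @param mixture A list of components, each
#'   `list(allele_id =, sequence =, fraction =)`; fractions must sum to 1.
#' @param n_reads Number of reads (>= 0).
#' @param err An [error_model()].
#' @param seed Integer seed.
#' @param read_span `NULL` for full-length reads, or a 0-based half-open
#'   interval `c(start, end)` on the allele sequence.
#' @return A data frame with columns `read_id`, `comment` (`allele=<id>`),
#'   `sequence`, `quality` (Phred+33 string), `true_allele`.
#' @export
simulate_reads <- function(mixture, n_reads, err = error_model(), seed = 1L,
                           read_span = NULL) {
  fr <- vapply(mixture, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  stopifnot(n_reads >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (n_reads == 0L)
    return(data.frame(read_id = character(0), comment = character(0),
                      sequence = character(0), quality = character(0),
                      true_allele = character(0)))
  which_allele <- sample.int(length(mixture), n_reads, replace = TRUE,
                             prob = fr)
  templates <- vapply(mixture, `[[`, character(1), "sequence")
  if (!is.null(read_span))
    templates <- substring(templates, read_span[1] + 1L, read_span[2])
  reads <- character(n_reads); quals <- character(n_reads)
  ids <- sprintf("read_%06d", seq_len(n_reads))
  alleles <- vapply(mixture, `[[`, character(1), "allele_id")[which_allele]
  zero_err <- err$sub_rate == 0 && err$ins_rate == 0 && err$del_rate == 0
  const_q <- err$quality_sd == 0
  if (const_q) {
    q1 <- min(41L, max(2L, as.integer(round(err$quality_mean))))
    qchar <- intToUtf8(q1 + 33L)
  }
  for (i in seq_len(n_reads)) {
    template <- templates[which_allele[i]]
    if (zero_err) {
      r <- template
      is_err <- logical(nchar(r))
    } else {
      cs <- corrupt_sequence(template, err)
      r <- cs$seq
      is_err <- cs$is_err
    }
    reads[i] <- r
    quals[i] <- if (const_q) strrep(qchar, nchar(r)) else {
      qm <- ifelse(is_err, err$quality_mean_error, err$quality_mean)
      q <- round(rnorm(nchar(r), qm, err$quality_sd))
      intToUtf8(pmin(41L, pmax(2L, q)) + 33L)
    }
  }
  data.frame(read_id = ids, comment = paste0("allele=", alleles),
             sequence = reads, quality = quals, true_allele = alleles,
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Data frame as from [simulate_reads()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  hdr <- ifelse(nzchar(reads$comment),
                paste(reads$read_id, reads$comment),
                reads$read_id)
  lines <- as.vector(rbind(paste0("@", hdr), reads$sequence, "+",
                           reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path.
#' @return Data frame with `read_id`, `comment`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  if (length(hdr) && any(!grepl("^@", hdr))) stop("malformed FASTQ header")
  hdr <- sub("^@", "", hdr)
  data.frame(
    read_id = sub("\\s.*$", "", hdr),
    comment = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
    sequence = lines[seq(2L, length(lines), by = 4L)],
    quality = lines[seq(4L, length(lines), by = 4L)],
    stringsAsFactors = FALSE)
}

#' Simulate clone genotypes under the donor-mixture model
#'
#' Each diploid clone draws its two alleles independently: an allele is
#' edited with probability `h`; an edited allele carries the mutant donor
#' with probability `p_mutant`, else the silent donor.
#'
#' @param p_mutant Fraction of mutant donor among delivered donors.
#' @param h Per-allele HDR probability.
#' @param n_clones Number of clones.
#' @param seed Integer seed.
#' @return Named integer vector of counts over the six genotype classes
#'   `hom_mut`, `het_mut_silent`, `hom_silent`, `mut_wt`, `silent_wt`,
#'   `unedited`.
#' @export
simulate_clones <- function(p_mutant, h, n_clones, seed = 1L) {
  stopifnot(p_mutant >= 0, p_mutant <= 1, h >= 0, h <= 1, n_clones >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw_allele <- function(n) {
    edited <- runif(n) < h
    mut <- runif(n) < p_mutant
    ifelse(!edited, "W", ifelse(mut, "M", "S"))
  }
  a1 <- draw_allele(n_clones); a2 <- draw_allele(n_clones)
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "")
  lab <- c(MM = "hom_mut", MS = "het_mut_silent", SS = "hom_silent",
           MW = "mut_wt", SW = "silent_wt", WW = "unedited")
  cls <- lab[key]
  counts <- table(factor(cls, levels = unname(lab)))
  setNames(as.integer(counts), names(counts))
}

#' Simulate limiting-dilution wells under the single-hit Poisson model
#'
#' A well seeded with `d` cells is negative with probability
#' `exp(-frequency * d)`.
#'
#' @param frequency Responding-cell frequency per cell (>= 0).
#' @param doses Data frame with columns `dose` (cells per well) and
#'   `n_wells`.
#' @param seed Integer seed.
#' @return The `doses` data frame with an added `n_negative` column.
#' @export
simulate_ld_wells <- function(frequency, doses, seed = 1L) {
  stopifnot(frequency >= 0, all(doses$dose > 0), all(doses$n_wells >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p_neg <- exp(-frequency * doses$dose)
  doses$n_negative <- rbinom(nrow(doses), doses$n_wells, p_neg)
  doses
}
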