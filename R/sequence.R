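#' @useDynLib ampedit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim p.adjust pt qnorm rbinom rgeom rnorm runif t.test
#'   setNames uniroot rmultinom pchisq glm binomial coef anova qbeta vcov
#' @importFrom utils read.delim write.table head
"_PACKAGE"

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Accepts the full IUPAC alphabet (upper or lower case); case is preserved.
#' An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq A single DNA string.
#' @return The reverse complement as a single string.
#' @export
#' @examples
#' revcomp("CGGCTGTGGTGTGAGTCCGG")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  from <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
  to   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"
  if (grepl(sprintf("[^%s]", from), seq))
    stop("non-IUPAC character in sequence")
  chartr(from, to, paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                         collapse = ""))
}

# vectorized per-base IUPAC membership: does base b match pattern letter p?
iupac_match <- function(bases, pattern) {
  stopifnot(length(bases) == length(pattern))
  ok <- logical(length(bases))
  for (i in seq_along(bases)) {
    set <- IUPAC_SETS[[toupper(pattern[i])]]
    if (is.null(set)) stop("invalid IUPAC letter: ", pattern[i])
    ok[i] <- toupper(bases[i]) %in% set
  }
  ok
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Amplicon reference sequence
#'
#' A labelled reference amplicon. Sequences are stored uppercase; positions
#' throughout the package are 0-based with half-open intervals `[start, end)`
#' (rendered tables use 1-based inclusive coordinates).
#'
#' @param id Unique identifier.
#' @param sequence DNA string over A/C/G/T (N tolerated but flagged).
#' @param description Optional free-text description.
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("amplicon sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("amplicon sequence restricted to A/C/G/T (N allowed)")
  has_n <- grepl("N", sequence, fixed = TRUE)
  structure(list(id = id, sequence = sequence, description = description,
                 has_ambiguous = has_n),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s (%d nt)%s\n", x$id, nchar(x$sequence),
              if (x$has_ambiguous) " [contains N]" else ""))
  invisible(x)
}

#' Read amplicon references from a FASTA file
#'
#' @param path Path to a FASTA file. IDs (first whitespace-delimited token of
#'   each header) must be unique.
#' @return A named list of [amplicon()] objects.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) stop("duplicate FASTA IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(seq_along(ids), function(i)
    paste(lines[!hdr & idx == i], collapse = ""), character(1))
  out <- lapply(seq_along(ids), function(i) amplicon(ids[i], seqs[i], desc[i]))
  names(out) <- ids
  out
}

#' Write amplicon references to a FASTA file
#'
#' @param amps A list of [amplicon()] objects (or a single one).
#' @param path Output path.
#' @param width Line width for wrapped sequence (default 60).
#' @export
write_fasta <- function(amps, path, width = 60L) {
  if (inherits(amps, "amplicon")) amps <- list(amps)
  con <- file(path, "w")
  on.exit(close(con))
  for (a in amps) {
    hdr <- if (nzchar(a$description)) paste(a$id, a$description) else a$id
    writeLines(paste0(">", hdr), con)
    s <- a$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
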