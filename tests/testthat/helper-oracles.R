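# Independent full-matrix DP oracle for the end-free two-piece affine
# alignment score: plain-R recurrences over the complete (unbanded) matrix,
# written without reference to the package's C++ implementation.
oracle_glocal_score <- function(read, ref, match = 2, mismatch = -4,
                                gap_open = 4, gap_extend = 2,
                                gap_open2 = 24, gap_extend2 = 1) {
  n <- nchar(read); m <- nchar(ref)
  rd <- strsplit(read, "")[[1]]; rf <- strsplit(ref, "")[[1]]
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1); X2 <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1); Y2 <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in seq_len(n)) {
    Y[i + 1, 1] <- -(gap_open + gap_extend * i)
    Y2[i + 1, 1] <- -(gap_open2 + gap_extend2 * i)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (rd[i] == rf[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], X2[i, j],
                             Y[i, j], Y2[i, j]) + s
      X[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             X[i + 1, j] - gap_extend)
      X2[i + 1, j + 1] <- max(M[i + 1, j] - gap_open2 - gap_extend2,
                              X2[i + 1, j] - gap_extend2)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             Y[i, j + 1] - gap_extend)
      Y2[i + 1, j + 1] <- max(M[i, j + 1] - gap_open2 - gap_extend2,
                              Y2[i, j + 1] - gap_extend2)
    }
  }
  max(M[n + 1, ], Y[n + 1, ], Y2[n + 1, ])
}

# brute-force protospacer scan: is spacer followed by an NGG anywhere on
# either strand?
oracle_protospacer_scan <- function(seqs, spacer) {
  scan1 <- function(s) {
    L <- nchar(spacer)
    if (nchar(s) < L + 3) return(FALSE)
    for (i in seq_len(nchar(s) - L - 2)) {
      if (substring(s, i, i + L - 1) == spacer &&
          substring(s, i + L + 1, i + L + 2) == "GG")
        return(TRUE)
    }
    FALSE
  }
  scan1(seqs) || scan1(revcomp(seqs))
}

# base-by-base complement, independent of the package's chartr path
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}
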