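# Independent brute-force reference for the skew index: window counting by
# string splitting, circularization by string concatenation, and a full
# double loop over every (start, transition) pair. Deliberately shares no
# code with the package internals.

oracle_alpha <- function(bases, w) {
  n <- nchar(bases) %/% w
  vapply(seq_len(n), function(i) {
    win <- substring(bases, (i - 1L) * w + 1L, i * w)
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    g <- sum(ch == "G")
    cc <- sum(ch == "C")
    if (g > cc) 1L else if (g < cc) -1L else 0L
  }, integer(1))
}

oracle_skewi <- function(bases, w, shift = 0.04) {
  L <- nchar(bases)
  circ <- paste0(bases, substring(bases, 1L, L %/% 2L))
  a <- oracle_alpha(circ, w)
  m <- L %/% w
  N <- length(a)
  h <- m %/% 2L
  d <- round(shift * m)
  best <- -Inf
  for (x in 0:(N - m)) {
    for (t in max(1L, h - d):min(m - 1L, h + d)) {
      A <- sum(a[(x + 1L):(x + t)])
      B <- sum(a[(x + t + 1L):(x + m)])
      if (abs(A - B) > best) best <- abs(A - B)
    }
  }
  list(score = best, skew_i = best / m)
}

# Uniform i.i.d. ACGT genome as a plain string.
random_bases <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Ideal two-compartment genome: first half G, second half C.
ideal_bases <- function(L) paste0(strrep("G", L %/% 2L), strrep("C", L - L %/% 2L))

rotate_seq <- function(seq, r) {
  L <- seq$length
  r <- r %% L
  if (r == 0L) return(seq)
  nucleotide_sequence(seq$id,
                      paste0(substr(seq$bases, r + 1L, L), substr(seq$bases, 1L, r)),
                      seq$description)
}

# Integer |A - B| score recovered from a skewi_result.
result_score <- function(res) abs(res$A - res$B)
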