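#' Parameters for skew-index computation
#'
#' @param window_size Window width `w` in bp. 20 kbp balances robustness to
#'   local polarity fluctuations (which depress the index at small `w`)
#'   against resolution on short chromosomes.
#' @param shift_fraction How far, as a fraction of genome length, the
#'   leading/lagging transition point may move from the midpoint in either
#'   direction; 0.04 allows the leading strand to span 46--54% of the genome.
#' @param min_windows Below this many windows per genome length a warning is
#'   issued: the index becomes unreliable when the genome is covered by only
#'   a handful of windows.
#' @param strict_min_windows Below this many windows computation is refused.
#' @return An object of class `skew_params`.
#' @export
skew_params <- function(window_size = 20000L, shift_fraction = 0.04,
                        min_windows = 10L, strict_min_windows = 2L) {
  window_size <- as.integer(window_size)
  stopifnot(length(window_size) == 1L, !is.na(window_size), window_size >= 1L,
            is.numeric(shift_fraction), length(shift_fraction) == 1L,
            shift_fraction >= 0, shift_fraction < 0.5,
            strict_min_windows >= 2L, min_windows >= strict_min_windows)
  structure(list(window_size = window_size,
                 shift_fraction = shift_fraction,
                 min_windows = as.integer(min_windows),
                 strict_min_windows = as.integer(strict_min_windows)),
            class = "skew_params")
}

#' Circularize a linear genome representation
#'
#' Bacterial chromosomes are circular but deposited as linear strings with an
#' arbitrary position 1. Appending the first `floor(L/2)` bases to the end
#' (total length 1.5L) guarantees that some contiguous genome-length stretch
#' of the result starts at the true origin of replication, wherever the
#' deposited coordinate origin lies.
#'
#' @param seq A `nuc_seq` of length L >= 2.
#' @return A `nuc_seq` of length `L + floor(L/2)` carrying the original
#'   length in field `original_length`. Callers apply this exactly once.
#' @examples
#' circularize(nucleotide_sequence("x", "ACGTAA"))$bases  # "ACGTAAACG"
#' @export
circularize <- function(seq) {
  stopifnot(inherits(seq, "nuc_seq"), seq$length >= 2L)
  half <- seq$length %/% 2L
  out <- nucleotide_sequence(seq$id,
                             paste0(seq$bases, substr(seq$bases, 1L, half)),
                             seq$description)
  out$original_length <- seq$length
  out
}

# Per-window G and C counts over adjacent non-overlapping windows of width w;
# a trailing partial window is discarded. Prefix sums over the raw bytes keep
# this O(n) for multi-megabase chromosomes.
.window_gc_counts <- function(bases, w) {
  r <- charToRaw(bases)
  nw <- length(r) %/% w
  if (nw == 0L) return(list(g = integer(0), c = integer(0), n_windows = 0L))
  r <- r[seq_len(nw * w)]
  cg <- cumsum(r == as.raw(71L))  # 'G'
  cc <- cumsum(r == as.raw(67L))  # 'C'
  at <- seq.int(w, nw * w, by = w)
  list(g = as.integer(diff(c(0, cg[at]))),
       c = as.integer(diff(c(0, cc[at]))),
       n_windows = nw)
}

#' Window polarity vector of a circularized genome
#'
#' Splits the circularized sequence into adjacent windows of width `w`
#' (trailing partial window discarded) and assigns each window a polarity
#' alpha: +1 if it holds more G than C, -1 if more C than G, 0 on ties.
#' Only literal G and C count; A, T, N and ambiguity codes contribute to
#' neither side.
#'
#' @param seq A circularized `nuc_seq` (from [circularize()]).
#' @param params A [skew_params()].
#' @return An object of class `alpha_vector`: list with `alphas` (integer
#'   vector in \{-1, 0, +1\}, one per window, `floor(1.5 L / w)` of them),
#'   `window_size`, `genome_length` (the original L), `m` (`floor(L / w)`,
#'   windows per genome length), and `g_counts` / `c_counts`.
#' @export
alpha_vector <- function(seq, params = skew_params()) {
  stopifnot(inherits(seq, "nuc_seq"))
  if (is.null(seq$original_length))
    stop("alpha_vector() expects a circularized sequence; call circularize() first")
  L <- seq$original_length
  w <- params$window_size
  m <- L %/% w
  if (m < params$strict_min_windows)
    stop(sprintf("genome too short for window size: %d bp yields %d window(s) per genome length (need >= %d)",
                 L, m, params$strict_min_windows))
  if (m < params$min_windows)
    warning(sprintf("only %d windows per genome length for '%s'; the skew index is unreliable below %d",
                    m, seq$id, params$min_windows))
  cnt <- .window_gc_counts(seq$bases, w)
  structure(list(alphas = as.integer(sign(cnt$g - cnt$c)),
                 window_size = w, genome_length = L, m = m,
                 g_counts = cnt$g, c_counts = cnt$c),
            class = "alpha_vector")
}

# Exhaustive search for the genome-length window and transition point that
# maximize |A - B|, via prefix sums over alpha. Integer arithmetic
# throughout; ties broken by smallest window start, then smallest transition.
.max_partition_diff <- function(alphas, m, shift_fraction) {
  N <- length(alphas)
  h <- m %/% 2L
  d <- as.integer(round(shift_fraction * m))
  ts <- seq.int(max(1L, h - d), min(m - 1L, h + d))
  S <- c(0L, cumsum(alphas))
  xs <- 0:(N - m)
  scores <- vapply(ts, function(t)
    abs(2L * S[xs + t + 1L] - S[xs + 1L] - S[xs + m + 1L]),
    numeric(length(xs)))
  scores <- matrix(scores, nrow = length(xs))
  best <- max(scores)
  hit <- which(scores == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
  x <- xs[hit[[1L]]]
  t <- ts[hit[[2L]]]
  list(score = best,
       x = x, t = t,
       A = S[x + t + 1L] - S[x + 1L],
       B = S[x + m + 1L] - S[x + t + 1L])
}

#' Skew index (SkewI) of a bacterial chromosome
#'
#' Computes the normalized skew index in \[0, 1\]: the genome is
#' circularized, cut into windows of width `w` with polarity alpha in
#' \{-1, 0, +1\} per window ([alpha_vector()]), and a genome-length window of
#' `m = floor(L/w)` consecutive windows slides across all starts. Each
#' candidate window is split into two partitions at a transition point
#' allowed to move up to `shift_fraction` of the genome length from the
#' midpoint (so the leading strand may span 46--54% of the genome at the
#' default), and the absolute difference of the partition alpha sums,
#' `|A - B|`, is maximized over all starts and transitions. The index is that
#' maximum divided by `m`. A genome with clean two-compartment polarity
#' scores 1; one with no compartment structure scores near 0.
#'
#' The search uses prefix sums but is exactly equivalent to direct
#' enumeration of every (start, transition) pair; all arithmetic is integer
#' until the final division. Ties in the argmax are broken toward the
#' smallest start, then the smallest transition (this affects only the
#' reported boundary, never the index).
#'
#' @param seq A `nuc_seq` (not circularized; that happens internally).
#' @param params A [skew_params()].
#' @return An object of class `skewi_result`: list with `id`, `skew_i`,
#'   `best_start` (window index of the maximizing genome-length window,
#'   0-based), `best_transition` (windows from `best_start` to the chosen
#'   partition boundary), `A`, `B` (partition alpha sums), `m`,
#'   `window_size`, `genome_length`, and `predicted_boundary_bp` (1-based
#'   base coordinate of the transition mapped onto the original genome — an
#'   estimate of an ori/ter location).
#' @examples
#' g <- nucleotide_sequence("ideal", paste0(strrep("G", 40000), strrep("C", 40000)))
#' skew_index(g, skew_params(window_size = 20000))$skew_i  # 1
#' @export
skew_index <- function(seq, params = skew_params()) {
  av <- alpha_vector(circularize(seq), params)
  res <- .max_partition_diff(av$alphas, av$m, params$shift_fraction)
  structure(list(id = seq$id,
                 skew_i = res$score / av$m,
                 best_start = res$x,
                 best_transition = res$t,
                 A = res$A, B = res$B,
                 m = av$m,
                 window_size = av$window_size,
                 genome_length = av$genome_length,
                 predicted_boundary_bp =
                   ((res$x + res$t) * av$window_size) %% av$genome_length + 1L),
            class = "skewi_result")
}

#' @export
print.skewi_result <- function(x, ...) {
  cat(sprintf("<skewi_result> %s  SkewI = %.4f  (L = %s bp, w = %s, m = %d)\n",
              x$id, x$skew_i, format(x$genome_length, big.mark = ","),
              format(x$window_size, big.mark = ","), x$m))
  cat(sprintf("  |A - B| = |%d - %d| = %d; predicted ori/ter boundary at bp %s\n",
              x$A, x$B, abs(x$A - x$B),
              format(x$predicted_boundary_bp, big.mark = ",")))
  invisible(x)
}

#' Tabulate skew-index results
#'
#' @param results A `skewi_result` or list of them.
#' @return data.frame with columns `id`, `length`, `window_size`, `skew_i`,
#'   `predicted_boundary_bp`.
#' @export
skewi_table <- function(results) {
  if (inherits(results, "skewi_result")) results <- list(results)
  data.frame(
    id = vapply(results, `[[`, character(1), "id"),
    length = vapply(results, function(r) as.integer(r$genome_length), integer(1)),
    window_size = vapply(results, function(r) as.integer(r$window_size), integer(1)),
    skew_i = vapply(results, `[[`, numeric(1), "skew_i"),
    predicted_boundary_bp = vapply(results, function(r)
      as.integer(r$predicted_boundary_bp), integer(1)),
    stringsAsFactors = FALSE)
}

#' GC-skew profile of a genome
#'
#' The classic windowed statistic `(G - C) / (G + C)` over adjacent
#' non-overlapping windows of the original (non-circularized) sequence,
#' together with its running (cumulative) sum. In the cumulative curve the
#' origin of replication sits at the global minimum and the terminus at the
#' global maximum for a typical chromosome. Windows with no G or C at all
#' are assigned skew 0.
#'
#' @param seq A `nuc_seq` with `length >= window_size`.
#' @param params A [skew_params()]; only `window_size` is used.
#' @return An object of class `skew_profile`: list with `id`, `window_size`,
#'   `window_starts` (0-based), `gc_skew`, `cumulative`.
#' @export
gc_skew_profile <- function(seq, params = skew_params()) {
  stopifnot(inherits(seq, "nuc_seq"))
  w <- params$window_size
  if (seq$length < w)
    stop(sprintf("sequence '%s' (%d bp) is shorter than one window (%d bp)",
                 seq$id, seq$length, w))
  cnt <- .window_gc_counts(seq$bases, w)
  den <- cnt$g + cnt$c
  skew <- ifelse(den == 0L, 0, (cnt$g - cnt$c) / pmax(den, 1L))
  structure(list(id = seq$id, window_size = w,
                 window_starts = (seq_len(cnt$n_windows) - 1L) * w,
                 gc_skew = skew,
                 cumulative = cumsum(skew)),
            class = "skew_profile")
}

#' @export
as.data.frame.skew_profile <- function(x, ...) {
  data.frame(id = x$id,
             window_start = x$window_starts,
             window_end = x$window_starts + x$window_size,
             gc_skew = x$gc_skew,
             cumulative = x$cumulative,
             stringsAsFactors = FALSE)
}

#' Write a GC-skew profile as a TSV table
#'
#' Columns: id, window_start (0-based), window_end, gc_skew, cumulative.
#'
#' @param profile A `skew_profile` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  if (inherits(profile, "skew_profile")) profile <- list(profile)
  tab <- do.call(rbind, lapply(profile, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
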