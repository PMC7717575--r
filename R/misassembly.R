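# chartr-based complement over the full IUPAC alphabet; reversal on raw bytes.
.revcomp_chr <- function(x) {
  rawToChar(rev(charToRaw(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x))))
}

#' Reverse complement of a sequence
#'
#' @param seq A `nuc_seq`.
#' @return A `nuc_seq` with the reverse-complemented bases (IUPAC ambiguity
#'   codes complemented to their mirror codes).
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "nuc_seq"))
  nucleotide_sequence(seq$id, .revcomp_chr(seq$bases), seq$description)
}

#' Simulate a translocation mis-assembly
#'
#' Excises a uniformly placed segment of length `round(k_percent * L / 100)`
#' and reinserts it intact (orientation preserved) at a uniform position in
#' the remaining sequence — the canonical model of a segment deposited at
#' the wrong place by an assembler. Output length and base composition equal
#' the input's. Draws from R's global random number stream; call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param seq A `nuc_seq`.
#' @param k_percent Segment length as a percentage of genome length, in
#'   \[0, 100\]. `k_percent = 0` returns the input unchanged.
#' @return List with `seq` (the mutated `nuc_seq`) and `rearrangement`
#'   (list with `kind`, `source_start`, `source_end`, `insert_pos`; all
#'   coordinates 0-based, half-open on the relevant string; `NULL` when
#'   `k_percent = 0`).
#' @export
translocate <- function(seq, k_percent) {
  stopifnot(inherits(seq, "nuc_seq"))
  if (!is.numeric(k_percent) || length(k_percent) != 1L ||
      k_percent < 0 || k_percent > 100)
    stop("k_percent must be a single value in [0, 100]")
  L <- seq$length
  if (k_percent == 0) return(list(seq = seq, rearrangement = NULL))
  seg <- as.integer(round(k_percent * L / 100))
  if (seg < 1L)
    stop(sprintf("segment length rounds to zero (k = %g%% of %d bp)", k_percent, L))
  src <- sample.int(L - seg + 1L, 1L) - 1L
  excised <- substr(seq$bases, src + 1L, src + seg)
  rest <- paste0(substr(seq$bases, 1L, src),
                 substr(seq$bases, src + seg + 1L, L))
  ins <- sample.int(L - seg + 1L, 1L) - 1L
  mutated <- paste0(substr(rest, 1L, ins), excised,
                    substr(rest, ins + 1L, L - seg))
  out <- nucleotide_sequence(seq$id, mutated, seq$description)
  list(seq = out,
       rearrangement = list(kind = "translocation",
                            source_start = src, source_end = src + seg,
                            insert_pos = ins))
}

#' Reverse-complement a segment in place
#'
#' The editing operator for correcting (or introducing) an assembly
#' inversion: bases in `[start, end)` are replaced by their reverse
#' complement, leaving length unchanged. Applying it twice with the same
#' coordinates restores the original sequence.
#'
#' @param seq A `nuc_seq`.
#' @param start,end 0-based half-open coordinates, `0 <= start < end <= L`.
#' @return The mutated `nuc_seq`.
#' @export
invert_segment <- function(seq, start, end) {
  stopifnot(inherits(seq, "nuc_seq"))
  L <- seq$length
  if (!(start >= 0 && start < end && end <= L))
    stop(sprintf("invalid segment [%s, %s) on a %d bp sequence", start, end, L))
  mutated <- paste0(substr(seq$bases, 1L, start),
                    .revcomp_chr(substr(seq$bases, start + 1L, end)),
                    substr(seq$bases, end + 1L, L))
  nucleotide_sequence(seq$id, mutated, seq$description)
}

# Deterministic per-cell seed: a polynomial hash of "<id>|<k>" folded into
# the master seed, kept below 2^31 so set.seed() accepts it. The rule is a
# pure function of (master seed, genome id, k), so rerunning any subset of
# the grid reproduces the full run's replicate streams.
.cell_seed <- function(master, id, k) {
  h <- 0
  for (ch in utf8ToInt(paste0(id, "|", format(k)))) h <- (h * 131 + ch) %% 2100000000
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Translocation detection-sensitivity experiment
#'
#' For each genome and each segment size `k` (percent of genome length),
#' generates `n_reps` independent random translocations, recomputes the skew
#' index of each mutant, and counts a detection whenever the mutant index
#' falls strictly below that genome's cohort threshold — the same rule used
#' for flagging real assemblies. Rates are also averaged per species when a
#' species map is given, mirroring how sensitivity is reported across a
#' species' genomes.
#'
#' Each (genome, k) cell draws from its own seeded stream derived
#' deterministically from `seed`, so the report is bit-reproducible and
#' partial reruns of a subset of genomes or k values match the full run.
#'
#' @param genomes List of `nuc_seq` objects.
#' @param thresholds Named numeric vector: skew-index threshold per genome
#'   id. Every genome must have one.
#' @param k_values Numeric vector of segment sizes in percent (e.g.
#'   `c(2.5, 5, ..., 30)`).
#' @param n_reps Replicates per (genome, k) cell.
#' @param params [skew_params()] used for scoring.
#' @param seed Master seed.
#' @param species Optional named character vector: species per genome id,
#'   used to average rates across genomes of a species.
#' @return Object of class `simulation_report`: list with `per_genome`
#'   (data.frame: genome_id, species, k, n, detected, rate, seed),
#'   `per_species` (data.frame: species, k, rate; `NULL` when no species
#'   map), `master_seed`, `params`.
#' @export
detection_experiment <- function(genomes, thresholds, k_values,
                                 n_reps = 100L, params = skew_params(),
                                 seed = 1L, species = NULL) {
  if (inherits(genomes, "nuc_seq")) genomes <- list(genomes)
  stopifnot(length(genomes) > 0L, n_reps >= 1L, length(k_values) > 0L,
            all(k_values >= 0 & k_values <= 100))
  ids <- vapply(genomes, `[[`, character(1), "id")
  missing_thr <- setdiff(ids, names(thresholds))
  if (length(missing_thr) > 0L)
    stop("no threshold supplied for genome(s): ",
         paste(missing_thr, collapse = ", "))
  rows <- vector("list", length(genomes) * length(k_values))
  cell <- 0L
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    thr <- thresholds[[g$id]]
    for (k in k_values) {
      cell <- cell + 1L
      cs <- .cell_seed(seed, g$id, k)
      set.seed(cs)
      detected <- 0L
      for (r in seq_len(n_reps)) {
        mut <- translocate(g, k)$seq
        if (skew_index(mut, params)$skew_i < thr) detected <- detected + 1L
      }
      rows[[cell]] <- data.frame(
        genome_id = g$id,
        species = if (is.null(species)) NA_character_ else species[[g$id]],
        k = k, n = as.integer(n_reps), detected = detected,
        rate = detected / n_reps, seed = cs,
        stringsAsFactors = FALSE)
    }
  }
  per_genome <- do.call(rbind, rows)
  per_species <- NULL
  if (!is.null(species)) {
    agg <- stats::aggregate(rate ~ species + k, data = per_genome, FUN = mean)
    per_species <- agg[order(agg$species, agg$k), , drop = FALSE]
    rownames(per_species) <- NULL
  }
  structure(list(per_genome = per_genome, per_species = per_species,
                 master_seed = seed, params = params),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("<simulation_report> %d genome(s) x %d k value(s), %d reps each (seed %d)\n",
              length(unique(x$per_genome$genome_id)),
              length(unique(x$per_genome$k)),
              x$per_genome$n[1L], x$master_seed))
  print(utils::head(x$per_genome, 12L))
  invisible(x)
}

#' Write a simulation report as TSV
#'
#' @param report A `simulation_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_report <- function(report, path) {
  utils::write.table(report$per_genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
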