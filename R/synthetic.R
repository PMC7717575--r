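# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; with seed = NULL the global stream is used.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic bacterial chromosome with known GC-skew structure
#'
#' Emulates the two-replichore organization of a circular bacterial
#' chromosome: on the leading-strand compartment G is enriched over C, on
#' the lagging-strand compartment the enrichment is mirrored, and A/T are
#' symmetric throughout. Bases are drawn i.i.d. — no dinucleotide or gene
#' structure — which is sufficient to exercise window-level polarity
#' statistics. The finished sequence is rotated left by `ori_offset` to
#' emulate the arbitrary coordinate origin of deposited assemblies.
#'
#' Per-position probabilities on the leading compartment are
#' `P(G) = gc (1 + delta) / 2`, `P(C) = gc (1 - delta) / 2`,
#' `P(A) = P(T) = (1 - gc) / 2`; on the lagging compartment G and C swap.
#' `delta = 0` gives a skew-free genome, `delta = 1` a compartment with no C
#' at all on the leading strand.
#'
#' @param length Genome length L in bp (>= 2).
#' @param gc_content Fraction of G+C, in \[0, 1\].
#' @param delta Skew strength in \[0, 1\]: the G-vs-C probability difference
#'   between replichores as a fraction of the GC probability.
#' @param ori_offset Left rotation in bp applied after generation, in
#'   \[0, L).
#' @param leading_fraction Fraction of the genome on the leading-strand
#'   compartment, in \[0.46, 0.54\] (matching the transition-point
#'   flexibility of the skew index); 0.5 gives equal replichores.
#' @param seed Optional seed; generation is reproducible from it and leaves
#'   the caller's RNG stream untouched.
#' @param id Record identifier; a descriptive default is built from the
#'   parameters.
#' @return A `nuc_seq`.
#' @examples
#' g <- synthetic_genome(100000, delta = 1, seed = 1)
#' skew_index(g, skew_params(window_size = 10000))$skew_i  # 1
#' @export
synthetic_genome <- function(length, gc_content = 0.5, delta = 0,
                             ori_offset = 0L, leading_fraction = 0.5,
                             seed = NULL, id = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 2L,
            gc_content >= 0, gc_content <= 1,
            delta >= 0, delta <= 1,
            ori_offset >= 0, ori_offset < length,
            leading_fraction >= 0.46, leading_fraction <= 0.54)
  if (is.null(id))
    id <- sprintf("synthetic_L%d_gc%g_d%g_r%d", length, gc_content, delta,
                  as.integer(ori_offset))
  n_lead <- as.integer(round(leading_fraction * length))
  pg <- gc_content * (1 + delta) / 2
  pc <- gc_content * (1 - delta) / 2
  pa <- (1 - gc_content) / 2
  bases <- .with_seed(seed, {
    lead <- sample(c("A", "C", "G", "T"), n_lead, replace = TRUE,
                   prob = c(pa, pc, pg, pa))
    lag <- sample(c("A", "C", "G", "T"), length - n_lead, replace = TRUE,
                  prob = c(pa, pg, pc, pa))
    paste(c(lead, lag), collapse = "")
  })
  ori_offset <- as.integer(ori_offset)
  if (ori_offset > 0L)
    bases <- paste0(substr(bases, ori_offset + 1L, length),
                    substr(bases, 1L, ori_offset))
  nucleotide_sequence(id, bases,
                      sprintf("synthetic chromosome gc=%g delta=%g ori_offset=%d",
                              gc_content, delta, ori_offset))
}

#' Generate a deterministic synthetic test cohort
#'
#' Builds several "genera" of synthetic genomes at distinct skew strengths —
#' a miniature of a multi-genus survey — together with the matching taxonomy
#' table. Optionally materializes both to disk (multi-FASTA plus taxonomy
#' TSV) for use as command-line fixtures.
#'
#' @param n_per_genus Genomes per genus.
#' @param deltas Named numeric vector: one skew strength per genus; names
#'   become genus names.
#' @param length Genome length for every cohort member, bp.
#' @param gc_content GC fraction for every member.
#' @param seed Master seed; member i of genus j gets a seed derived from it.
#' @param out_dir If non-NULL, writes `genomes.fasta` and `taxonomy.tsv`
#'   there (directory created if needed).
#' @return List with `genomes` (list of `nuc_seq`) and `taxonomy`
#'   (data.frame: sequence_id, genus, species, delta), invisibly when
#'   writing to disk.
#' @export
synthetic_cohort <- function(n_per_genus = 12L,
                             deltas = c(Altoskewia = 0.9,
                                        Mesoskewia = 0.6,
                                        Paraskewia = 0.3),
                             length = 200000L, gc_content = 0.5,
                             seed = 1L, out_dir = NULL) {
  stopifnot(n_per_genus >= 1L, !is.null(names(deltas)), all(nzchar(names(deltas))))
  genomes <- list()
  tax <- list()
  idx <- 0L
  for (j in seq_along(deltas)) {
    genus <- names(deltas)[j]
    for (i in seq_len(n_per_genus)) {
      idx <- idx + 1L
      sid <- sprintf("%s_g%02d", tolower(genus), i)
      g <- synthetic_genome(length, gc_content = gc_content,
                            delta = deltas[[j]],
                            ori_offset = ((i - 1L) * (length %/% n_per_genus)) %% length,
                            seed = .cell_seed(seed, sid, deltas[[j]]),
                            id = sid)
      genomes[[idx]] <- g
      tax[[idx]] <- data.frame(sequence_id = sid, genus = genus,
                               species = sprintf("%s exemplaris", genus),
                               delta = deltas[[j]], stringsAsFactors = FALSE)
    }
  }
  taxonomy <- do.call(rbind, tax)
  out <- list(genomes = genomes, taxonomy = taxonomy)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genomes, file.path(out_dir, "genomes.fasta"))
    utils::write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
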