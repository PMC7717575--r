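test_that("translocation conserves length and base composition", {
  g <- synthetic_genome(10000, delta = 0.5, seed = 41)
  set.seed(1)
  for (k in c(2.5, 10, 50, 100)) {
    mut <- translocate(g, k)
    expect_equal(mut$seq$length, g$length)
    expect_identical(sort(strsplit(mut$seq$bases, "")[[1]]),
                     sort(strsplit(g$bases, "")[[1]]))
    r <- mut$rearrangement
    expect_equal(r$source_end - r$source_start, round(k * g$length / 100))
    expect_true(r$source_start >= 0 && r$source_end <= g$length)
    expect_true(r$insert_pos >= 0 &&
                r$insert_pos <= g$length - (r$source_end - r$source_start))
  }
})

test_that("translocation edge cases: k = 0 is the identity, bad k errors", {
  g <- synthetic_genome(1000, seed = 42)
  mut <- translocate(g, 0)
  expect_identical(mut$seq$bases, g$bases)
  expect_null(mut$rearrangement)
  expect_error(translocate(g, -1), "0, 100")
  expect_error(translocate(g, 101), "0, 100")
  tiny <- nucleotide_sequence("t", "ACGTACGT")
  expect_error(translocate(tiny, 0.5), "rounds to zero")
})

test_that("segment inversion is an in-place reverse complement and an involution", {
  s <- nucleotide_sequence("x", "AAGGGGTT")
  inv <- invert_segment(s, 2, 6)
  expect_equal(inv$bases, "AACCCCTT")
  expect_equal(invert_segment(inv, 2, 6)$bases, s$bases)

  g <- synthetic_genome(5000, delta = 0.7, seed = 43)
  twice <- invert_segment(invert_segment(g, 1234, 4321), 1234, 4321)
  expect_identical(twice$bases, g$bases)

  expect_error(invert_segment(s, -1, 4), "invalid segment")
  expect_error(invert_segment(s, 4, 4), "invalid segment")
  expect_error(invert_segment(s, 4, 9), "invalid segment")
})

test_that("reverse complement matches Biostrings over the IUPAC alphabet", {
  s <- nucleotide_sequence("x", "ACGTRYSWKMBDHVNACGT")
  expect_equal(reverse_complement(s)$bases,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(s$bases))))
  g <- synthetic_genome(3000, delta = 0.4, seed = 44)
  expect_equal(reverse_complement(g)$bases,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$bases))))
})

test_that("inverting one replichore of an ideal genome collapses the index", {
  p <- skew_params(window_size = 10000)
  ideal <- nucleotide_sequence("ideal", ideal_bases(200000))
  expect_equal(skew_index(ideal, p)$skew_i, 1)
  # reverse-complementing the G compartment turns the genome all-C: every
  # window has the same polarity, and all that remains of |A - B| is the
  # partition-size imbalance the transition shift allows, 2 * round(0.04 m)
  flipped <- invert_segment(ideal, 0, 100000)
  res <- skew_index(flipped, p)
  expect_lt(res$skew_i, skew_index(ideal, p)$skew_i)
  expect_equal(res$skew_i, 2 * round(0.04 * res$m) / res$m)
  expect_identical(res$skew_i, oracle_skewi(flipped$bases, 10000)$skew_i)
})

test_that("whole-replichore moves keep the circular pattern; straddling moves break it", {
  p <- skew_params(window_size = 10000)
  L <- 200000L
  # excising the entire G compartment and reinserting it intact is a circular
  # rotation: the G block stays contiguous on the circle and the index stays 1
  aligned <- nucleotide_sequence("a", paste0(strrep("C", 50000), strrep("G", 100000),
                                             strrep("C", 50000)))
  expect_equal(skew_index(aligned, p)$skew_i, 1)
  # a half-genome segment straddling the ori/ter boundary splits both
  # compartments and destroys the two-block structure
  straddle <- nucleotide_sequence("s", paste0(strrep("G", 50000), strrep("C", 50000),
                                              strrep("G", 50000), strrep("C", 50000)))
  expect_lt(skew_index(straddle, p)$skew_i, 1)
})

test_that("the detection experiment is reproducible and consistent across reruns", {
  p <- skew_params(window_size = 5000)
  genomes <- lapply(1:2, function(i)
    synthetic_genome(50000, delta = 1, seed = 50 + i, id = paste0("g", i)))
  thr <- setNames(c(1, 1), c("g1", "g2"))
  rep1 <- detection_experiment(genomes, thr, c(0, 10, 30), n_reps = 5,
                               params = p, seed = 99)
  rep2 <- detection_experiment(genomes, thr, c(0, 10, 30), n_reps = 5,
                               params = p, seed = 99)
  expect_identical(rep1$per_genome, rep2$per_genome)

  # k = 0 never perturbs a genome at or above its threshold
  expect_equal(rep1$per_genome$rate[rep1$per_genome$k == 0], c(0, 0))
  expect_true(all(rep1$per_genome$detected >= 0 &
                  rep1$per_genome$detected <= rep1$per_genome$n))
  expect_equal(rep1$per_genome$rate,
               rep1$per_genome$detected / rep1$per_genome$n)

  # per-cell seeding: rerunning a subset of the grid matches the full run
  sub <- detection_experiment(genomes[1], thr["g1"], c(30), n_reps = 5,
                              params = p, seed = 99)
  full_row <- rep1$per_genome[rep1$per_genome$genome_id == "g1" &
                              rep1$per_genome$k == 30, ]
  rownames(full_row) <- NULL
  expect_identical(sub$per_genome, full_row)
})

test_that("species-level averaging and the TSV export work", {
  p <- skew_params(window_size = 5000)
  genomes <- lapply(1:2, function(i)
    synthetic_genome(50000, delta = 1, seed = 60 + i, id = paste0("g", i)))
  thr <- setNames(c(1, 1), c("g1", "g2"))
  spp <- setNames(c("Speciesa one", "Speciesa one"), c("g1", "g2"))
  rep <- detection_experiment(genomes, thr, c(10, 30), n_reps = 4,
                              params = p, seed = 7, species = spp)
  expect_equal(nrow(rep$per_species), 2L)
  for (k in c(10, 30)) {
    expect_equal(rep$per_species$rate[rep$per_species$k == k],
                 mean(rep$per_genome$rate[rep$per_genome$k == k]))
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_simulation_report(rep, f)
  expect_equal(read.delim(f)$detected, rep$per_genome$detected)

  expect_error(detection_experiment(genomes, thr["g1"], 10), "threshold")
})
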