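#' Read a taxonomy table
#'
#' A delimited text file mapping sequence identifiers to taxa. Must contain a
#' `sequence_id` column and at least one grouping column (typically `genus`
#' and/or `species`); `taxid` and `gc_content` are carried along when
#' present. Tab- or comma-delimited, detected from the header line.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @return data.frame with a unique, non-missing `sequence_id` column.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"")
  if (!"sequence_id" %in% names(tab))
    stop("taxonomy table must contain a 'sequence_id' column; found: ",
         paste(names(tab), collapse = ", "))
  if (anyDuplicated(tab$sequence_id))
    stop("taxonomy table has duplicated sequence_id values")
  tab
}

#' Genus outlier threshold from cohort mean and standard deviation
#'
#' The flagging rule places the threshold two standard deviations below the
#' cohort mean: genomes strictly below it are considered possibly
#' mis-assembled.
#'
#' @param mean_skewi,sd_skewi Cohort mean and standard deviation of the skew
#'   index. Vectorized.
#' @return `mean_skewi - 2 * sd_skewi`.
#' @examples
#' genus_threshold(0.8729, 0.0620)  # 0.7489
#' @export
genus_threshold <- function(mean_skewi, sd_skewi) {
  mean_skewi - 2 * sd_skewi
}

#' Per-genus skew-index statistics and mis-assembly thresholds
#'
#' Joins per-genome skew indices to a taxonomy table and summarizes each
#' taxon: count, mean, sample standard deviation (n - 1 denominator), and —
#' for taxa with at least `min_genomes` genomes — the outlier threshold
#' `mean - 2 * sd` plus the identifiers of genomes strictly below it.
#' Smaller cohorts carry their statistics but no threshold: two standard
#' deviations estimated from a handful of genomes would be meaningless.
#'
#' @param skewi data.frame with columns `id` and `skew_i` (as produced by
#'   [skewi_table()]), or a list of `skewi_result` objects.
#' @param taxonomy data.frame with `sequence_id` and the grouping column
#'   (see [read_taxonomy()]).
#' @param group_by Grouping column name: `"genus"` (default) or `"species"`
#'   (or any column of `taxonomy`).
#' @param min_genomes Minimum cohort size for a threshold to be defined.
#' @return data.frame of class `genus_stats`, one row per taxon, ordered by
#'   decreasing count: columns `genus`, `n`, `mean_skewi`, `sd_skewi`,
#'   `threshold` (NA when `n < min_genomes`), `n_below`,
#'   `below_threshold_ids` (list column), and `mean_gc_content` when the
#'   taxonomy provides `gc_content`.
#' @export
summarize_by_genus <- function(skewi, taxonomy, group_by = "genus",
                               min_genomes = 10L) {
  if (is.list(skewi) && !is.data.frame(skewi)) skewi <- skewi_table(skewi)
  stopifnot(is.data.frame(skewi), all(c("id", "skew_i") %in% names(skewi)),
            is.data.frame(taxonomy), "sequence_id" %in% names(taxonomy))
  if (!group_by %in% names(taxonomy))
    stop("taxonomy table has no '", group_by, "' column")
  idx <- match(skewi$id, taxonomy$sequence_id)
  orphan <- skewi$id[is.na(idx)]
  if (length(orphan) == nrow(skewi))
    stop("no skew-index record joins to the taxonomy table; orphan ids: ",
         paste(utils::head(orphan, 10L), collapse = ", "))
  if (length(orphan) > 0L)
    warning(sprintf("%d record(s) missing from the taxonomy table were excluded: %s",
                    length(orphan), paste(utils::head(orphan, 10L), collapse = ", ")))
  joined <- data.frame(id = skewi$id[!is.na(idx)],
                       skew_i = skewi$skew_i[!is.na(idx)],
                       group = taxonomy[[group_by]][idx[!is.na(idx)]],
                       stringsAsFactors = FALSE)
  if (any(is.na(joined$group) | !nzchar(joined$group)))
    stop("empty '", group_by, "' value for joined record(s): ",
         paste(utils::head(joined$id[is.na(joined$group) | !nzchar(joined$group)], 10L),
               collapse = ", "))
  has_gc <- "gc_content" %in% names(taxonomy)
  if (has_gc) joined$gc_content <- taxonomy$gc_content[idx[!is.na(idx)]]

  groups <- split(joined, joined$group)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    mu <- mean(g$skew_i)
    sdev <- stats::sd(g$skew_i)  # sample SD, NA for n = 1
    thr <- if (n >= min_genomes) genus_threshold(mu, sdev) else NA_real_
    below <- if (is.na(thr)) character(0) else g$id[g$skew_i < thr]
    out <- data.frame(genus = g$group[1L], n = n, mean_skewi = mu,
                      sd_skewi = sdev, threshold = thr,
                      n_below = length(below), stringsAsFactors = FALSE)
    out$below_threshold_ids <- list(below)
    if (has_gc) out$mean_gc_content <- mean(g$gc_content)
    out
  })
  stats <- do.call(rbind, rows)
  stats <- stats[order(-stats$n, stats$genus), , drop = FALSE]
  rownames(stats) <- NULL
  attr(stats, "group_by") <- group_by
  attr(stats, "min_genomes") <- as.integer(min_genomes)
  class(stats) <- c("genus_stats", "data.frame")
  stats
}

#' Flag a genome's skew index against its cohort threshold
#'
#' @param skew_i Numeric vector of skew-index values.
#' @param genus Character vector (recycled) naming each genome's taxon.
#' @param stats A `genus_stats` table from [summarize_by_genus()].
#' @return Character vector: `"below_threshold"` when the taxon has a
#'   threshold and the value is strictly below it, `"ok"` when it has a
#'   threshold and the value is at or above it, `"no_threshold"` when the
#'   taxon is absent from `stats` or its cohort was too small.
#' @export
flag_genome <- function(skew_i, genus, stats) {
  stopifnot(inherits(stats, "genus_stats"))
  n <- max(length(skew_i), length(genus))
  skew_i <- rep_len(skew_i, n)
  genus <- rep_len(genus, n)
  thr <- stats$threshold[match(genus, stats$genus)]
  out <- rep("no_threshold", n)
  has <- !is.na(thr)
  out[has & skew_i < thr] <- "below_threshold"
  out[has & skew_i >= thr] <- "ok"
  out
}

#' Per-genome cohort report
#'
#' Joins skew indices, taxonomy and cohort thresholds into the per-genome
#' table: one row per genome with its taxon, threshold and flag.
#'
#' @inheritParams summarize_by_genus
#' @param stats A `genus_stats` table; computed from `skewi`/`taxonomy` when
#'   omitted.
#' @return data.frame with columns `id`, `genus`, `skew_i`, `threshold`,
#'   `flag`.
#' @export
flag_cohort <- function(skewi, taxonomy, stats = NULL, group_by = "genus") {
  if (is.list(skewi) && !is.data.frame(skewi)) skewi <- skewi_table(skewi)
  if (is.null(stats)) stats <- summarize_by_genus(skewi, taxonomy, group_by)
  idx <- match(skewi$id, taxonomy$sequence_id)
  keep <- !is.na(idx)
  genus <- taxonomy[[group_by]][idx[keep]]
  thr <- stats$threshold[match(genus, stats$genus)]
  data.frame(id = skewi$id[keep],
             genus = genus,
             skew_i = skewi$skew_i[keep],
             threshold = thr,
             flag = flag_genome(skewi$skew_i[keep], genus, stats),
             stringsAsFactors = FALSE)
}

#' Write genus statistics as TSV
#'
#' Columns mirror a per-genus survey table: genus, genome count, mean and SD
#' of the skew index, threshold, number of genomes below threshold, their
#' ids (comma-separated) and mean GC content when available.
#'
#' @param stats A `genus_stats` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genus_stats <- function(stats, path) {
  flat <- as.data.frame(stats)
  flat$below_threshold_ids <- vapply(stats$below_threshold_ids,
                                     paste, character(1), collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
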