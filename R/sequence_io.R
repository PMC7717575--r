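# Letters accepted in a normalized sequence: the four bases plus the IUPAC
# ambiguity codes. Gap/alignment characters are deliberately excluded.
IUPAC_DNA_LETTERS <- "ACGTRYSWKMBDHVN"

#' Construct a nucleotide sequence record
#'
#' A lightweight container for one chromosome (or plasmid) sequence: an
#' identifier, the free-text description from the FASTA header, and the
#' uppercased base string. Bases are validated against the IUPAC nucleotide
#' alphabet (`ACGT` plus ambiguity codes and `N`); any other character is
#' rejected.
#'
#' @param id Record identifier (the first whitespace-delimited token of a
#'   FASTA header). Must be a non-empty string.
#' @param bases Sequence string; lowercase letters are uppercased.
#' @param description Free text following the identifier in the header.
#' @return An object of class `nuc_seq`: a list with elements `id`,
#'   `description`, `bases` and `length` (in bp).
#' @examples
#' s <- nucleotide_sequence("chr1", "acgtACGT")
#' s$length
#' @export
nucleotide_sequence <- function(id, bases, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(bases), length(bases) == 1L,
            is.character(description), length(description) == 1L)
  bases <- toupper(bases)
  bad <- gsub(sprintf("[%s]", IUPAC_DNA_LETTERS), "", bases)
  if (nzchar(bad)) {
    stop(sprintf("sequence '%s' contains non-IUPAC nucleotide character(s): %s",
                 id, paste(unique(strsplit(bad, "", fixed = TRUE)[[1]]), collapse = " ")))
  }
  structure(list(id = id, description = description, bases = bases,
                 length = nchar(bases)),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s  (%s bp)%s\n", x$id, format(x$length, big.mark = ","),
              if (nzchar(x$description)) paste0("  ", x$description) else ""))
  preview <- if (x$length > 60) paste0(substr(x$bases, 1, 60), "...") else x$bases
  cat(" ", preview, "\n")
  invisible(x)
}

# First non-blank line of the file (plain or gzip) with its line number,
# or NULL for a blank file.
.first_content_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 100L, warn = FALSE)
    if (length(chunk) == 0L) return(NULL)
    hit <- which(nzchar(trimws(chunk)))
    if (length(hit) > 0L)
      return(list(line = sub("\r$", "", chunk[hit[1L]]), number = n + hit[1L]))
    n <- n + length(chunk)
  }
}

# Re-scan a FASTA file that Biostrings refused, to report the offending line.
.fasta_diagnose <- function(path, original_msg) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con, warn = FALSE))
  bad_re <- sprintf("[^%s]", IUPAC_DNA_LETTERS)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) { seen_header <- TRUE; next }
    if (!seen_header)
      stop(sprintf("malformed FASTA '%s': sequence data before any '>' header at line %d",
                   path, i))
    if (grepl(bad_re, toupper(ln)))
      stop(sprintf("malformed FASTA '%s': invalid nucleotide character at line %d",
                   path, i))
  }
  stop(sprintf("malformed FASTA '%s': %s", path, original_msg))
}

#' Read a FASTA file of nucleotide sequences
#'
#' Reads plain or gzip-compressed FASTA (single- or multi-record, wrapped or
#' single-line, CRLF tolerated) and returns one [nucleotide_sequence()] record
#' per entry, in file order, with bases uppercased. Parsing is delegated to
#' `Biostrings::readDNAStringSet()`; when it rejects a file, the file is
#' re-scanned so the error names the offending line.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A list of `nuc_seq` objects; an empty list (with a warning) for a
#'   file containing no records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- .first_content_line(path)
  if (is.null(first)) {
    warning("no FASTA records found in ", path)
    return(list())
  }
  if (!startsWith(first$line, ">"))
    stop(sprintf("malformed FASTA '%s': sequence data before any '>' header at line %d",
                 path, first$number))
  # readDNAStringSet silently drops letters outside its alphabet (with a
  # warning); escalate that to a parse error naming the offending line.
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
             error = function(e) .fasta_diagnose(path, conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        .fasta_diagnose(path, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) {
    warning("no FASTA records found in ", path)
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  chars <- as.character(set)
  out <- vector("list", length(set))
  for (i in seq_along(out)) {
    # Biostrings admits gap characters ('-', '+', '.') that we do not.
    out[[i]] <- tryCatch(nucleotide_sequence(ids[i], chars[[i]], descs[i]),
                         error = function(e) .fasta_diagnose(path, conditionMessage(e)))
  }
  out
}

#' Write nucleotide sequences to a FASTA file
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output path; `.gz` suffix triggers compression.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s)
    if (nzchar(s$description)) paste(s$id, s$description) else s$id, character(1))
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "bases"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Sequence inclusion policy
#'
#' Cohort analyses of bacterial chromosomes conventionally keep only
#' sequences longer than 50 kbp and drop plasmids; this object captures that
#' policy. Plasmids are recognised by the token "plasmid" (case-insensitive)
#' in the FASTA description, the way complete-genome records label them.
#'
#' @param min_length Minimum length in bp; records must be strictly longer.
#' @param exclude_plasmids Drop records whose description mentions "plasmid".
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_length = 50000L, exclude_plasmids = TRUE) {
  min_length <- as.integer(min_length)
  stopifnot(length(min_length) == 1L, !is.na(min_length), min_length >= 1L,
            is.logical(exclude_plasmids), length(exclude_plasmids) == 1L)
  structure(list(min_length = min_length, exclude_plasmids = exclude_plasmids),
            class = "filter_policy")
}

#' Partition sequences into kept and rejected sets
#'
#' Applies a [filter_policy()]: a record is kept when its length strictly
#' exceeds `min_length` and (if plasmid exclusion is on) its description does
#' not contain "plasmid". Every rejected record carries a machine-readable
#' reason; length is checked before the plasmid test, so a short plasmid is
#' reported as `"too_short"`.
#'
#' @param seqs List of `nuc_seq` records.
#' @param policy A [filter_policy()].
#' @return A list with `kept` (list of `nuc_seq`) and `rejected`
#'   (data.frame with columns `id`, `length`, `reason`; reasons are
#'   `"too_short"` or `"plasmid"`).
#' @export
apply_filters <- function(seqs, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  reasons <- vapply(seqs, function(s) {
    if (s$length <= policy$min_length) return("too_short")
    if (policy$exclude_plasmids && grepl("plasmid", s$description, ignore.case = TRUE))
      return("plasmid")
    ""
  }, character(1))
  keep <- !nzchar(reasons)
  rejected <- data.frame(
    id = vapply(seqs[!keep], `[[`, character(1), "id"),
    length = vapply(seqs[!keep], `[[`, integer(1), "length"),
    reason = reasons[!keep],
    stringsAsFactors = FALSE)
  list(kept = seqs[keep], rejected = rejected)
}

#' Write the rejected-record report as TSV
#'
#' @param rejected The `rejected` data.frame from [apply_filters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
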