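#' Trim the 3' sequencing adapter from reads
#'
#' Locates, in each read, the leftmost position where the adapter begins:
#' either a full occurrence of the adapter, or an adapter prefix running into
#' the end of the read with at least `min_overlap` exactly matching bases.
#' The read is truncated at that position. Reads with no adapter occurrence
#' cannot be delimited (the insert ran past the read length) and are returned
#' as `NA`; reads where the adapter starts at position 1 are adapter dimers
#' and trim to the empty string.
#'
#' @param reads Character vector of read sequences.
#' @param adapter 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap Minimum exact overlap with the adapter prefix at the
#'   read end (default 6).
#' @return Character vector: trimmed insert per read, `NA` where no adapter
#'   occurrence was found.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  adapter <- toupper(adapter)
  if (nchar(adapter) < min_overlap) {
    stop("adapter (", nchar(adapter), " nt) is shorter than the minimum ",
         "overlap of ", min_overlap)
  }
  reads <- toupper(reads)
  # common case: full adapter present in the read
  pos <- regexpr(adapter, reads, fixed = TRUE)
  cut <- ifelse(pos > 0L, as.integer(pos), NA_integer_)
  alen <- nchar(adapter)
  todo <- which(is.na(cut))
  for (i in todo) {
    r <- reads[i]
    rl <- nchar(r)
    # only partial overlaps at the 3' end remain possible
    for (p in seq_len(rl)) {
      ov <- min(alen, rl - p + 1L)
      if (ov < min_overlap) break
      if (substr(r, p, p + ov - 1L) == substr(adapter, 1L, ov)) {
        cut[i] <- p
        break
      }
    }
  }
  ifelse(is.na(cut), NA_character_, substr(reads, 1L, cut - 1L))
}

#' Mean-quality and N-content read filter
#'
#' A read passes when its mean Phred quality is at or above `min_mean_q`
#' (inclusive boundary) and its sequence contains no N. Reads without
#' quality strings (FASTA input) are judged on sequence content alone.
#'
#' @param sequences Character vector of read sequences.
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   aligned with `sequences` (may be `NULL` for FASTA input).
#' @param min_mean_q Minimum mean Phred score, default 20.
#' @return Logical pass/fail vector.
#' @export
quality_filter <- function(sequences, qualities = NULL, min_mean_q = 20) {
  pass <- !grepl("N", sequences, fixed = TRUE)
  if (!is.null(qualities)) {
    stopifnot(length(qualities) == length(sequences))
    meanq <- vapply(qualities, function(q) {
      if (nchar(q) == 0L) return(0)
      mean(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    pass <- pass & meanq >= min_mean_q
  }
  pass
}

#' Collapse trimmed reads into unique (sequence, length) species
#'
#' Reads outside the `[min_len, max_len]` window are discarded (and counted);
#' identical sequences are merged with summed counts. The retained read total
#' is the reads-per-million denominator, so RPM values always sum to 10^6
#' over the read set.
#'
#' @param sequences Character vector of trimmed, filtered read sequences.
#' @param sample_id Sample identifier.
#' @param species Species tag.
#' @param min_len,max_len Length window, default 8-30 nt.
#' @return An object of class `read_set`: list with `sample_id`, `species`,
#'   `reads` (data.frame `sequence`, `length`, `count`, `rpm`, ordered by
#'   length then sequence), `total_clean_reads`, and a `discarded` length-2
#'   vector (`short`, `long`).
#' @export
collapse_reads <- function(sequences, sample_id = "sample", species = "NA",
                           min_len = 8L, max_len = 30L) {
  len <- nchar(sequences)
  keep <- len >= min_len & len <= max_len
  discarded <- c(short = sum(len < min_len), long = sum(len > max_len))
  sequences <- sequences[keep]
  if (length(sequences) == 0L) {
    stop("no reads in the ", min_len, "-", max_len, " nt window")
  }
  counts <- table(sequences)
  total <- sum(counts)
  reads <- data.frame(
    sequence = names(counts),
    length = nchar(names(counts)),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  reads$rpm <- reads$count / total * 1e6
  reads <- reads[order(reads$length, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  structure(
    list(sample_id = sample_id, species = species, reads = reads,
         total_clean_reads = as.integer(total), discarded = discarded),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$sample_id, "' (", x$species, "): ",
      nrow(x$reads), " unique reads, ", x$total_clean_reads,
      " clean reads\n", sep = "")
  invisible(x)
}

read_fastx <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(sequences = as.character(x),
         qualities = as.character(S4Vectors::mcols(x)$qualities),
         format = "fastq")
  } else {
    x <- Biostrings::readBStringSet(path)
    list(sequences = chartr("U", "T", toupper(as.character(x))),
         qualities = NULL, format = "fasta")
  }
}

#' Ingest a FASTQ/FASTA file into a collapsed read set
#'
#' Full ingest stage: parse, quality-filter (FASTQ only), trim the 3'
#' adapter (FASTQ/raw input; FASTA input is taken as pre-trimmed), discard
#' undelimited reads and adapter dimers, and collapse into unique reads.
#' Per-stage read counts are attached as the `"log"` attribute.
#'
#' @param path Input FASTQ (Phred+33) or FASTA file.
#' @param adapter 3' adapter; `NULL` skips trimming (pre-trimmed input).
#' @param sample_id,species Identifiers carried into the read set.
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`.
#' @param min_mean_q Quality threshold for [quality_filter()].
#' @param min_len,max_len Collapsing window, default 8-30.
#' @return A `read_set` (see [collapse_reads()]).
#' @export
ingest_reads <- function(path, adapter = NULL, sample_id = "sample",
                         species = "NA", format = "auto", min_mean_q = 20,
                         min_len = 8L, max_len = 30L) {
  fx <- read_fastx(path, format)
  n_in <- length(fx$sequences)
  pass <- quality_filter(fx$sequences, fx$qualities, min_mean_q)
  seqs <- fx$sequences[pass]
  n_dimer <- 0L
  n_undelimited <- 0L
  if (!is.null(adapter)) {
    trimmed <- trim_adapter(seqs, adapter)
    n_undelimited <- sum(is.na(trimmed))
    trimmed <- trimmed[!is.na(trimmed)]
    n_dimer <- sum(nchar(trimmed) == 0L)
    seqs <- trimmed[nchar(trimmed) > 0L]
  }
  rs <- collapse_reads(seqs, sample_id = sample_id, species = species,
                       min_len = min_len, max_len = max_len)
  attr(rs, "log") <- c(
    input = n_in, failed_quality = n_in - sum(pass),
    no_adapter = n_undelimited, adapter_dimer = n_dimer,
    too_short = unname(rs$discarded["short"]),
    too_long = unname(rs$discarded["long"]),
    clean = rs$total_clean_reads
  )
  rs
}

#' Write a collapsed read table as TSV
#'
#' @param rs A `read_set`.
#' @param path Output TSV path.
#' @param header_comment Optional comment lines (without `#`) written first.
#' @export
write_read_set_tsv <- function(rs, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(rs$reads, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export unique reads as count-encoded FASTA
#'
#' Headers follow the collapsed-read dialect `>seq<i>_x<count>`.
#'
#' @param rs A `read_set`.
#' @param path Output FASTA path.
#' @export
write_unique_fasta <- function(rs, path) {
  headers <- sprintf(">seq%d_x%d", seq_len(nrow(rs$reads)), rs$reads$count)
  writeLines(as.vector(rbind(headers, rs$reads$sequence)), path)
  invisible(path)
}
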