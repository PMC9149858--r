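#' Recognized biotype classes for reference sets
#'
#' Ordered vocabulary of the reference biotypes the classifier can search.
#' `miRNA_precursor` and `miRNA_mature` are kept separate because a read can
#' fall inside a precursor without touching the mature sequence.
#'
#' @return Character vector of the seven biotype names.
#' @export
biotype_levels <- function() {
  c("rRNA", "tRNA", "snoRNA", "miRNA_precursor", "miRNA_mature",
    "piRNA", "other_ncRNA")
}

# Query length window supported by the index; matches the sequencing window.
QUERY_MIN_LEN <- 8L
QUERY_MAX_LEN <- 30L

#' Load one biotype's reference sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA, uppercases sequences
#' and converts RNA U to DNA T, so all downstream matching runs on the
#' A/C/G/T alphabet. Records containing any other character (N, IUPAC
#' ambiguity codes, gaps) are excluded rather than masked, which keeps
#' Hamming-distance semantics exact; the rejected ids are attached as the
#' `"rejected"` attribute.
#'
#' @param fasta_path Path to a FASTA file.
#' @param biotype One of [biotype_levels()].
#' @param species Free-text species tag carried through to reports.
#' @return A data.frame with columns `ref_id`, `biotype`, `species`,
#'   `sequence`, one row per accepted record, with attribute `rejected`
#'   (data.frame of `ref_id`, `reason`).
#' @export
load_references <- function(fasta_path, biotype, species) {
  biotype <- match.arg(biotype, biotype_levels())
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("reference FASTA is empty: ", fasta_path)
  }
  # FASTA headers may carry descriptions after the id token
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated reference id(s) in ", fasta_path, ": ",
         paste(dup, collapse = ", "))
  }
  raw <- toupper(as.character(seqs))
  dna <- chartr("U", "T", raw)
  ok <- !grepl("[^ACGT]", dna) & nchar(dna) > 0L
  rejected <- data.frame(
    ref_id = ids[!ok],
    reason = rep("non-ACGTU character or empty sequence", sum(!ok)),
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    ref_id = ids[ok],
    biotype = biotype,
    species = species,
    sequence = unname(dna[ok]),
    stringsAsFactors = FALSE
  )
  attr(records, "rejected") <- rejected
  records
}

#' Build an indexed reference database
#'
#' Combines per-biotype reference records into a database object answering
#' substring queries of length 8-30 with at most `m_max` substitutions.
#' Matching is delegated to `Biostrings`; every hit is re-verified by direct
#' Hamming comparison at the reported offset.
#'
#' @param records A data.frame of reference records (rbind of
#'   [load_references()] outputs, or an equivalent data.frame with columns
#'   `ref_id`, `biotype`, `species`, `sequence`).
#' @param m_max Maximum substitution capacity of the index (default 1).
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(records, m_max = 1L) {
  stopifnot(is.data.frame(records),
            all(c("ref_id", "biotype", "species", "sequence") %in%
                  names(records)))
  if (nrow(records) == 0L) stop("no reference records supplied")
  if (any(grepl("[^ACGT]", records$sequence))) {
    stop("reference sequences must be over A/C/G/T (load_references() ",
         "normalizes and filters)")
  }
  bad <- !records$biotype %in% biotype_levels()
  if (any(bad)) {
    stop("unknown biotype(s): ", paste(unique(records$biotype[bad]),
                                       collapse = ", "))
  }
  key <- paste(records$species, records$biotype, records$ref_id)
  if (anyDuplicated(key)) {
    stop("duplicated (species, biotype, ref_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  # deterministic record order: biotype vocabulary order, then ref_id
  ord <- order(match(records$biotype, biotype_levels()), records$ref_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  subjects <- lapply(split(records, records$biotype), function(df) {
    s <- Biostrings::DNAStringSet(df$sequence)
    names(s) <- df$ref_id
    s
  })
  structure(
    list(records = records, subjects = subjects, m_max = as.integer(m_max)),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  tab <- table(x$records$biotype)
  cat("reference_db:", nrow(x$records), "records, m_max =", x$m_max, "\n")
  for (b in names(tab)) cat("  ", b, ": ", tab[[b]], "\n", sep = "")
  invisible(x)
}

hamming <- function(a, b) {
  # both A/C/G/T strings of equal length
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Find all reference occurrences of a short query
#'
#' Returns every (reference, offset) pair where the query matches the sense
#' strand of a reference with at most `m` substitutions (no gaps, no
#' reverse-complement search), together with the exact mismatch count.
#' Hits are ordered by biotype priority rank, then `ref_id`, then start.
#'
#' @param db A [reference_db()].
#' @param seq Query sequence, 8-30 nt over A/C/G/T (U accepted, converted).
#' @param m Substitution budget, 0 or 1 (must not exceed `db$m_max`).
#' @param biotypes Optional subset of biotypes to search (in the order
#'   given); defaults to all biotypes present, in [biotype_levels()] order.
#' @return A data.frame with columns `ref_id`, `biotype`, `start`, `end`
#'   (0-based half-open on the parent), `mismatches`.
#' @export
query_db <- function(db, seq, m = 0L, biotypes = NULL) {
  stopifnot(inherits(db, "reference_db"))
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n < QUERY_MIN_LEN || n > QUERY_MAX_LEN) {
    stop("query length ", n, " outside the supported ", QUERY_MIN_LEN, "-",
         QUERY_MAX_LEN, " nt window")
  }
  if (m > db$m_max) stop("m = ", m, " exceeds index capacity m_max = ", db$m_max)
  if (grepl("[^ACGT]", seq)) stop("query contains non-ACGT characters")
  if (is.null(biotypes)) {
    biotypes <- intersect(biotype_levels(), names(db$subjects))
  }
  out <- vector("list", length(biotypes))
  pat <- Biostrings::DNAString(seq)
  for (i in seq_along(biotypes)) {
    subj <- db$subjects[[biotypes[i]]]
    if (is.null(subj)) next
    mi <- Biostrings::vmatchPattern(pat, subj, max.mismatch = m, fixed = TRUE)
    starts <- Biostrings::startIndex(mi)
    hits <- which(lengths(starts) > 0L)
    if (length(hits) == 0L) next
    rows <- lapply(hits, function(j) {
      st <- starts[[j]]
      parent <- as.character(subj[[j]])
      mm <- vapply(st, function(s) {
        hamming(substr(parent, s, s + n - 1L), seq)
      }, integer(1))
      keep <- mm <= m  # guard against any edge-effect matches
      data.frame(
        ref_id = names(subj)[j],
        biotype = biotypes[i],
        start = st[keep] - 1L,
        end = st[keep] - 1L + n,
        mismatches = mm[keep],
        stringsAsFactors = FALSE
      )
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    return(data.frame(ref_id = character(), biotype = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- res[order(match(res$biotype, biotypes), res$ref_id, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
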