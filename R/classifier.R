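#' Biotype call classes emitted by the classifier
#'
#' @return Character vector of the possible calls, including `undefined`.
#' @export
call_levels <- function() {
  c("miRNA", "miRNA_fragment", "piRNA", "piRF", "sdRNA", "tRF", "rRF",
    "other_sncRNA", "undefined")
}

#' Prioritized two-pass classification policy
#'
#' Defines the order in which the per-biotype references are searched
#' (first match wins) and the two mismatch passes: an exact pass over all
#' biotypes, then a one-substitution rescue pass for reads still
#' unassigned. Many annotated piRNAs are themselves derived from tRNA or
#' rRNA genes, so rRNA and tRNA must precede piRNA in the order; this
#' constraint is validated.
#'
#' @param order Biotype search order; each of [biotype_levels()] at most
#'   once.
#' @param m_pass1,m_pass2 Mismatch budgets of the two passes (0 and 1).
#' @return Object of class `priority_policy`.
#' @export
priority_policy <- function(order = c("rRNA", "tRNA", "miRNA_mature",
                                      "miRNA_precursor", "snoRNA", "piRNA",
                                      "other_ncRNA"),
                            m_pass1 = 0L, m_pass2 = 1L) {
  if (anyDuplicated(order)) stop("each biotype may appear once in the order")
  bad <- setdiff(order, biotype_levels())
  if (length(bad)) stop("unknown biotype(s) in order: ",
                        paste(bad, collapse = ", "))
  if ("piRNA" %in% order) {
    pi_rank <- match("piRNA", order)
    for (b in c("rRNA", "tRNA")) {
      if (!b %in% order || match(b, order) > pi_rank) {
        stop(b, " must precede piRNA in the priority order")
      }
    }
  }
  structure(list(order = order, m_pass1 = as.integer(m_pass1),
                 m_pass2 = as.integer(m_pass2)),
            class = "priority_policy")
}

#' Positional origin label of a fragment on its parent
#'
#' Labels a hit interval relative to the parent ends, with a tolerance of
#' `tol` nucleotides: fragments missing up to `tol` leading bases still
#' count as 5' end (dominant sdRNAs are reported e.g. as the snoRNA 5' end
#' "without the 3 first nt"). A fragment within `tol` of both ends is
#' full-length; otherwise 5' end, 3' end, or middle.
#'
#' @param start,end 0-based half-open interval on the parent.
#' @param parent_len Parent sequence length.
#' @param tol End tolerance in nt, default 3.
#' @return One of `"five_prime"`, `"three_prime"`, `"middle"`,
#'   `"full_length"`.
#' @export
origin_label <- function(start, end, parent_len, tol = 3L) {
  if (!(start >= 0L && start < end && end <= parent_len)) {
    stop("invalid coordinates: start=", start, " end=", end,
         " parent_len=", parent_len)
  }
  if (tol < 0L) stop("tol must be >= 0")
  at5 <- start <= tol
  at3 <- (parent_len - end) <= tol
  if (at5 && at3) "full_length"
  else if (at5) "five_prime"
  else if (at3) "three_prime"
  else "middle"
}

# map the winning biotype + hit geometry to the reported call class
call_from_hit <- function(seq, biotype, start, end, parent_len) {
  n <- nchar(seq)
  switch(biotype,
    rRNA = "rRF",
    tRNA = "tRF",
    snoRNA = "sdRNA",
    other_ncRNA = "other_sncRNA",
    piRNA = if (start == 0L && end == parent_len) "piRNA" else "piRF",
    miRNA_mature = if (n >= 16L && start <= 2L && (parent_len - end) <= 2L)
      "miRNA" else "miRNA_fragment",
    miRNA_precursor = "miRNA_fragment",
    stop("unhandled biotype: ", biotype)
  )
}

#' Classify one unique read
#'
#' Two-pass prioritized search: pass 1 walks the policy's biotype order at
#' zero mismatches and the first biotype with a hit determines the call;
#' pass 2 repeats at one substitution for reads still unassigned; anything
#' left is `undefined` (a value, not an error). Within the winning biotype
#' the selected hit is the first in (ref_id, start) order; the number of
#' competing hits is reported in `n_hits` so multi-parent ambiguity can be
#' audited.
#'
#' @param seq Read sequence (8-30 nt).
#' @param db A [reference_db()].
#' @param policy A [priority_policy()].
#' @param tol End tolerance for [origin_label()].
#' @return One-row data.frame: `sequence`, `call`, `parent_id`, `start`,
#'   `end`, `mismatches`, `origin`, `n_hits` (NA fields for `undefined`).
#' @export
classify_read <- function(seq, db, policy = priority_policy(), tol = 3L) {
  seq <- chartr("U", "T", toupper(seq))
  for (m in unique(c(policy$m_pass1, policy$m_pass2))) {
    for (b in policy$order) {
      if (!b %in% names(db$subjects)) next
      hits <- query_db(db, seq, m = m, biotypes = b)
      if (nrow(hits) == 0L) next
      h <- hits[1L, ]
      subj <- db$subjects[[b]]
      parent_len <- Biostrings::width(subj)[match(h$ref_id, names(subj))]
      return(data.frame(
        sequence = seq,
        call = call_from_hit(seq, b, h$start, h$end, parent_len),
        parent_id = h$ref_id, start = h$start, end = h$end,
        mismatches = h$mismatches,
        origin = origin_label(h$start, h$end, parent_len, tol),
        n_hits = nrow(hits), stringsAsFactors = FALSE
      ))
    }
  }
  data.frame(sequence = seq, call = "undefined", parent_id = NA_character_,
             start = NA_integer_, end = NA_integer_,
             mismatches = NA_integer_, origin = NA_character_,
             n_hits = 0L, stringsAsFactors = FALSE)
}

#' Classify every unique read of a read set
#'
#' Applies [classify_read()] to each unique read, carrying count and RPM
#' through for downstream profiling. Deterministic: the annotation order
#' follows the read set's (length, sequence) order and repeated runs give
#' identical tables.
#'
#' @param rs A `read_set` (or a data.frame with columns `sequence`,
#'   `length`, `count`, `rpm`).
#' @param db A [reference_db()].
#' @param policy A [priority_policy()].
#' @param tol End tolerance for [origin_label()].
#' @return data.frame: `sequence`, `length`, `count`, `rpm`, `call`,
#'   `parent_id`, `start`, `end`, `mismatches`, `origin`, `n_hits`.
#' @export
classify_set <- function(rs, db, policy = priority_policy(), tol = 3L) {
  reads <- if (inherits(rs, "read_set")) rs$reads else rs
  ann <- lapply(reads$sequence, classify_read, db = db, policy = policy,
                tol = tol)
  ann <- do.call(rbind, ann)
  out <- cbind(reads[, c("sequence", "length", "count", "rpm")],
               ann[, setdiff(names(ann), "sequence")])
  rownames(out) <- NULL
  out
}

#' Write an annotation table as TSV
#'
#' @param ann Output of [classify_set()].
#' @param path Output path.
#' @param header_comment Optional comment lines (without `#`).
#' @export
write_annotation_tsv <- function(ann, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(ann, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
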