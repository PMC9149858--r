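# Brute-force oracles and tiny fixture builders, independent of the
# package's index/classifier code paths.

oracle_hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# all-offsets Hamming scan over every reference; same column/order contract
# as query_db()
oracle_query <- function(records, seq, m,
                         biotype_order = sRNAtlas::biotype_levels()) {
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(nrow(records))) {
    parent <- records$sequence[i]
    L <- nchar(parent)
    if (L < n) next
    for (s in 0:(L - n)) {
      d <- oracle_hamming(substr(parent, s + 1L, s + n), seq)
      if (d <= m) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = records$ref_id[i], biotype = records$biotype[i],
          start = s, end = s + n, mismatches = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_id = character(), biotype = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$biotype, biotype_order), res$ref_id,
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force two-pass priority classification: exact pass over the order,
# then a 1-mismatch pass; first hit of the winning biotype in (ref_id,
# start) order; returns the call class only
oracle_classify <- function(records, seq, order) {
  for (m in c(0L, 1L)) {
    for (b in order) {
      sub <- records[records$biotype == b, , drop = FALSE]
      if (nrow(sub) == 0L) next
      hits <- oracle_query(sub, seq, m)
      if (nrow(hits) == 0L) next
      h <- hits[1L, ]
      plen <- nchar(sub$sequence[match(h$ref_id, sub$ref_id)])
      n <- nchar(seq)
      call <- switch(b,
        rRNA = "rRF", tRNA = "tRF", snoRNA = "sdRNA",
        other_ncRNA = "other_sncRNA",
        piRNA = if (h$start == 0L && h$end == plen) "piRNA" else "piRF",
        miRNA_mature = if (n >= 16L && h$start <= 2L &&
                             (plen - h$end) <= 2L) "miRNA"
                       else "miRNA_fragment",
        miRNA_precursor = "miRNA_fragment")
      return(call)
    }
  }
  "undefined"
}

# exhaustive 1-D k-means: enumerate contiguous partitions of the sorted
# values (the 1-D optimum is contiguous) and take the minimum total
# within-cluster sum of squares
oracle_kmeans1d_obj <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, j], n)
    tot <- 0
    for (q in seq_len(k)) tot <- tot + ss(xs[(b[q] + 1L):b[q + 1L]])
    if (tot < best) best <- tot
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small random reference table spanning several biotypes
random_records <- function(n_per_biotype = 1L, len = 200L,
                           biotypes = c("rRNA", "tRNA", "piRNA")) {
  recs <- list()
  for (b in biotypes) {
    for (i in seq_len(n_per_biotype)) {
      recs[[length(recs) + 1L]] <- data.frame(
        ref_id = paste0(b, "-", i), biotype = b, species = "test",
        sequence = random_dna_str(len), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

# mutate one random position of a DNA string
mutate1 <- function(seq) {
  p <- sample.int(nchar(seq), 1L)
  ch <- strsplit(seq, "")[[1]]
  ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# expected call implied by a simulation truth row (intended biotype plus
# hit geometry), for truth-table comparisons
expected_call_from_truth <- function(biotype, start, end, parent_len, len) {
  switch(biotype,
    rRNA = "rRF", tRNA = "tRF", snoRNA = "sdRNA",
    other_ncRNA = "other_sncRNA",
    piRNA = if (start == 0L && end == parent_len) "piRNA" else "piRF",
    miRNA_mature = if (len >= 16L && start <= 2L &&
                         (parent_len - end) <= 2L) "miRNA"
                   else "miRNA_fragment",
    miRNA_precursor = "miRNA_fragment")
}

write_tmp_fasta <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
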