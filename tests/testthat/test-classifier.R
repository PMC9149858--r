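# fixed references used across classifier tests
make_fixture_db <- function() {
  set.seed(101)
  trna <- paste0("GCATTGGTGGTTCAGTGG", random_dna_str(58))   # 76 nt
  rrna <- random_dna_str(160)
  substr(rrna, 61, 79) <- "CTCGTACGACTCTTAGCGG"
  mirna <- "TGAGGTAGTAGGTTGTATAGTT"                           # 22 nt mature
  pirna_trna <- "GCATTGGTGGTTCAGTGG"   # piRNA entry equal to the tRNA 5' end
  pirna <- random_dna_str(28)
  snorna <- paste0("TCGCTATGATGA", random_dna_str(60))
  reference_db(data.frame(
    ref_id = c("tRNA-Gly-GCC-3-1", "rRNA-5.8S", "let-7-like",
               "piR-trna-derived", "piR-full", "SNORD-like"),
    biotype = c("tRNA", "rRNA", "miRNA_mature", "piRNA", "piRNA", "snoRNA"),
    species = "test",
    sequence = c(trna, rrna, mirna, pirna_trna, pirna, snorna),
    stringsAsFactors = FALSE
  ))
}

test_that("the priority order must keep rRNA and tRNA before piRNA", {
  expect_s3_class(priority_policy(), "priority_policy")
  expect_error(priority_policy(c("piRNA", "rRNA", "tRNA")), "precede")
  expect_error(priority_policy(c("rRNA", "piRNA", "snoRNA")), "precede")
  expect_error(priority_policy(c("rRNA", "rRNA", "tRNA", "piRNA")), "once")
})

test_that("a tRNA/piRNA dual-membership sequence is called tRF, never piRNA", {
  db <- make_fixture_db()
  ann <- classify_read("GCATTGGTGGTTCAGTGG", db)
  expect_equal(ann$call, "tRF")
  expect_equal(ann$parent_id, "tRNA-Gly-GCC-3-1")
  expect_equal(ann$origin, "five_prime")
  expect_equal(ann$mismatches, 0L)
})

test_that("reads matching no reference at one mismatch are undefined", {
  db <- make_fixture_db()
  ann <- classify_read(strrep("AT", 12), db)
  expect_equal(ann$call, "undefined")
  expect_true(is.na(ann$parent_id))
  expect_equal(ann$n_hits, 0L)
})

test_that("full-length mature miRNA reads are miRNA; their short 5' sub-reads are fragments", {
  db <- make_fixture_db()
  full <- classify_read("TGAGGTAGTAGGTTGTATAGTT", db)
  expect_equal(full$call, "miRNA")
  expect_equal(full$origin, "full_length")
  semi <- classify_read(substr("TGAGGTAGTAGGTTGTATAGTT", 1, 12), db)
  expect_equal(semi$call, "miRNA_fragment")
  # 20-nt read one base in from each terminus still counts as the mature form
  iso <- classify_read(substr("TGAGGTAGTAGGTTGTATAGTT", 2, 21), db)
  expect_equal(iso$call, "miRNA")
})

test_that("piRNA calls split into full-entry piRNA versus fragment piRF", {
  db <- make_fixture_db()
  pir <- as.character(db$subjects[["piRNA"]][["piR-full"]])
  expect_equal(classify_read(pir, db)$call, "piRNA")
  expect_equal(classify_read(substr(pir, 3, 20), db)$call, "piRF")
})

test_that("one-mismatch hits only rescue reads with no exact hit anywhere", {
  db <- make_fixture_db()
  core <- "GACTCTTAGCGG"
  mm <- core
  substr(mm, 5, 5) <- if (substr(mm, 5, 5) == "A") "C" else "A"
  ann <- classify_read(mm, db)
  expect_equal(ann$call, "rRF")
  expect_equal(ann$mismatches, 1L)
})

test_that("an exact low-priority hit beats a 1-mismatch high-priority hit", {
  # pass 1 completes over all biotypes before pass 2 begins
  set.seed(55)
  probe <- "ACGTTACGGATCCA"
  probe_mut <- mutate1(probe)
  recs <- data.frame(
    ref_id = c("rrna-x", "other-x"),
    biotype = c("rRNA", "other_ncRNA"), species = "t",
    sequence = c(paste0(random_dna_str(40), probe_mut, random_dna_str(40)),
                 paste0(random_dna_str(30), probe, random_dna_str(30))),
    stringsAsFactors = FALSE)
  db <- reference_db(recs)
  ann <- classify_read(probe, db)
  expect_equal(ann$call, "other_sncRNA")
  expect_equal(ann$mismatches, 0L)
})

test_that("origin labels follow the end-tolerance rule", {
  expect_equal(origin_label(0, 17, 72, 3), "five_prime")
  expect_equal(origin_label(3, 20, 72, 3), "five_prime")  # without 3 first nt
  expect_equal(origin_label(0, 72, 72, 3), "full_length")
  expect_equal(origin_label(30, 42, 130, 3), "middle")
  expect_equal(origin_label(55, 72, 72, 3), "three_prime")
  expect_error(origin_label(10, 5, 72, 3), "invalid")
  expect_error(origin_label(0, 80, 72, 3), "invalid")
})

test_that("classify_read agrees with the brute-force two-pass oracle", {
  set.seed(202)
  n_reads <- 500L
  recs <- random_records(n_per_biotype = 1L, len = 100L,
                         biotypes = c("rRNA", "tRNA", "miRNA_mature",
                                      "snoRNA", "piRNA", "other_ncRNA"))
  db <- reference_db(recs)
  order <- priority_policy()$order
  for (i in seq_len(n_reads)) {
    qlen <- sample(8:30, 1L)
    q <- if (i %% 3L == 0L) random_dna_str(qlen) else {
      src <- recs$sequence[sample.int(nrow(recs), 1L)]
      s <- sample.int(nchar(src) - qlen + 1L, 1L)
      frag <- substr(src, s, s + qlen - 1L)
      if (i %% 2L == 0L) mutate1(frag) else frag
    }
    expect_equal(classify_read(q, db)$call, oracle_classify(recs, q, order),
                 info = q)
  }
})

test_that("classify_set is total, unique and order-independent", {
  db <- make_fixture_db()
  set.seed(77)
  seqs <- c("GCATTGGTGGTTCAGTGG", "GACTCTTAGCGG",
            replicate(20, random_dna_str(sample(8:30, 1))))
  seqs <- unique(seqs)
  rs <- collapse_reads(sample(rep(seqs, times = sample(1:5, length(seqs),
                                                       replace = TRUE))))
  ann <- classify_set(rs, db)
  expect_equal(nrow(ann), nrow(rs$reads))          # exactly one call each
  expect_true(all(ann$call %in% call_levels()))
  expect_identical(is.na(ann$parent_id), ann$call == "undefined")
  # a permuted read set gives the identical multiset of annotations
  rs2 <- rs
  rs2$reads <- rs2$reads[rev(seq_len(nrow(rs2$reads))), ]
  ann2 <- classify_set(rs2, db)
  expect_equal(ann2[order(ann2$sequence), ], ann[order(ann$sequence), ],
               ignore_attr = TRUE)
})
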