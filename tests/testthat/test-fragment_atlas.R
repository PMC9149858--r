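family4 <- c("GACTCTTAGCGG", "CGACTCTTAGCGG", "TCGTACGACTCTTAGCGG",
             "CTCGTACGACTCTTAGCGG")

test_that("nested fragments collapse into one group seeded by the shortest member", {
  g <- group_by_seed(family4)
  expect_length(g, 1L)
  expect_equal(g[[1]]$seed, "GACTCTTAGCGG")
  expect_equal(nchar(g[[1]]$seed), 12L)
  expect_equal(nrow(g[[1]]$members), 4L)
})

test_that("extensions report the exact 5' flanks of the nested family", {
  g <- group_by_seed(family4)
  ext <- extensions(g[[1]])
  get <- function(s, col) ext[[col]][ext$sequence == s]
  expect_equal(get("CGACTCTTAGCGG", "ext5"), "C")
  expect_equal(get("CGACTCTTAGCGG", "ext5_len"), 1L)
  expect_equal(get("TCGTACGACTCTTAGCGG", "ext5"), "TCGTAC")
  expect_equal(get("TCGTACGACTCTTAGCGG", "ext5_len"), 6L)
  expect_equal(get("CTCGTACGACTCTTAGCGG", "ext5"), "CTCGTAC")
  expect_true(all(ext$ext3 == ""))
  expect_equal(get("GACTCTTAGCGG", "ext5"), "")
})

test_that("a two-member family with a 1-nt 5' extension groups on the shorter sequence", {
  g <- group_by_seed(c("ACTCTAAGCGG", "AACTCTAAGCGG"))
  expect_length(g, 1L)
  expect_equal(g[[1]]$seed, "ACTCTAAGCGG")
  expect_equal(extensions(g[[1]])$ext5, c("", "A"))
})

test_that("singletons form their own group with empty extensions", {
  g <- group_by_seed(c("ACGTACGTACGT"))
  expect_length(g, 1L)
  ext <- extensions(g[[1]])
  expect_equal(ext$ext5, "")
  expect_equal(ext$ext3, "")
})

test_that("members reconstruct as ext5 + seed + ext3 and grouping is order-invariant", {
  set.seed(12)
  seqs <- unique(c(family4, "ACTCTAAGCGG", "AACTCTAAGCGG",
                   replicate(15, random_dna_str(sample(8:30, 1)))))
  g <- group_by_seed(seqs)
  for (grp in g) {
    m <- grp$members
    expect_equal(paste0(m$ext5, grp$seed, m$ext3), m$sequence)
    expect_true(all(vapply(m$sequence, grepl, logical(1),
                           pattern = grp$seed, fixed = TRUE)))
  }
  g2 <- group_by_seed(rev(seqs))
  norm <- function(x) lapply(x, function(grp) {
    grp$members <- grp$members[order(grp$members$sequence), ]
    rownames(grp$members) <- NULL
    grp[c("seed", "members")]
  })
  seeds <- vapply(g, function(grp) grp$seed, character(1))
  seeds2 <- vapply(g2, function(grp) grp$seed, character(1))
  expect_equal(norm(g)[order(seeds)], norm(g2)[order(seeds2)])
  expect_error(group_by_seed(c("AA", "AA")), "unique")
})

test_that("leftmost anchoring is used when the seed repeats in a member", {
  g <- group_by_seed(c("ACGTACGT", "ACGTACGTACGTACGT"))
  expect_equal(g[[1]]$seed, "ACGTACGT")
  m <- g[[1]]$members
  expect_equal(m$ext5[m$length == 16], "")
  expect_equal(m$ext3[m$length == 16], "ACGTACGT")
  expect_equal(m$seed_multiplicity[m$length == 16], 2L)
})

test_that("staircase flags only counts above the outlier factor times the median", {
  g <- group_by_seed(c("ACGTACGTACGTACGT", "CGTACGTACGTACGT",
                       "GTACGTACGTACGT", "TACGTACGTACGT", "ACGTACGTACGT"),
                     counts = c(1000L, 8L, 6L, 5L, 3L))
  st <- staircase(g[[1]], outlier_factor = 10)
  expect_equal(st$members$outlier,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(st$median_count, 6)
  expect_equal(st$direction, "5'->3'")  # all members are suffixes
  expect_error(staircase(g[[1]], outlier_factor = 1), "factor")
})

test_that("a clean geometric ladder has no outliers at factor 10", {
  parent <- "TCAGGACTACGGTTACCGGATCAATCGGAT"
  lens <- 18:12
  seqs <- substring(parent, 31 - lens, 30)    # 3'-anchored, 5' recedes
  counts <- as.integer(round(1000 * 0.5^(18 - lens)))
  g <- group_by_seed(seqs, counts = counts)
  expect_length(g, 1L)
  st <- staircase(g[[1]], outlier_factor = 10)
  expect_false(any(st$members$outlier))
  expect_equal(st$direction, "5'->3'")
  # 3'-truncation ladder points the other way
  seqs3 <- substring(parent, 1, lens)
  g3 <- group_by_seed(seqs3, counts = counts)
  expect_equal(staircase(g3[[1]], 10)$direction, "3'->5'")
})

test_that("the dominant shared 3'-terminal motif is recovered with its support", {
  mot <- motif_3prime(c("TCGCTATGATGA", "AGATATGATGA", "CGCTGTGATGA"))
  expect_equal(mot$motif, "ATGA")
  expect_equal(mot$support, 1.0)
  # all-distinct terminal 4-mers: support 1/n, lexicographic tie-break
  mot2 <- motif_3prime(c("ACGTACGATTTT", "ACGTACGACCCC", "ACGTACGAGGGG"))
  expect_equal(mot2$support, 1 / 3)
  expect_equal(mot2$motif, "CCCC")
  expect_error(motif_3prime(c("ACGTACGT", "ACG")), "shortest")
  expect_error(motif_3prime("ACGTACGT"), "at least 2")
})

test_that("equal-length variants in different groups surface as near misses", {
  a <- "ACGGATCCATTGCA"
  b <- a; substr(b, 4, 4) <- "T"   # Hamming 1, not a substring of a
  g <- group_by_seed(c(a, b))
  expect_length(g, 2L)
  nm <- near_misses(g)
  expect_equal(nrow(nm), 1L)
  expect_equal(nm$hamming, 1L)
  expect_setequal(c(nm$sequence_a, nm$sequence_b), c(a, b))
})

test_that("the alignment rendering pads members so the seed columns line up", {
  g <- group_by_seed(family4)
  lines <- render_seed_alignment(g[[1]])
  expect_equal(nchar(lines), rep(19L, 4))        # all padded to longest
  expect_true(all(substr(lines, 8, 19) == "GACTCTTAGCGG"))
})
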