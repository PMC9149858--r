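# minimal annotation table builder
ann_table <- function(sequence, count, call = "rRF", parent_id = "p",
                      origin = "five_prime") {
  total <- sum(count)
  data.frame(sequence = sequence, length = nchar(sequence), count = count,
             rpm = count / total * 1e6, call = call, parent_id = parent_id,
             start = 0L, end = nchar(sequence), mismatches = 0L,
             origin = origin, n_hits = 1L, stringsAsFactors = FALSE)
}

test_that("a single-read profile puts all RPM and diversity at its length", {
  ann <- ann_table("GACTCTTAGCGG", 5L)
  p <- length_profile(ann)
  expect_equal(p$total_rpm[p$length == 12], 1e6)
  expect_equal(p$unique_count[p$length == 12], 1L)
  expect_equal(sum(p$total_rpm), 1e6)
  expect_equal(sum(p$unique_count), 1L)
})

test_that("unique counts reflect diversity, not abundance", {
  a1 <- ann_table(c("ACGTACGTACGT", "TTTTCCCCAAAAT"), c(1L, 1L))
  a2 <- ann_table(c("ACGTACGTACGT", "TTTTCCCCAAAAT"), c(90L, 10L))
  expect_equal(length_profile(a1)$unique_count,
               length_profile(a2)$unique_count)
  expect_false(isTRUE(all.equal(length_profile(a1)$total_rpm,
                                length_profile(a2)$total_rpm)))
})

test_that("window shares are computed at the fixed 15|16 boundary and sum to 1", {
  short_only <- ann_table("ACGTACGTACGT", 4L)     # 12 nt
  expect_equal(window_share(length_profile(short_only))$short_share, 1.0)
  both <- ann_table(c("ACGTACGTACGT", "ACGTACGTACGTACGTACGT"), c(5L, 5L))
  ws <- window_share(length_profile(both))
  expect_equal(ws$short_share, 0.5)
  expect_equal(ws$short_share + ws$standard_share, 1.0)
  # 15-nt reads belong to the short window, 16-nt reads do not
  edge <- ann_table(c("ACGTACGTACGTACG", "ACGTACGTACGTACGT"), c(1L, 3L))
  expect_equal(window_share(length_profile(edge))$short_share, 0.25)
})

test_that("biotype percentages sum to 100 per window and skip empty windows", {
  ann <- rbind(ann_table("ACGTACGTACGT", 3L, call = "rRF"),
               ann_table("TTTTCCCCAAAA", 1L, call = "sdRNA"))
  ann$rpm <- ann$count / sum(ann$count) * 1e6
  bd <- biotype_distribution(ann)
  expect_equal(sum(bd$percent), 100)
  expect_equal(bd$percent[bd$call == "rRF"], 75)
  expect_true(all(bd$window == "8-15"))   # empty standard window: no rows
  expect_false(any(is.nan(bd$percent)))
})

test_that("dominant sequences rank by count with lexicographic ties and exact shares", {
  ann <- ann_table(c("CCCCCCCCCCCC", "AAAAAAAAAAAA", "GGGGGGGGGGGG"),
                   c(5L, 5L, 90L))
  d <- dominant_sequences(ann, 12, top_n = 3)
  expect_equal(d$sequence,
               c("GGGGGGGGGGGG", "AAAAAAAAAAAA", "CCCCCCCCCCCC"))
  expect_equal(d$share_of_length, c(90, 5, 5))
  expect_equal(sum(d$share_of_length), 100)
  one <- dominant_sequences(ann_table("ACGTACGTACGT", 7L), 12, top_n = 1)
  expect_equal(one$share_of_length, 100)
  expect_equal(nrow(dominant_sequences(ann, 20)), 0L)
})

test_that("perfectly separated values split into their natural three clusters", {
  x <- c(0, 0, 10, 10, 20, 20)
  km <- kmeans1d(x, 3)
  expect_equal(km$centers, c(0, 10, 20))
  expect_equal(km$cluster, c(1, 1, 2, 2, 3, 3))
  expect_equal(km$withinss, 0)
})

test_that("1-D k-means matches the exhaustive contiguous-partition optimum", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- round(stats::rnorm(n, sd = 3), 2)
    while (length(unique(x)) < 3) x <- round(stats::rnorm(n, sd = 3), 2)
    km <- kmeans1d(x, 3)
    expect_equal(km$withinss, oracle_kmeans1d_obj(x, 3), tolerance = 1e-9)
    # clusters are contiguous in value order
    ord <- order(x)
    expect_true(all(diff(km$cluster[ord]) >= 0))
  }
})

test_that("abundance clustering masks zeros, labels by center order and flags degenerate biotypes", {
  m <- matrix(c(0, 1e1, 1e1, 1e4, 1e4, 1e6), nrow = 2,
              dimnames = list(c("s1", "s2"), c("12", "13", "14")))
  cl <- abundance_clusters(list(rRF = m), k = 3)
  cells <- cl$rRF$cells
  expect_equal(nrow(cells), 5L)                    # zero cell masked
  expect_false(cl$rRF$flagged)
  expect_equal(cells$cluster[cells$log10_rpm == 6], "high")
  expect_equal(sort(unique(cells$cluster)), c("high", "low", "mid"))
  expect_true(all(diff(cl$rRF$centers) <= 0))      # high >= mid >= low
  # fewer distinct values than k: fewer clusters, flagged
  m2 <- matrix(c(10, 10, 10, 100), nrow = 2)
  cl2 <- abundance_clusters(list(tRF = m2), k = 3)
  expect_true(cl2$tRF$flagged)
  expect_equal(cl2$tRF$k_used, 2L)
  expect_error(abundance_clusters(list(x = matrix(0, 2, 2))), "masked")
})

test_that("peak listing reports the argmax and local maxima without smoothing", {
  ann <- rbind(ann_table("ACGTACGTACGT", 10L),          # 12 nt
               ann_table("ACGTACGTACGTA", 50L),         # 13 nt
               ann_table("ACGTACGTACGTACGTA", 20L))     # 17 nt
  ann$rpm <- ann$count / sum(ann$count) * 1e6
  pk <- profile_peaks(length_profile(ann))
  expect_equal(pk$argmax, 13L)
  expect_equal(pk$local_maxima, c(13L, 17L))
})
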