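#' Length distribution of a read set or annotation table
#'
#' Total RPM and unique-sequence count per read length over the 8-30 nt
#' range. With a biotype filter the profile is restricted to one call class
#' (RPM then no longer sums to 10^6; it keeps the library scale so profiles
#' of different biotypes are comparable, as in per-biotype length heatmaps).
#'
#' @param x A `read_set`, or an annotation/read data.frame with columns
#'   `length`, `rpm`, `sequence` (and `call` when `biotype` is used).
#' @param biotype Optional call class (see [call_levels()]) to restrict to.
#' @param min_len,max_len Profile range, default 8-30.
#' @return data.frame: `length`, `total_rpm`, `unique_count`.
#' @export
length_profile <- function(x, biotype = NULL, min_len = 8L, max_len = 30L) {
  df <- if (inherits(x, "read_set")) x$reads else x
  if (!is.null(biotype)) {
    if (!"call" %in% names(df)) {
      stop("biotype filtering needs an annotated set (classify_set output)")
    }
    df <- df[df$call == biotype, , drop = FALSE]
  }
  lens <- min_len:max_len
  rpm <- vapply(lens, function(l) sum(df$rpm[df$length == l]), numeric(1))
  uc <- vapply(lens, function(l) sum(df$length == l), integer(1))
  data.frame(length = lens, total_rpm = rpm, unique_count = uc)
}

#' Peaks of a length profile
#'
#' The global argmax plus all local maxima of the RPM-by-length curve
#' (no smoothing), for prose like "a major peak at 12 and/or 13 nt".
#'
#' @param profile Output of [length_profile()].
#' @return List with `argmax` (length of the global maximum) and
#'   `local_maxima` (lengths that exceed both neighbours).
#' @export
profile_peaks <- function(profile) {
  y <- profile$total_rpm
  n <- length(y)
  locmax <- profile$length[which(
    y > c(-Inf, y[-n]) & y > c(y[-1], -Inf) & y > 0
  )]
  list(argmax = profile$length[which.max(y)], local_maxima = locmax)
}

#' Share of abundance in the short versus standard length window
#'
#' Fraction of RPM carried by unusually short reads (8 to `split` nt)
#' versus standard-length reads (`split`+1 to 30 nt).
#'
#' @param profile Output of [length_profile()].
#' @param split Last length of the short window, default 15.
#' @return data.frame with one row: `short_share`, `standard_share`.
#' @export
window_share <- function(profile, split = 15L) {
  tot <- sum(profile$total_rpm)
  if (tot == 0) stop("profile carries no abundance")
  short <- sum(profile$total_rpm[profile$length <= split]) / tot
  data.frame(short_share = short, standard_share = 1 - short)
}

#' Per-window biotype composition
#'
#' Percentage of window RPM per call class, separately for the short
#' (8 to `split`) and standard (`split`+1 to 30) windows; `undefined` is a
#' class of its own. Percentages within a window sum to 100; a window with
#' no reads contributes no rows (never NaN).
#'
#' @param ann Annotation table from [classify_set()].
#' @param split Window boundary, default 15.
#' @return data.frame: `window`, `call`, `rpm`, `percent`.
#' @export
biotype_distribution <- function(ann, split = 15L) {
  win <- ifelse(ann$length <= split,
                paste0("8-", split), paste0(split + 1L, "-30"))
  out <- lapply(unique(c(paste0("8-", split), paste0(split + 1L, "-30"))),
                function(w) {
    sub <- ann[win == w, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    rpm <- vapply(split(sub$rpm, sub$call), sum, numeric(1))
    data.frame(window = w, call = names(rpm), rpm = unname(rpm),
               percent = unname(rpm) / sum(rpm) * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(window = character(), call = character(),
                      rpm = numeric(), percent = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Dominant sequences at one read length
#'
#' The `top_n` most abundant sequences of a given length, each with its
#' share of all reads of that length ("% of reads from sequences having the
#' same length") and its origin label. Ties in count break lexicographically
#' on the sequence, so output is deterministic.
#'
#' @param ann Annotation table from [classify_set()].
#' @param length Read length in nt (8-30).
#' @param top_n Number of rows to return, default 3.
#' @return data.frame: `length`, `sequence`, `count`, `rpm`,
#'   `share_of_length` (percent), `origin`, `origin_label`; zero rows when
#'   the length stratum is empty.
#' @export
dominant_sequences <- function(ann, length, top_n = 3L) {
  stopifnot(length >= 8L, length <= 30L)
  sub <- ann[ann$length == length, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(length = integer(), sequence = character(),
                      count = integer(), rpm = numeric(),
                      share_of_length = numeric(), origin = character(),
                      origin_label = character(), stringsAsFactors = FALSE))
  }
  sub <- sub[order(-sub$count, sub$sequence), , drop = FALSE]
  sub <- utils::head(sub, top_n)
  lab <- ifelse(sub$call == "undefined", "undefined",
                paste(c(five_prime = "5' end", three_prime = "3' end",
                        middle = "middle", full_length = "full-length"
                        )[sub$origin],
                      "of", sub$parent_id))
  out <- data.frame(
    length = length, sequence = sub$sequence, count = sub$count,
    rpm = sub$rpm,
    share_of_length = 100 * sub$count / sum(ann$count[ann$length == length]),
    origin = ifelse(is.na(sub$origin), "undefined", sub$origin),
    origin_label = lab, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Exact one-dimensional k-means
#'
#' Globally optimal k-means in one dimension by dynamic programming over
#' contiguous partitions of the sorted values (the 1-D Euclidean optimum is
#' always contiguous in value order). Deterministic; no random
#' initialization.
#'
#' @param x Numeric vector (no NA).
#' @param k Number of clusters, `1 <= k <= length(unique(x))`.
#' @return List: `cluster` (1-based label per element of `x`, labels ordered
#'   by increasing center), `centers` (increasing), `withinss` (total
#'   within-cluster sum of squares).
#' @export
kmeans1d <- function(x, k) {
  stopifnot(is.numeric(x), !anyNA(x), k >= 1L)
  n <- length(x)
  if (k > length(unique(x))) {
    stop("k = ", k, " exceeds the number of distinct values (",
         length(unique(x)), ")")
  }
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # cost of one cluster over sorted positions i..j
  segcost <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, k, n)       # D[q, j]: best cost of first j points in q clusters
  B <- matrix(0L, k, n)        # start index of the last cluster
  for (j in 1:n) {
    D[1L, j] <- segcost(1L, j)
    B[1L, j] <- 1L
  }
  if (k > 1L) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          c_ <- D[q - 1L, i - 1L] + segcost(i, j)
          if (c_ < D[q, j]) {
            D[q, j] <- c_
            B[q, j] <- i
          }
        }
      }
    }
  }
  # backtrack cluster boundaries
  lab_sorted <- integer(n)
  j <- n
  for (q in k:1) {
    i <- B[q, j]
    lab_sorted[i:j] <- q
    j <- i - 1L
  }
  centers <- vapply(1:k, function(q) mean(xs[lab_sorted == q]), numeric(1))
  cluster <- integer(n)
  cluster[ord] <- lab_sorted
  list(cluster = cluster, centers = centers,
       withinss = max(D[k, n], 0))
}

#' Cluster per-biotype length-abundance matrices into high/mid/low
#'
#' For each biotype, takes a (sample x length) RPM matrix, log10-transforms
#' the non-zero cells (zero-RPM cells are masked, the heatmap's "gray
#' boxes", not pseudocounted) and partitions the cell values into k = 3
#' abundance groups by exact 1-D k-means (Euclidean). Clusters are
#' relabelled `high`/`mid`/`low` by decreasing center. When a biotype has
#' fewer distinct non-masked values than `k`, fewer clusters are fitted and
#' the biotype is flagged.
#'
#' @param matrices Named list (by biotype) of numeric matrices of RPM with
#'   samples in rows and lengths in columns (dimnames used in output).
#' @param k Number of abundance groups, default 3.
#' @return Object of class `abundance_clusters`: named list per biotype with
#'   `cells` (data.frame `sample`, `length`, `log10_rpm`, `cluster`),
#'   `centers`, `k_used`, `flagged`.
#' @export
abundance_clusters <- function(matrices, k = 3L) {
  stopifnot(is.list(matrices), length(matrices) > 0L)
  out <- lapply(names(matrices), function(b) {
    m <- matrices[[b]]
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      stop("biotype '", b, "': all cells are zero (masked); nothing to cluster")
    }
    v <- log10(m[idx])
    k_used <- min(k, length(unique(v)))
    km <- kmeans1d(v, k_used)
    # rank 1 = highest center
    rank_by_center <- order(km$centers, decreasing = TRUE)
    label_names <- c("high", "mid", "low")[seq_len(min(k_used, 3L))]
    if (k_used > 3L) label_names <- paste0("c", seq_len(k_used))
    lab <- label_names[match(km$cluster, rank_by_center)]
    cells <- data.frame(
      sample = if (!is.null(rownames(m))) rownames(m)[idx[, 1]] else idx[, 1],
      length = if (!is.null(colnames(m))) as.integer(colnames(m)[idx[, 2]])
               else idx[, 2],
      log10_rpm = v, cluster = lab, stringsAsFactors = FALSE
    )
    list(cells = cells, centers = sort(km$centers, decreasing = TRUE),
         k_used = k_used, flagged = k_used < k)
  })
  names(out) <- names(matrices)
  structure(out, class = "abundance_clusters")
}

#' Assemble the (sample x length) RPM matrix of one biotype
#'
#' @param anns Named list of annotation tables (one per sample).
#' @param biotype Call class to extract.
#' @param min_len,max_len Length range, default 8-30.
#' @return Numeric matrix, samples in rows, lengths in columns.
#' @export
biotype_length_matrix <- function(anns, biotype, min_len = 8L, max_len = 30L) {
  lens <- min_len:max_len
  m <- t(vapply(anns, function(a) {
    p <- length_profile(a, biotype = biotype, min_len = min_len,
                        max_len = max_len)
    p$total_rpm
  }, numeric(length(lens))))
  colnames(m) <- lens
  m
}
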