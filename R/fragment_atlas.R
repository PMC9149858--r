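#' Group fragment sequences on a minimal common seed
#'
#' Deterministic substring-containment grouping: unique sequences are
#' sorted ascending by (length, lexicographic); each still-unclaimed
#' sequence founds a group with itself as the seed and claims every
#' unclaimed longer sequence that contains the seed as a contiguous
#' substring. Members are then aligned on the leftmost seed occurrence to
#' expose their 5' and 3' extensions. A sequence claimed by no earlier seed
#' forms a singleton group. Transitive chaining through non-substring
#' overlap is deliberately not performed: a sequence joins a group only if
#' it contains the seed itself.
#'
#' @param sequences Character vector of unique fragment sequences.
#' @param counts Optional integer counts aligned with `sequences`.
#' @param rpm Optional RPM values aligned with `sequences`.
#' @return Object of class `seed_groups`: list of groups, each a list with
#'   `group_id`, `seed`, and `members` — a data.frame `sequence`, `length`,
#'   `count`, `rpm`, `ext5`, `ext3`, `seed_multiplicity`, ordered by
#'   (length, sequence).
#' @export
group_by_seed <- function(sequences, counts = NULL, rpm = NULL) {
  if (anyDuplicated(sequences)) stop("sequences must be unique")
  n <- length(sequences)
  if (n == 0L) return(structure(list(), class = "seed_groups"))
  if (is.null(counts)) counts <- rep(NA_integer_, n)
  if (is.null(rpm)) rpm <- rep(NA_real_, n)
  ord <- order(nchar(sequences), sequences)
  sequences <- sequences[ord]; counts <- counts[ord]; rpm <- rpm[ord]
  claimed <- logical(n)
  groups <- list()
  for (i in seq_len(n)) {
    if (claimed[i]) next
    seed <- sequences[i]
    member_idx <- i
    if (i < n) {
      cand <- (i + 1L):n
      cand <- cand[!claimed[cand]]
      hit <- cand[grepl(seed, sequences[cand], fixed = TRUE)]
      member_idx <- c(member_idx, hit)
    }
    claimed[member_idx] <- TRUE
    members <- seed_align(sequences[member_idx], seed)
    members$count <- counts[member_idx]
    members$rpm <- rpm[member_idx]
    members <- members[, c("sequence", "length", "count", "rpm",
                           "ext5", "ext3", "seed_multiplicity")]
    groups[[length(groups) + 1L]] <- list(
      group_id = sprintf("grp%03d", length(groups) + 1L),
      seed = seed, members = members
    )
  }
  structure(groups, class = "seed_groups")
}

# align members on the leftmost seed occurrence; returns extension columns
seed_align <- function(members, seed) {
  pos <- regexpr(seed, members, fixed = TRUE)
  stopifnot(all(pos > 0L))  # grouping invariant: seed contained in member
  mult <- vapply(members, function(s) {
    length(gregexpr(seed, s, fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(
    sequence = members,
    length = nchar(members),
    ext5 = substr(members, 1L, pos - 1L),
    ext3 = substr(members, pos + nchar(seed), nchar(members)),
    seed_multiplicity = mult,
    stringsAsFactors = FALSE
  )
}

#' @export
print.seed_groups <- function(x, ...) {
  cat("seed_groups:", length(x), "groups\n")
  for (g in x) {
    cat("  ", g$group_id, " seed=", g$seed, " (", nchar(g$seed), " nt, ",
        nrow(g$members), " members)\n", sep = "")
  }
  invisible(x)
}

#' 5'/3' extensions of each member relative to the group seed
#'
#' Anchors the seed at its leftmost occurrence in each member (repeated
#' occurrences are reported through `seed_multiplicity`) and returns the
#' flanking strings. For every member, `ext5 + seed + ext3` reconstructs
#' the member exactly.
#'
#' @param group One element of a [group_by_seed()] result.
#' @return data.frame: `sequence`, `ext5`, `ext5_len`, `ext3`, `ext3_len`,
#'   `seed_multiplicity`.
#' @export
extensions <- function(group) {
  m <- group$members
  data.frame(
    sequence = m$sequence,
    ext5 = m$ext5, ext5_len = nchar(m$ext5),
    ext3 = m$ext3, ext3_len = nchar(m$ext3),
    seed_multiplicity = m$seed_multiplicity,
    stringsAsFactors = FALSE
  )
}

#' Staircase (degradation-ladder) profile of a seed group
#'
#' Orders members by decreasing length and reports, per member, its count
#' and an outlier flag: a count strictly greater than `outlier_factor`
#' times the group's median count is abnormally high for a passive
#' degradation ladder and marks the member as a candidate discrete product.
#' The truncation direction compares each member with the longest member:
#' a member that is a suffix of the longest lost 5' bases (5'->3'
#' degradation), a prefix lost 3' bases.
#'
#' @param group One element of a [group_by_seed()] result (counts required).
#' @param outlier_factor Multiple of the median above which a count is
#'   flagged, default 10; must be > 1.
#' @return Object of class `staircase_report`: list with `group_id`,
#'   `members` (data.frame `sequence`, `length`, `count`, `outlier`,
#'   `side`), `direction` (`"5'->3'"`, `"3'->5'"`, `"mixed"`, or `"single"`),
#'   `median_count`, `outlier_factor`, and `decay_profile` (data.frame
#'   `length`, `count`).
#' @export
staircase <- function(group, outlier_factor = 10) {
  if (outlier_factor <= 1) stop("outlier_factor must be > 1")
  m <- group$members
  if (anyNA(m$count)) stop("staircase() needs member counts")
  m <- m[order(-m$length, m$sequence), , drop = FALSE]
  med <- stats::median(m$count)
  longest <- m$sequence[1L]
  side <- vapply(m$sequence, function(s) {
    if (s == longest) "anchor"
    else if (substr(longest, nchar(longest) - nchar(s) + 1L,
                    nchar(longest)) == s) "five_prime_trimmed"
    else if (substr(longest, 1L, nchar(s)) == s) "three_prime_trimmed"
    else "internal"
  }, character(1), USE.NAMES = FALSE)
  members <- data.frame(
    sequence = m$sequence, length = m$length, count = m$count,
    outlier = m$count > outlier_factor * med, side = side,
    stringsAsFactors = FALSE
  )
  steps <- side[side != "anchor"]
  direction <- if (length(steps) == 0L) "single"
    else if (all(steps == "five_prime_trimmed")) "5'->3'"
    else if (all(steps == "three_prime_trimmed")) "3'->5'"
    else "mixed"
  decay <- stats::aggregate(count ~ length, data = members, FUN = sum)
  decay <- decay[order(-decay$length), , drop = FALSE]
  rownames(decay) <- NULL
  structure(list(group_id = group$group_id, members = members,
                 direction = direction, median_count = med,
                 outlier_factor = outlier_factor, decay_profile = decay),
            class = "staircase_report")
}

#' Shared 3'-terminal motif of a sequence family
#'
#' Most frequent terminal k-mer among the sequences (ties broken
#' lexicographically) and the fraction of sequences carrying it — e.g. the
#' ATGA motif shared at the 3' end of dominant short sdRNAs.
#'
#' @param sequences Character vector (>= 2 sequences).
#' @param k Motif length, default 4; must not exceed the shortest sequence.
#' @return List: `motif`, `support` (fraction in \[0, 1\]).
#' @export
motif_3prime <- function(sequences, k = 4L) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (k > min(nchar(sequences))) {
    stop("k = ", k, " exceeds the shortest sequence (",
         min(nchar(sequences)), " nt)")
  }
  term <- substr(sequences, nchar(sequences) - k + 1L, nchar(sequences))
  tab <- table(term)
  tab <- tab[order(-tab, names(tab))]
  list(motif = names(tab)[1L],
       support = as.numeric(tab[1L]) / length(sequences))
}

#' Near-miss variants between seed groups
#'
#' Reports pairs of equal-length sequences that sit in different seed
#' groups yet differ by at most `max_hamming` substitutions — variants that
#' substring containment cannot join (the red-letter substitutions of
#' dominant-sequence tables). Purely informational; grouping is unchanged.
#'
#' @param groups A [group_by_seed()] result.
#' @param max_hamming Maximum substitution distance, default 1.
#' @return data.frame: `sequence_a`, `group_a`, `sequence_b`, `group_b`,
#'   `hamming`.
#' @export
near_misses <- function(groups, max_hamming = 1L) {
  seqs <- unlist(lapply(groups, function(g) g$members$sequence))
  gid <- unlist(lapply(groups, function(g)
    rep(g$group_id, nrow(g$members))))
  out <- list()
  if (length(seqs) >= 2L) {
    for (i in seq_len(length(seqs) - 1L)) {
      for (j in (i + 1L):length(seqs)) {
        if (gid[i] == gid[j]) next
        if (nchar(seqs[i]) != nchar(seqs[j])) next
        d <- hamming(seqs[i], seqs[j])
        if (d <= max_hamming) {
          out[[length(out) + 1L]] <- data.frame(
            sequence_a = seqs[i], group_a = gid[i],
            sequence_b = seqs[j], group_b = gid[j],
            hamming = d, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_a = character(), group_a = character(),
                      sequence_b = character(), group_b = character(),
                      hamming = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Column-aligned text rendering of a seed group
#'
#' Pads members so the seed occupies one column block, the conventional way
#' fragment-family alignments are shown in supplementary files.
#'
#' @param group One element of a [group_by_seed()] result.
#' @return Character vector, one line per member (longest 5' extension
#'   left-padded with spaces).
#' @export
render_seed_alignment <- function(group) {
  m <- group$members
  pad <- max(nchar(m$ext5)) - nchar(m$ext5)
  lines <- paste0(strrep(" ", pad), m$sequence)
  ord <- order(-m$length, m$sequence)
  lines[ord]
}
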