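#' Sequences conserved across species (or sample groups)
#'
#' A sequence is conserved when it is present — exact string identity, no
#' homology or mismatch tolerance — in at least one sample of every group,
#' and its length falls inside the requested window. Groups normally pool
#' the samples of one species. Abundance is ignored: a sequence counts once
#' however many reads carry it. Biotype calls are taken per group from the
#' supplied annotations; when groups disagree on a conserved sequence's
#' call, the first group's call is reported and the disagreement is logged
#' in the `disagreements` element.
#'
#' @param groups Named list (>= 2 entries) of lists of `read_set` objects;
#'   each entry is one species/group, each inner element one sample.
#' @param window Length-2 integer vector `(min, max)` within 8-30. The
#'   default `c(8, 14)` reads "shorter than 15 nt" literally; use
#'   `c(8, 15)` for the full short window.
#' @param annotations Optional named list parallel to `groups`: one
#'   annotation table (from [classify_set()], sequences pooled over the
#'   group's samples) per group. Without it all sequences are reported
#'   under the call `"unclassified"`.
#' @return Object of class `conservation_report`: list with `sequences`
#'   (data.frame `sequence`, `length`, `call`, plus one `in_<group>`
#'   presence column per group), `counts` (named per-call tally),
#'   `disagreements` (data.frame of sequences with discordant calls), and
#'   `window`.
#' @export
conserved_sequences <- function(groups, window = c(8L, 14L),
                                annotations = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups to intersect")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named")
  }
  if (window[1] < 8L || window[2] > 30L || window[1] > window[2]) {
    stop("window must lie within 8-30")
  }
  pooled <- lapply(groups, function(g) {
    if (length(g) == 0L) stop("empty group")
    unique(unlist(lapply(g, function(rs) {
      r <- if (inherits(rs, "read_set")) rs$reads else rs
      r$sequence[r$length >= window[1] & r$length <= window[2]]
    })))
  })
  common <- Reduce(intersect, pooled)
  common <- common[order(nchar(common), common)]
  calls <- rep("unclassified", length(common))
  disagreements <- data.frame(sequence = character(),
                              stringsAsFactors = FALSE)
  if (!is.null(annotations) && length(common) > 0L) {
    stopifnot(identical(names(annotations), names(groups)))
    per_group <- vapply(annotations, function(a) {
      a$call[match(common, a$sequence)]
    }, character(length(common)))
    per_group <- matrix(per_group, nrow = length(common))
    calls <- per_group[, 1L]
    calls[is.na(calls)] <- "unclassified"
    discord <- apply(per_group, 1L, function(r) {
      length(unique(stats::na.omit(r))) > 1L
    })
    disagreements <- data.frame(sequence = common[discord],
                                stringsAsFactors = FALSE)
  }
  presence <- matrix(FALSE, nrow = length(common), ncol = length(pooled),
                     dimnames = list(NULL, paste0("in_", names(groups))))
  for (j in seq_along(pooled)) presence[, j] <- common %in% pooled[[j]]
  sequences <- cbind(
    data.frame(sequence = common, length = nchar(common), call = calls,
               stringsAsFactors = FALSE),
    as.data.frame(presence)
  )
  counts <- if (length(common)) table(calls) else table(character())
  structure(list(sequences = sequences,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 disagreements = disagreements, window = window),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("conservation_report: ", nrow(x$sequences), " sequences conserved in ",
      sum(startsWith(names(x$sequences), "in_")), " groups (window ",
      x$window[1], "-", x$window[2], " nt)\n", sep = "")
  if (length(x$counts)) {
    for (b in names(x$counts)) cat("  ", b, ": ", x$counts[[b]], "\n", sep = "")
  }
  invisible(x)
}
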