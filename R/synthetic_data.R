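#' Simulation configuration
#'
#' Bundles everything needed to generate a reference set and a FASTQ sample
#' with ground truth: reference specs, fragment events, read number, the
#' per-base substitution error rate, adapter, and the number of sequencing
#' cycles (51-cycle single-end chemistry by default, which with a 21-nt
#' adapter leaves room for the full adapter after any 8-30 nt insert).
#'
#' @param rng_seed Integer seed; the whole sample is a deterministic
#'   function of it.
#' @param references List of specs `list(ref_id, biotype, length)`;
#'   sequences are drawn uniformly over ACGT.
#' @param embeds Optional list of `list(ref_id, at, seq)` planting a fixed
#'   subsequence at a 0-based offset of a reference (overwrites the random
#'   bases there).
#' @param extra_refs Optional list of `list(ref_id, biotype, seq)` added
#'   verbatim (e.g. a piRNA entry equal to a tRNA 5' sub-sequence, to model
#'   piRNA annotations that are themselves tRNA-derived).
#' @param events List of fragment events, see [fragment_event()].
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution probability on the insert
#'   (never on the adapter), `0 <= error_rate < 0.1`.
#' @param adapter 3' adapter sequence.
#' @param read_cycles Read length in cycles, default 51.
#' @param species Species tag for the references.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(rng_seed, references, events, embeds = list(),
                       extra_refs = list(), n_reads = 10000L,
                       error_rate = 0,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_cycles = 51L, species = "synthetic") {
  stopifnot(error_rate >= 0, error_rate < 0.1,
            length(references) > 0L, length(events) > 0L)
  w <- vapply(events, function(e) e$weight, numeric(1))
  if (sum(w) <= 0) stop("event weights must sum to > 0")
  structure(list(rng_seed = as.integer(rng_seed), references = references,
                 embeds = embeds, extra_refs = extra_refs, events = events,
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 adapter = toupper(adapter),
                 read_cycles = as.integer(read_cycles), species = species),
            class = "sim_config")
}

#' Define one fragment-generating event
#'
#' Three kinds: `discrete` (one fixed interval on the parent — recurrent
#' fragments of discrete length), `full_length` (the entire parent entry —
#' mature miRNAs/piRNAs), and `ladder` (a staircase of fragments anchored
#' at one end of the interval, emitting lengths `min_len..max_len` with
#' weight proportional to `decay^(max_len - len)` — a degradation ladder).
#'
#' @param kind `"discrete"`, `"ladder"`, or `"full_length"`.
#' @param parent_ref Reference id of the parent.
#' @param start,end 0-based half-open interval on the parent (ignored for
#'   `full_length`; for `ladder`, the maximal fragment).
#' @param weight Relative abundance of the event.
#' @param anchor_end For ladders: `"5p"` (start fixed, 3' side recedes) or
#'   `"3p"` (end fixed, 5' side recedes).
#' @param min_len,max_len For ladders: emitted length range; `max_len` must
#'   equal `end - start`.
#' @param decay For ladders: per-nucleotide decay ratio in (0, 1).
#' @return List describing the event.
#' @export
fragment_event <- function(kind = c("discrete", "ladder", "full_length"),
                           parent_ref, start = NULL, end = NULL, weight = 1,
                           anchor_end = c("3p", "5p"), min_len = NULL,
                           max_len = NULL, decay = 0.5) {
  kind <- match.arg(kind)
  if (kind == "ladder") {
    anchor_end <- match.arg(anchor_end)
    stopifnot(!is.null(min_len), !is.null(max_len), min_len <= max_len,
              decay > 0, decay < 1, max_len == end - start)
  } else {
    anchor_end <- NA_character_
  }
  list(kind = kind, parent_ref = parent_ref, start = start, end = end,
       weight = weight, anchor_end = anchor_end, min_len = min_len,
       max_len = max_len, decay = decay)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all (length, probability, start, end) rows an event can emit
event_emissions <- function(e) {
  if (e$kind == "ladder") {
    lens <- e$min_len:e$max_len
    p <- e$decay^(e$max_len - lens)
    p <- p / sum(p)
    if (e$anchor_end == "5p") {
      data.frame(length = lens, prob = p, start = e$start, end = e$start + lens)
    } else {
      data.frame(length = lens, prob = p, start = e$end - lens, end = e$end)
    }
  } else {
    data.frame(length = e$end - e$start, prob = 1, start = e$start,
               end = e$end)
  }
}

#' Expected fragment spectrum of a configuration
#'
#' Analytic per-(event, length) emission probabilities implied by the event
#' weights and ladder decay laws — the ground truth that observed window
#' shares, biotype distributions and dominant-sequence shares converge to.
#'
#' @param cfg A [sim_config()].
#' @param refs Output of [make_references()] (for biotype lookup).
#' @return data.frame: `event`, `parent_ref`, `biotype`, `length`, `start`,
#'   `end`, `prob` (sums to 1 over all rows).
#' @export
expected_spectrum <- function(cfg, refs) {
  w <- vapply(cfg$events, function(e) e$weight, numeric(1))
  w <- w / sum(w)
  rows <- lapply(seq_along(cfg$events), function(i) {
    e <- cfg$events[[i]]
    em <- event_emissions(e)
    data.frame(event = i, parent_ref = e$parent_ref,
               biotype = refs$biotype[match(e$parent_ref, refs$ref_id)],
               length = em$length, start = em$start, end = em$end,
               prob = em$prob * w[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the reference set of a simulation
#'
#' Draws random ACGT sequences per spec, overwrites embedded cores, adds
#' verbatim extra references, then applies a rejection step: every fragment
#' sequence the events can emit must not occur exactly in any reference of
#' a biotype ranked higher than (or different from, at equal priority) its
#' parent's, and each embedded core must occur only where planted. This
#' guarantees unambiguous recovery of the intended biotype at error rate 0.
#' Regenerates (new substream) up to `max_tries` times if violated.
#'
#' @param cfg A [sim_config()].
#' @param priority Biotype priority used by the rejection check; defaults
#'   to [priority_policy()]'s order.
#' @param max_tries Rejection-sampling attempts, default 50.
#' @return data.frame of reference records (as [load_references()]), ready
#'   for [reference_db()].
#' @export
make_references <- function(cfg, priority = priority_policy()$order,
                            max_tries = 50L) {
  for (lst in cfg$references) {
    if (lst$length < 1L) stop("infeasible reference length for ", lst$ref_id)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$rng_seed)
  for (try in seq_len(max_tries)) {
    recs <- lapply(cfg$references, function(r) {
      data.frame(ref_id = r$ref_id, biotype = r$biotype,
                 species = cfg$species, sequence = random_dna(r$length),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    for (em in cfg$embeds) {
      i <- match(em$ref_id, recs$ref_id)
      if (is.na(i)) stop("embed targets unknown reference: ", em$ref_id)
      s <- recs$sequence[i]
      if (em$at + nchar(em$seq) > nchar(s)) {
        stop("embed does not fit in ", em$ref_id)
      }
      substr(s, em$at + 1L, em$at + nchar(em$seq)) <- em$seq
      recs$sequence[i] <- s
    }
    for (xr in cfg$extra_refs) {
      recs <- rbind(recs, data.frame(ref_id = xr$ref_id, biotype = xr$biotype,
                                     species = cfg$species,
                                     sequence = toupper(xr$seq),
                                     stringsAsFactors = FALSE))
    }
    if (references_admissible(cfg, recs, priority)) return(recs)
  }
  stop("could not generate an admissible reference set in ", max_tries,
       " attempts; shorten fragments or enlarge references")
}

# rejection check: emitted fragments must map unambiguously
references_admissible <- function(cfg, recs, priority) {
  rank <- match(recs$biotype, priority)
  for (e in cfg$events) {
    pi <- match(e$parent_ref, recs$ref_id)
    if (is.na(pi)) stop("event references unknown parent: ", e$parent_ref)
    em <- event_emissions(e)
    parent_rank <- rank[pi]
    for (j in seq_len(nrow(em))) {
      frag <- substr(recs$sequence[pi], em$start[j] + 1L, em$end[j])
      # occurrences in any other reference of an equal-or-higher priority
      for (i in seq_len(nrow(recs))) {
        if (i == pi) next
        if (!is.na(rank[i]) && rank[i] <= parent_rank &&
            grepl(frag, recs$sequence[i], fixed = TRUE)) {
          # allowed only for extra refs planted as exact copies on purpose
          if (!identical(recs$sequence[i], frag)) return(FALSE)
        }
      }
    }
  }
  for (em in cfg$embeds) {
    core <- em$seq
    n_occ <- sum(vapply(recs$sequence, function(s) {
      length(gregexpr(core, s, fixed = TRUE)[[1]]) *
        (regexpr(core, s, fixed = TRUE) > 0L)
    }, numeric(1)))
    planted <- 1L + sum(vapply(cfg$extra_refs, function(x) {
      grepl(core, x$seq, fixed = TRUE)
    }, logical(1)))
    if (n_occ > planted) return(FALSE)
  }
  TRUE
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate one sRNA-seq sample with ground truth
#'
#' Draws `n_reads` events multinomially by weight, draws ladder lengths
#' from the decay law, applies per-base substitutions at `error_rate` to
#' the insert only, appends the adapter, pads with random bases and
#' truncates to `read_cycles`, at constant Q40. The draw order (events,
#' then lengths, then errors, then padding) is fixed, so the same seed
#' yields byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @param refs Output of [make_references()].
#' @param fastq_path Optional path; when given, a Phred+33 FASTQ is written.
#' @param truth_path Optional path for the ground-truth TSV.
#' @return List: `sequences` (full reads incl. adapter), `qualities`,
#'   `truth` — data.frame `read_id`, `event`, `parent_ref`, `biotype`,
#'   `start`, `end`, `length`, `sequence` (the errored insert), `errored`.
#' @export
simulate_sample <- function(cfg, refs, fastq_path = NULL, truth_path = NULL) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  # offset keeps the read stream independent of the reference stream
  set.seed(cfg$rng_seed + 1L)
  w <- vapply(cfg$events, function(e) e$weight, numeric(1))
  ev <- sample.int(length(cfg$events), cfg$n_reads, replace = TRUE,
                   prob = w / sum(w))
  emis <- lapply(cfg$events, event_emissions)
  pick <- integer(cfg$n_reads)
  for (i in seq_along(cfg$events)) {
    idx <- which(ev == i)
    if (length(idx) == 0L) next
    em <- emis[[i]]
    pick[idx] <- if (nrow(em) == 1L) 1L
      else sample.int(nrow(em), length(idx), replace = TRUE, prob = em$prob)
  }
  starts <- vapply(seq_len(cfg$n_reads),
                   function(r) emis[[ev[r]]]$start[pick[r]], numeric(1))
  ends <- vapply(seq_len(cfg$n_reads),
                 function(r) emis[[ev[r]]]$end[pick[r]], numeric(1))
  parent_seq <- refs$sequence[match(
    vapply(cfg$events, function(e) e$parent_ref, character(1))[ev],
    refs$ref_id)]
  inserts <- substr(parent_seq, starts + 1L, ends)
  errored <- logical(cfg$n_reads)
  if (cfg$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (r in seq_len(cfg$n_reads)) {
      s <- inserts[r]
      hit <- which(stats::runif(nchar(s)) < cfg$error_rate)
      if (length(hit)) {
        ch <- strsplit(s, "")[[1]]
        for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        inserts[r] <- paste(ch, collapse = "")
        errored[r] <- TRUE
      }
    }
  }
  reads <- paste0(inserts, cfg$adapter)
  pad_len <- pmax(0L, cfg$read_cycles - nchar(reads))
  if (sum(pad_len) > 0L) {
    pool <- sample(c("A", "C", "G", "T"), sum(pad_len), replace = TRUE)
    pads <- vapply(split(pool, rep(seq_along(pad_len), pad_len)),
                   paste, character(1), collapse = "")
    reads[pad_len > 0L] <- paste0(reads[pad_len > 0L], pads)
  }
  reads <- substr(reads, 1L, cfg$read_cycles)
  quals <- strrep("I", nchar(reads))  # constant Q40
  parent_ids <- vapply(cfg$events, function(e) e$parent_ref,
                       character(1))[ev]
  truth <- data.frame(
    read_id = sprintf("read%06d", seq_len(cfg$n_reads)),
    event = ev, parent_ref = parent_ids,
    biotype = refs$biotype[match(parent_ids, refs$ref_id)],
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(ends - starts), sequence = inserts,
    errored = errored, stringsAsFactors = FALSE
  )
  if (!is.null(fastq_path)) {
    writeLines(as.vector(rbind(paste0("@", truth$read_id), reads,
                               "+", quals)), fastq_path)
  }
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(sequences = reads, qualities = quals, truth = truth)
}

#' Write simulated references as FASTA
#'
#' @param refs Output of [make_references()].
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(refs, path) {
  writeLines(as.vector(rbind(paste0(">", refs$ref_id), refs$sequence)), path)
  invisible(path)
}

#' Canned scenario reproducing the dominant rRF fragment family
#'
#' A ready-made configuration that plants, on an rRNA parent, the nested
#' discrete 12/13/18/19-nt fragment family whose members extend a common
#' 12-nt core (GACTCTTAGCGG) by C, TCGTAC and CTCGTAC on the 5' side —
#' together with a tRNA whose 5' 18-mer is also present verbatim as a
#' piRNA entry (the classic tRNA-derived piRNA annotation), a full-length
#' 22-nt mature miRNA, a full-length 28-nt piRNA, a 12-nt snoRNA 5'
#' fragment ending in ATGA, and a low-weight 3'-anchored degradation
#' ladder on a second rRNA. Event weights are fixed so the 12-nt core
#' dominates its length stratum and roughly half the abundance falls in
#' the 8-15 nt window, as in bilaterian libraries.
#'
#' @param rng_seed Seed, default 20220519.
#' @param n_reads Reads to simulate, default 50000.
#' @param error_rate Substitution rate, default 0.
#' @return A [sim_config()].
#' @export
table_scenario <- function(rng_seed = 20220519L, n_reads = 50000L,
                           error_rate = 0) {
  core19 <- "CTCGTACGACTCTTAGCGG"          # 19-mer; suffixes give 18/13/12
  trf18 <- "GCATTGGTGGTTCAGTGG"            # tRNA 5' end, also a piRNA entry
  sno12 <- "TCGCTATGATGA"                  # snoRNA 5' end, 3' ATGA motif
  refs <- list(
    list(ref_id = "rRNA-5.8S-syn", biotype = "rRNA", length = 160L),
    list(ref_id = "rRNA-28S-syn", biotype = "rRNA", length = 200L),
    list(ref_id = "tRNA-Gly-GCC-syn", biotype = "tRNA", length = 76L),
    list(ref_id = "miR-22nt-syn", biotype = "miRNA_mature", length = 22L),
    list(ref_id = "piR-28nt-syn", biotype = "piRNA", length = 28L),
    list(ref_id = "SNORD-syn", biotype = "snoRNA", length = 72L)
  )
  embeds <- list(
    list(ref_id = "rRNA-5.8S-syn", at = 60L, seq = core19),
    list(ref_id = "tRNA-Gly-GCC-syn", at = 0L, seq = trf18),
    list(ref_id = "SNORD-syn", at = 0L, seq = sno12)
  )
  extra <- list(
    list(ref_id = "piR-syn-trna-derived", biotype = "piRNA", seq = trf18)
  )
  ev <- list(
    # nested rRF family: 12/13/18/19 nt sharing the 12-nt core
    fragment_event("discrete", "rRNA-5.8S-syn", 67L, 79L, weight = 0.18),
    fragment_event("discrete", "rRNA-5.8S-syn", 66L, 79L, weight = 0.22),
    fragment_event("discrete", "rRNA-5.8S-syn", 61L, 79L, weight = 0.13),
    fragment_event("discrete", "rRNA-5.8S-syn", 60L, 79L, weight = 0.04),
    # tRNA 5' 18-mer (dual tRNA/piRNA membership)
    fragment_event("discrete", "tRNA-Gly-GCC-syn", 0L, 18L, weight = 0.12),
    # full-length mature species
    fragment_event("full_length", "miR-22nt-syn", 0L, 22L, weight = 0.10),
    fragment_event("full_length", "piR-28nt-syn", 0L, 28L, weight = 0.06),
    # snoRNA 5' fragment with the 3' ATGA motif
    fragment_event("discrete", "SNORD-syn", 0L, 12L, weight = 0.05),
    # background degradation ladder, 3'-anchored, on the second rRNA
    fragment_event("ladder", "rRNA-28S-syn", 50L, 70L, weight = 0.10,
                   anchor_end = "3p", min_len = 8L, max_len = 20L,
                   decay = 0.55)
  )
  sim_config(rng_seed = rng_seed, references = refs, events = ev,
             embeds = embeds, extra_refs = extra, n_reads = n_reads,
             error_rate = error_rate)
}

#' Dominant human rRF sequences of the nested 12-nt-core family
#'
#' The five most abundant rRF sequences reported for the three human
#' samples (umbilical-vein endothelial cells, neutrophils, HEK293): the
#' 12-nt core GACTCTTAGCGG and its 5'-extended 13-, 18- and 19-nt forms.
#' The 18-mer appears twice because two samples rank it; sequences are
#' returned as printed (duplicates included).
#'
#' @return Character vector of 5 sequences.
#' @export
dominant_human_rrfs <- function() {
  c("TCGTACGACTCTTAGCGG",
    "CTCGTACGACTCTTAGCGG",
    "TCGTACGACTCTTAGCGG",
    "GACTCTTAGCGG",
    "CGACTCTTAGCGG")
}
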