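#' Configuration for the synthetic isoform generator
#'
#' The generator emulates the structure of the deposited CD44 corpus:
#' isoforms carrying catalogued splice-event combinations, sprinkled benign
#' point substitutions and single-residue indels, the same protein deposited
#' under several accessions, and C-terminally truncated partial records.
#' Defaults follow the observed corpus structure: most entries within a
#' group differ by at most one point change, and duplicates and partials
#' each make up a few percent of records.
#'
#' @param seed Integer RNG seed.
#' @param n_isoforms Number of base isoforms to generate.
#' @param event_sets List of character vectors of catalogue event names to
#'   sample from (each set must have mutually non-overlapping ranges);
#'   `NULL` uses the recognised exon patterns of the packaged catalogue.
#' @param substitution_rate Per-residue substitution probability
#'   (default 0.005).
#' @param indel_rate Per-residue probability of a single-residue insertion
#'   or deletion (default 0.001).
#' @param duplication_rate Probability a record is re-emitted byte-identical
#'   under a second fake accession (default 0.05).
#' @param partial_rate Probability of C-terminal truncation (default 0.05).
#' @param truncation_fraction_range Range of the retained prefix fraction
#'   for partials (default `c(0.3, 0.9)`).
#' @param adversarial Plant one substitution flush against an event boundary
#'   (stress for the delins merge rule).
#' @param repeat_stress Allow inserted residues equal to their flanks
#'   (stresses 3'-normalization instead of avoiding it).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_isoforms = 60L, event_sets = NULL,
                             substitution_rate = 0.005, indel_rate = 0.001,
                             duplication_rate = 0.05, partial_rate = 0.05,
                             truncation_fraction_range = c(0.3, 0.9),
                             adversarial = FALSE, repeat_stress = FALSE) {
  rates <- c(substitution_rate, indel_rate, duplication_rate, partial_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (length(truncation_fraction_range) != 2L ||
      truncation_fraction_range[1] > truncation_fraction_range[2] ||
      any(truncation_fraction_range <= 0 | truncation_fraction_range > 1)) {
    abort("truncation_fraction_range must be an increasing interval in (0, 1]")
  }
  structure(list(seed = as.integer(seed), n_isoforms = as.integer(n_isoforms),
                 event_sets = event_sets,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 duplication_rate = duplication_rate,
                 partial_rate = partial_rate,
                 truncation_fraction_range = truncation_fraction_range,
                 adversarial = isTRUE(adversarial),
                 repeat_stress = isTRUE(repeat_stress)),
            class = "synthetic_config")
}

# recognised exon patterns used when cfg$event_sets is NULL
.default_event_sets <- function() {
  list(
    character(0),
    "exon V2 spliced out",
    "exons V2-V3 spliced out",
    "exons V2-V4 spliced out",
    "exons V2-V7 spliced out",
    "exons V2-V9 spliced out",
    "exons V2-V10 spliced out",
    "exons V2-15 spliced out",
    "exon V6 spliced out",
    "exon V9 spliced out",
    "exon V10 spliced out",
    "exon 19 spliced out (short tail)",
    "part of exon 5 spliced out",
    "part of exon V3 spliced out",
    c("exons V2-V10 spliced out", "exon 19 spliced out (short tail)"),
    c("part of exon 5 spliced out", "exon V6 spliced out"),
    c("part of exon V3 spliced out", "exon V6 spliced out"),
    c("exon V2 spliced out", "exons V4-V7 spliced out"),
    c("exons V2-V7 spliced out", "exon V10 spliced out"),
    c("exons V2-V7 spliced out", "exons V9-V10 spliced out"),
    "exons 2-19 spliced out",
    "exons 3-19 spliced out (SST tail)",
    c("exon V2 spliced out", "exons V7-19 spliced out")
  )
}

.validate_event_sets <- function(event_sets, catalogue) {
  for (set in event_sets) {
    if (length(set) == 0L) next
    idx <- match(set, catalogue$name)
    if (anyNA(idx)) {
      abort(sprintf("unknown catalogue event '%s'", set[which(is.na(idx))[1]]))
    }
    if (length(idx) > 1L) {
      st <- catalogue$replaced_start[idx]; en <- catalogue$replaced_end[idx]
      o <- order(st)
      if (any(st[o][-1] <= en[o][-length(o)])) {
        abort(sprintf("event set {%s} has overlapping ranges",
                      paste(set, collapse = ", ")))
      }
    }
  }
  invisible(event_sets)
}

#' Generate a synthetic isoform set with ground truth
#'
#' Emits FASTA-ready records built by applying sampled catalogue event sets
#' to the canonical sequence, then planting point substitutions and
#' single-residue indels outside the event ranges (so the planted truth is
#' unambiguous), optional byte-identical duplicates under second accessions,
#' and prefix-truncated partials. Point edits are kept at least four residues
#' away from event boundaries and from each other, and inserted residues
#' differ from their flanks, so every planted descriptor is its own 3'-normal
#' form; `adversarial`/`repeat_stress` relax this deliberately. Output is
#' deterministic under a fixed seed.
#'
#' @param cfg A [synthetic_config()].
#' @param canonical Reference sequence.
#' @param catalogue Event catalogue.
#' @return List with `records` (tibble compatible with [write_fasta()]) and
#'   `truth` (tibble: `record_id`, `event_names`, `residuals` (rendered
#'   descriptor strings), `descriptors` (list of difference sets),
#'   `is_duplicate_of`, `is_partial`, `full_length`).
#' @examples
#' gen <- generate_isoform_set(synthetic_config(seed = 7, n_isoforms = 5))
#' gen$truth$event_names
#' @export
generate_isoform_set <- function(cfg = synthetic_config(),
                                 canonical = cd44_canonical(),
                                 catalogue = load_event_catalogue()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- .seq_of(canonical)
  event_sets <- cfg$event_sets %||% .default_event_sets()
  .validate_event_sets(event_sets, catalogue)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  records <- list(); truth <- list()
  emit <- 0L
  for (i in seq_len(cfg$n_isoforms)) {
    set_i <- event_sets[[sample.int(length(event_sets), 1L)]]
    idx <- match(set_i, catalogue$name)
    ev <- catalogue[idx, , drop = FALSE]
    ev_ds <- if (nrow(ev) > 0L) {
      tibble(kind = ifelse(nzchar(ev$insert), "delins", "deletion"),
             start = ev$replaced_start, end = ev$replaced_end,
             ref = substr(rep(s, nrow(ev)), ev$replaced_start, ev$replaced_end),
             alt = ev$insert)
    } else .empty_ds()

    # positions blocked for point edits: event ranges +/- 4 residues. Under the
    # affine scoring a point indel separated from an event block by fewer than
    # 3 match columns is absorbed into the block by a better-scoring merged
    # alignment (5k < |gap_open| for k <= 2 rescued matches), which would make
    # the planted truth ambiguous.
    blocked <- rep(FALSE, nchar(s))
    for (k in seq_len(nrow(ev_ds))) {
      lo <- max(1L, ev_ds$start[k] - 4L)
      hi <- min(nchar(s), ev_ds$end[k] + 4L)
      blocked[lo:hi] <- TRUE
    }
    blocked[c(1L, nchar(s))] <- TRUE     # keep termini clean

    point <- .empty_ds()
    sv <- strsplit(s, "")[[1]]
    free <- which(!blocked)
    for (p in free) {
      if (nrow(point) > 0L && min(abs(p - point$start)) < 5L) next
      u <- runif(1)
      if (u < cfg$substitution_rate) {
        alt <- sample(setdiff(.AA20, sv[p]), 1L)
        point <- rbind(point, tibble(kind = "substitution", start = p, end = p,
                                     ref = sv[p], alt = alt))
      } else if (u < cfg$substitution_rate + cfg$indel_rate) {
        if (runif(1) < 0.5) {
          # single-residue deletion, planted only where it is its 3'-normal form
          if (p < nchar(s) && sv[p + 1L] != sv[p]) {
            point <- rbind(point, tibble(kind = "deletion", start = p, end = p,
                                         ref = sv[p], alt = ""))
          }
        } else {
          excl <- if (cfg$repeat_stress) character(0) else c(sv[p], sv[p + 1L])
          alt <- sample(setdiff(.AA20, excl), 1L)
          point <- rbind(point, tibble(kind = "insertion", start = p,
                                       end = p + 1L, ref = "", alt = alt))
        }
      }
    }
    if (cfg$adversarial && nrow(ev_ds) > 0L) {
      p <- ev_ds$end[1] + 1L
      if (p < nchar(s) && !any(point$start == p)) {
        point <- rbind(point, tibble(kind = "substitution", start = p, end = p,
                                     ref = sv[p],
                                     alt = sample(setdiff(.AA20, sv[p]), 1L)))
      }
    }
    ds <- rbind(ev_ds, point)
    ds <- ds[order(ds$start, ds$end), ]
    seq_i <- hgvs_apply(ds, s)

    emit <- emit + 1L
    rid <- sprintf("SYN%04d", emit)
    is_partial <- runif(1) < cfg$partial_rate
    emitted <- seq_i
    if (is_partial) {
      frac <- runif(1, cfg$truncation_fraction_range[1],
                    cfg$truncation_fraction_range[2])
      emitted <- substr(seq_i, 1L, max(1L, floor(frac * nchar(seq_i))))
    }
    records[[length(records) + 1L]] <- tibble(
      record_id = rid,
      description = paste0(rid, if (is_partial) " partial" else ""),
      accessions = list(rid),
      sequence = emitted,
      is_partial_hint = is_partial)
    truth[[length(truth) + 1L]] <- tibble(
      record_id = rid, event_names = list(sort(set_i)),
      residuals = list(if (nrow(point) > 0L) hgvs_render(point) else character(0)),
      descriptors = list(ds), is_duplicate_of = NA_character_,
      is_partial = is_partial, full_length = nchar(seq_i))

    if (runif(1) < cfg$duplication_rate) {
      emit <- emit + 1L
      did <- sprintf("SYN%04d", emit)
      records[[length(records) + 1L]] <- tibble(
        record_id = did,
        description = paste0(did, " duplicate of ", rid,
                             if (is_partial) " partial" else ""),
        accessions = list(did), sequence = emitted,
        is_partial_hint = is_partial)
      truth[[length(truth) + 1L]] <- tibble(
        record_id = did, event_names = list(sort(set_i)),
        residuals = list(if (nrow(point) > 0L) hgvs_render(point) else character(0)),
        descriptors = list(ds), is_duplicate_of = rid,
        is_partial = is_partial, full_length = nchar(seq_i))
    }
  }
  rec_proto <- tibble(record_id = character(), description = character(),
                      accessions = list(), sequence = character(),
                      is_partial_hint = logical())
  truth_proto <- tibble(record_id = character(), event_names = list(),
                        residuals = list(), descriptors = list(),
                        is_duplicate_of = character(), is_partial = logical(),
                        full_length = integer())
  list(records = dplyr::bind_rows(c(list(rec_proto), records)),
       truth = dplyr::bind_rows(c(list(truth_proto), truth)))
}

#' Generate a genomic exon fixture with planted alternative splice sites
#'
#' Builds a synthetic genomic fragment: exon bodies free of AG and GT
#' dinucleotides (so the only splice-site candidates are the planted ones),
#' joined by intron stubs that begin with the canonical donor GT and end
#' with the canonical acceptor AG, plus flanking context. Requested internal
#' AG (acceptor) or GT (donor) sites are planted at stated offsets; planting
#' that would collide with another requested site is an error.
#'
#' @param seed Integer RNG seed.
#' @param exon_lengths Integer vector of exon body lengths (nt).
#' @param planted_alt_sites Tibble with columns `exon` (index into
#'   `exon_lengths`), `site_kind` (`"acceptor"` or `"donor"`), `offset_nt`.
#' @param flank Flanking/intron context length in nt (default 20).
#' @param phases Integer vector of per-exon phases (default all 0).
#' @return List with `dna` (the full fragment), `exons` (tibble usable with
#'   the splice-scan functions), and `truth` (the planted sites).
#' @export
generate_genomic_fixture <- function(seed, exon_lengths,
                                     planted_alt_sites = NULL, flank = 20L,
                                     phases = NULL) {
  if (any(exon_lengths <= 0L)) abort("exon lengths must be positive")
  if (flank < 2L) abort("flank must be at least 2 nt")
  phases <- phases %||% rep(0L, length(exon_lengths))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # sample a DNA string with no AG or GT dinucleotide anywhere inside it
  sample_clean <- function(n) {
    v <- character(n)
    for (k in seq_len(n)) {
      ok <- c("A", "C", "G", "T")
      if (k > 1L) {
        if (v[k - 1L] == "A") ok <- setdiff(ok, "G")
        if (v[k - 1L] == "G") ok <- setdiff(ok, "T")
      }
      v[k] <- sample(ok, 1L)
    }
    v
  }

  pieces <- character(0)
  exon_rows <- list()
  pos <- 0L
  left <- sample_clean(flank)
  left[flank - 1L] <- "A"; left[flank] <- "G"   # canonical acceptor into exon 1
  if (flank >= 3L && left[flank - 2L] == "A") left[flank - 2L] <- "C"
  pieces <- c(pieces, paste(left, collapse = ""))
  pos <- flank
  for (e in seq_along(exon_lengths)) {
    body <- sample_clean(exon_lengths[e])
    if (!is.null(planted_alt_sites)) {
      mine <- planted_alt_sites[planted_alt_sites$exon == e, , drop = FALSE]
      for (k in seq_len(nrow(mine))) {
        site <- mine[k, ]
        if (site$site_kind == "acceptor") {
          at <- site$offset_nt - 1L            # AG ends right before the new start
          di <- c("A", "G")
        } else {
          at <- exon_lengths[e] - site$offset_nt + 1L  # GT right after the new end
          di <- c("G", "T")
        }
        if (at < 1L || at + 1L > exon_lengths[e]) {
          abort(sprintf("planted %s site at offset %d outside exon %d",
                        site$site_kind, site$offset_nt, e))
        }
        body[at] <- di[1]; body[at + 1L] <- di[2]
        # avoid accidental AG/GT straddling the planted dinucleotide
        if (at > 1L) {
          if (body[at - 1L] == "A" && body[at] == "G") body[at - 1L] <- "C"
          if (body[at - 1L] == "G" && body[at] == "T") body[at - 1L] <- "C"
        }
        if (at + 2L <= exon_lengths[e]) {
          if (body[at + 1L] == "A" && body[at + 2L] == "G") body[at + 2L] <- "C"
          if (body[at + 1L] == "G" && body[at + 2L] == "T") body[at + 2L] <- "C"
        }
      }
      # verify all requested sites survived the straddle fix-up
      for (k in seq_len(nrow(mine))) {
        site <- mine[k, ]
        at <- if (site$site_kind == "acceptor") site$offset_nt - 1L
              else exon_lengths[e] - site$offset_nt + 1L
        di <- if (site$site_kind == "acceptor") c("A", "G") else c("G", "T")
        if (!identical(body[at:(at + 1L)], di)) {
          abort(sprintf("planted sites in exon %d conflict with each other", e))
        }
      }
    }
    pieces <- c(pieces, paste(body, collapse = ""))
    exon_rows[[e]] <- tibble(exon_id = sprintf("exon%02d", e),
                             exon_start_in_string = pos + 1L,
                             exon_end_in_string = pos + exon_lengths[e],
                             phase = phases[e], flank = flank)
    pos <- pos + exon_lengths[e]
    if (e < length(exon_lengths)) {
      intron <- sample_clean(flank)
      intron[1L] <- "G"; intron[2L] <- "T"
      if (flank >= 3L && intron[3L] == "T") intron[3L] <- "C"
      intron[flank - 1L] <- "A"; intron[flank] <- "G"
      if (flank >= 3L && intron[flank - 2L] == "A") intron[flank - 2L] <- "C"
      pieces <- c(pieces, paste(intron, collapse = ""))
      pos <- pos + flank
    }
  }
  right <- sample_clean(flank)
  right[1L] <- "G"; right[2L] <- "T"            # canonical donor out of last exon
  if (flank >= 3L && right[3L] == "T") right[3L] <- "C"
  pieces <- c(pieces, paste(right, collapse = ""))
  dna <- paste(pieces, collapse = "")
  exons <- dplyr::bind_rows(exon_rows)
  exons$dna <- dna
  truth <- planted_alt_sites %||% tibble(exon = integer(),
                                         site_kind = character(),
                                         offset_nt = integer())
  list(dna = dna, exons = exons, truth = truth)
}
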