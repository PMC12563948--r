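#' Convert catalogue events to variant descriptors
#'
#' @param catalogue Event catalogue tibble (see [load_event_catalogue()]).
#' @param canonical Reference sequence.
#' @param mode Normalization mode for the returned descriptors.
#' @return Difference-set tibble with an extra `name` column.
#' @export
events_as_descriptors <- function(catalogue, canonical = cd44_canonical(),
                                  mode = c("hgvs3", "as-deposited")) {
  mode <- match.arg(mode)
  s <- .seq_of(canonical)
  key <- paste(mode, substr(s, 1, 50), nchar(s),
               paste(catalogue$name, catalogue$replaced_start,
                     catalogue$replaced_end, catalogue$insert, collapse = "|"))
  hit <- .cd44iso_cache$event_descriptors
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(catalogue)), function(k) {
    e <- catalogue[k, ]
    ref <- substr(s, e$replaced_start, e$replaced_end)
    kind <- if (!nzchar(e$insert)) "deletion"
      else if (e$replaced_start == e$replaced_end && nchar(e$insert) == 1L &&
               e$insert != ref) "substitution"
      else "delins"
    d <- tibble(kind = kind, start = e$replaced_start, end = e$replaced_end,
                ref = ref, alt = e$insert)
    d <- hgvs_normalize(d, s, mode)
    d$name <- e$name
    d
  }))
  .cd44iso_cache$event_descriptors <- list(key = key, value = out)
  out
}

#' Match observed differences against the splice-event catalogue
#'
#' A descriptor counts as a catalogued event only when it is a
#' deletion-insertion (or a catalogued pure deletion) and its
#' (start, end, insert) triple equals a catalogue entry exactly — after both
#' sides are put into the same normalization mode. Fuzzy matching is
#' deliberately absent: the microexon events (e.g. the partial exon 5
#' splice-out) differ from full-exon events only by their boundaries, so a
#' boundary off by up to 2 residues raises a warning, never a match.
#' Unmatched delins descriptors replacing at least `novel_min` residues are
#' reported as novel (putative unannotated splice) events; everything else is
#' a residual variant.
#'
#' @param ds Difference-set tibble (canonical coordinates).
#' @param catalogue Event catalogue.
#' @param canonical Reference sequence.
#' @param mode `"hgvs3"` (default) compares 3'-normalized forms;
#'   `"as-deposited"` compares raw forms.
#' @param novel_min Minimum replaced length for an unmatched delins to count
#'   as novel (default 8, the size of the smallest catalogued non-point
#'   event).
#' @return List with `matched` (character vector of event names), `residual`
#'   (difference-set tibble), `novel` (difference-set tibble).
#' @export
match_events <- function(ds, catalogue = load_event_catalogue(),
                         canonical = cd44_canonical(),
                         mode = c("hgvs3", "as-deposited"), novel_min = 8L) {
  mode <- match.arg(mode)
  s <- .seq_of(canonical)
  ev <- events_as_descriptors(catalogue, s, mode)
  dsn <- hgvs_normalize(ds, s, mode)
  matched <- character(0)
  residual_idx <- integer(0)
  novel_idx <- integer(0)
  ev_key <- paste(ev$start, ev$end, ev$alt)
  for (k in seq_len(nrow(dsn))) {
    d <- dsn[k, ]
    hit <- d$kind %in% c("delins", "deletion") &&
      paste(d$start, d$end, d$alt) %in% ev_key
    if (hit) {
      matched <- c(matched, ev$name[match(paste(d$start, d$end, d$alt), ev_key)])
    } else if (d$kind == "delins" && (d$end - d$start + 1L) >= novel_min) {
      near <- abs(ev$start - d$start) <= 2L & abs(ev$end - d$end) <= 2L
      if (any(near)) {
        warn(sprintf("descriptor %s is within 2 residues of catalogued event '%s' but was not matched",
                     hgvs_render(d), ev$name[which(near)[1]]))
      }
      novel_idx <- c(novel_idx, k)
    } else {
      residual_idx <- c(residual_idx, k)
    }
  }
  list(matched = matched, residual = dsn[residual_idx, ], novel = dsn[novel_idx, ])
}

#' Classify the C-terminus of an isoform
#'
#' The canonical cytoplasmic long tail occupies positions 675-742. A
#' sequence is `long` when no event-scale edit disturbs that segment (point
#' variants inside the tail do not change the class), `short` when it
#' carries the catalogued replacement of the whole segment by a single
#' serine (yielding the RRS short-tail ending), `alternative` when its
#' C-terminus is a novel suffix — either one of the known alternative
#' endings or an unalignable replacement — and `truncated` when it simply
#' stops early with no novel residues.
#'
#' @param seq The isoform sequence.
#' @param ds Difference set of the isoform against the canonical.
#' @param endings Known alternative endings (see [load_tail_endings()]).
#' @param canonical Reference sequence.
#' @return List with `tail_class` (one of `long`, `short`, `alternative`,
#'   `truncated`) and `c_terminal_segment` (empty unless `alternative`).
#' @export
classify_tail <- function(seq, ds, endings = load_tail_endings(),
                          canonical = cd44_canonical()) {
  s <- .seq_of(canonical)
  n <- nchar(s)
  event_scale <- ds$end >= .TAIL_START &
    ds$kind %in% c("deletion", "delins") &
    ((ds$end - ds$start + 1L) >= 8L | ds$end == n)
  if (!any(event_scale)) {
    return(list(tail_class = "long", c_terminal_segment = ""))
  }
  rows <- ds[event_scale, ]
  short <- rows$start == .TAIL_START & rows$end == n & rows$alt == "S"
  if (any(short)) {
    return(list(tail_class = "short", c_terminal_segment = ""))
  }
  last <- rows[nrow(rows), ]
  if (last$end == n) {
    if (!nzchar(last$alt)) {
      return(list(tail_class = "truncated", c_terminal_segment = ""))
    }
    known <- endings$ending[vapply(endings$ending,
                                   function(e) endsWith(seq, e), logical(1))]
    seg <- if (length(known) > 0L) known[which.max(nchar(known))] else last$alt
    return(list(tail_class = "alternative", c_terminal_segment = seg))
  }
  # internal event-scale edit inside the tail segment without a novel suffix
  list(tail_class = "alternative", c_terminal_segment = "")
}

# Whole-tail replacement events (replaced_end == canonical end, insert of
# >= 2 aa) do not survive naive global alignment as a single block: their
# insert finds short spurious matches inside the huge replaced span. When the
# query ends with such an insert, align only the remainder against the
# canonical truncated at the event start and keep the decomposition if it
# reproduces the query exactly.
.tail_anchored_differences <- function(query, canonical, catalogue, params) {
  s <- .seq_of(canonical)
  cand <- catalogue[catalogue$replaced_end == nchar(s) &
                      nchar(catalogue$insert) >= 2L, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-nchar(cand$insert)), ]
  for (k in seq_len(nrow(cand))) {
    e <- cand[k, ]
    if (!endsWith(query, e$insert)) next
    prefix <- substr(query, 1, nchar(query) - nchar(e$insert))
    head_ref <- substr(s, 1, e$replaced_start - 1L)
    if (!nzchar(prefix) || !nzchar(head_ref)) next
    ds_head <- extract_differences(global_align(head_ref, prefix, params))
    tail_d <- tibble(kind = if (nzchar(e$insert)) "delins" else "deletion",
                     start = e$replaced_start, end = e$replaced_end,
                     ref = substr(s, e$replaced_start, e$replaced_end),
                     alt = e$insert)
    ds <- dplyr::bind_rows(ds_head, tail_d)
    ds <- ds[order(ds$start, ds$end), ]
    ok <- tryCatch(hgvs_apply(ds, s) == query, error = function(err) FALSE)
    if (isTRUE(ok)) return(ds)
  }
  NULL
}

#' Classify one isoform against the canonical reference
#'
#' Composes the pipeline for a single record: global alignment to the
#' canonical, descriptor extraction, catalogue matching, tail
#' classification, and flagging. A record is flagged `partial` when its
#' length covers less than `coverage` of the span expected after accounting
#' for its matched and novel events; `low-coverage` marks sequences whose
#' aligned fraction is below 0.5 (significantly divergent records).
#'
#' @param rec A one-row tibble (or list) with `record_id`, `sequence`, and
#'   optionally `accessions`.
#' @param canonical Reference sequence.
#' @param catalogue Event catalogue.
#' @param params Alignment scoring parameters.
#' @param endings Known alternative C-terminal endings.
#' @param mode Normalization mode for descriptor comparison.
#' @param coverage Partial-record threshold on expected-span coverage
#'   (default 0.95).
#' @return One-row classification tibble with list columns
#'   `matched_events`, `novel_events`, `residual_variants`, `accessions`,
#'   `flags`, plus `tail_class`, `c_terminal_segment`, `group_key`,
#'   `length`, `expected_length`, and `query_coverage`.
#' @export
classify_isoform <- function(rec, canonical = cd44_canonical(),
                             catalogue = load_event_catalogue(),
                             params = scoring_params(),
                             endings = load_tail_endings(),
                             mode = c("hgvs3", "as-deposited"),
                             coverage = 0.95) {
  mode <- match.arg(mode)
  s <- .seq_of(canonical)
  query <- rec[["sequence"]]
  if (is.list(query)) query <- query[[1]]
  record_id <- if (is.null(rec[["record_id"]])) "" else as.character(rec[["record_id"]])[1]
  accessions <- if (is.null(rec[["accessions"]])) list(character(0)) else {
    a <- rec[["accessions"]]
    if (is.list(a) && !is.character(a)) a[1] else list(a)
  }
  tryCatch({
    ds <- .tail_anchored_differences(query, s, catalogue, params)
    qcov <- NA_real_
    if (is.null(ds)) {
      aln <- global_align(s, query, params)
      qcov <- alignment_coverage(aln)$query_coverage
      ds <- extract_differences(aln, mode)
    }
    mt <- match_events(ds, catalogue, s, mode)
    tail <- classify_tail(query, ds, endings, s)
    evd <- events_as_descriptors(catalogue, s, mode)
    evd <- evd[evd$name %in% mt$matched, , drop = FALSE]
    expected_length <- nchar(s) -
      sum(nchar(mt$novel$ref)) + sum(nchar(mt$novel$alt)) -
      sum(nchar(evd$ref)) + sum(nchar(evd$alt))
    cov_expected <- min(1, nchar(query) / expected_length)
    flags <- character(0)
    if (cov_expected < coverage) flags <- c(flags, "partial")
    if (!is.na(qcov) && qcov < 0.5) flags <- c(flags, "low-coverage")
    novel_sig <- if (nrow(mt$novel) > 0L) hgvs_render(mt$novel) else character(0)
    key_parts <- sort(c(mt$matched, novel_sig))
    tibble(
      record_id = record_id,
      accessions = accessions,
      length = nchar(query),
      matched_events = list(sort(mt$matched)),
      novel_events = list(novel_sig),
      residual_variants = list(mt$residual),
      tail_class = tail$tail_class,
      c_terminal_segment = tail$c_terminal_segment,
      group_key = paste(key_parts, collapse = " + "),
      expected_length = expected_length,
      query_coverage = cov_expected,
      flags = list(flags)
    )
  }, error = function(e) {
    abort(sprintf("record '%s': %s", record_id, conditionMessage(e)), parent = e)
  })
}

#' Classify a batch of isoform records
#'
#' @param records Tibble of records as returned by [read_fasta()].
#' @param ... Passed to [classify_isoform()].
#' @return Classification tibble, one row per record, in input order.
#' @examples
#' recs <- tibble::tibble(record_id = "canonical",
#'                        sequence = cd44_canonical()$sequence)
#' classify_isoforms(recs)
#' @export
classify_isoforms <- function(records, ...) {
  if (nrow(records) == 0L) {
    return(tibble(record_id = character(), accessions = list(),
                  length = integer(), matched_events = list(),
                  novel_events = list(), residual_variants = list(),
                  tail_class = character(), c_terminal_segment = character(),
                  group_key = character(), expected_length = integer(),
                  query_coverage = numeric(), flags = list()))
  }
  purrr::list_rbind(purrr::map(seq_len(nrow(records)),
                               function(k) classify_isoform(records[k, ], ...)))
}

#' Group classified isoforms by exon composition
#'
#' Partitions non-partial records by `group_key` (the sorted combination of
#' matched and novel events): isoforms sharing exactly the same splice
#' events fall in one group regardless of residual point variants. Partials
#' are excluded from grouping and reported separately. Group order is by the
#' smallest input index of a member, so permuting the input changes nothing
#' but bookkeeping.
#'
#' @param results Classification tibble.
#' @return List with `groups` (tibble: `group_key`,
#'   `canonical_event_label`, `n_members`, `members` list column) and
#'   `partials` (character vector of excluded record ids).
#' @export
group_isoforms <- function(results) {
  is_partial <- vapply(results$flags, function(f) "partial" %in% f, logical(1))
  kept <- results[!is_partial, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(groups = tibble(group_key = character(),
                                canonical_event_label = character(),
                                n_members = integer(), members = list()),
                partials = results$record_id[is_partial]))
  }
  first_idx <- tapply(seq_len(nrow(kept)), kept$group_key, min)
  keys <- names(sort(first_idx))
  groups <- dplyr::bind_rows(lapply(keys, function(k) {
    m <- kept$record_id[kept$group_key == k]
    tibble(group_key = k,
           canonical_event_label = if (nzchar(k)) k else "full-length",
           n_members = length(m), members = list(m))
  }))
  list(groups = groups, partials = results$record_id[is_partial])
}

#' Cluster byte-identical sequences across accessions
#'
#' Emulates cross-database deduplication: records with identical sequences
#' (e.g. the same isoform deposited under an NCBI and a UniProt accession)
#' are merged into one cluster whose accession list is the first-seen-order
#' union of the members'.
#'
#' @param records Record tibble with `record_id`, `sequence`, and optionally
#'   `accessions`.
#' @return Tibble with one row per distinct sequence: `cluster_id`,
#'   `record_id` (representative, first seen), `member_ids`, `accessions`
#'   (list columns), `sequence`, `n_members`.
#' @export
merge_identical <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(cluster_id = integer(), record_id = character(),
                  member_ids = list(), accessions = list(),
                  sequence = character(), n_members = integer()))
  }
  acc <- if ("accessions" %in% names(records)) records$accessions
         else as.list(records$record_id)
  firsts <- !duplicated(records$sequence)
  reps <- records$sequence[firsts]
  dplyr::bind_rows(lapply(seq_along(reps), function(i) {
    idx <- which(records$sequence == reps[i])
    tibble(cluster_id = i,
           record_id = records$record_id[idx[1]],
           member_ids = list(records$record_id[idx]),
           accessions = list(unique(unlist(acc[idx]))),
           sequence = reps[i],
           n_members = length(idx))
  }))
}

#' Bucket records by sequence length
#'
#' Single-linkage clustering over sequence length with the given tolerance —
#' an optional pre-clustering accelerator mirroring size-based grouping of
#' database records (lengths within the tolerance chain into one bucket).
#'
#' @param records Record tibble with a `sequence` column.
#' @param tolerance Maximum length difference joining two buckets
#'   (default 1).
#' @return `records` with added `length` and `length_bucket` columns;
#'   buckets are numbered by increasing length.
#' @export
group_by_length <- function(records, tolerance = 1L) {
  if (tolerance < 0L) abort("tolerance must be >= 0")
  if (nrow(records) == 0L) {
    records$length <- integer(0)
    records$length_bucket <- integer(0)
    return(records)
  }
  records$length <- nchar(records$sequence)
  lens <- sort(unique(records$length))
  bucket_of_len <- cumsum(c(1L, diff(lens) > tolerance))
  records$length_bucket <- bucket_of_len[match(records$length, lens)]
  records
}

#' Plot exon-pattern group composition
#'
#' Tile plot of which catalogued events each exon-pattern group carries.
#'
#' @param results Classification tibble.
#' @return A ggplot object.
#' @export
plot_exon_patterns <- function(results) {
  grp <- group_isoforms(results)$groups
  df <- dplyr::bind_rows(lapply(seq_len(nrow(grp)), function(k) {
    evs <- strsplit(grp$group_key[k], " \\+ ")[[1]]
    evs <- evs[nzchar(evs)]
    tibble(group = grp$canonical_event_label[k],
           event = if (length(evs) > 0L) evs else "(none)",
           n_members = grp$n_members[k])
  }))
  df$group <- factor(df$group, levels = rev(grp$canonical_event_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$group,
                                   fill = .data$n_members)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::labs(x = "splice event", y = "exon-pattern group",
                  fill = "isoforms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
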