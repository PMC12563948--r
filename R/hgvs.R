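#' Build a variant descriptor tibble
#'
#' A difference set is a tibble of protein-level variant descriptors expressed
#' against a reference sequence, one row per descriptor, with columns `kind`
#' (`substitution`, `deletion`, `insertion`, `delins`), `start`, `end`
#' (1-based inclusive; for an insertion `start`/`end` are the flanking
#' positions and `end == start + 1`), `ref` (reference residues, empty for an
#' insertion) and `alt` (replacement residues, empty for a deletion). Rows are
#' kept sorted by `start` and must not overlap.
#'
#' @param kind,start,end,ref,alt Parallel vectors describing the descriptors.
#' @return A validated difference-set tibble sorted by `start`.
#' @examples
#' difference_set(kind = "substitution", start = 417, end = 417, ref = "K", alt = "R")
#' @export
difference_set <- function(kind = character(), start = integer(),
                           end = integer(), ref = character(),
                           alt = character()) {
  ds <- tibble(kind = as.character(kind), start = as.integer(start),
               end = as.integer(end), ref = as.character(ref),
               alt = as.character(alt))
  ds <- ds[order(ds$start, ds$end), ]
  validate_differences(ds)
  ds
}

.empty_ds <- function() {
  tibble(kind = character(), start = integer(), end = integer(),
         ref = character(), alt = character())
}

#' Validate a difference set
#'
#' Checks per-kind shape invariants and pairwise non-overlap. When `seq` is
#' supplied the stated reference residues are verified against it
#' (a disagreement is a reference-mismatch error).
#'
#' @param ds Difference-set tibble.
#' @param seq Optional reference sequence to verify `ref` residues against.
#' @return `ds`, invisibly.
#' @export
validate_differences <- function(ds, seq = NULL) {
  for (k in seq_len(nrow(ds))) {
    d <- ds[k, ]
    bad <- switch(d$kind,
      substitution = !(d$start == d$end && nchar(d$ref) == 1L &&
                         nchar(d$alt) == 1L && d$ref != d$alt),
      deletion = !(nchar(d$alt) == 0L && nchar(d$ref) == d$end - d$start + 1L),
      insertion = !(nchar(d$ref) == 0L && nchar(d$alt) >= 1L &&
                      d$end == d$start + 1L),
      delins = !(nchar(d$ref) == d$end - d$start + 1L && nchar(d$ref) >= 1L &&
                   nchar(d$alt) >= 1L &&
                   !(nchar(d$ref) == 1L && nchar(d$alt) == 1L)),
      TRUE)
    if (isTRUE(bad)) {
      abort(sprintf("invalid %s descriptor at %d-%d (ref '%s', alt '%s')",
                    d$kind, d$start, d$end, d$ref, d$alt))
    }
    if (!is.null(seq) && d$kind != "insertion") {
      actual <- substr(.seq_of(seq), d$start, d$end)
      if (actual != d$ref) {
        abort(sprintf("reference mismatch at %d-%d: descriptor states '%s', sequence has '%s'",
                      d$start, d$end, d$ref, actual))
      }
    }
  }
  if (nrow(ds) > 1L) {
    # an insertion occupies the boundary between start and start + 1
    lo <- ifelse(ds$kind == "insertion", ds$start + 0.5, ds$start)
    hi <- ifelse(ds$kind == "insertion", ds$start + 0.5, ds$end)
    o <- order(lo, hi)
    if (any(lo[o][-1] <= hi[o][-length(o)])) {
      abort("overlapping descriptors in difference set")
    }
  }
  invisible(ds)
}

#' Render descriptors as HGVS p. short forms
#'
#' Uses one-letter amino-acid codes throughout. Deletions are rendered in
#' named form (`p.A428del`, `p.G266_S273del`), insertions and
#' deletion-insertions in positional form (`p.345_346insA`,
#' `p.385_428delinsT`), substitutions as `p.K417R`.
#'
#' @param ds Difference-set tibble.
#' @return Character vector, one HGVS string per row.
#' @export
hgvs_render <- function(ds) {
  vapply(seq_len(nrow(ds)), function(k) {
    d <- ds[k, ]
    switch(d$kind,
      substitution = sprintf("p.%s%d%s", d$ref, d$start, d$alt),
      deletion = if (d$start == d$end) {
        sprintf("p.%s%ddel", d$ref, d$start)
      } else {
        sprintf("p.%s%d_%s%ddel", substr(d$ref, 1, 1), d$start,
                substr(d$ref, nchar(d$ref), nchar(d$ref)), d$end)
      },
      insertion = sprintf("p.%d_%dins%s", d$start, d$end, d$alt),
      delins = sprintf("p.%d_%ddelins%s", d$start, d$end, d$alt)
    )
  }, character(1))
}

#' Parse HGVS p. short-form strings into descriptors
#'
#' Accepted shapes mirror the rendering convention: `p.K417R`, `p.A428del`,
#' `p.G266_S273del`, `p.345_346insA`, `p.385_428delinsT`. Reference residues
#' are filled in from `canonical`; any residue named in the string that
#' disagrees with the canonical at that position is a reference-mismatch
#' error.
#'
#' @param x Character vector of HGVS strings.
#' @param canonical Reference the coordinates refer to (defaults to the
#'   packaged canonical CD44 sequence).
#' @return A difference-set tibble, one row per input string, sorted by
#'   position.
#' @examples
#' hgvs_parse(c("p.K417R", "p.385_428delinsT"))
#' @export
hgvs_parse <- function(x, canonical = cd44_canonical()) {
  seq <- .seq_of(canonical)
  n <- nchar(seq)
  one <- function(s) {
    check_pos <- function(p) {
      if (p < 1L || p > n) abort(sprintf("'%s': position %d outside 1..%d", s, p, n))
      p
    }
    check_ref <- function(named, p) {
      actual <- substr(seq, p, p)
      if (named != actual) {
        abort(sprintf("'%s': reference mismatch at %d (stated %s, canonical has %s)",
                      s, p, named, actual))
      }
    }
    if (grepl("^p\\.([A-Z])(\\d+)_([A-Z])(\\d+)del$", s)) {
      m <- regmatches(s, regexec("^p\\.([A-Z])(\\d+)_([A-Z])(\\d+)del$", s))[[1]]
      st <- check_pos(as.integer(m[3])); en <- check_pos(as.integer(m[5]))
      if (st > en) abort(sprintf("'%s': start after end", s))
      check_ref(m[2], st); check_ref(m[4], en)
      tibble(kind = "deletion", start = st, end = en,
             ref = substr(seq, st, en), alt = "")
    } else if (grepl("^p\\.([A-Z])(\\d+)del$", s)) {
      m <- regmatches(s, regexec("^p\\.([A-Z])(\\d+)del$", s))[[1]]
      st <- check_pos(as.integer(m[3]))
      check_ref(m[2], st)
      tibble(kind = "deletion", start = st, end = st,
             ref = substr(seq, st, st), alt = "")
    } else if (grepl("^p\\.(\\d+)_(\\d+)ins([A-Z]+)$", s)) {
      m <- regmatches(s, regexec("^p\\.(\\d+)_(\\d+)ins([A-Z]+)$", s))[[1]]
      st <- check_pos(as.integer(m[2])); en <- check_pos(as.integer(m[3]))
      if (en != st + 1L) abort(sprintf("'%s': insertion flanks must be adjacent", s))
      tibble(kind = "insertion", start = st, end = en, ref = "", alt = m[4])
    } else if (grepl("^p\\.(\\d+)[_-](\\d+)delins([A-Z]+)$", s)) {
      m <- regmatches(s, regexec("^p\\.(\\d+)[_-](\\d+)delins([A-Z]+)$", s))[[1]]
      st <- check_pos(as.integer(m[2])); en <- check_pos(as.integer(m[3]))
      if (st > en) abort(sprintf("'%s': start after end", s))
      ref <- substr(seq, st, en)
      if (st == en && nchar(m[4]) == 1L) {
        if (m[4] == ref) abort(sprintf("'%s': not a variant", s))
        tibble(kind = "substitution", start = st, end = en, ref = ref, alt = m[4])
      } else {
        tibble(kind = "delins", start = st, end = en, ref = ref, alt = m[4])
      }
    } else if (grepl("^p\\.([A-Z])(\\d+)([A-Z])$", s)) {
      m <- regmatches(s, regexec("^p\\.([A-Z])(\\d+)([A-Z])$", s))[[1]]
      st <- check_pos(as.integer(m[3]))
      check_ref(m[2], st)
      if (m[2] == m[4]) abort(sprintf("'%s': not a variant (identical residues)", s))
      tibble(kind = "substitution", start = st, end = st, ref = m[2], alt = m[4])
    } else {
      abort(sprintf("cannot parse HGVS descriptor '%s'", s))
    }
  }
  ds <- dplyr::bind_rows(lapply(x, one))
  ds <- ds[order(ds$start, ds$end), ]
  validate_differences(ds, seq)
  ds
}

#' Apply a difference set to a reference sequence
#'
#' Edits are applied in descending start order so earlier coordinates never
#' shift. The result length is `nchar(seq) - sum(nchar(ref)) +
#' sum(nchar(alt))`. Stated reference residues must match `seq`
#' (reference-mismatch error otherwise); overlapping descriptors are an
#' error.
#'
#' @param ds Difference-set tibble.
#' @param seq Reference sequence (string or `canonical_reference`).
#' @return The edited sequence string.
#' @examples
#' nchar(hgvs_apply(hgvs_parse("p.223_604delinsR"), cd44_canonical()))
#' @export
hgvs_apply <- function(ds, seq = cd44_canonical()) {
  s <- .seq_of(seq)
  validate_differences(ds, s)
  for (k in rev(order(ds$start, ds$end))) {
    d <- ds[k, ]
    if (d$kind == "insertion") {
      s <- paste0(substr(s, 1, d$start), d$alt,
                  substr(s, d$start + 1L, nchar(s)))
    } else {
      s <- paste0(substr(s, 1, d$start - 1L), d$alt,
                  substr(s, d$end + 1L, nchar(s)))
    }
  }
  s
}

# rightmost minimal single-edit difference between `a` and its edited form `b`:
# maximise the common prefix, then the common suffix of the remainder
.diff_minimal <- function(a, b) {
  if (a == b) return(.empty_ds())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  lim <- min(na, nb)
  neq <- which(av[seq_len(lim)] != bv[seq_len(lim)])
  p <- if (length(neq) == 0L) lim else neq[1] - 1L
  slim <- lim - p
  sneq <- which(av[na - seq_len(slim) + 1L] != bv[nb - seq_len(slim) + 1L])
  s <- if (length(sneq) == 0L) slim else sneq[1] - 1L
  ref <- substr(a, p + 1L, na - s)
  alt <- substr(b, p + 1L, nb - s)
  if (nchar(ref) == 0L) {
    if (p == 0L) {
      # N-terminal extension; represent as a delins on the first residue
      return(difference_set("delins", 1L, 1L, substr(a, 1, 1),
                            paste0(alt, substr(a, 1, 1))))
    }
    difference_set("insertion", p, p + 1L, "", alt)
  } else if (nchar(alt) == 0L) {
    difference_set("deletion", p + 1L, na - s, ref, "")
  } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
    difference_set("substitution", p + 1L, p + 1L, ref, alt)
  } else {
    difference_set("delins", p + 1L, na - s, ref, alt)
  }
}

#' Normalize variant descriptors
#'
#' Under mode `"hgvs3"` each descriptor is rewritten as the
#' highest-coordinate (most C-terminal) representation among all descriptors
#' producing the same edited sequence — the 3'-rule. This shifts ambiguous
#' deletions/insertions within repeat runs (deleting one A of the canonical
#' 427-429 AAA run becomes `p.A429del`) and reduces delins descriptors that
#' share residues with the reference. Mode `"as-deposited"` returns
#' descriptors unchanged, for echoing database-deposited forms such as
#' `p.A428del`.
#'
#' Two descriptors are equivalent exactly when applying them yields identical
#' strings; `"hgvs3"` maps every equivalence class to one representative.
#'
#' @param ds Difference-set tibble.
#' @param seq Reference sequence the descriptors are expressed against.
#' @param mode `"hgvs3"` (default) or `"as-deposited"`.
#' @return A difference-set tibble.
#' @export
hgvs_normalize <- function(ds, seq = cd44_canonical(),
                           mode = c("hgvs3", "as-deposited")) {
  mode <- match.arg(mode)
  s <- .seq_of(seq)
  validate_differences(ds, s)
  if (mode == "as-deposited" || nrow(ds) == 0L) return(ds)
  norm <- dplyr::bind_rows(lapply(seq_len(nrow(ds)), function(k) {
    edited <- hgvs_apply(ds[k, ], s)
    nd <- .diff_minimal(s, edited)
    if (nrow(nd) == 0L) ds[k, ] else nd
  }))
  norm <- norm[order(norm$start, norm$end), ]
  # a 3' shift may in rare repeat contexts slide a descriptor onto its
  # neighbour; keep the original representation for the offenders
  ok <- tryCatch({ validate_differences(norm); TRUE }, error = function(e) FALSE)
  if (!ok) return(ds)
  norm
}

#' Extract variant descriptors from a pairwise alignment
#'
#' Partitions the alignment columns into maximal blocks of non-identity
#' columns (gap columns together with mismatch columns strictly contiguous to
#' them) and converts each block into one descriptor: pure query-side gaps
#' become a deletion, pure reference-side gaps an insertion, mixed blocks a
#' delins, and an isolated mismatch a substitution. Coordinates refer to the
#' reference (canonical) sequence. The result is normalized under the given
#' mode (3'-rule by default).
#'
#' @param aln A `protein_alignment` from [global_align()] with the canonical
#'   as reference.
#' @param mode Normalization mode passed to [hgvs_normalize()].
#' @return A difference-set tibble.
#' @examples
#' ref <- cd44_canonical()
#' iso <- hgvs_apply(hgvs_parse("p.K417R"), ref)
#' extract_differences(global_align(ref, iso))
#' @export
extract_differences <- function(aln, mode = c("hgvs3", "as-deposited")) {
  mode <- match.arg(mode)
  rv <- strsplit(aln$aligned_ref, "")[[1]]
  qv <- strsplit(aln$aligned_query, "")[[1]]
  if (length(rv) != length(qv)) abort("malformed alignment: unequal row lengths")
  if (any(rv == "-" & qv == "-")) abort("malformed alignment: gap-in-both column")
  ref_seq <- gsub("-", "", aln$aligned_ref, fixed = TRUE)
  ref_pos <- cumsum(rv != "-")          # canonical position at/left of column
  is_diff <- !(rv != "-" & qv != "-" & rv == qv)
  if (!any(is_diff)) return(.empty_ds())
  r <- rle(is_diff)
  block_end <- cumsum(r$lengths)
  block_start <- block_end - r$lengths + 1L
  blocks <- which(r$values)
  ds <- dplyr::bind_rows(lapply(blocks, function(b) {
    cols <- block_start[b]:block_end[b]
    ref_part <- paste(rv[cols][rv[cols] != "-"], collapse = "")
    alt_part <- paste(qv[cols][qv[cols] != "-"], collapse = "")
    if (nchar(ref_part) == 0L) {
      p <- ref_pos[cols[1]]            # flanking position left of the block
      if (p == 0L) {
        # leading insertion before residue 1: delins on the first residue
        return(tibble(kind = "delins", start = 1L, end = 1L,
                      ref = substr(ref_seq, 1, 1),
                      alt = paste0(alt_part, substr(ref_seq, 1, 1))))
      }
      tibble(kind = "insertion", start = p, end = p + 1L, ref = "", alt = alt_part)
    } else {
      st <- ref_pos[cols[rv[cols] != "-"][1]]
      en <- st + nchar(ref_part) - 1L
      if (nchar(alt_part) == 0L) {
        tibble(kind = "deletion", start = st, end = en, ref = ref_part, alt = "")
      } else if (nchar(ref_part) == 1L && nchar(alt_part) == 1L) {
        tibble(kind = "substitution", start = st, end = en, ref = ref_part,
               alt = alt_part)
      } else {
        tibble(kind = "delins", start = st, end = en, ref = ref_part,
               alt = alt_part)
      }
    }
  }))
  ds <- ds[order(ds$start, ds$end), ]
  validate_differences(ds, ref_seq)
  hgvs_normalize(ds, ref_seq, mode)
}
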