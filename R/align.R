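#' Scoring parameters for global alignment
#'
#' Identity scoring is used rather than a substitution matrix: the sequences
#' compared here are isoforms of a single gene, so residue-similarity scores
#' would only blur the distinction between point substitutions (which should
#' align as mismatch columns) and splice events (which should align as gap
#' runs). The steep gap-open / shallow gap-extend ratio strongly favours one
#' long contiguous gap over scattered short gaps, so a spliced-out multi-exon
#' block appears as a single gap run.
#'
#' @param match Score for an identical residue pair (default 2). `X` never
#'   counts as a match.
#' @param mismatch Score for a non-identical pair (default -3).
#' @param gap_open Score for the first column of a gap run (default -12).
#' @param gap_extend Score for each further column (default -0.5).
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(match = 2, mismatch = -3, gap_open = -12,
                           gap_extend = -0.5) {
  if (!(gap_open <= gap_extend && gap_extend <= 0 && match > 0 && mismatch < 0)) {
    abort("require gap_open <= gap_extend <= 0 < match and mismatch < 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_params")
}

#' Global pairwise alignment with affine gaps
#'
#' Deterministic Needleman-Wunsch alignment with affine gap runs (Gotoh
#' recursion). Among co-optimal alignments the traceback prefers the one
#' whose gap runs sit at the highest (most C-terminal) coordinates, so
#' descriptor extraction lands directly on 3'-normalized HGVS coordinates in
#' most cases. End gaps are charged normally; partial sequences are detected
#' downstream via coverage, not by free end gaps.
#'
#' @param ref Reference sequence (string or `canonical_reference`).
#' @param query Query sequence.
#' @param params A [scoring_params()] object.
#' @return A `protein_alignment`: list with `aligned_ref`, `aligned_query`
#'   (equal-length strings with `-` gaps, no column gap in both), `score`,
#'   and `params`.
#' @examples
#' global_align("ACDEFG", "ACDFG")
#' @export
global_align <- function(ref, query, params = scoring_params()) {
  r <- .seq_of(ref); q <- .seq_of(query)
  if (!nzchar(r) || !nzchar(q)) abort("sequences must be non-empty")
  res <- .gotoh_align(r, q, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(list(aligned_ref = res$aligned_ref,
                 aligned_query = res$aligned_query,
                 score = res$score, params = params),
            class = "protein_alignment")
}

#' Alignment coverage on both rows
#'
#' Fraction of residues of each sequence sitting in gap-free columns.
#' A query that is an exact prefix of the reference has query coverage 1 but
#' reference coverage below 1; low query coverage signals a divergent
#' sequence, low reference coverage a partial record.
#'
#' @param aln A `protein_alignment`.
#' @return A one-row tibble with `query_coverage` and `ref_coverage`,
#'   both in `[0, 1]`.
#' @export
alignment_coverage <- function(aln) {
  rv <- strsplit(aln$aligned_ref, "")[[1]]
  qv <- strsplit(aln$aligned_query, "")[[1]]
  both <- sum(rv != "-" & qv != "-")
  tibble(query_coverage = both / sum(qv != "-"),
         ref_coverage = both / sum(rv != "-"))
}

#' Gap runs of an alignment
#'
#' @param aln A `protein_alignment`.
#' @return Tibble with one row per maximal gap run: `row` (`"ref"` or
#'   `"query"`), `col_start`, `col_end`, `length`.
#' @export
gap_runs <- function(aln) {
  runs_of <- function(s, row) {
    v <- strsplit(s, "")[[1]] == "-"
    if (!any(v)) return(NULL)
    r <- rle(v)
    e <- cumsum(r$lengths); b <- e - r$lengths + 1L
    keep <- which(r$values)
    tibble(row = row, col_start = b[keep], col_end = e[keep],
           length = r$lengths[keep])
  }
  out <- dplyr::bind_rows(runs_of(aln$aligned_query, "query"),
                          runs_of(aln$aligned_ref, "ref"))
  if (nrow(out) == 0L) {
    return(tibble(row = character(), col_start = integer(),
                  col_end = integer(), length = integer()))
  }
  out[order(out$col_start), ]
}

#' @export
print.protein_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("<protein_alignment> score %.1f, %d columns\n",
              x$score, nchar(x$aligned_ref)))
  rv <- strsplit(x$aligned_ref, "")[[1]]
  qv <- strsplit(x$aligned_query, "")[[1]]
  mk <- ifelse(rv == qv & rv != "-" & rv != "X", "|",
               ifelse(rv == "-" | qv == "-", " ", "."))
  for (b in seq(1L, length(rv), by = width)) {
    e <- min(b + width - 1L, length(rv))
    cat("ref   ", paste(rv[b:e], collapse = ""), "\n")
    cat("      ", paste(mk[b:e], collapse = ""), "\n")
    cat("query ", paste(qv[b:e], collapse = ""), "\n\n")
  }
  invisible(x)
}

#' Tidy an alignment into variant descriptors
#'
#' Broom-style accessor: equivalent to [extract_differences()] with default
#' normalization.
#'
#' @param x A `protein_alignment`.
#' @param ... Unused.
#' @return A difference-set tibble.
#' @export
tidy.protein_alignment <- function(x, ...) {
  extract_differences(x)
}

#' One-row alignment summary
#'
#' @param x A `protein_alignment`.
#' @param ... Unused.
#' @return Tibble with score, column count, identity, coverages and the
#'   number of gap runs.
#' @export
glance.protein_alignment <- function(x, ...) {
  rv <- strsplit(x$aligned_ref, "")[[1]]
  qv <- strsplit(x$aligned_query, "")[[1]]
  cov <- alignment_coverage(x)
  tibble(score = x$score,
         n_columns = length(rv),
         identity = sum(rv == qv & rv != "-" & rv != "X") / length(rv),
         query_coverage = cov$query_coverage,
         ref_coverage = cov$ref_coverage,
         n_gap_runs = nrow(gap_runs(x)))
}

#' Plot an alignment column classification
#'
#' Tile strip along the alignment marking match, mismatch, and gap columns —
#' a quick visual check that a splice-out appears as one contiguous gap run.
#'
#' @param object A `protein_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_alignment <- function(object, ...) {
  rv <- strsplit(object$aligned_ref, "")[[1]]
  qv <- strsplit(object$aligned_query, "")[[1]]
  cls <- ifelse(rv == "-", "insertion (gap in ref)",
                ifelse(qv == "-", "deletion (gap in query)",
                       ifelse(rv == qv & rv != "X", "match", "mismatch")))
  df <- tibble(column = seq_along(rv), class = cls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = 1, fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "alignment column", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
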