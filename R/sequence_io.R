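#' Read protein records from a FASTA file
#'
#' Parses a protein FASTA file into a tibble of records. Accessions are taken
#' from the first whitespace-delimited header token, split on `|` so that both
#' NCBI (`NP_000601.3`) and UniProt (`sp|P16070|CD44_HUMAN`) header dialects
#' yield their accession strings without any network lookup. Sequences are
#' upper-cased and a single trailing `*` (stop) is stripped; any character
#' outside the 20 standard one-letter codes or `X` is an error naming the
#' record and position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `record_id` (first header token),
#'   `description` (full header), `accessions` (list of character vectors),
#'   `sequence`, and `is_partial_hint` (`TRUE` when the header mentions
#'   "partial"). Positions in `sequence` are 1-based and inclusive everywhere
#'   in this package.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">NP_000601.3 CD44", "MDKFWWHAAW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  first_tok <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  recs <- tibble(
    record_id = first_tok,
    description = headers,
    accessions = lapply(first_tok, function(tok) {
      acc <- strsplit(tok, "|", fixed = TRUE)[[1]]
      unique(acc[nzchar(acc)])
    }),
    sequence = unname(seqs),
    is_partial_hint = grepl("partial", headers, ignore.case = TRUE)
  )
  for (k in seq_len(nrow(recs))) {
    if (!nzchar(recs$sequence[k])) {
      abort(sprintf("record '%s': empty sequence", recs$record_id[k]))
    }
    .check_residues(recs$sequence[k], recs$record_id[k])
  }
  recs
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(records))` reproduces
#' ids and sequences exactly.
#'
#' @param records Tibble with at least `record_id` and `sequence` columns
#'   (a `description` column, when present, is used as the full header).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  headers <- if ("description" %in% names(records)) records$description else records$record_id
  lines <- character(0)
  for (k in seq_len(nrow(records))) {
    s <- records$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, paste0(">", headers[k]),
               substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

.cd44iso_cache <- new.env(parent = emptyenv())

#' The canonical full-length CD44 reference sequence
#'
#' Returns the packaged 742-residue canonical human CD44 sequence
#' (NP_000601.3 / P16070-1), the isoform containing all nine variable exons,
#' against which every descriptor coordinate in this package is expressed.
#' The fixture is validated at load (length exactly 742, initial methionine,
#' standard residues only) and the returned object is constant across calls.
#'
#' @return An object of class `canonical_reference`: a list with elements
#'   `name` and `sequence`.
#' @examples
#' nchar(cd44_canonical()$sequence)
#' @export
cd44_canonical <- function() {
  if (!is.null(.cd44iso_cache$canonical)) return(.cd44iso_cache$canonical)
  path <- system.file("extdata", "cd44_canonical.fasta", package = "cd44iso",
                      mustWork = TRUE)
  rec <- read_fasta(path)
  seq <- rec$sequence[1]
  if (nchar(seq) != .CANONICAL_LENGTH || substr(seq, 1, 1) != "M" ||
      !all(strsplit(seq, "")[[1]] %in% .AA20)) {
    abort("packaged canonical reference is corrupted")
  }
  ref <- structure(list(name = rec$record_id[1], sequence = seq),
                   class = "canonical_reference")
  .cd44iso_cache$canonical <- ref
  ref
}

#' @export
print.canonical_reference <- function(x, ...) {
  cat(sprintf("<canonical_reference> %s (%d aa)\n%s...\n",
              x$name, nchar(x$sequence), substr(x$sequence, 1, 30)))
  invisible(x)
}

#' Load the exon-splice event catalogue
#'
#' Each catalogue entry names one alternative-splicing event as its footprint
#' on the canonical protein: the replaced canonical range (1-based inclusive)
#' and the short junction insert that takes its place (empty for a pure
#' deletion). The packaged default covers the recognised CD44 splice-out
#' patterns, from single variable exons (V2, V6, V9, V10) through multi-exon
#' blocks (V2-V7, V2-V10, ...) to whole-tail replacements and the two
#' microexon events within exons 5 and V3.
#'
#' @param path Optional path to a TSV with columns `name`, `replaced_start`,
#'   `replaced_end`, `insert` (and optionally `source_note`). `NULL` loads the
#'   packaged catalogue.
#' @return A tibble of splice events, unique on (range, insert). Row order
#'   follows the file, but every operation that consumes the catalogue is
#'   order-independent.
#' @examples
#' load_event_catalogue() |> dplyr::filter(replaced_start == 223)
#' @export
load_event_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cd44_splice_events.tsv",
                                package = "cd44iso", mustWork = TRUE)
  cat_tbl <- readr::read_tsv(
    path, na = character(),
    col_types = readr::cols(
      name = readr::col_character(),
      replaced_start = readr::col_integer(),
      replaced_end = readr::col_integer(),
      insert = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("name", "replaced_start", "replaced_end", "insert")
  if (!all(need %in% names(cat_tbl))) {
    abort(sprintf("event catalogue must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (!"source_note" %in% names(cat_tbl)) cat_tbl$source_note <- ""
  cat_tbl$insert[is.na(cat_tbl$insert)] <- ""
  bad <- cat_tbl$replaced_start < 1L | cat_tbl$replaced_end > .CANONICAL_LENGTH |
    cat_tbl$replaced_start > cat_tbl$replaced_end
  if (any(bad)) {
    abort(sprintf("event '%s': replaced range %d-%d outside 1..%d",
                  cat_tbl$name[which(bad)[1]],
                  cat_tbl$replaced_start[which(bad)[1]],
                  cat_tbl$replaced_end[which(bad)[1]], .CANONICAL_LENGTH))
  }
  key <- paste(cat_tbl$replaced_start, cat_tbl$replaced_end, cat_tbl$insert)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate catalogue entry: %s", key[duplicated(key)][1]))
  }
  for (k in seq_len(nrow(cat_tbl))) {
    if (nzchar(cat_tbl$insert[k])) .check_residues(cat_tbl$insert[k], cat_tbl$name[k], allow_x = FALSE)
  }
  cat_tbl[, c(need, "source_note")]
}

#' Load the catalogue of alternative C-terminal endings
#'
#' The known alternative C-termini observed among deposited CD44 isoforms:
#' sequence suffixes that do not align to the canonical long or short tail.
#'
#' @param path Optional TSV path (columns `abbreviation`, `accessions`,
#'   `ending`); `NULL` loads the packaged list.
#' @return A tibble with one row per known alternative ending.
#' @export
load_tail_endings <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cd44_tail_endings.tsv",
                                package = "cd44iso", mustWork = TRUE)
  tbl <- readr::read_tsv(path, na = character(),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- cd44_canonical()$sequence
  if (any(vapply(tbl$ending, function(e) endsWith(canonical, e), logical(1)))) {
    abort("tail-ending catalogue contains a canonical suffix")
  }
  tbl
}

#' Write a classification report as TSV
#'
#' Serialises classification results (see [classify_isoforms()]) into a flat
#' Table-1-style report. List columns are collapsed with `;`; row order is the
#' input order.
#'
#' @param results Classification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(results, path) {
  collapse <- function(x) purrr::map_chr(x, paste, collapse = ";")
  flat <- tibble(
    record_id = as.character(results$record_id),
    accessions = collapse(results$accessions),
    length = as.integer(results$length),
    group_key = as.character(results$group_key),
    events = collapse(results$matched_events),
    residual_variants = vapply(results$residual_variants, function(ds) {
      if (is.null(ds) || nrow(ds) == 0L) "" else paste(hgvs_render(ds), collapse = ";")
    }, character(1)),
    tail_class = as.character(results$tail_class),
    flags = collapse(results$flags)
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Write full classification results as JSON
#'
#' @param results Classification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(results, path) {
  out <- lapply(seq_len(nrow(results)), function(k) {
    r <- results[k, ]
    list(
      record_id = r$record_id,
      accessions = r$accessions[[1]],
      length = r$length,
      group_key = r$group_key,
      matched_events = r$matched_events[[1]],
      novel_events = r$novel_events[[1]],
      residual_variants = if (nrow(r$residual_variants[[1]]) > 0L)
        hgvs_render(r$residual_variants[[1]]) else character(0),
      tail_class = r$tail_class,
      c_terminal_segment = r$c_terminal_segment,
      flags = r$flags[[1]]
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
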