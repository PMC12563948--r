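#' Describe a genomic exon with flanking context
#'
#' Coordinates are local to the supplied string (1-based inclusive); no
#' genome-assembly coordinates are used. `phase` is the codon offset at the
#' exon start (0, 1 or 2). At least 2 nt of flanking intron context is
#' required on each side so canonical splice dinucleotides are visible.
#'
#' @param exon_id Label.
#' @param dna Upper-case A/C/G/T string: the exon plus flanking context.
#' @param exon_start_in_string,exon_end_in_string Exon body coordinates
#'   within `dna`.
#' @param phase Codon offset at exon start (0/1/2).
#' @param flank Recorded flanking context length (defaults to the left
#'   flank implied by `exon_start_in_string`).
#' @return A one-row exon tibble.
#' @export
genomic_exon <- function(exon_id, dna, exon_start_in_string,
                         exon_end_in_string, phase = 0L, flank = NULL) {
  dna <- toupper(dna)
  if (grepl("[^ACGT]", dna)) abort("genomic sequence must contain only A/C/G/T")
  n <- nchar(dna)
  st <- as.integer(exon_start_in_string); en <- as.integer(exon_end_in_string)
  if (st < 3L || en > n - 2L || st > en) {
    abort("exon coordinates must leave at least 2 nt of flanking context inside the string")
  }
  if (!phase %in% 0:2) abort("phase must be 0, 1 or 2")
  tibble(exon_id = exon_id, dna = dna, exon_start_in_string = st,
         exon_end_in_string = en, phase = as.integer(phase),
         flank = as.integer(flank %||% (st - 1L)))
}

.as_exon_row <- function(exon) {
  if (is.data.frame(exon)) {
    if (nrow(exon) != 1L) abort("expected a single exon row")
    exon <- as.list(exon)
  }
  if (grepl("[^ACGT]", exon$dna)) abort("genomic sequence must contain only A/C/G/T")
  exon
}

#' Scan an exon for internal splice-site dinucleotides
#'
#' Enumerates every internal position of the exon body where the
#' site-defining dinucleotide occurs: `AG` immediately 5' of a candidate new
#' exon start (alternative acceptor) or `GT` immediately 3' of a candidate
#' new exon end (alternative donor). Only the minimal dinucleotide rule is
#' applied — no position-weight or MaxEnt scoring — because the biological
#' claim such a scan supports is the bare existence of a competing site.
#' Candidates never overlap the flanking intron context.
#'
#' @param exon One-row exon tibble (see [genomic_exon()]).
#' @param site_kind `"acceptor"` or `"donor"`.
#' @return Tibble with `exon_id`, `site_kind`, `offset_nt` (nucleotides
#'   trimmed from the 5' (acceptor) or 3' (donor) end of the exon),
#'   `dinucleotide`, `trimmed_codons` (offset / 3, possibly fractional),
#'   `phase_consistent` (whole-codon trim), sorted by offset.
#' @export
scan_splice_sites <- function(exon, site_kind = c("acceptor", "donor")) {
  site_kind <- match.arg(site_kind)
  e <- .as_exon_row(exon)
  body <- substr(e$dna, e$exon_start_in_string, e$exon_end_in_string)
  len <- nchar(body)
  empty <- tibble(exon_id = character(), site_kind = character(),
                  offset_nt = integer(), dinucleotide = character(),
                  trimmed_codons = numeric(), phase_consistent = logical())
  if (len < 3L) return(empty)
  bv <- strsplit(body, "")[[1]]
  if (site_kind == "acceptor") {
    # new start at body offset o + 1; AG occupies body positions o-1, o
    offs <- which(bv[-len] == "A" & bv[-1] == "G") + 1L
    offs <- offs[offs >= 2L & offs <= len - 1L]
    di <- "AG"
  } else {
    # new end at body position len - o; GT occupies positions len-o+1, len-o+2
    gt_at <- which(bv[-len] == "G" & bv[-1] == "T")
    offs <- len - gt_at + 1L
    offs <- sort(offs[offs >= 2L & offs <= len - 1L])
    di <- "GT"
  }
  if (length(offs) == 0L) return(empty)
  tibble(exon_id = e$exon_id, site_kind = site_kind, offset_nt = offs,
         dinucleotide = di, trimmed_codons = offs / 3,
         phase_consistent = offs %% 3L == 0L)
}

#' Find alternative splice acceptors matching a protein-level trim
#'
#' Returns the internal `AG` positions whose use as an alternative acceptor
#' would trim exactly `target_trim_aa` whole residues from the 5' end of the
#' exon's peptide (offset of 3 x target nucleotides; a whole-codon trim
#' leaves the exon phase unchanged).
#'
#' @param exon One-row exon tibble.
#' @param target_trim_aa Number of residues the protein-level descriptor
#'   removes (>= 1).
#' @return Candidate tibble as in [scan_splice_sites()] with an extra
#'   `trimmed_peptide_length` column, sorted by offset.
#' @export
find_alternative_acceptors <- function(exon, target_trim_aa) {
  if (target_trim_aa < 1L) abort("target_trim_aa must be >= 1")
  hits <- scan_splice_sites(exon, "acceptor")
  hits <- hits[hits$offset_nt == 3L * target_trim_aa, , drop = FALSE]
  hits$trimmed_peptide_length <- if (nrow(hits) > 0L) as.numeric(target_trim_aa) else numeric(0)
  hits
}

#' Find alternative splice donors matching a protein-level trim
#'
#' Mirror of [find_alternative_acceptors()] for internal `GT` dinucleotides
#' immediately 3' of a candidate new exon end.
#'
#' @inheritParams find_alternative_acceptors
#' @return Candidate tibble, sorted by offset.
#' @export
find_alternative_donors <- function(exon, target_trim_aa) {
  if (target_trim_aa < 1L) abort("target_trim_aa must be >= 1")
  hits <- scan_splice_sites(exon, "donor")
  hits <- hits[hits$offset_nt == 3L * target_trim_aa, , drop = FALSE]
  hits$trimmed_peptide_length <- if (nrow(hits) > 0L) as.numeric(target_trim_aa) else numeric(0)
  hits
}

#' Tabulate splice-site candidates with consistency verdicts
#'
#' One row per candidate with a verdict against the protein-level
#' observation: `consistent` when the trim removes whole codons matching the
#' expected residue count, `phase-shift` when the trimmed nucleotides do not
#' divide into whole codons (reported, never silently dropped), and
#' `inconsistent` for whole-codon trims of the wrong size.
#'
#' @param candidates Candidate tibble ([scan_splice_sites()] or the
#'   `find_alternative_*` functions).
#' @param protein_trim_aa Optional expected residue trim from the
#'   protein-level descriptor.
#' @return Report tibble (`exon_id`, `site_kind`, `offset_nt`,
#'   `trimmed_codons`, `verdict`).
#' @export
microexon_report <- function(candidates, protein_trim_aa = NULL) {
  if (nrow(candidates) == 0L) {
    return(tibble(exon_id = character(), site_kind = character(),
                  offset_nt = integer(), trimmed_codons = numeric(),
                  verdict = character()))
  }
  verdict <- ifelse(!candidates$phase_consistent, "phase-shift",
                    if (is.null(protein_trim_aa)) "consistent"
                    else ifelse(candidates$trimmed_codons == protein_trim_aa,
                                "consistent", "inconsistent"))
  tibble(exon_id = candidates$exon_id, site_kind = candidates$site_kind,
         offset_nt = candidates$offset_nt,
         trimmed_codons = candidates$trimmed_codons, verdict = verdict)
}

#' Read genomic exons from FASTA plus a BED-like exon table
#'
#' @param fasta_path DNA FASTA (one record per fragment).
#' @param tsv_path TSV with columns `exon_id`, `fragment` (FASTA record id),
#'   `exon_start_in_string`, `exon_end_in_string`, `phase`, `flank`.
#' @return Exon tibble usable with the scanning functions.
#' @export
read_exon_table <- function(fasta_path, tsv_path) {
  frags <- read_fasta_dna(fasta_path)
  tbl <- readr::read_tsv(tsv_path, col_types = readr::cols(
    exon_id = readr::col_character(), fragment = readr::col_character(),
    exon_start_in_string = readr::col_integer(),
    exon_end_in_string = readr::col_integer(),
    phase = readr::col_integer(), flank = readr::col_integer()),
    progress = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(tbl)), function(k) {
    r <- tbl[k, ]
    dna <- frags$sequence[match(r$fragment, frags$record_id)]
    if (is.na(dna)) abort(sprintf("fragment '%s' not found in %s", r$fragment, fasta_path))
    genomic_exon(r$exon_id, dna, r$exon_start_in_string,
                 r$exon_end_in_string, r$phase, r$flank)
  }))
}

#' Read DNA records from FASTA
#'
#' @param path FASTA path.
#' @return Tibble with `record_id` and upper-case `sequence` (A/C/G/T/N).
#' @export
read_fasta_dna <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) abort(sprintf("record '%s': non-nucleotide characters", ids[which(bad)[1]]))
  tibble(record_id = ids, sequence = unname(seqs))
}
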