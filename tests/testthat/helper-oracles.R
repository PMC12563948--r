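# Independent alignment oracles, used only by the tests.

# score an explicit alignment (two gapped strings) under affine gap runs:
# a run of length L costs gap_open + (L - 1) * gap_extend
score_alignment <- function(ar, aq, params) {
  rv <- strsplit(ar, "")[[1]]; qv <- strsplit(aq, "")[[1]]
  sc <- 0; prev <- "M"
  for (k in seq_along(rv)) {
    state <- if (rv[k] == "-") "Y" else if (qv[k] == "-") "X" else "M"
    if (state == "M") {
      sc <- sc + if (rv[k] == qv[k] && rv[k] != "X") params$match else params$mismatch
    } else {
      sc <- sc + if (prev == state) params$gap_extend else params$gap_open
    }
    prev <- state
  }
  sc
}

# exhaustive enumeration of every global alignment of x and y
all_alignments <- function(x, y) {
  n <- nchar(x); m <- nchar(y)
  res <- list()
  rec <- function(i, j, ar, aq) {
    if (i > n && j > m) {
      res[[length(res) + 1L]] <<- c(ar, aq)
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1L, j + 1L, paste0(ar, substr(x, i, i)),
                              paste0(aq, substr(y, j, j)))
    if (i <= n) rec(i + 1L, j, paste0(ar, substr(x, i, i)), paste0(aq, "-"))
    if (j <= m) rec(i, j + 1L, paste0(ar, "-"), paste0(aq, substr(y, j, j)))
  }
  rec(1L, 1L, "", "")
  res
}

# brute-force optimal score by full enumeration (tiny sequences only)
enum_align_score <- function(x, y, params) {
  max(vapply(all_alignments(x, y),
             function(a) score_alignment(a[1], a[2], params), numeric(1)))
}

# memoized suffix recursion over (i, j, previous-column state); an
# independent formulation of the same optimum, feasible up to length ~8
memo_align_score <- function(x, y, params) {
  n <- nchar(x); m <- nchar(y)
  xv <- strsplit(x, "")[[1]]; yv <- strsplit(y, "")[[1]]
  memo <- array(NA_real_, dim = c(n + 1L, m + 1L, 3L))
  f <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j, prev])) return(memo[i, j, prev])
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (xv[i] == yv[j] && xv[i] != "X") params$match else params$mismatch
      best <- max(best, s + f(i + 1L, j + 1L, 1L))
    }
    if (i <= n) {
      g <- if (prev == 2L) params$gap_extend else params$gap_open
      best <- max(best, g + f(i + 1L, j, 2L))
    }
    if (j <= m) {
      g <- if (prev == 3L) params$gap_extend else params$gap_open
      best <- max(best, g + f(i, j + 1L, 3L))
    }
    memo[i, j, prev] <<- best
    best
  }
  f(1L, 1L, 1L)
}

random_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force splice-site scan over every dinucleotide position of the exon
oracle_splice_offsets <- function(exon, kind) {
  body <- substr(exon$dna, exon$exon_start_in_string, exon$exon_end_in_string)
  len <- nchar(body)
  want <- if (kind == "acceptor") "AG" else "GT"
  offs <- integer(0)
  for (o in 2:(len - 1L)) {
    di <- if (kind == "acceptor") substr(body, o - 1L, o)
          else substr(body, len - o + 1L, len - o + 2L)
    if (di == want) offs <- c(offs, o)
  }
  sort(offs)
}
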