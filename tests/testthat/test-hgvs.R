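test_that("rendering and parsing reproduce the guideline example strings", {
  for (s in table2_examples) {
    expect_equal(hgvs_render(hgvs_parse(s)), s)
  }
  # parse fills reference residues from the canonical
  d <- hgvs_parse("p.A428del")
  expect_equal(d$kind, "deletion")
  expect_equal(d$start, 428L)
  expect_equal(d$ref, "A")
  d2 <- hgvs_parse("p.385_428delinsT")
  expect_equal(nchar(d2$ref), 44L)
  expect_equal(d2$alt, "T")
})

test_that("parse rejects malformed and degenerate descriptors", {
  expect_error(hgvs_parse("p.K417K"), "not a variant")
  expect_error(hgvs_parse("p.A417R"), "reference mismatch")  # 417 is K
  expect_error(hgvs_parse("417KR"), "cannot parse")
  expect_error(hgvs_parse("p.0_1insA"), "outside")
  expect_error(hgvs_parse("p.345_347insA"), "adjacent")
  expect_error(hgvs_parse("p.K900R"), "outside")
})

test_that("parse-render is the identity on generated descriptors", {
  withr::local_seed(99L)
  gen <- generate_isoform_set(synthetic_config(seed = 31, n_isoforms = 30))
  for (k in seq_len(nrow(gen$truth))) {
    ds <- gen$truth$descriptors[[k]]
    if (nrow(ds) == 0) next
    strs <- hgvs_render(ds)
    re <- dplyr::bind_rows(lapply(strs, hgvs_parse))
    expect_equal(re[order(re$start), c("kind", "start", "end", "ref", "alt")],
                 ds[order(ds$start), c("kind", "start", "end", "ref", "alt")],
                 ignore_attr = TRUE)
  }
})

test_that("applying descriptors edits the sequence with exact length bookkeeping", {
  can <- cd44_canonical()
  expect_equal(hgvs_apply(cd44iso:::.empty_ds(), can), can$sequence)
  expect_equal(nchar(hgvs_apply(hgvs_parse("p.223_604delinsR"), can)), 361L)
  expect_equal(nchar(hgvs_apply(
    hgvs_parse(c("p.223_604delinsR", "p.675_742delinsS")), can)), 294L)

  # length conservation across generated difference sets
  gen <- generate_isoform_set(synthetic_config(seed = 17, n_isoforms = 25))
  for (k in which(!gen$truth$is_partial)) {
    ds <- gen$truth$descriptors[[k]]
    expect_equal(nchar(gen$records$sequence[k]),
                 742L - sum(nchar(ds$ref)) + sum(nchar(ds$alt)))
  }
})

test_that("apply rejects reference mismatches and overlaps", {
  can <- cd44_canonical()
  bad <- difference_set("substitution", 417, 417, "A", "R")  # 417 is K
  expect_error(hgvs_apply(bad, can), "reference mismatch")
  expect_error(
    difference_set(c("delins", "deletion"), c(385, 400), c(428, 400),
                   c(substr(can$sequence, 385, 428), substr(can$sequence, 400, 400)),
                   c("T", "")),
    "overlapping")
})

test_that("3'-normalization shifts ambiguous edits in repeat runs", {
  can <- cd44_canonical()
  # the canonical has an AAA run at 427-429: deleting any one A is equivalent
  d427 <- difference_set("deletion", 427, 427, "A", "")
  d428 <- hgvs_parse("p.A428del")
  d429 <- difference_set("deletion", 429, 429, "A", "")
  expect_equal(hgvs_apply(d427, can), hgvs_apply(d429, can))
  for (d in list(d427, d428, d429)) {
    expect_equal(hgvs_render(hgvs_normalize(d, can)), "p.A429del")
  }
  expect_equal(hgvs_render(hgvs_normalize(d428, can, mode = "as-deposited")),
               "p.A428del")

  # substitutions are never ambiguous
  sub <- hgvs_parse("p.K417R")
  expect_equal(hgvs_normalize(sub, can), sub)

  # insertion of A inside a poly-A run shifts to after the run's last A
  seq <- "MKAAAGW"
  ins2 <- difference_set("insertion", 3, 4, "", "A")
  ins_norm <- hgvs_normalize(ins2, seq)
  expect_equal(ins_norm$start, 5L)
  expect_equal(hgvs_apply(ins_norm, seq), hgvs_apply(ins2, seq))

  # the single-residue insertion at 345/346 sits in a non-repetitive context,
  # so both modes print the same form
  insA <- hgvs_parse("p.345_346insA")
  expect_equal(hgvs_render(hgvs_normalize(insA, can)), "p.345_346insA")
})

test_that("normalization maps equivalent descriptors to one representative", {
  # brute force on short sequences: every single-residue deletion/insertion
  # representation producing the same edited string must normalize identically
  withr::local_seed(55L)
  for (rep in 1:30) {
    seq <- paste(sample(c("A", "C", "D"), sample(6:15, 1), replace = TRUE),
                 collapse = "")
    n <- nchar(seq)
    p <- sample(n, 1)
    d <- difference_set("deletion", p, p, substr(seq, p, p), "")
    edited <- hgvs_apply(d, seq)
    # all equivalent single-deletion representations
    equiv <- Filter(Negate(is.null), lapply(seq_len(n), function(q) {
      dq <- difference_set("deletion", q, q, substr(seq, q, q), "")
      if (hgvs_apply(dq, seq) == edited) dq else NULL
    }))
    reps <- unique(vapply(equiv, function(dq)
      hgvs_render(hgvs_normalize(dq, seq)), character(1)))
    expect_length(reps, 1L)
    # the representative is the highest-coordinate member
    expect_equal(hgvs_normalize(d, seq)$start,
                 max(vapply(equiv, function(dq) dq$start, integer(1))))
  }
})

test_that("extraction returns the exact difference set of an edited sequence", {
  can <- cd44_canonical()
  expect_equal(nrow(extract_differences(global_align(can, can$sequence))), 0L)

  a1 <- global_align(can, hgvs_apply(hgvs_parse("p.K417R"), can))
  expect_equal(hgvs_render(extract_differences(a1)), "p.K417R")

  a2 <- global_align(can, hgvs_apply(hgvs_parse("p.223_266delinsS"), can))
  expect_equal(hgvs_render(extract_differences(a2)), "p.223_266delinsS")
})

test_that("extract-then-apply round trips generated isoforms byte-exactly", {
  can <- cd44_canonical()
  gen <- generate_isoform_set(synthetic_config(seed = 23, n_isoforms = 40,
                                               partial_rate = 0))
  cat_tbl <- load_event_catalogue()
  params <- scoring_params()
  for (k in seq_len(nrow(gen$records))) {
    q <- gen$records$sequence[k]
    ds <- cd44iso:::.tail_anchored_differences(q, can$sequence, cat_tbl, params)
    if (is.null(ds)) ds <- extract_differences(global_align(can, q, params))
    expect_identical(hgvs_apply(ds, can), q, info = gen$records$record_id[k])
    # and extraction reproduces the planted set in normalized form
    planted <- hgvs_normalize(gen$truth$descriptors[[k]], can)
    expect_equal(ds[, c("kind", "start", "end", "ref", "alt")],
                 planted[, c("kind", "start", "end", "ref", "alt")],
                 ignore_attr = TRUE, info = gen$records$record_id[k])
  }
})

test_that("adjacent mismatch columns merge into a delins, distant ones do not", {
  can <- cd44_canonical()
  # a substitution two residues from the V6 delins stays a separate residual
  iso <- hgvs_apply(hgvs_parse(c("p.385_428delinsT", "p.I479T")), can)
  ds <- extract_differences(global_align(can, iso))
  expect_equal(sort(hgvs_render(ds)), sort(c("p.385_428delinsT", "p.I479T")))

  # a substitution flush against the event boundary is absorbed (delins grows)
  adv <- generate_isoform_set(synthetic_config(
    seed = 41, n_isoforms = 6, substitution_rate = 0, indel_rate = 0,
    partial_rate = 0, duplication_rate = 0, adversarial = TRUE,
    event_sets = list("exon V6 spliced out")))
  for (k in seq_len(nrow(adv$records))) {
    q <- adv$records$sequence[k]
    ds_k <- extract_differences(global_align(can, q))
    planted <- adv$truth$descriptors[[k]]
    # the edit is re-segmented: the flush substitution is never returned as a
    # separate residual next to the 385-428 event ...
    expect_false(identical(sort(hgvs_render(ds_k)), sort(hgvs_render(planted))))
    expect_equal(max(ds_k$end), 429L)    # ... its position is swallowed
    # ... but the extracted representation is still exact
    expect_identical(hgvs_apply(ds_k, can), q)
  }
})
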