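test_that("event matching separates catalogued events from residuals and novels", {
  can <- cd44_canonical()
  mt <- match_events(hgvs_parse("p.223_604delinsR"))
  expect_equal(mt$matched, "exons V2-V10 spliced out")
  expect_equal(nrow(mt$residual), 0L)

  # the epican pattern: one event plus two benign substitutions
  ds <- dplyr::bind_rows(hgvs_parse("p.223_266delinsS"),
                         hgvs_parse("p.E410V"), hgvs_parse("p.I479T"))
  mt2 <- match_events(ds)
  expect_equal(mt2$matched, "exon V2 spliced out")
  expect_equal(sort(hgvs_render(mt2$residual)), c("p.E410V", "p.I479T"))
  expect_equal(nrow(mt2$novel), 0L)

  # an uncatalogued large delins is a novel event, not a residual
  novel <- difference_set("delins", 300, 450,
                          substr(can$sequence, 300, 450), "Q")
  mt3 <- match_events(novel)
  expect_equal(length(mt3$matched), 0L)
  expect_equal(nrow(mt3$novel), 1L)

  # the catalogued pure deletion (microexon within V3) matches as an event
  mt4 <- match_events(hgvs_parse("p.G266_S273del"))
  expect_equal(mt4$matched, "part of exon V3 spliced out")
})

test_that("boundary near-misses warn and stay unmatched", {
  can <- cd44_canonical()
  near <- difference_set("delins", 385, 430,
                         substr(can$sequence, 385, 430), "T")
  expect_warning(mt <- match_events(near), "within 2 residues")
  expect_equal(length(mt$matched), 0L)
  expect_equal(nrow(mt$novel), 1L)
})

test_that("tail classification covers long, short, alternative and truncated", {
  can <- cd44_canonical()
  expect_equal(classify_tail(can$sequence, cd44iso:::.empty_ds())$tail_class,
               "long")

  st_ds <- hgvs_parse(c("p.223_604delinsR", "p.675_742delinsS"))
  st_seq <- hgvs_apply(st_ds, can)
  tl <- classify_tail(st_seq, st_ds)
  expect_equal(tl$tail_class, "short")
  expect_true(endsWith(st_seq, "RRS"))   # short-tail marker at end of exon 17

  # a known alternative ending is recognised and returned
  alt_ds <- hgvs_parse("p.428_742delinsGDCGSMAWVKKYFSFIFL")
  alt_seq <- hgvs_apply(alt_ds, can)
  ta <- classify_tail(alt_seq, alt_ds)
  expect_equal(ta$tail_class, "alternative")
  expect_equal(ta$c_terminal_segment, "GDCGSMAWVKKYFSFIFL")

  # a bare C-terminal truncation has no novel suffix
  tr_ds <- difference_set("deletion", 600, 742,
                          substr(can$sequence, 600, 742), "")
  expect_equal(classify_tail(hgvs_apply(tr_ds, can), tr_ds)$tail_class,
               "truncated")

  # a point variant inside the tail does not change the class
  pt <- hgvs_parse("p.S697I")
  expect_equal(classify_tail(hgvs_apply(pt, can), pt)$tail_class, "long")
})

test_that("classifying the canonical is the pipeline's fixed point", {
  res <- classify_isoform(list(record_id = "canonical",
                               sequence = cd44_canonical()$sequence))
  expect_equal(res$matched_events[[1]], character(0))
  expect_equal(nrow(res$residual_variants[[1]]), 0L)
  expect_equal(res$group_key, "")
  expect_equal(res$tail_class, "long")
  expect_equal(res$flags[[1]], character(0))
})

test_that("reconstructed recognised isoforms classify to their printed rows", {
  res <- classify_isoforms(table1_isoforms())
  by_id <- function(id) res[res$record_id == id, ]

  e <- by_id("CD44E")
  expect_equal(e$length, 493L)
  expect_equal(e$matched_events[[1]], "exons V2-V7 spliced out")

  n9 <- by_id("NCBI9")
  expect_equal(n9$length, 743L)
  expect_equal(n9$matched_events[[1]], character(0))
  expect_equal(hgvs_render(n9$residual_variants[[1]]), "p.345_346insA")

  n11 <- by_id("NCBI11")
  expect_equal(n11$length, 712L)
  expect_equal(n11$matched_events[[1]], "part of exon 5 spliced out")
  expect_equal(hgvs_render(n11$residual_variants[[1]]), "p.345_346insA")

  st <- by_id("CD44st")
  expect_equal(st$length, 294L)
  expect_equal(st$tail_class, "short")

  sp <- by_id("CD44SP")
  expect_equal(sp$length, 29L)
  expect_equal(sp$matched_events[[1]], "exons 2-19 spliced out")
  expect_equal(sp$tail_class, "alternative")
})

test_that("grouping partitions non-partial records by exon composition", {
  can <- cd44_canonical()
  recs <- dplyr::bind_rows(
    iso_record("a", "p.223_266delinsS"),
    iso_record("b", c("p.223_266delinsS", "p.K417R")),
    iso_record("c", "p.223_604delinsR"))
  res <- classify_isoforms(recs)
  grp <- group_isoforms(res)
  expect_equal(nrow(grp$groups), 2L)
  expect_equal(grp$groups$members[[1]], c("a", "b"))
  expect_equal(grp$groups$n_members, c(2L, 1L))

  # permuting the input yields the same partition
  res_perm <- classify_isoforms(recs[c(3, 1, 2), ])
  grp_perm <- group_isoforms(res_perm)
  expect_equal(sort(grp_perm$groups$group_key), sort(grp$groups$group_key))
  expect_equal(lapply(grp_perm$groups$members[order(grp_perm$groups$group_key)], sort),
               lapply(grp$groups$members[order(grp$groups$group_key)], sort))

  # every non-partial record lands in exactly one group
  all_members <- unlist(grp$groups$members)
  expect_equal(sort(all_members), sort(recs$record_id))
})

test_that("group count equals the number of distinct planted event sets", {
  gen <- generate_isoform_set(synthetic_config(seed = 19, n_isoforms = 60,
                                               partial_rate = 0))
  res <- classify_isoforms(gen$records)
  grp <- group_isoforms(res)
  planted_sets <- unique(vapply(gen$truth$event_names, paste,
                                character(1), collapse = " + "))
  expect_equal(nrow(grp$groups), length(planted_sets))
})

test_that("partials are excluded from grouping and reported separately", {
  gen <- generate_isoform_set(synthetic_config(seed = 29, n_isoforms = 30,
                                               partial_rate = 0.5,
                                               duplication_rate = 0))
  res <- classify_isoforms(gen$records)
  flagged <- vapply(res$flags, function(f) "partial" %in% f, logical(1))
  expect_equal(flagged, gen$truth$is_partial)
  grp <- group_isoforms(res)
  expect_equal(sort(grp$partials), sort(gen$truth$record_id[gen$truth$is_partial]))
  expect_false(any(unlist(grp$groups$members) %in% grp$partials))
})

test_that("identical sequences merge into one cluster with pooled accessions", {
  can <- cd44_canonical()$sequence
  recs <- tibble::tibble(
    record_id = c("NP_000601.3", "P16070-1", "other"),
    sequence = c(can, can, paste0(substr(can, 1, 741), "A")),
    accessions = list("NP_000601.3", "P16070-1", "other"))
  cl <- merge_identical(recs)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$accessions[[1]], c("NP_000601.3", "P16070-1"))
  expect_equal(cl$n_members, c(2L, 1L))

  # idempotent and order-independent up to representative choice
  cl2 <- merge_identical(cl[, c("record_id", "sequence", "accessions")])
  expect_equal(nrow(cl2), 2L)
  cl3 <- merge_identical(recs[c(3, 2, 1), ])
  set_of <- function(cl) sort(vapply(cl$member_ids, function(m)
    paste(sort(m), collapse = ","), character(1)))
  expect_equal(set_of(cl3), set_of(cl))

  # all-distinct batch gives singletons
  gen <- generate_isoform_set(synthetic_config(seed = 3, n_isoforms = 10,
                                               duplication_rate = 0,
                                               substitution_rate = 0.05))
  expect_equal(nrow(merge_identical(gen$records)),
               length(unique(gen$records$sequence)))
})

test_that("length bucketing chains lengths within the tolerance", {
  recs <- tibble::tibble(record_id = c("a", "b", "c"),
                         sequence = c(strrep("A", 742), strrep("A", 743),
                                      strrep("A", 699)))
  b1 <- group_by_length(recs, tolerance = 1)
  expect_equal(b1$length_bucket[b1$record_id == "a"],
               b1$length_bucket[b1$record_id == "b"])
  expect_false(b1$length_bucket[b1$record_id == "c"] ==
                 b1$length_bucket[b1$record_id == "a"])

  b0 <- group_by_length(recs, tolerance = 0)
  expect_equal(length(unique(b0$length_bucket)), 3L)

  empty <- group_by_length(recs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(group_by_length(recs, tolerance = -1), ">= 0")
})

test_that("exon-pattern plot builds from classification results", {
  res <- classify_isoforms(table1_isoforms()[1:4, ])
  expect_s3_class(plot_exon_patterns(res), "ggplot")
})
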