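# Reconstructions of recognised isoforms from their descriptor strings.

iso_record <- function(id, descriptors) {
  ds <- if (length(descriptors) > 0L) hgvs_parse(descriptors) else
    cd44iso:::.empty_ds()
  tibble::tibble(record_id = id,
                 sequence = hgvs_apply(ds, cd44_canonical()))
}

table1_isoforms <- function() {
  dplyr::bind_rows(
    iso_record("canonical", character(0)),
    iso_record("CD44s", "p.223_604delinsR"),
    iso_record("CD44v3-10", "p.223_266delinsS"),
    iso_record("CD44E", "p.223_472delinsN"),
    iso_record("CD44v10", "p.223_536delinsN"),
    iso_record("CD44st", c("p.223_604delinsR", "p.675_742delinsS")),
    iso_record("CD44s-exon15", "p.223_625delinsR"),
    iso_record("NCBI9", "p.345_346insA"),
    iso_record("NCBI10", "p.A428del"),
    iso_record("NCBI11", c("p.192_223delinsA", "p.345_346insA")),
    iso_record("SST-isoform", "p.78_742delinsSST"),
    iso_record("CD44SP", "p.23_742delinsGVGRRKS")
  )
}

table2_examples <- c("p.385_428delinsT", "p.A428del", "p.G266_S273del",
                     "p.345_346insA", "p.K417R")
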