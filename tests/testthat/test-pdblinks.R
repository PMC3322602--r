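test_that("LINK records parse by fixed columns; LINKR carries the link id", {
  hdr <- make_link_header()
  rec <- parse_link_records(hdr, source = "hdr1")
  expect_equal(nrow(rec), 6L)
  first <- rec[1, ]
  expect_equal(first$atom1, "CB"); expect_equal(first$res1, "TYR")
  expect_equal(first$chain1, "A"); expect_equal(first$seq1, 120L)
  expect_equal(first$atom2, "ND1"); expect_equal(first$res2, "HIS")
  expect_equal(first$distance, 1.53)

  linkr <- rec[!is.na(rec$link_id), ]
  expect_equal(nrow(linkr), 1L)
  expect_equal(linkr$link_id, "ALPHA1-4")
  expect_true(is.na(linkr$distance))

  expect_equal(nrow(parse_link_records(c("HEADER    X", "END"))), 0L)
  expect_warning(out <- parse_link_records("LINK        CB  TYR"),
                 "truncated")
  expect_equal(nrow(out), 0L)
})

test_that("the amino-amino filter drops peptide bonds and disulfides", {
  rec <- parse_link_records(make_link_header(), source = "hdr1")
  kept <- filter_amino_amino(rec)
  pair <- function(d) paste(d$res1, d$atom1, d$res2, d$atom2)
  expect_true("TYR CB HIS ND1" %in% pair(kept))
  expect_false("TYR C SER N" %in% pair(kept))          # peptide-bond mistake
  expect_false("CYS SG CYS SG" %in% pair(kept))        # disulfide mistake
  expect_false(any(kept$res1 == "NAG" | kept$res2 == "NAG"))  # not amino-amino

  # pure subset: excluded + retained = input, rows unaltered
  excluded <- rec[!rownames(rec) %in% rownames(kept), ]
  expect_equal(nrow(kept) + nrow(excluded), nrow(rec))
  expect_true(all(pair(kept) %in% pair(rec)))
})

test_that("the tally canonicalizes swapped sides and counts files", {
  rec <- filter_amino_amino(parse_link_records(make_link_header(),
                                               source = "hdr1"))
  rec2 <- rec
  rec2$source <- "hdr2"
  tal <- tally_links(rbind(rec, rec2))
  # TYR CB - HIS ND1 appears twice per file (once side-swapped), two files
  row <- tal[tal$res1 == "HIS" & tal$atom1 == "ND1", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_total, 4L)
  expect_equal(row$n_files, 2L)

  # swapping sides of every record leaves the tally unchanged
  swapped <- rec
  swapped[c("atom1", "res1", "chain1", "seq1",
            "atom2", "res2", "chain2", "seq2")] <-
    rec[c("atom2", "res2", "chain2", "seq2",
          "atom1", "res1", "chain1", "seq1")]
  expect_equal(tally_links(swapped), tally_links(rec))

  empty <- tally_links(rec[0, ])
  expect_equal(nrow(empty), 0L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_links_tally(tal, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$n_total, tal$n_total)
})
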