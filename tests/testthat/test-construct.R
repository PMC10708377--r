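test_that("the syndecan-4 construct parses to 57 residues with the expected composition", {
  cons <- sdc4_construct()
  expect_s3_class(cons, "nmr_construct")
  expect_length(cons, 57)
  expect_identical(count_residue(cons, "N"), 1L)
  expect_identical(count_residue(cons, "Y"), 4L)
  expect_identical(count_residue(cons, "W"), 0L)
  # serialising the sequence reproduces the (whitespace-stripped) input
  expect_identical(
    cons$sequence,
    gsub(" ", "", "ERTEV LAALI VGGVV GILFA VFLIL LLVYR IKKKD EGSYD LGKKP IYKKA PTNEF YA")
  )
})

test_that("construct validation reports empty and invalid sequences with position", {
  expect_error(make_construct(""), "empty sequence")
  expect_error(make_construct("   \n "), "empty sequence")
  expect_error(make_construct("MGKX"), "position 4")
  expect_length(make_construct("M G K"), 3)
})

test_that("domain spans are validated against the sequence", {
  expect_error(make_construct("MGKL", domain_spans = list(tm = c(1, 9))), "outside")
  expect_error(
    make_construct("MGKLMGKL", domain_spans = list(ecto = c(1, 4), tm = c(4, 8))),
    "overlap"
  )
  expect_error(make_construct("MGKL", domain_spans = list(weird = c(1, 2))), "unknown")
})

test_that("residue numbering maps bijectively onto full-length numbering", {
  cons <- sdc4_construct()
  m <- map_residue(cons, 1:57)
  expect_identical(m$full_number, 142:198)
  expect_identical(anyDuplicated(m$full_number), 0L)
  # the unique cytoplasmic serine maps to the Ser179 phosphosite
  expect_identical(map_residue(cons, 38)$label, "Ser179")
  expect_identical(map_residue(cons, 1)$label, "Glu142")
  # the alternative offset convention puts the V-domain tyrosine at 187
  expect_identical(map_residue(sdc4_construct(first_full_number = 141), 47)$label, "Tyr187")
  expect_error(map_residue(cons, 58), "out of range")
  expect_error(map_residue(cons, 0), "out of range")
})

test_that("GXXXG detection finds the transmembrane dimerisation motif", {
  g <- find_gxxxg(sdc4_construct())
  expect_identical(nrow(g), 1L)
  expect_identical(g$start, 12L)
  expect_identical(g$end, 16L)
  expect_identical(g$motif, "GGVVG")

  expect_identical(find_gxxxg(make_construct("GAAAG"))$start, 1L)
  expect_identical(nrow(find_gxxxg(make_construct("AAAAA"))), 0L)
  # overlapping matches are all reported, ordered by start
  gg <- find_gxxxg(make_construct("GAAAGAAAG"))
  expect_identical(gg$start, c(1L, 5L))
})

test_that("GXXXG scan agrees with a brute-force oracle on repeated non-overlapping motifs", {
  for (k in 1:4) {
    seqk <- paste(rep("GLLLG", k), collapse = "AA")
    cons <- make_construct(seqk)
    found <- find_gxxxg(cons)
    # oracle: direct character comparison at every offset
    v <- strsplit(seqk, "")[[1]]
    oracle <- which(vapply(
      seq_len(length(v) - 4),
      function(i) v[i] == "G" && v[i + 4] == "G", logical(1)
    ))
    expect_identical(found$start, as.integer(oracle))
    expect_identical(nrow(found), k)
  }
  expect_identical(nrow(find_gxxxg(make_construct("ALLLAVVLA"))), 0L)
})

test_that("FASTA round trip preserves the sequence", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">syd4", "ERTEVLAALI", "VGGVVG"), path)
  cons <- read_construct_fasta(path, first_full_number = 142)
  expect_identical(cons$sequence, "ERTEVLAALIVGGVVG")
  writeLines(c(">a", "MGK", ">b", "MGK"), path)
  expect_error(read_construct_fasta(path), "exactly one record")
})

test_that("amide positions exclude residue 1 and prolines", {
  cons <- sdc4_construct()
  tbl <- tidy(cons)
  pro <- tbl$residue[tbl$aa == "P"]
  expect_identical(pro, c(45L, 51L))
  pair <- gen_hsqc_pair(cons, synth_spec())
  expect_false(1L %in% pair$free$residue)
  expect_false(any(pro %in% pair$free$residue))
  expect_identical(nrow(pair$free), 54L)
})
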