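# Pure character attributes, diagnosis counts, Table-2-style formatting.

three_block_fixture <- function() {
  # 8 columns; planted diagnostics: pos 2 'A' fixed in block1 vs C/G
  # elsewhere; pos 5 gap fixed in block3; pos 7 'T' in block1 but an R
  # (A/G) outside at pos 8 spoils nothing there
  seqs <- c(
    b1_s1 = "CAGTC-GT", b1_s2 = "CAGTC-GT",
    b2_s1 = "CCGTC-GA", b2_s2 = "CCGTC-GA",
    b3_s1 = "CGGT-TGA", b3_s2 = "CGGT-TGA")
  aln <- new_alignment(seqs, "COI")
  part <- partition_from_labels(setNames(
    c("block1", "block1", "block2", "block2", "block3", "block3"),
    names(seqs)))
  list(aln = aln, part = part)
}

test_that("planted diagnostic sites are recovered, including gaps", {
  fx <- three_block_fixture()
  tab <- pure_character_attributes(fx$aln, fx$part)
  b1 <- tab[tab$species == "block1", ]
  expect_true(any(b1$position == 2 & b1$state == "A"))
  b3 <- tab[tab$species == "block3", ]
  expect_true(any(b3$position == 5 & b3$state == "-"))   # gap as a state
  # shared column (1: all C) is never diagnostic
  expect_false(any(tab$position == 1))
})

test_that("ambiguity codes disqualify diagnoses on either side", {
  # block1 fixed A at pos 1; one outsider has R (= A/G): not diagnostic
  aln <- new_alignment(c(x1 = "AC", x2 = "AC", y1 = "RC", y2 = "GC"),
                       "COI")
  part <- partition_from_labels(c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  tab <- pure_character_attributes(aln, part)
  expect_false(any(tab$species == "X" & tab$position == 1))

  # an ambiguity inside the block disqualifies fixation
  aln2 <- new_alignment(c(x1 = "AC", x2 = "RC", y1 = "GC", y2 = "GC"),
                        "COI")
  tab2 <- pure_character_attributes(aln2, part)
  expect_false(any(tab2$species == "X" & tab2$position == 1))
  # but Y is fixed G and excluded from X (A, R can be G? R = A/G -> no)
  expect_false(any(tab2$species == "Y" & tab2$position == 1))

  # 'N' outside excludes any base, but not the gap
  aln3 <- new_alignment(c(x1 = "-C", x2 = "-C", y1 = "NC", y2 = "AC"),
                        "COI")
  tab3 <- pure_character_attributes(aln3, part)
  expect_true(any(tab3$species == "X" & tab3$position == 1 &
                    tab3$state == "-"))
})

test_that("emitted attributes equal the brute-force column scan", {
  set.seed(41)
  for (i in 1:10) {
    fx <- random_blocked_alignment(n_blocks = 3, per_block = 3,
                                   ncol = 120)
    got <- pure_character_attributes(fx$alignment, fx$partition)
    want <- pure_ca_oracle(fx$alignment, fx$partition)
    key <- function(d) sort(paste(d$species, d$position, d$state))
    expect_identical(key(as.data.frame(got)), key(want))
  }
})

test_that("diagnosis output is independent of sequence order", {
  fx <- three_block_fixture()
  tab1 <- pure_character_attributes(fx$aln, fx$part)
  perm <- sample(length(fx$aln$ids))
  aln2 <- new_alignment(fx$aln$mat[perm, , drop = FALSE], "COI")
  tab2 <- pure_character_attributes(aln2, fx$part)
  key <- function(d) sort(paste(d$species, d$locus, d$position, d$state))
  expect_identical(key(as.data.frame(tab1)), key(as.data.frame(tab2)))
})

test_that("blocks without sequence data at a locus report na", {
  fx <- three_block_fixture()
  extra <- partition_from_labels(setNames(
    c(partition_labels(fx$part), "block4"),
    c(names(partition_labels(fx$part)), "b4_s1")))
  tab <- pure_character_attributes(fx$aln, extra)
  na_e <- attr(tab, "na_entries")
  expect_true(any(na_e$species == "block4" & na_e$locus == "COI"))
})

test_that("diagnosis counts treat na as zero and track extremes", {
  fx <- three_block_fixture()
  tab <- pure_character_attributes(fx$aln, fx$part)
  dc <- diagnosis_counts(tab)
  expect_equal(dc$counts[dc$counts$species == "block1", "COI"],
               sum(tab$species == "block1"))
  expect_gte(dc$max, dc$min)

  empty <- pure_character_attributes(
    new_alignment(c(a = "AC", b = "AC", c = "AC"), "COI"),
    partition_from_labels(c(a = "X", b = "X", c = "Y")))
  dc0 <- diagnosis_counts(empty)
  expect_equal(c(dc0$min, dc0$max), c(0L, 0L))
})

test_that("formatting follows the published table layout", {
  txt <- "28S: 182 T, 212 A | COI: 79 G, 381 G | ITS: 1040 G, 1041 T, 1175 C, 2005 A"
  tab <- parse_diagnosis(txt, species = "Niphargus gottscheeanensis")
  expect_length(attr(tab, "flags"), 0)
  expect_equal(format_diagnosis(tab, "Niphargus gottscheeanensis"),
               paste0("28 S: 182 T, 212 A | COI: 79 G, 381 G | ",
                      "ITS: 1040 G, 1041 T, 1175 C, 2005 A"))

  tab2 <- parse_diagnosis("28S: 471 C, 472 T | COI: 345 A | ITS: na",
                          species = "sp")
  expect_match(format_diagnosis(tab2, "sp"), "ITS: na")
  expect_error(format_diagnosis(tab2, "nope"), "unknown species")
})

test_that("the parser flags the printed typographic anomalies", {
  fx <- paper_fixtures()
  cvajcki <- fx$table2$diagnosis[fx$table2$species == "Niphargus cvajcki"]
  tab <- parse_diagnosis(cvajcki, species = "Niphargus cvajcki")
  flags <- attr(tab, "flags")
  expect_true(any(grepl("1032", flags)))          # position without state
  expect_true(any(grepl("increasing order", flags)))  # the 13338 jump

  chag <- fx$table2$diagnosis[fx$table2$species == "Niphargus chagankae"]
  tabc <- parse_diagnosis(chag, species = "Niphargus chagankae")
  gaps <- tabc[tabc$state == "-", ]
  expect_true(all(c(1200, 1229, 2070) %in% gaps$position))
})
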