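test_that("local alignment self-scores, degenerates and symmetry behave", {
  b62 <- blosum62()
  for (s in c("LQENDRAT", "ITFIQFRMIH", "W")) {
    ch <- strsplit(s, "")[[1]]
    al <- smithWaterman(s, s)
    expect_equal(al$score, sum(b62[cbind(ch, ch)]))
    expect_equal(al$identity, 100)
    expect_equal(al$gaps, 0)
  }
  expect_equal(smithWaterman("LQENDRAT", "")$score, 0)
  expect_equal(smithWaterman("", "")$length, 0L)
  set.seed(1)
  for (i in 1:8) {
    a <- paste(sample(aminoAcidAlphabet(), 10, TRUE), collapse = "")
    b <- paste(sample(aminoAcidAlphabet(), 12, TRUE), collapse = "")
    expect_equal(smithWaterman(a, b)$score, smithWaterman(b, a)$score)
    expect_gte(smithWaterman(a, a)$score, smithWaterman(a, b)$score)
  }
  expect_error(smithWaterman("AA", "AA", gapOpen = 0), "positive")
})

test_that("alignment scores equal the brute-force enumeration oracle", {
  red <- blosum62()[c("A", "R", "N", "D"), c("A", "R", "N", "D")]
  set.seed(2)
  for (i in 1:15) {
    a <- paste(sample(c("A", "R", "N", "D"), sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "R", "N", "D"), sample(1:8, 1), TRUE), collapse = "")
    expect_equal(smithWaterman(a, b, red, gapOpen = 3, gapExtend = 1)$score,
                 bruteLocalAlign(a, b, red, 3, 1),
                 info = paste(a, b))
  }
})

test_that("novelty scanning flags near-duplicates at the inclusive 90% boundary", {
  refs <- c(r1 = "ACDEFGHIKL", r2 = "MNPQRSTVMN")
  nv <- noveltyScan(c(x = "ACDEFGHIKL"), refs)
  expect_true(nv$flagged)
  expect_equal(nv$identity, 100)
  expect_identical(nv$best_hit, "r1")
  # exactly 9/10 identical over a full-length gapless alignment: flagged
  nv90 <- noveltyScan(c(x = "ACDEFGHIKV"), c(r = "ACDEFGHIKL"))
  expect_equal(nv90$identity, 90)
  expect_true(nv90$flagged)
  # disjoint residue usage: weak local hit, not flagged
  nvlo <- noveltyScan(c(x = "WWWWYYWWW"), refs)
  expect_false(nvlo$flagged)
  expect_error(noveltyScan("ACD", character(0)), "empty")
})

test_that("motif summaries count residue classes and grade proximity", {
  ms <- motifSummary("FWY")
  expect_equal(ms$basic_count, 0L)
  expect_equal(ms$aromatic_count, 3L)
  expect_identical(ms$proximity, "absent")
  expect_identical(motifSummary("KW")$proximity, "present")
  # two aromatic-basic pairs within three positions
  expect_identical(motifSummary("KWAAKW")$proximity, "strong")
  expect_identical(motifSummary("KVYSSDAWGSMIMNCGEWKLFKVQKWCM")$proximity,
                   "strong")
  tb <- motifTable(c("FWY", "KW"))
  expect_equal(tb$aromatic, c(3L, 1L))
  expect_true(all(tb$basic <= tb$length))
  expect_gte(min(tb$amphipathic_moment), 0)
})

test_that("helical wheel places residues at 100-degree steps with classes", {
  hw <- helicalWheel("LQENDRAT")
  expect_equal(hw$angle[1:3], c(0, 100, 200))
  expect_identical(hw$class[hw$residue == "E"], "acidic")
  expect_identical(hw$class[hw$residue == "R"], "basic")
  long <- helicalWheel(strrep("A", 19))
  expect_equal(long$angle[19], 0)       # residue 18 (0-based): 1800 mod 360
  # designed amphipathic 18-mer: leucines wherever the wheel angle falls in
  # the upper half-plane, lysines elsewhere
  ang <- (100 * (0:17)) %% 360
  pat <- paste(ifelse(ang < 180, "L", "K"), collapse = "")
  hw2 <- helicalWheel(pat)
  hydro <- hw2$angle[hw2$class == "hydrophobic"]
  expect_true(all(hydro < 180))
  expect_gt(hydrophobicMoment(pat), 0.5)
})
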