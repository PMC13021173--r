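test_that("composition and dipeptide segments are exact probability vectors", {
  a <- aminoAcidComposition("AAAA")
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)
  ac <- aminoAcidComposition("ACAC")
  expect_equal(unname(ac[c("A", "C")]), c(0.5, 0.5))
  dp <- dipeptideFrequency("ACAC")   # pairs: AC, CA, AC over 3 positions
  expect_equal(unname(dp["AC"]), 2 / 3)
  expect_equal(unname(dp["CA"]), 1 / 3)
  expect_equal(sum(dp), 1)
  expect_equal(unname(dipeptideFrequency("AA")["AA"]), 1)
  expect_identical(sum(dipeptideFrequency("W")), 0)   # degenerate length 1
  set.seed(4)
  for (i in 1:5) {
    s <- paste(sample(aminoAcidAlphabet(), sample(8:50, 1), TRUE), collapse = "")
    expect_equal(sum(aminoAcidComposition(s)), 1, tolerance = 1e-12)
    expect_equal(sum(dipeptideFrequency(s)), 1, tolerance = 1e-12)
    expect_true(all(aminoAcidComposition(s) >= 0))
  }
})

test_that("net charge is strictly non-increasing in pH", {
  set.seed(11)
  grid <- seq(0.5, 13.5, by = 0.5)
  seqs <- c("KKKK", "DDEE", replicate(4, paste(
    sample(aminoAcidAlphabet(), 20, TRUE), collapse = "")))
  for (s in seqs) {
    ch <- vapply(grid, function(p) netCharge(s, p), numeric(1))
    expect_true(all(diff(ch) < 0))
  }
})

test_that("isoelectric point is the unique charge root and matches a grid scan", {
  # two-group symmetric case has the closed-form midpoint of the termini
  expect_equal(isoelectricPoint("GGGGG"), (8.0 + 3.1) / 2, tolerance = 1e-2)
  expect_gt(isoelectricPoint("KKKK"), 7)
  set.seed(21)
  for (i in 1:5) {
    s <- paste(sample(aminoAcidAlphabet(), 15, TRUE), collapse = "")
    pi <- isoelectricPoint(s)
    expect_lt(abs(netCharge(s, pi)), 1e-3)
    # independent dense grid scan oracle
    grid <- seq(0.01, 13.99, by = 1e-3)
    ch <- netCharge(s, 7)  # warm input check
    charges <- vapply(grid, function(p) netCharge(s, p), numeric(1))
    expect_lt(abs(grid[which.min(abs(charges))] - pi), 1e-3 + 1e-3)
  }
})

test_that("hydrophobic moment follows the helical vector-sum closed forms", {
  sc <- hydrophobicityScale("eisenberg")
  expect_equal(hydrophobicMoment("W"), abs(sc[["W"]]))
  # 18 residues x 100 degrees = 5 full turns: unit vectors cancel exactly
  expect_lt(hydrophobicMoment(strrep("A", 18)), 1e-9)
  set.seed(31)
  for (i in 1:5) {
    s <- paste(sample(aminoAcidAlphabet(), sample(5:30, 1), TRUE), collapse = "")
    expect_gte(hydrophobicMoment(s), 0)
  }
})

test_that("instability index and global properties follow their definitions", {
  # single-pair formula: (10/2) * DIWV(W, W), and DIWV(W, W) = 1
  expect_equal(instabilityIndex("WW"), 5)
  expect_equal(instabilityIndex("W"), 0)
  gp <- globalProperties("FWY")
  expect_equal(gp$aromaticity, 1)
  expect_equal(globalProperties("AAAA")$aromaticity, 0)
  # peptide mass: free amino-acid masses minus one water per bond
  expect_equal(globalProperties("AA")$molecular_weight,
               2 * 89.04768 - 18.010565, tolerance = 1e-4)
})

test_that("the 430-dim descriptor vector is the documented concatenation", {
  v <- physchemVector("ACAC")
  expect_length(v, 430L)
  expect_equal(unname(v[1:20]), unname(aminoAcidComposition("ACAC")))
  expect_equal(unname(v[21:420]), unname(dipeptideFrequency("ACAC")))
  expect_identical(physchemVector("LQENDRAT"), physchemVector("LQENDRAT"))
  M <- descriptorMatrix(tinyPeptides())
  expect_equal(dim(M), c(3L, 430L))
  expect_identical(rownames(M), c("p1", "p2", "p3"))
})

test_that("the profiling report rounds charge half-away-from-zero to 2 decimals", {
  df <- profilePeptides(c("LQENDRAT", "ITFIQFRMIH"))
  expect_equal(df$Charge, c(-1.09, 1.00))
  expect_equal(df$Length, c(8L, 10L))
})
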