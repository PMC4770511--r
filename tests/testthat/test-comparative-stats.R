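test_that("the uncorrected SD uses the N denominator", {
  ## {3,4} -> 0.5 distinguishes N from N-1 (which gives 0.707...)
  expect_equal(uncorrectedSD(c(3, 4)), 0.5)
  expect_lt(uncorrectedSD(c(3, 4)), sd(c(3, 4)))
  expect_equal(uncorrectedSD(c(4, 4, 4)), 0)
})

test_that("S_N equals a brute-force two-pass oracle on random samples", {
  set.seed(123)
  for (k in 1:1000) {
    x <- sample(1:25, sample(2:12, 1), replace = TRUE)
    expect_equal(uncorrectedSD(x), oracleSN(x))
    expect_lte(uncorrectedSD(x), sd(x) + 1e-12)
  }
})

mkAssign <- function(family, taxon, counts, partial = FALSE, species = NULL) {
  n <- length(counts)
  data.frame(precursor_id = paste0(family, taxon, seq_len(n)),
             species = if (is.null(species)) paste0(taxon, "_sp", seq_len(n))
                       else species,
             taxon_group = taxon, family = family, paracopy_count = counts,
             partial = partial, stringsAsFactors = FALSE)
}

test_that("paracopy summaries follow the full-length / single / partial-only conventions", {
  asg <- rbind(
    mkAssign("CAPA/PK:PVK", "Diplura", c(3, 4)),
    mkAssign("CAPA/PK:PVK", "Protura", c(4, 4, 4)),
    mkAssign("MIP", "Collembola", 7),
    mkAssign("kinin", "Archaeognatha", c(14, 20), partial = TRUE))
  s <- summarizeParacopies(asg)
  dip <- s[s$family == "CAPA/PK:PVK" & s$taxon == "Diplura", ]
  expect_equal(dip$mean, 3.5)
  expect_equal(dip$s_n, 0.5)
  pro <- s[s$family == "CAPA/PK:PVK" & s$taxon == "Protura", ]
  expect_equal(pro$mean, 4)
  expect_equal(pro$s_n, 0)
  single <- s[s$family == "MIP", ]
  expect_equal(single$mean, 7)
  expect_true(is.na(single$s_n))
  part <- s[s$family == "kinin", ]
  expect_equal(part$n_full, 0L)
  expect_equal(part$max_partial, 20L)
})

test_that("rendering matches the mixed '4 ± 0' / '3.5 ± 0.5' / '(≥20)' style", {
  asg <- rbind(mkAssign("A", "Diplura", c(3, 4)),
               mkAssign("B", "Protura", c(2, 2)),
               mkAssign("C", "Zygentoma", 7),
               mkAssign("D", "Archaeognatha", 20, partial = TRUE))
  r <- renderParacopyTable(summarizeParacopies(asg))
  expect_equal(r$rendered[r$family == "A"], "3.5 ± 0.5")
  expect_equal(r$rendered[r$family == "B"], "2 ± 0")
  expect_equal(r$rendered[r$family == "C"], "7")
  expect_equal(r$rendered[r$family == "D"], "(≥20)")
})

test_that("presence matrix counts species and renders true absences as zero", {
  asg <- rbind(mkAssign("PDF", "Collembola", c(1, 1, 1)),
               mkAssign("MIP", "Collembola", c(5, 5, 5)),
               mkAssign("MIP", "Diplura", c(11, 11)))
  m <- presenceMatrix(asg, taxa = c("Collembola", "Diplura"),
                      families = c("PDF", "MIP"))
  expect_equal(m["PDF", "Collembola"], 3L)
  expect_equal(m["PDF", "Diplura"], 0L)
  expect_equal(m["MIP", "Diplura"], 2L)
  expect_equal(dim(presenceMatrix(asg[0, ])), c(0L, 0L))
})

test_that("logo information content follows the entropy formula", {
  ## all-conserved column: log2(20) bits
  lg <- buildLogo(rep("F", 8))
  expect_equal(lg$info[1], log2(20), tolerance = 1e-12)
  ## uniform over all 20 residues: 0 bits
  lg2 <- buildLogo(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(lg2$info[1], 0)
  ## 50/50 split over two residues, n = 20, no correction:
  ## log2(20) - 1 = 3.3219; heights 1.6610 each
  lg3 <- buildLogo(rep(c("F", "Y"), 10))
  expect_equal(lg3$info[1], log2(20) - 1, tolerance = 1e-6)
  expect_equal(unname(lg3$heights[1, "F"]), (log2(20) - 1) / 2,
               tolerance = 1e-6)
  ## small-sample correction subtracts (1/ln 2) * 19 / (2n)
  lg4 <- buildLogo(rep("F", 8), small_sample_correction = TRUE)
  expect_equal(lg4$info[1], log2(20) - (1 / log(2)) * 19 / 16,
               tolerance = 1e-9)
})

test_that("logo invariants: heights sum to info, bounded, monotone under flattening", {
  set.seed(5)
  res20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- vapply(1:30, function(i)
    paste(sample(res20, 8, replace = TRUE), collapse = ""), character(1))
  lg <- buildLogo(peps)
  expect_true(all(abs(rowSums(lg$heights) - lg$info) < 1e-9))
  expect_true(all(lg$info >= 0 & lg$info <= log2(20) + 1e-12))
  ## majorization: nested distributions with flattening columns
  flat2 <- buildLogo(c(rep("A", 10), rep("C", 10)))
  flat4 <- buildLogo(c(rep("A", 5), rep("C", 5), rep("D", 5), rep("E", 5)))
  flat8 <- buildLogo(rep(c("A", "C", "D", "E", "F", "G", "H", "I"),
                         length.out = 20))
  expect_gt(flat2$info[1], flat4$info[1])
  expect_gt(flat4$info[1], flat8$info[1])
})

test_that("gap policies renormalize or dilute as documented", {
  peps <- c("F-", "FA", "F-", "FA")
  ig <- buildLogo(peps, gap_policy = "ignore_gaps")
  expect_equal(sum(ig$freqs[2, ]), 1)      # renormalized over non-gaps
  cg <- buildLogo(peps, gap_policy = "count_gaps")
  expect_equal(sum(cg$freqs[2, ]), 0.5)    # gaps dilute
  expect_error(buildLogo(c("FA", "FAA")), "same length")
  ## the "X = no residue at this position" marker behaves like a gap
  xg <- buildLogo(c("FX", "FA", "FX", "FA"))
  expect_equal(sum(xg$freqs[2, ]), 1)
  ## C-terminal padding helper aligns the C-termini
  expect_equal(padAlignC(c("AFGL", "FGL")), c("AFGL", "-FGL"))
})
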