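reg <- defaultRegistry()

test_that("generators are byte-identical under a fixed seed", {
  g1 <- genPrecursor("CCAP", 1, seed = 7, registry = reg)
  g2 <- genPrecursor("CCAP", 1, seed = 7, registry = reg)
  expect_identical(as.character(sequences(g1$transcript)),
                   as.character(sequences(g2$transcript)))
  expect_identical(as.character(sequences(g1$precursor)),
                   as.character(sequences(g2$precursor)))
  expect_identical(g1$truth, g2$truth)
  p1 <- genTaxonPanel(taxonProfile("Collembola"), 3, seed = 5,
                      registry = reg)
  p2 <- genTaxonPanel(taxonProfile("Collembola"), 3, seed = 5,
                      registry = reg)
  expect_identical(as.character(sequences(p1$precursors)),
                   as.character(sequences(p2$precursors)))
  c1 <- corruptRecord(g1, "in_frame_stop", seed = 3)
  c2 <- corruptRecord(g2, "in_frame_stop", seed = 3)
  expect_identical(c1$truth$lesion, c2$truth$lesion)
})

test_that("planted truth spans tile the precursor consistently", {
  for (fam in c("AST-A", "FMRFa", "SK", "CCAP", "proctolin")) {
    n <- if (getFamily(reg, fam)$copy_class == "multiple") 4L else 1L
    g <- genPrecursor(fam, n, seed = 21, registry = reg)
    prot <- as.character(sequences(g$precursor))[[1]]
    tp <- g$truth$peptides
    expect_true(all(tp$start > g$truth$signal_end))
    expect_true(all(tp$end <= nchar(prot)))
    ## the encoded segment matches the processed truth after removing the
    ## amide donor and pyroGlu display marks
    raw <- substring(prot, tp$start, tp$end)
    enc <- vapply(tp$processed, function(p) {
      core <- sub("a$", "", p)
      core <- sub("^pQ", "Q", core)
      core
    }, character(1), USE.NAMES = FALSE)
    expect_identical(raw, paste0(enc, ifelse(tp$amidated, "G", "")))
  }
})

test_that("full pipeline recovers a 14-copy allatostatin A precursor", {
  g <- genPrecursor("AST-A", 14, seed = 1, registry = reg)
  a <- annotatePrecursor(as.character(sequences(g$precursor))[[1]], reg)
  expect_equal(a@family, "AST-A")
  expect_equal(paracopyCount(a), 14L)
})

test_that("spacer mutations leave planted peptides recoverable (Monte-Carlo)", {
  hits <- 0L; total <- 0L
  for (k in 1:200) {
    fam <- c("AST-A", "MIP", "kinin", "FMRFa")[(k %% 4) + 1]
    g <- genPrecursor(fam, 3, seed = 3000 + k, mutation_rate = 0.05,
                      registry = reg)
    a <- annotatePrecursor(as.character(sequences(g$precursor))[[1]], reg)
    got <- maturePeptides(a)$processed
    for (p in g$truth$peptides$processed) {
      total <- total + 1L
      if (p %in% got) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("taxon panels honour presence/absence switches", {
  pan <- genTaxonPanel(taxonProfile("Collembola"), 9, seed = 3,
                       registry = reg)
  expect_false(any(pan$truth$family == "elevenin"))
  expect_false(any(pan$truth$family == "CNMa"))
  expect_true(any(pan$truth$family == "PDF"))
  pan2 <- genTaxonPanel(taxonProfile("Diplura"), 3, seed = 3,
                        registry = reg)
  expect_false(any(pan2$truth$family == "PDF"))
  ann <- annotatePrecursorSet(pan2$precursors, reg)
  asg <- familyAssignments(ann)
  m <- presenceMatrix(asg, taxa = "Diplura",
                      families = c("PDF", "MIP"))
  expect_equal(m["PDF", "Diplura"], 0L)
  expect_equal(m["MIP", "Diplura"], 3L)
})

test_that("fixed-count panels are recovered exactly through the pipeline", {
  prof <- taxonProfile("Diplura")
  pan <- genTaxonPanel(prof, 3, seed = 2, fixed_counts = TRUE,
                       registry = reg)
  ann <- annotatePrecursorSet(pan$precursors, reg)
  asg <- familyAssignments(ann)
  s <- summarizeParacopies(asg)
  for (fam in c("AST-A", "MIP", "FMRFa", "SK")) {
    row <- s[s$family == fam & s$taxon == "Diplura", ]
    expect_equal(row$mean, round(prof$families[[fam]]$mean), info = fam)
    expect_equal(row$s_n, 0, info = fam)
  }
})

test_that("3' truncation leaves the kept copies with lower-bound semantics", {
  g <- genPrecursor("AST-A", 10, seed = 13, registry = reg)
  gt <- corruptRecord(g, "truncate_3p", seed = 1, keep_copies = 5)
  expect_false(seqInfo(gt$precursor)$c_complete)
  expect_equal(nrow(gt$truth$peptides), 5L)
  info <- seqInfo(gt$precursor)
  a <- annotatePrecursor(as.character(sequences(gt$precursor))[[1]], reg,
                         c_complete = info$c_complete)
  asg <- familyAssignments(list(a))
  s <- summarizeParacopies(asg)
  expect_equal(s$n_full, 0L)
  expect_equal(s$max_partial, 5L)
  expect_equal(renderParacopyTable(s)$rendered, "(≥5)")
})

test_that("5' truncation suppresses the signal-peptide call", {
  g <- genPrecursor("MIP", 3, seed = 17, registry = reg)
  gt <- corruptRecord(g, "truncate_5p", seed = 1)
  info <- seqInfo(gt$precursor)
  expect_false(info$n_complete)
  a <- annotatePrecursor(as.character(sequences(gt$precursor))[[1]], reg,
                         n_complete = info$n_complete)
  expect_false(a@signal$present)
  expect_equal(a@signal$reason, "N-terminally incomplete")
})
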