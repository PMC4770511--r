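test_that("the documented example complements classify to their patterns", {
  gc <- GeneComplement("sp", "Protura",
                       list(c(rep("PVK", 4), "trypto_PK", rep("PK", 3))))
  expect_equal(classifyArchitecture(gc)$pattern, "B")

  c1 <- GeneComplement("sp", "Diplura",
                       list(c(rep("PVK", 3), "trypto_PK"), rep("PK", 4)))
  expect_equal(classifyArchitecture(c1)$pattern, "C1")

  c3 <- GeneComplement("sp", "Zygentoma",
                       list(c(rep("PVK", 3), "trypto_PK", rep("PK", 2)),
                            c("trypto_PK", rep("PK", 2))))
  expect_equal(classifyArchitecture(c3)$pattern, "C3")

  a <- GeneComplement("sp", "Chilopoda", list(c("PVK", "PVK", "PK")))
  expect_equal(classifyArchitecture(a)$pattern, "A")

  b1 <- GeneComplement("sp", "Collembola",
                       list(list(c("PVK", "trypto_PK", "PK"),
                                 c("PVK", "trypto_PK"))))
  expect_equal(classifyArchitecture(b1)$pattern, "B1")

  c2 <- GeneComplement("sp", "Zygentoma",
                       list(c("PVK", "trypto_PK"),
                            c("trypto_PK", "PK", "PK")))
  expect_equal(classifyArchitecture(c2)$pattern, "C2")
})

test_that("derived single-ligand states are unresolved with explicit rationales", {
  pvk_only <- GeneComplement("Daphnia-like", "Branchiopoda",
                             list(rep("PVK", 3)))
  r <- classifyArchitecture(pvk_only)
  expect_equal(r$pattern, "unresolved")
  expect_equal(r$rationale, "derived: PVK-only")
  pk_only <- GeneComplement("sp", "other", list(rep("PK", 5)))
  expect_equal(classifyArchitecture(pk_only)$rationale, "derived: PK-only")
  two_pvk_free <- GeneComplement("sp", "other",
                                 list(rep("PK", 2), c("trypto_PK", "PK")))
  expect_equal(classifyArchitecture(two_pvk_free)$pattern, "unresolved")
})

test_that("classifier equals the brute-force decision table over ligand multisets", {
  counts <- 0:3
  mkset <- function(np, nt, nk)
    c(rep("PVK", np), rep("trypto_PK", nt), rep("PK", nk))
  ## single gene, single transcript: all non-empty multisets (<= 6 copies
  ## per type via symmetry: pattern depends on presence only, checked with
  ## representative multiplicities 0..3 and a 6-copy spot check)
  for (np in counts) for (ntr in counts) for (nk in counts) {
    if (np + ntr + nk == 0) next
    gc <- GeneComplement("s", "other", list(mkset(np, ntr, nk)))
    expect_equal(classifyArchitecture(gc)$pattern,
                 oracleArchitecture(list(list(mkset(np, ntr, nk)))),
                 info = paste(np, ntr, nk))
  }
  gc6 <- GeneComplement("s", "other", list(mkset(6, 6, 6)))
  expect_equal(classifyArchitecture(gc6)$pattern, "B")

  ## two genes, single transcripts each
  presets <- list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 1), c(1, 1, 0),
                  c(1, 1, 1), c(3, 1, 0), c(3, 1, 2), c(0, 1, 4))
  for (g1 in presets) for (g2 in presets) {
    genes <- list(mkset(g1[1], g1[2], g1[3]), mkset(g2[1], g2[2], g2[3]))
    gc <- GeneComplement("s", "other", genes)
    expect_equal(classifyArchitecture(gc)$pattern,
                 oracleArchitecture(lapply(genes, list)),
                 info = paste(paste(g1, collapse = ""),
                              paste(g2, collapse = "")))
  }

  ## one gene, two transcripts
  for (t1 in presets) for (t2 in presets) {
    gene <- list(list(mkset(t1[1], t1[2], t1[3]),
                      mkset(t2[1], t2[2], t2[3])))
    gc <- GeneComplement("s", "other", gene)
    expect_equal(classifyArchitecture(gc)$pattern,
                 oracleArchitecture(gene),
                 info = paste(paste(t1, collapse = ""),
                              paste(t2, collapse = "")))
  }
})

test_that("pattern is invariant to paracopy multiplicity", {
  base <- list(c("PVK", "trypto_PK"), c("PK"))
  more <- list(c(rep("PVK", 6), rep("trypto_PK", 2)), rep("PK", 6))
  expect_equal(classifyArchitecture(GeneComplement("s", "other", base))$pattern,
               classifyArchitecture(GeneComplement("s", "other", more))$pattern)
})

test_that("taxon pattern histograms count patterns and flag mixed taxa", {
  mk <- function(sp, tax, genes) GeneComplement(sp, tax, genes)
  comps <- list(
    mk("d1", "Diplura", list(c("PVK", "trypto_PK"), c("PK"))),
    mk("d2", "Diplura", list(c("PVK", "trypto_PK"), c("PK"))),
    mk("d3", "Diplura", list(c("PVK", "trypto_PK"), c("PK"))),
    mk("d4", "Diplura", list(c("PVK", "trypto_PK"), c("PK"))),
    mk("z1", "Zygentoma", list(c("PVK", "trypto_PK"), c("trypto_PK", "PK"))),
    mk("z2", "Zygentoma", list(c("PVK", "trypto_PK"), c("trypto_PK", "PK"))),
    mk("z3", "Zygentoma", list(c("PVK", "trypto_PK"), c("trypto_PK", "PK"))),
    mk("z4", "Zygentoma", list(c("PVK", "trypto_PK", "PK"),
                               c("trypto_PK", "PK"))))
  s <- summarizePatterns(comps)
  expect_equal(as.integer(s$histogram["Diplura", "C1"]), 4L)
  expect_equal(as.integer(s$histogram["Zygentoma", "C2"]), 3L)
  expect_equal(as.integer(s$histogram["Zygentoma", "C3"]), 1L)
  expect_equal(s$mixed, "Zygentoma")
  ## an empty taxon is simply absent
  expect_false("Protura" %in% rownames(s$histogram))
})

test_that("gene complements built from annotated precursors match the planted architecture", {
  reg <- defaultRegistry()
  for (tx in c("Protura", "Collembola", "Diplura", "Zygentoma")) {
    pan <- genTaxonPanel(taxonProfile(tx), 2, seed = 4, registry = reg)
    ann <- annotatePrecursorSet(pan$precursors, reg)
    comps <- buildGeneComplements(ann)
    pats <- vapply(comps, function(cc) classifyArchitecture(cc)$pattern,
                   character(1))
    expect_true(all(pats == taxonProfile(tx)$capa$pattern), info = tx)
  }
})
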