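reg <- defaultRegistry()

test_that("signal peptides are recovered at the planted position", {
  ## generator templates followed by an acidic propeptide region
  for (tmpl in NeuropeptideMiner:::SIGNAL_TEMPLATES) {
    prot <- paste0(tmpl, "DNEQHDNEQHDN", "KR", "SPAYNFGLG", "KR", "DNEQHD")
    sp <- predictSignalPeptide(prot)
    expect_true(sp$present)
    expect_equal(sp$cleavage_after, nchar(tmpl))
  }
  ## the classical 16-residue test signal
  sp <- predictSignalPeptide(paste0("MKTLLVLAVLLAVASA", strrep("DNEQH", 8)))
  expect_equal(sp$cleavage_after, 16L)
})

test_that("signal prediction refuses degenerate inputs with stated reasons", {
  ## no hydrophobic core: 30 charged residues
  sp <- predictSignalPeptide(strrep("DEKR", 10))
  expect_false(sp$present)
  sp2 <- predictSignalPeptide("MKTLLVLAVLLAVASA")  # < 25 residues
  expect_false(sp2$present)
  expect_equal(sp2$reason, "too short")
  sp3 <- predictSignalPeptide(strrep("MKTLLVLAVLLAVASA", 4),
                              n_complete = FALSE)
  expect_false(sp3$present)
  expect_equal(sp3$reason, "N-terminally incomplete")
})

test_that("external signal predictions override the heuristic", {
  ext <- data.frame(id = "x1", cleavage_after = 21, score = 0.93)
  sp <- predictSignalPeptide(strrep("A", 60), external = ext, id = "x1")
  expect_true(sp$present)
  expect_equal(sp$cleavage_after, 21L)
})

test_that("dibasic, proline-block and monobasic cleavage rules fire as documented", {
  s <- predictCleavageSites("NAFTGCGKRSVDNE", signal_end = 0)
  kr <- s[s$site_class == "KR", ]
  expect_true(kr$accepted)
  ## proline at P1' blocks even a KR site
  s2 <- predictCleavageSites("NAFTGAGKRPQDNE", signal_end = 0)
  expect_false(s2[s2$site_class == "KR", "accepted"])
  expect_match(s2[s2$site_class == "KR", "reason"], "proline")
  ## monobasic K never cleaves; monobasic R needs a lone basic at P4/P6/P8
  s3 <- predictCleavageSites("AAAAKAAAAA", signal_end = 0)
  expect_false(any(s3$accepted))
  s4 <- predictCleavageSites("AAKAARAAAA", signal_end = 0)  # K at P4 of R6
  expect_true(s4[s4$site_class == "mono_R", "accepted"])
  ## cysteine protection
  s5 <- predictCleavageSites("AAATGAGKRCQDNE", signal_end = 0)
  expect_false(s5[s5$site_class == "KR", "accepted"])
})

test_that("cleavage decisions equal the literal rule-table oracle over enumerated contexts", {
  ## exhaustive P4/P2/P1/P1' contexts around a central basic: residues
  ## drawn from a discriminating alphabet at each varying position
  alphabet <- c("A", "K", "R", "P", "C", "G")
  cases <- expand.grid(p4 = alphabet, p2 = alphabet, p1 = c("K", "R"),
                       p1p = alphabet, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    cc <- cases[k, ]
    res <- paste0("AAA", cc$p4, "A", cc$p2, cc$p1, cc$p1p, "AAA")
    ## evaluate the downstream-most basic of the run containing position 7
    ch <- strsplit(res, "")[[1]]
    p1 <- 7L
    while (p1 < nchar(res) && ch[p1 + 1L] %in% c("K", "R")) p1 <- p1 + 1L
    sites <- predictCleavageSites(res, signal_end = 0)
    got <- sites$accepted[sites$p1_index == p1]
    expect_equal(got, oracleCleavageAccept(res, p1),
                 info = paste("context", res))
  }
})

test_that("excision reconstructs the precursor and calls amidation/pyroGlu", {
  ## CCAP-style segment followed by the amide donor G and a KR site
  prot <- paste0("MKTLLVLAVLLAVASA", "PFCNAFAGC", "G", "KR", "DNEQHD")
  sites <- predictCleavageSites(prot, signal_end = 16)
  pep <- excisePeptides(prot, signal_end = 16, sites = sites)
  expect_equal(pep$processed[1], "PFCNAFAGCa")
  expect_true(pep$amidated[1])
  ## the collembolan C-terminally extended variant
  prot2 <- paste0("MKTLLVLAVLLAVASA", "TFCNAFTGCA", "G", "KR", "DNEQHD")
  pep2 <- excisePeptides(prot2, signal_end = 16,
                         sites = predictCleavageSites(prot2, signal_end = 16))
  expect_equal(pep2$processed[1], "TFCNAFTGCAa")
  ## N-terminal Q displays as pyroglutamate
  prot3 <- paste0("MKTLLVLAVLLAVASA", "QTFQYSRGWTN", "G", "KR", "DNE")
  pep3 <- excisePeptides(prot3, signal_end = 16,
                         sites = predictCleavageSites(prot3, signal_end = 16))
  expect_true(pep3$pyroglu[1])
  expect_equal(pep3$processed[1], "pQTFQYSRGWTNa")
})

test_that("partition identity holds on 500 synthetic precursors", {
  fams <- familyNames(reg)
  for (k in 1:500) {
    fam <- fams[(k - 1L) %% length(fams) + 1L]
    n <- if (getFamily(reg, fam)$copy_class == "multiple")
      (k %% 5L) + 1L else 1L
    g <- genPrecursor(fam, n, seed = 9000 + k, registry = reg)
    prot <- as.character(sequences(g$precursor))[[1]]
    sig <- predictSignalPeptide(prot)
    sig_end <- if (sig$present) sig$cleavage_after else 0L
    sites <- predictCleavageSites(prot, signal_end = sig_end)
    pep <- excisePeptides(prot, signal_end = sig_end, sites = sites)
    ## signal + raw segments + consumed cleavage residues tile the input
    covered <- rep(FALSE, nchar(prot))
    if (sig_end > 0) covered[1:sig_end] <- TRUE
    for (j in seq_len(nrow(pep))) covered[pep$start[j]:pep$end[j]] <- TRUE
    acc <- sites[sites$accepted, ]
    for (j in seq_len(nrow(acc)))
      covered[acc$consumed_start[j]:acc$p1_index[j]] <- TRUE
    expect_true(all(covered), info = paste(fam, "seed", 9000 + k))
    ## and raw always equals the substring of its span
    expect_identical(pep$raw,
                     substring(prot, pep$start, pep$end))
  }
})

test_that("splice variants group by shared prefix with length-ordered tags", {
  shared <- paste0("MKTLLVLAVLLAVASA", "DDNEQHDDNEQHDDNEQKR",
                   "SFFDIQCKGVYDKSIFDQLDRVGLSDLV", "KR")
  a <- paste0(shared, "DNEQHDNEQHDDDNNEEQQ")
  b <- paste0(shared, "GSLDNVAGTE")
  df <- data.frame(id = c("itp_a", "itp_b"), species = "sp1",
                   residues = c(a, b), stringsAsFactors = FALSE)
  gr <- groupSpliceVariants(df)
  expect_length(gr, 1L)
  expect_equal(gr[[1]]$variants$variant_tag, c("a", "b"))
  expect_equal(gr[[1]]$variants$id[1], "itp_a")  # longer gets "a"
  expect_gte(gr[[1]]$shared_prefix_len, 30L)

  ## byte-identical duplicates collapse, no group
  df2 <- data.frame(id = c("x", "y"), species = "sp1",
                    residues = c(a, a), stringsAsFactors = FALSE)
  expect_length(groupSpliceVariants(df2), 0L)

  ## a plain prefix (likely an incomplete assembly) does not group
  df3 <- data.frame(id = c("x", "y"), species = "sp1",
                    residues = c(a, substr(a, 1, 60)),
                    stringsAsFactors = FALSE)
  expect_length(groupSpliceVariants(df3), 0L)

  ## different species never group
  df4 <- df
  df4$species <- c("sp1", "sp2")
  expect_length(groupSpliceVariants(df4), 0L)
})

test_that("planted signal positions and peptide counts are recovered on synthetic data", {
  fams <- familyNames(reg)
  n_ok_sig <- 0L; n_ok_cnt <- 0L; tot <- 0L
  for (k in 1:120) {
    fam <- fams[(k - 1L) %% length(fams) + 1L]
    n <- if (getFamily(reg, fam)$copy_class == "multiple")
      (k %% 6L) + 1L else 1L
    g <- genPrecursor(fam, n, seed = 500 + k, registry = reg)
    a <- annotatePrecursor(as.character(sequences(g$precursor))[[1]], reg)
    tot <- tot + 1L
    if (!is.na(a@signal$cleavage_after) &&
        abs(a@signal$cleavage_after - g$truth$signal_end) <= 1)
      n_ok_sig <- n_ok_sig + 1L
    expected <- if (getFamily(reg, fam)$copy_class == "single") 1L else n
    if (a@family == fam && a@paracopy_count == expected)
      n_ok_cnt <- n_ok_cnt + 1L
  }
  expect_gte(n_ok_sig / tot, 0.95)
  expect_gte(n_ok_cnt / tot, 0.98)
})
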