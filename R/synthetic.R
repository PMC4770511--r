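## Signal-peptide templates used by the generator. Each ends at its planted
## cleavage position: a positively charged n-region, an 8+ residue
## hydrophobic h-region whose strongest window sits well upstream of the
## cleavage point, and a small-residue c-region (Ala-X-Ala style at the
## -3/-1 positions). Verified to be recovered exactly by
## predictSignalPeptide when followed by a non-small spacer residue.
SIGNAL_TEMPLATES <- c(
  "MKTLLVLAVLLAVASA",          # 16
  "MKRFAVVLLLAVVSHEASA",       # 19
  "MRLNTLLVIAVLLLVNHSSA",      # 20
  "MKQNTSFLVVLLLAVVAHAASA")    # 22

## spacer alphabet: hydrophilic, non-basic, non-small at the signal -3/-1
## sense, and disjoint from every motif's required residue classes, so
## spacers can never spawn chance motif matches
SPACER_ALPHABET <- c("D", "E", "N", "Q", "H")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## standard-code codons per residue (for uniform synonymous back-translation)
CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG",
  Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA", "GTG"))

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param protein amino-acid string (20 standard residues).
#' @return nucleotide string of length 3 x nchar(protein).
#' @export
backTranslate <- function(protein) {
  ch <- strsplit(toupper(protein), "")[[1]]
  paste(vapply(ch, function(aa) {
    cods <- CODON_TABLE[[aa]]
    if (is.null(cods)) stop("cannot back-translate residue ", aa)
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

.randSpacer <- function(len)
  paste(sample(SPACER_ALPHABET, len, replace = TRUE), collapse = "")

## raw-encoded form of a processed exemplar: pQ -> Q, trailing amide "a"
## becomes the glycine donor
.rawFromProcessed <- function(processed) {
  amid <- endsWith(processed, "a")
  core <- if (amid) substr(processed, 1, nchar(processed) - 1) else processed
  if (startsWith(core, "pQ")) core <- paste0("Q", substr(core, 3, nchar(core)))
  list(raw = if (amid) paste0(core, "G") else core, amidated = amid)
}

## UTR free of ATG, ending (5') or starting (3') with an in-frame stop
.randUTR <- function(len, side = c("5p", "3p")) {
  side <- match.arg(side)
  u <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  while (grepl("ATG", u, fixed = TRUE))
    u <- sub("ATG", "ATT", u, fixed = TRUE)
  if (side == "5p") paste0(u, "TAA") else paste0("TAA", u)
}

#' Generate one synthetic precursor with planted truth
#'
#' Builds a precursor protein for one registry family: a signal peptide
#' (planted cleavage position 16-24), alternating acidic spacers and
#' peptide paracopies instantiating the family's exemplar, each peptide
#' followed by a glycine amide donor (when the family is amidated) and a KR
#' cleavage site. Families whose mature peptide starts with proline,
#' cysteine or a basic residue (which would veto the upstream cleavage
#' site) are placed directly behind the signal peptide; these are all
#' single-copy families. The protein is back-translated with uniform
#' synonymous codons and framed by ATG-free UTRs. At
#' \code{mutation_rate > 0}, point substitutions hit spacer positions
#' (neutral divergence outside the diagnostic residues); motif-critical
#' positions are never touched.
#'
#' @param family family name in the registry.
#' @param n_copies number of paracopies (forced to 1 for single-copy
#'   families).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param mutation_rate per-residue substitution rate on spacers, in
#'   [0, 0.2].
#' @param registry a \code{FamilyRegistry}.
#' @param species,taxon_group metadata planted on the records.
#' @param id record id.
#' @param min_protein_len precursors are padded with extra propeptide
#'   segments up to this length (real precursors carry substantial
#'   non-bioactive sequence besides the mature peptides).
#' @return list(transcript = TranscriptSet, precursor = PrecursorSet,
#'   truth = list(precursor_id, signal_end, peptides, family)).
#' @export
genPrecursor <- function(family, n_copies = 1, seed = 1, mutation_rate = 0,
                         registry = defaultRegistry(),
                         species = "Synthetica exempli",
                         taxon_group = "other",
                         id = paste0(gsub("[^A-Za-z0-9]", "", family), "_syn"),
                         min_protein_len = 70) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.2, n_copies >= 1)
  fam <- getFamily(registry, family)
  if (fam$copy_class == "single") n_copies <- 1L
  set.seed(seed)
  sig <- sample(SIGNAL_TEMPLATES, 1)
  ex <- .rawFromProcessed(fam$exemplar)
  pep_raw <- ex$raw
  protected <- grepl("^[PCKR]", pep_raw) ||
    grepl("C", substr(pep_raw, 1, 2))
  parts <- character(0)
  pep_spans <- matrix(0L, nrow = n_copies, ncol = 2)
  spacer_idx <- list()   # character positions open to mutation
  pos <- nchar(sig)
  addPart <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s); }
  if (protected) {
    addPart(pep_raw)
    pep_spans[1, ] <- c(nchar(sig) + 1L, pos)
    addPart("KR")
  } else {
    for (k in seq_len(n_copies)) {
      sp <- .randSpacer(sample(6:12, 1))
      spacer_idx[[length(spacer_idx) + 1L]] <- (pos + 1L):(pos + nchar(sp))
      addPart(sp)
      addPart("KR")
      pep_start <- pos + 1L
      addPart(pep_raw)
      pep_spans[k, ] <- c(pep_start, pos)
      addPart("KR")
    }
  }
  tail_sp <- .randSpacer(sample(6:10, 1))
  spacer_idx[[length(spacer_idx) + 1L]] <- (pos + 1L):(pos + nchar(tail_sp))
  addPart(tail_sp)
  ## pad short precursors with further propeptide segments: real precursors
  ## carry substantial non-bioactive sequence besides the mature peptides
  while (pos < min_protein_len) {
    addPart("KR")
    sp <- .randSpacer(sample(8:14, 1))
    spacer_idx[[length(spacer_idx) + 1L]] <- (pos + 1L):(pos + nchar(sp))
    addPart(sp)
  }
  protein <- paste0(sig, paste(parts, collapse = ""))
  ## spacer mutations (never inside signal, peptides, donors or sites)
  if (mutation_rate > 0 && length(spacer_idx)) {
    ch <- strsplit(protein, "")[[1]]
    for (i in unlist(spacer_idx)) {
      if (stats::runif(1) < mutation_rate)
        ch[i] <- sample(AA20, 1)
    }
    protein <- paste(ch, collapse = "")
  }
  nt <- paste0(.randUTR(30, "5p"), backTranslate(protein), "TAA",
               .randUTR(30, "3p"))
  ligand <- if (family %in% c("CAPA", "PK/PBAN"))
    typeCapaLigand(fam$exemplar) else NA_character_
  truth <- list(
    precursor_id = id,
    signal_end = nchar(sig),
    peptides = data.frame(
      start = pep_spans[, 1], end = pep_spans[, 2],
      processed = rep(fam$exemplar, n_copies),
      family = family, ligand_type = ligand,
      amidated = ex$amidated, stringsAsFactors = FALSE),
    family = family)
  list(transcript = TranscriptSet(nt, id = id, species = species,
                                  taxon_group = taxon_group),
       precursor = PrecursorSet(protein, id = id, species = species,
                                taxon_group = taxon_group),
       truth = truth)
}

## a multi-family precursor for the capa/pk complex: explicit ligand plan
.genCapaPrecursor <- function(ligand_plan, seed, id, species, taxon_group,
                              shared_prefix = NULL) {
  ## ligand_plan: character vector like c("PVK","PVK","trypto_PK","PK")
  set.seed(seed)
  exemplars <- c(PVK = "ASGLVAFPRVa", trypto_PK = "SGDMWFGPRLa",
                 PK = "SVPFSPRLa")
  sig <- if (is.null(shared_prefix)) sample(SIGNAL_TEMPLATES, 1)
         else shared_prefix$signal
  parts <- character(0)
  pos <- nchar(sig)
  spans <- list()
  addPart <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s); }
  if (!is.null(shared_prefix)) {
    addPart(shared_prefix$body)
  }
  for (k in seq_along(ligand_plan)) {
    sp <- .randSpacer(sample(6:12, 1))
    addPart(sp); addPart("KR")
    ex <- .rawFromProcessed(exemplars[[ligand_plan[k]]])
    pep_start <- pos + 1L
    addPart(ex$raw)
    spans[[k]] <- c(pep_start, pos)
    addPart("KR")
  }
  addPart(.randSpacer(sample(6:10, 1)))
  protein <- paste0(sig, paste(parts, collapse = ""))
  list(precursor = PrecursorSet(protein, id = id, species = species,
                                taxon_group = taxon_group),
       truth = list(precursor_id = id, signal_end = nchar(sig),
                    ligand_plan = ligand_plan,
                    peptides = data.frame(
                      start = vapply(spans, `[`, integer(1), 1),
                      end = vapply(spans, `[`, integer(1), 2),
                      processed = unname(exemplars[ligand_plan]),
                      family = "CAPA/PK", ligand_type = ligand_plan,
                      amidated = TRUE, stringsAsFactors = FALSE)))
}

#' Default per-taxon generator profiles
#'
#' Copy-number distributions (mean and uncorrected SD per multiple-copy
#' family), presence/absence switches, the capa/pk architecture pattern and
#' the splice-variant families for each of the five focal taxa. The numbers
#' parameterize the generator to emulate the comparative structure of the
#' study system: springtails with the lowest paracopy numbers, silverfish
#' with the highest FMRFa counts, PDF missing from coneheads and dipluran
#' bristletails, elevenin and CNMa missing where noted, three-ligand capa/pk
#' genes in Protura/Collembola (with the collembolan splice variant),
#' separate capa and pk genes in Diplura (C1) and Zygentoma (C2/C3).
#'
#' @param taxon one of Protura, Collembola, Diplura, Archaeognatha,
#'   Zygentoma.
#' @return a profile list.
#' @export
taxonProfile <- function(taxon = c("Protura", "Collembola", "Diplura",
                                   "Archaeognatha", "Zygentoma")) {
  taxon <- match.arg(taxon)
  fam <- function(mean, sd = 0) list(mean = mean, sd = sd)
  base <- switch(taxon,
    Protura = list(
      families = list("AST-A" = fam(14, 0.8), MIP = fam(9, 1),
        FMRFa = fam(2), TKRP = fam(5), natalisin = fam(6),
        kinin = fam(6.5, 0.5), RYa = fam(1.3, 0.5), ETH = fam(2),
        SK = fam(2), EFLa = fam(18)),
      capa = list(pattern = "B", pvk = fam(4), pk = fam(3)),
      absent = c("PDF", "CNMa"),
      splice_families = character(0)),
    Collembola = list(
      families = list("AST-A" = fam(4.2, 0.9), MIP = fam(5.3, 0.9),
        FMRFa = fam(3), TKRP = fam(3.6, 0.47), natalisin = fam(2),
        kinin = fam(4, 2.5), RYa = fam(2), ETH = fam(1),
        SK = fam(2.1, 0.3), EFLa = fam(4.5, 0.5)),
      capa = list(pattern = "B1", pvk = fam(3), pk = fam(3.6, 1.1)),
      absent = c("elevenin", "CNMa"),
      splice_families = c("ITP", "orcokinin")),
    Diplura = list(
      families = list("AST-A" = fam(12.5, 0.5), MIP = fam(11),
        FMRFa = fam(4), TKRP = fam(4), natalisin = fam(3),
        kinin = fam(5), RYa = fam(3), ETH = fam(2), SK = fam(2),
        EFLa = fam(9, 2.2)),
      capa = list(pattern = "C1", pvk = fam(3.5, 0.5), pk = fam(4.5, 0.5)),
      absent = "PDF",
      splice_families = "ITP"),
    Archaeognatha = list(
      families = list("AST-A" = fam(15.3, 1.7), MIP = fam(9.5, 0.5),
        FMRFa = fam(7, 0.8), TKRP = fam(4.3, 0.98), natalisin = fam(10),
        kinin = fam(20), RYa = fam(3), ETH = fam(2), SK = fam(2),
        EFLa = fam(12)),
      capa = list(pattern = "B", pvk = fam(4), pk = fam(3.7, 0.4)),
      absent = character(0),
      splice_families = c("ITP", "orcokinin")),
    Zygentoma = list(
      families = list("AST-A" = fam(18, 2.9), MIP = fam(12.2, 1.1),
        FMRFa = fam(11.6, 2.9), TKRP = fam(9), natalisin = fam(9),
        kinin = fam(19), RYa = fam(3), ETH = fam(2), SK = fam(2),
        EFLa = fam(17.5, 0.5)),
      capa = list(pattern = "C2", pvk = fam(3, 1), pk = fam(1.7, 0.2)),
      absent = character(0),
      splice_families = c("ITP", "orcokinin")))
  c(base, list(taxon = taxon,
               singles = c("CCAP", "MS", "corazonin", "PDF", "elevenin",
                           "CNMa", "ITP", "orcokinin")))
}

.capaPlans <- function(pattern, pvk, pk) {
  ## list of genes; each gene: list of transcripts; transcript = ligand plan
  reps <- function(t, n) rep(t, n)
  switch(pattern,
    A = list(list(c(reps("PVK", pvk), reps("PK", pk)))),
    B = list(list(c(reps("PVK", pvk), "trypto_PK", reps("PK", pk)))),
    B1 = list(list(c(reps("PVK", pvk), "trypto_PK", reps("PK", pk)),
                   c(reps("PVK", pvk), "trypto_PK"))),
    C1 = list(list(c(reps("PVK", pvk), "trypto_PK")),
              list(reps("PK", pk))),
    C2 = list(list(c(reps("PVK", pvk), "trypto_PK")),
              list(c("trypto_PK", reps("PK", pk)))),
    C3 = list(list(c(reps("PVK", pvk), "trypto_PK", reps("PK", max(1, pk %/% 2)))),
              list(c("trypto_PK", reps("PK", pk)))),
    stop("unknown capa/pk pattern: ", pattern))
}

#' Generate a per-taxon panel of synthetic species
#'
#' Realizes a \code{\link{taxonProfile}} for \code{n_species} species: one
#' precursor per present family with copy numbers drawn from a rounded
#' Gaussian clipped to >= 1 (or fixed at the rounded mean when
#' \code{fixed_counts}), the capa/pk gene complement realizing the
#' profile's architecture pattern (including the B1 splice pair and the
#' two-gene C states), splice pairs for the switched-on splice families,
#' and the profile's absent families omitted from every species.
#'
#' @param profile from \code{\link{taxonProfile}}.
#' @param n_species number of species.
#' @param seed RNG seed.
#' @param fixed_counts use the rounded profile means as exact counts
#'   (exact-recovery mode).
#' @param registry a \code{FamilyRegistry}.
#' @return list(precursors = PrecursorSet, truth = data.frame with one row
#'   per precursor, capa_truth = per-species pattern).
#' @export
genTaxonPanel <- function(profile, n_species, seed = 1, fixed_counts = FALSE,
                          registry = defaultRegistry()) {
  all_prec <- list()
  truth_rows <- list()
  addRecord <- function(ps, species, fam, n, role = NA_character_) {
    all_prec[[length(all_prec) + 1L]] <<- ps
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      precursor_id = seqInfo(ps)$id[1], species = species,
      taxon_group = profile$taxon, family = fam, n_copies = n,
      capa_role = role, stringsAsFactors = FALSE)
  }
  for (si in seq_len(n_species)) {
    species <- paste0(profile$taxon, "_sp", si)
    sp_seed <- (seed * 1000L + si * 131L) %% .Machine$integer.max
    ## multiple-copy families
    fi <- 0L
    for (fam in names(profile$families)) {
      fi <- fi + 1L
      pf <- profile$families[[fam]]
      set.seed(sp_seed + fi)
      n <- if (fixed_counts || pf$sd == 0) as.integer(round(pf$mean))
           else max(1L, as.integer(round(stats::rnorm(1, pf$mean, pf$sd))))
      g <- genPrecursor(fam, n_copies = n, seed = sp_seed + 100L + fi,
                        registry = registry, species = species,
                        taxon_group = profile$taxon,
                        id = paste0(species, "_",
                                    gsub("[^A-Za-z0-9]", "", fam)))
      addRecord(g$precursor, species, fam, n)
    }
    ## single-copy families, minus the profile's absences
    for (fam in setdiff(profile$singles,
                        c(profile$absent, profile$splice_families))) {
      fi <- fi + 1L
      g <- genPrecursor(fam, 1, seed = sp_seed + 100L + fi,
                        registry = registry, species = species,
                        taxon_group = profile$taxon,
                        id = paste0(species, "_",
                                    gsub("[^A-Za-z0-9]", "", fam)))
      addRecord(g$precursor, species, fam, 1L)
    }
    ## splice families: a/b variant pair sharing signal + first peptide
    for (fam in setdiff(profile$splice_families, profile$absent)) {
      fi <- fi + 1L
      g <- genPrecursor(fam, 1, seed = sp_seed + 100L + fi,
                        registry = registry, species = species,
                        taxon_group = profile$taxon,
                        id = paste0(species, "_",
                                    gsub("[^A-Za-z0-9]", "", fam), "a"))
      base_prot <- as.character(sequences(g$precursor))[[1]]
      set.seed(sp_seed + 500L + fi)
      tail_b <- paste0(.randSpacer(6), "GSLDNVAGTE")
      ## variant b: identical through the mature peptide, divergent tail
      cut <- g$truth$peptides$end[1] + 2L   # through the following KR
      prot_b <- paste0(substr(base_prot, 1, cut), tail_b)
      ps_b <- PrecursorSet(prot_b,
                           id = paste0(species, "_",
                                       gsub("[^A-Za-z0-9]", "", fam), "b"),
                           species = species, taxon_group = profile$taxon)
      addRecord(g$precursor, species, fam, 1L)
      addRecord(ps_b, species, fam, 1L)
    }
    ## capa/pk complement realizing the profile pattern
    cp <- profile$capa
    set.seed(sp_seed + 900L)
    drawN <- function(pf) if (fixed_counts || pf$sd == 0)
      max(1L, as.integer(round(pf$mean)))
    else max(1L, as.integer(round(stats::rnorm(1, pf$mean, pf$sd))))
    plans <- .capaPlans(cp$pattern, drawN(cp$pvk), drawN(cp$pk))
    gi <- 0L
    for (gene in plans) {
      gi <- gi + 1L
      shared <- NULL
      for (ti in seq_along(gene)) {
        cid <- paste0(species, "_capapk_g", gi,
                      if (length(gene) > 1) letters[ti] else "")
        gg <- .genCapaPrecursor(gene[[ti]],
                                seed = sp_seed + 700L + gi * 10L + ti,
                                id = cid, species = species,
                                taxon_group = profile$taxon,
                                shared_prefix = shared)
        if (ti == 1L && length(gene) > 1) {
          ## splice transcripts share signal + first-peptide block
          prot <- as.character(sequences(gg$precursor))[[1]]
          cut <- gg$truth$peptides$end[1] + 2L
          shared <- list(signal = substr(prot, 1, gg$truth$signal_end),
                         body = substr(prot, gg$truth$signal_end + 1L, cut))
          ## variant b re-generated with the shared prefix and the rest of
          ## its own plan (first peptide already inside the shared body)
        }
        if (ti > 1L) {
          gg <- .genCapaPrecursor(gene[[ti]][-1],
                                  seed = sp_seed + 700L + gi * 10L + ti,
                                  id = cid, species = species,
                                  taxon_group = profile$taxon,
                                  shared_prefix = shared)
          gg$truth$ligand_plan <- gene[[ti]]
        }
        fam_label <- if (any(gene[[ti]] == "PVK")) "CAPA" else "PK/PBAN"
        addRecord(gg$precursor, species, fam_label, length(gene[[ti]]),
                  role = paste0("gene", gi))
      }
    }
  }
  seqs <- unlist(lapply(all_prec, function(p) as.character(sequences(p))))
  infos <- do.call(rbind, lapply(all_prec, seqInfo))
  precursors <- PrecursorSet(seqs, id = infos$id, species = infos$species,
                             taxon_group = infos$taxon_group)
  list(precursors = precursors,
       truth = do.call(rbind, truth_rows),
       capa_truth = data.frame(
         species = paste0(profile$taxon, "_sp", seq_len(n_species)),
         taxon_group = profile$taxon, pattern = profile$capa$pattern,
         stringsAsFactors = FALSE))
}

#' Plant a lesion in a generated precursor
#'
#' Corrupts the output of \code{\link{genPrecursor}} with exactly one
#' lesion of the requested kind at a recorded position:
#' \describe{
#'   \item{in_frame_stop}{a codon inside the first peptide's span is
#'     replaced by TAA in the transcript;}
#'   \item{frameshift}{one nucleotide is deleted from the spacer directly
#'     upstream of the first peptide;}
#'   \item{truncate_5p}{the precursor loses its N-terminus into the signal
#'     peptide (n_complete becomes FALSE);}
#'   \item{truncate_3p}{the precursor is cut after \code{keep_copies}
#'     peptides (c_complete becomes FALSE).}
#' }
#'
#' @param gen output of \code{\link{genPrecursor}}.
#' @param kind lesion kind.
#' @param seed RNG seed (position choice is deterministic given the seed).
#' @param keep_copies for truncate_3p: paracopies to keep.
#' @return the gen list with the lesion applied and
#'   \code{truth$lesion} recording kind and position.
#' @export
corruptRecord <- function(gen, kind = c("in_frame_stop", "frameshift",
                                        "truncate_5p", "truncate_3p"),
                          seed = 1, keep_copies = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  truth <- gen$truth
  prot <- as.character(sequences(gen$precursor))[[1]]
  nt <- as.character(sequences(gen$transcript))[[1]]
  info <- seqInfo(gen$precursor)
  utr5 <- 33L  # .randUTR(30) + TAA
  if (kind == "in_frame_stop") {
    pep <- truth$peptides[1, ]
    res_pos <- pep$start + sample.int(pep$end - pep$start - 1L, 1)
    nt_pos <- utr5 + 3L * (res_pos - 1L) + 1L
    substr(nt, nt_pos, nt_pos + 2L) <- "TAA"
    gen$transcript <- TranscriptSet(nt, id = info$id, species = info$species,
                                    taxon_group = info$taxon_group)
    gen$truth$lesion <- list(kind = kind, nt_position = nt_pos,
                             residue = res_pos)
  } else if (kind == "frameshift") {
    pep <- truth$peptides[1, ]
    ## delete inside the spacer between signal/previous site and peptide
    res_pos <- pep$start - 4L
    nt_pos <- utr5 + 3L * (res_pos - 1L) + 1L
    nt <- paste0(substr(nt, 1, nt_pos - 1L),
                 substr(nt, nt_pos + 1L, nchar(nt)))
    gen$transcript <- TranscriptSet(nt, id = info$id, species = info$species,
                                    taxon_group = info$taxon_group)
    gen$truth$lesion <- list(kind = kind, nt_position = nt_pos)
  } else if (kind == "truncate_5p") {
    cut <- truth$signal_end - 4L
    prot2 <- substr(prot, cut + 1L, nchar(prot))
    gen$precursor <- PrecursorSet(prot2, id = info$id,
                                  species = info$species,
                                  taxon_group = info$taxon_group,
                                  n_complete = FALSE)
    gen$truth$lesion <- list(kind = kind, residue = cut)
    gen$truth$signal_end <- NA_integer_
    gen$truth$peptides$start <- gen$truth$peptides$start - cut
    gen$truth$peptides$end <- gen$truth$peptides$end - cut
  } else {
    stopifnot(!is.null(keep_copies),
              keep_copies >= 1, keep_copies <= nrow(truth$peptides))
    cut <- truth$peptides$end[keep_copies] + 2L  # through the KR site
    prot2 <- substr(prot, 1, cut)
    gen$precursor <- PrecursorSet(prot2, id = info$id,
                                  species = info$species,
                                  taxon_group = info$taxon_group,
                                  c_complete = FALSE)
    gen$truth$peptides <- gen$truth$peptides[seq_len(keep_copies), ,
                                             drop = FALSE]
    gen$truth$lesion <- list(kind = kind, residue = cut,
                             kept = keep_copies)
  }
  gen
}
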