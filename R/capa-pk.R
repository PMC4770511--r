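.presence <- function(tr) sort(unique(tr[tr %in% c("PVK", "trypto_PK", "PK")]))

.setEq <- function(a, b) setequal(a, b)

#' Classify a capa/pk gene complement into architecture patterns A-C3
#'
#' The decision works on ligand-type presence (paracopy multiplicity is
#' irrelevant) and gene/transcript structure:
#' \itemize{
#'   \item A: one gene, one transcript, PVK + PK, no tryptopyrokinin
#'     anywhere (the ancient two-ligand gene of myriapods/chelicerates);
#'   \item B: one gene, one transcript, PVK + trypto-PK + PK (the basic
#'     hexapod three-ligand gene);
#'   \item B1: one gene, two splice transcripts, one carrying all three
#'     ligand types and the other only PVK + trypto-PK;
#'   \item C1: two genes, the capa-like gene (the one with PVKs) carrying
#'     PVK + trypto-PK and the pk-like gene only PKs;
#'   \item C2: as C1 but the pk-like gene carries its own trypto-PK;
#'   \item C3: as C2 but the capa-like gene additionally carries PKs.
#' }
#' Everything else is \code{unresolved} with an explicit rationale; in
#' particular the derived single-ligand states (a lone PVK-only gene as in
#' the water flea, or a lone PK-only gene) are reported as
#' "derived: PVK-only" / "derived: PK-only" rather than forced into A-C3.
#' Two PVK-free genes cannot be labelled capa-like/pk-like and are likewise
#' unresolved.
#'
#' @param complement a \code{GeneComplement}.
#' @return list(pattern, rationale).
#' @export
classifyArchitecture <- function(complement) {
  stopifnot(is(complement, "GeneComplement"))
  genes <- complement@genes
  if (!length(genes)) stop("empty gene complement")
  gene_presence <- lapply(genes, function(g)
    sort(unique(unlist(lapply(g, .presence)))))
  any_trypto <- any(vapply(gene_presence, function(p) "trypto_PK" %in% p,
                           logical(1)))
  if (length(genes) == 1L) {
    g <- genes[[1]]
    trs <- lapply(g, .presence)
    if (length(trs) == 1L) {
      p <- trs[[1]]
      if (.setEq(p, c("PVK", "PK")) && !any_trypto)
        return(list(pattern = "A",
                    rationale = "single gene, single transcript, PVK+PK, no trypto-PK"))
      if (.setEq(p, c("PVK", "trypto_PK", "PK")))
        return(list(pattern = "B",
                    rationale = "single gene, single transcript with all three ligand types"))
      if (.setEq(p, "PVK"))
        return(list(pattern = "unresolved", rationale = "derived: PVK-only"))
      if (.setEq(p, "PK"))
        return(list(pattern = "unresolved", rationale = "derived: PK-only"))
      return(list(pattern = "unresolved",
                  rationale = paste("single-gene composition not in the decision table:",
                                    paste(p, collapse = "+"))))
    }
    if (length(trs) == 2L) {
      full <- vapply(trs, function(p) .setEq(p, c("PVK", "trypto_PK", "PK")),
                     logical(1))
      part <- vapply(trs, function(p) .setEq(p, c("PVK", "trypto_PK")),
                     logical(1))
      if (any(full) && any(part) && sum(full) + sum(part) == 2L)
        return(list(pattern = "B1",
                    rationale = "one gene, second splice transcript restricted to PVK+trypto-PK"))
      return(list(pattern = "unresolved",
                  rationale = "two-transcript gene outside the B1 composition"))
    }
    return(list(pattern = "unresolved",
                rationale = sprintf("%d transcripts on a single gene", length(trs))))
  }
  if (length(genes) == 2L) {
    has_pvk <- vapply(gene_presence, function(p) "PVK" %in% p, logical(1))
    if (sum(has_pvk) == 2L)
      return(list(pattern = "unresolved",
                  rationale = "two PVK-bearing genes; capa-like gene not unique"))
    if (sum(has_pvk) == 0L)
      return(list(pattern = "unresolved",
                  rationale = "two PVK-free genes; no capa-like gene"))
    capa <- gene_presence[[which(has_pvk)]]
    pk <- gene_presence[[which(!has_pvk)]]
    if (.setEq(capa, c("PVK", "trypto_PK")) && .setEq(pk, "PK"))
      return(list(pattern = "C1",
                  rationale = "capa-like PVK+trypto-PK; pk-like gene PKs only"))
    if (.setEq(capa, c("PVK", "trypto_PK")) &&
        .setEq(pk, c("trypto_PK", "PK")))
      return(list(pattern = "C2",
                  rationale = "pk-like gene carries its own trypto-PK besides the PKs"))
    if (.setEq(capa, c("PVK", "trypto_PK", "PK")) &&
        .setEq(pk, c("trypto_PK", "PK")))
      return(list(pattern = "C3",
                  rationale = "additional PKs encoded within the capa-like gene"))
    return(list(pattern = "unresolved",
                rationale = sprintf("two-gene composition not in the decision table: capa %s / pk %s",
                                    paste(capa, collapse = "+"),
                                    paste(pk, collapse = "+"))))
  }
  list(pattern = "unresolved",
       rationale = sprintf("%d capa/pk genes", length(genes)))
}

#' Build capa/pk gene complements from annotated precursors
#'
#' Collects the capa/pk-complex precursors (assigned family CAPA or
#' PK/PBAN) of each species, groups splice variants into genes (without a
#' genome, two transcripts that do not share a splice group are treated as
#' two genes), and records each transcript's ligand-type multiset.
#'
#' @param annotated list of \code{AnnotatedPrecursor}.
#' @param prefix_len splice-grouping prefix length (default 30).
#' @return named list of \code{GeneComplement}, one per species with at
#'   least one capa/pk precursor.
#' @export
buildGeneComplements <- function(annotated, prefix_len = 30) {
  capa <- Filter(function(a) a@family %in% c("CAPA", "PK/PBAN"), annotated)
  if (!length(capa)) return(list())
  out <- list()
  for (sp in unique(vapply(capa, function(a) a@species, character(1)))) {
    sub <- Filter(function(a) a@species == sp, capa)
    groups <- groupSpliceVariants(sub, prefix_len = prefix_len)
    grouped_ids <- unlist(lapply(groups, function(g) g$variants$id))
    ligands <- function(a) {
      pep <- a@peptides
      types <- vapply(seq_len(nrow(pep)), function(k)
        typeCapaLigand(pep$processed[k], pep$amidated[k]), character(1))
      types[types != "other"]
    }
    genes <- list()
    for (g in groups)
      genes[[g$gene_label]] <- lapply(g$variants$id, function(id)
        ligands(sub[[which(vapply(sub, function(a) a@id, character(1)) == id)]]))
    for (a in sub)
      if (!a@id %in% grouped_ids) genes[[a@id]] <- list(ligands(a))
    genes <- Filter(function(g) any(lengths(g) > 0), genes)
    if (!length(genes)) next
    out[[sp]] <- GeneComplement(sp, sub[[1]]@taxon_group, genes)
  }
  out
}

#' Summarize architecture patterns by taxon
#'
#' @param complements list of \code{GeneComplement}.
#' @return list(histogram = taxon x pattern table, mixed = character vector
#'   of taxa showing more than one pattern, patterns = per-species
#'   data.frame with rationale).
#' @export
summarizePatterns <- function(complements) {
  stopifnot(length(complements) >= 1)
  rows <- lapply(complements, function(cc) {
    cls <- classifyArchitecture(cc)
    data.frame(species = cc@species, taxon_group = cc@taxon_group,
               pattern = cls$pattern, rationale = cls$rationale,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  hist <- table(factor(df$taxon_group, levels = unique(df$taxon_group)),
                factor(df$pattern, levels = ARCHITECTURE_PATTERNS))
  hist <- hist[, colSums(hist) > 0, drop = FALSE]
  mixed <- rownames(hist)[rowSums(hist > 0) > 1]
  list(histogram = hist, mixed = mixed, patterns = df)
}

#' Pattern report as a TSV-ready table
#'
#' One row per species: pattern, rationale and a per-gene composition
#' string such as \code{"gene1: PVKx3+trypto_PK; gene2: PKx4"}.
#'
#' @param complements list of \code{GeneComplement}.
#' @return data.frame.
#' @export
patternReport <- function(complements) {
  rows <- lapply(complements, function(cc) {
    cls <- classifyArchitecture(cc)
    comp <- vapply(names(cc@genes), function(nm) {
      g <- cc@genes[[nm]]
      trs <- vapply(g, function(tr) {
        tt <- table(tr)
        paste(ifelse(tt > 1, paste0(names(tt), "x", tt), names(tt)),
              collapse = "+")
      }, character(1))
      paste0(nm, ": ", paste(trs, collapse = " | "))
    }, character(1))
    data.frame(species = cc@species, taxon = cc@taxon_group,
               pattern = cls$pattern, rationale = cls$rationale,
               composition = paste(comp, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
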