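#' Annotate one precursor protein
#'
#' Runs the full annotation chain on a single precursor: signal-peptide
#' prediction, convertase cleavage-site assignment, mature-peptide excision
#' with amidation/pyroglutamate calls, and family assignment with paracopy
#' counting.
#'
#' @param residues precursor amino-acid string.
#' @param registry a \code{FamilyRegistry}.
#' @param id,species,taxon_group record metadata.
#' @param n_complete,c_complete completeness flags.
#' @param signal_threshold decision threshold passed to
#'   \code{\link{predictSignalPeptide}}.
#' @param allow_KK accept KK/RK dibasic sites.
#' @param external_signal optional precomputed signal predictions
#'   (data.frame id, cleavage_after, score).
#' @return an \code{AnnotatedPrecursor}.
#' @export
annotatePrecursor <- function(residues, registry, id = "precursor",
                              species = "unknown", taxon_group = "other",
                              n_complete = TRUE, c_complete = TRUE,
                              signal_threshold = 2, allow_KK = TRUE,
                              external_signal = NULL) {
  residues <- toupper(as.character(residues))
  sig <- predictSignalPeptide(residues, n_complete = n_complete,
                              threshold = signal_threshold,
                              external = external_signal, id = id)
  sig_end <- if (sig$present) sig$cleavage_after else 0L
  sites <- predictCleavageSites(residues, signal_end = sig_end,
                                allow_KK = allow_KK)
  peptides <- excisePeptides(residues, signal_end = sig_end, sites = sites)
  ann <- new("AnnotatedPrecursor", id = id, species = species,
             taxon_group = taxon_group, residues = residues,
             n_complete = n_complete, c_complete = c_complete,
             partial = !n_complete || !c_complete,
             signal = sig, sites = sites, peptides = peptides,
             family = "unassigned", paracopy_count = 0L,
             ligand_counts = integer(0))
  fa <- assignFamily(ann, registry)
  ann@family <- fa$family
  ann@paracopy_count <- fa$paracopy_count
  ann@ligand_counts <- fa$ligand_counts
  ann@partial <- fa$partial
  validObject(ann)
  ann
}

#' Annotate every precursor of a PrecursorSet
#'
#' @param precursors a \code{PrecursorSet}.
#' @param registry a \code{FamilyRegistry}.
#' @param ... passed to \code{\link{annotatePrecursor}}.
#' @return list of \code{AnnotatedPrecursor}, one per record.
#' @export
annotatePrecursorSet <- function(precursors, registry, ...) {
  info <- seqInfo(precursors)
  seqs <- as.character(sequences(precursors))
  lapply(seq_len(length(precursors)), function(i)
    annotatePrecursor(seqs[i], registry, id = info$id[i],
                      species = info$species[i],
                      taxon_group = info$taxon_group[i],
                      n_complete = info$n_complete[i],
                      c_complete = info$c_complete[i], ...))
}

#' Family-assignment table of annotated precursors
#'
#' One row per precursor: the inputs expected by
#' \code{\link{summarizeParacopies}} and \code{\link{presenceMatrix}}. For
#' capa/pk-complex precursors additional rows report the per-ligand-type
#' counts under the pseudo-family names \code{"CAPA/PK:PVK"},
#' \code{"CAPA/PK:trypto-PK"} and \code{"CAPA/PK:PK"}, matching the way
#' paracopy tables are reported for the three-ligand gene complex.
#'
#' @param annotated list of \code{AnnotatedPrecursor}.
#' @param split_capa_ligands emit the per-ligand pseudo-family rows
#'   (default TRUE).
#' @return data.frame(precursor_id, species, taxon_group, family,
#'   paracopy_count, partial).
#' @export
familyAssignments <- function(annotated, split_capa_ligands = TRUE) {
  rows <- list()
  add <- function(a, family, count)
    rows[[length(rows) + 1L]] <<- data.frame(
      precursor_id = a@id, species = a@species, taxon_group = a@taxon_group,
      family = family, paracopy_count = count, partial = a@partial,
      stringsAsFactors = FALSE)
  for (a in annotated) {
    add(a, a@family, a@paracopy_count)
    if (split_capa_ligands && length(a@ligand_counts)) {
      lig_names <- c(PVK = "CAPA/PK:PVK", trypto_PK = "CAPA/PK:trypto-PK",
                     PK = "CAPA/PK:PK")
      for (lt in names(a@ligand_counts))
        if (a@ligand_counts[[lt]] > 0)
          add(a, lig_names[[lt]], a@ligand_counts[[lt]])
    }
  }
  do.call(rbind, rows)
}
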