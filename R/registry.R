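#' Load a family registry
#'
#' Reads a YAML registry of neuropeptide/protein-hormone family definitions
#' and validates it: unique names, at least one motif per family, and --
#' unless \code{allow_custom} -- exactly the 39 families of the default
#' registry shipped with the package.
#'
#' @param path YAML file; defaults to the packaged registry.
#' @param allow_custom allow a registry with a different family census.
#' @return a \code{FamilyRegistry}.
#' @export
loadRegistry <- function(path = NULL, allow_custom = FALSE) {
  if (is.null(path))
    path <- system.file("extdata", "family_registry.yaml",
                        package = "NeuropeptideMiner", mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  fams <- lapply(doc$families, function(f) {
    motifs <- unlist(f$motifs)
    list(name = f$name,
         motifs = motifs,
         copy_class = f$copy_class,
         requires_amidation = isTRUE(f$requires_amidation),
         priority = as.integer(f$priority),
         confidence = if (is.null(f$confidence)) "high" else f$confidence,
         exemplar = f$exemplar,
         comment = if (is.null(f$comment)) "" else f$comment)
  })
  nms <- vapply(fams, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate family name in registry: ",
         nms[duplicated(nms)][1])
  names(fams) <- nms
  if (!allow_custom && length(fams) != 39)
    stop("registry must define exactly 39 families (found ", length(fams),
         "); pass allow_custom = TRUE for a custom registry")
  new("FamilyRegistry", families = fams)
}

#' The packaged default registry
#' @return a \code{FamilyRegistry} with the 39 default families.
#' @export
defaultRegistry <- function() loadRegistry()

#' Classify a processed peptide against the registry
#'
#' Matches the processed display string (trailing \code{"a"} = amide,
#' leading \code{"pQ"} = pyroglutamate) against every family motif. Families
#' that require amidation only match amidated peptides. Matches are returned
#' sorted by decreasing priority; classification is deterministic and does
#' not depend on registry order beyond the explicit priority integers (name
#' is the final tie-break).
#'
#' @param processed processed peptide display string.
#' @param registry a \code{FamilyRegistry}.
#' @return data.frame(family, motif_id, priority), possibly empty.
#' @export
classifyPeptide <- function(processed, registry) {
  processed <- as.character(processed)
  amidated <- endsWith(processed, "a")
  rows <- list()
  for (f in registry@families) {
    if (f$requires_amidation && !amidated) next
    for (mi in seq_along(f$motifs)) {
      if (grepl(f$motifs[[mi]], processed)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = f$name, motif_id = names(f$motifs)[mi],
          priority = f$priority, stringsAsFactors = FALSE)
        break
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), motif_id = character(0),
               priority = integer(0))
  out[order(-out$priority, out$family), , drop = FALSE]
}

#' Ligand-type a capa/pk-complex peptide
#'
#' Maps an amidated peptide to one of the three capa/pk ligand classes,
#' with the priority tryptopyrokinin > pyrokinin > periviscerokinin so that
#' the classes are mutually exclusive (each has its own receptor):
#' tryptopyrokinins end W[FY]GPRLa, pyrokinins F-X-PRLa, periviscerokinins
#' PR[VIL]a. Non-amidated peptides are \code{"other"}.
#'
#' @param processed processed peptide display string.
#' @param amidated is the peptide amidated? Defaults to the trailing "a".
#' @return one of \code{"trypto_PK"}, \code{"PK"}, \code{"PVK"},
#'   \code{"other"}.
#' @export
typeCapaLigand <- function(processed, amidated = endsWith(processed, "a")) {
  if (!amidated) return("other")
  if (grepl("W[FY]GPRLa$", processed)) return("trypto_PK")
  if (grepl("F.PRLa$", processed)) return("PK")
  if (grepl("PR[VIL]a$", processed)) return("PVK")
  "other"
}

## peptide-level classification table for a peptide data.frame
.classifyPeptideTable <- function(peptides, registry) {
  if (!nrow(peptides))
    return(data.frame(copy_index = integer(0), family = character(0),
                      motif_id = character(0), priority = integer(0)))
  rows <- list()
  for (k in seq_len(nrow(peptides))) {
    hits <- classifyPeptide(peptides$processed[k], registry)
    if (nrow(hits))
      rows[[length(rows) + 1L]] <-
        cbind(copy_index = peptides$copy_index[k], hits)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(copy_index = integer(0), family = character(0),
               motif_id = character(0), priority = integer(0))
}

#' Assign a precursor to a family and count paracopies
#'
#' The precursor family is the highest-priority family matched by at least
#' one excised peptide. For the capa/pk complex (families CAPA and PK/PBAN
#' share the tryptopyrokinin and overlap on generic C-termini) the decision
#' is made on ligand types: a precursor with any periviscerokinin is a CAPA
#' precursor, a PVK-free pyrokinin precursor is PK/PBAN. The paracopy count
#' is the number of matched peptides for multiple-copy families and 1 for
#' single-copy families (extra same-family precursors in one species are
#' gene duplications, not paracopies). A precursor that is incomplete at
#' either end carries \code{partial = TRUE}, so downstream statistics use
#' its count only as a lower bound.
#'
#' @param annotated an \code{AnnotatedPrecursor} (family slots may be
#'   unfilled) or a peptide data.frame from \code{\link{excisePeptides}}.
#' @param registry a \code{FamilyRegistry}.
#' @return list(family, paracopy_count, matched, ligand_counts, partial).
#' @export
assignFamily <- function(annotated, registry) {
  if (is(annotated, "AnnotatedPrecursor")) {
    peptides <- annotated@peptides
    partial <- !annotated@n_complete || !annotated@c_complete
  } else {
    peptides <- annotated
    partial <- FALSE
  }
  tab <- .classifyPeptideTable(peptides, registry)
  ligand_counts <- integer(0)
  if (!nrow(tab))
    return(list(family = "unassigned", paracopy_count = 0L,
                matched = tab, ligand_counts = ligand_counts,
                partial = partial))
  fam_best <- tab[!duplicated(tab$copy_index), , drop = FALSE]  # per-peptide top
  top <- fam_best$family[which.max(fam_best$priority)]
  if (top %in% c("CAPA", "PK/PBAN")) {
    capa_peps <- peptides[peptides$copy_index %in%
      tab$copy_index[tab$family %in% c("CAPA", "PK/PBAN")], , drop = FALSE]
    types <- vapply(seq_len(nrow(capa_peps)), function(k)
      typeCapaLigand(capa_peps$processed[k], capa_peps$amidated[k]),
      character(1))
    types <- types[types != "other"]
    ligand_counts <- vapply(c("PVK", "trypto_PK", "PK"),
                            function(t) sum(types == t), integer(1))
    top <- if (ligand_counts[["PVK"]] > 0) "CAPA" else "PK/PBAN"
    count <- as.integer(sum(ligand_counts))
  } else {
    count <- length(unique(tab$copy_index[tab$family == top]))
    if (getFamily(registry, top)$copy_class == "single")
      count <- 1L
  }
  list(family = top, paracopy_count = as.integer(count),
       matched = tab[tab$family == top, , drop = FALSE],
       ligand_counts = ligand_counts, partial = partial)
}
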