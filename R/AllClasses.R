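#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Recognised higher taxa
#'
#' The taxon groups used throughout the package. Records with any other
#' label are mapped to \code{"other"}, never dropped.
#' @export
TAXON_GROUPS <- c("Protura", "Collembola", "Diplura", "Archaeognatha",
                  "Zygentoma", "Remipedia", "Malacostraca", "Branchiopoda",
                  "Chilopoda", "Symphyla", "Diplopoda", "Diptera", "other")

#' The capa/pk ligand classes
#' @export
LIGAND_TYPES <- c("PVK", "trypto_PK", "PK", "other")

#' The capa/pk gene-architecture patterns
#' @export
ARCHITECTURE_PATTERNS <- c("A", "B", "B1", "C1", "C2", "C3", "unresolved")

#' PrecursorSet: amino-acid precursors with per-record metadata
#'
#' A set of precursor proteins (as an \code{AAStringSet}) together with
#' per-record metadata: species, taxon group, N-/C-terminal completeness and
#' whether an artifact repair was applied. Incompleteness markers
#' (\code{"..."} or terminal \code{X} runs) in the input are stripped on read
#' and recorded as completeness flags.
#'
#' @slot sequences an \code{AAStringSet}, one entry per precursor.
#' @slot info a \code{DataFrame} with columns \code{id}, \code{species},
#'   \code{taxon_group}, \code{n_complete}, \code{c_complete},
#'   \code{corrected}, \code{source_transcript}.
#' @export
setClass("PrecursorSet",
  representation(sequences = "AAStringSet", info = "DataFrame"))

setValidity("PrecursorSet", function(object) {
  msg <- character()
  req <- c("id", "species", "taxon_group", "n_complete", "c_complete",
           "corrected", "source_transcript")
  if (!all(req %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(req, collapse = ", ")))
  else {
    if (length(object@sequences) != nrow(object@info))
      msg <- c(msg, "sequences and info lengths differ")
    if (anyDuplicated(object@info$id))
      msg <- c(msg, "precursor ids must be unique")
    if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
      msg <- c(msg, "empty sequences are not allowed")
    if (!all(object@info$taxon_group %in% TAXON_GROUPS))
      msg <- c(msg, "unknown taxon_group (map unknowns to 'other')")
  }
  if (length(msg)) msg else TRUE
})

#' TranscriptSet: nucleotide transcripts with per-record metadata
#'
#' @slot sequences a \code{DNAStringSet}.
#' @slot info a \code{DataFrame} with columns \code{id}, \code{species},
#'   \code{taxon_group}.
#' @export
setClass("TranscriptSet",
  representation(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  msg <- character()
  req <- c("id", "species", "taxon_group")
  if (!all(req %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(req, collapse = ", ")))
  else {
    if (length(object@sequences) != nrow(object@info))
      msg <- c(msg, "sequences and info lengths differ")
    if (anyDuplicated(object@info$id))
      msg <- c(msg, "transcript ids must be unique")
    if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
      msg <- c(msg, "empty sequences are not allowed")
    if (!all(object@info$taxon_group %in% TAXON_GROUPS))
      msg <- c(msg, "unknown taxon_group (map unknowns to 'other')")
  }
  if (length(msg)) msg else TRUE
})

#' FamilyRegistry: the neuropeptide/protein-hormone family definitions
#'
#' Holds one definition per family: anchored motifs (POSIX regular
#' expressions matched against the processed peptide display string, in which
#' a C-terminal amide is written as a trailing \code{"a"} and an N-terminal
#' pyroglutamate as a leading \code{"pQ"}), the copy-number class, whether
#' mature peptides are amidated, a priority integer for tie-breaking, and a
#' representative mature peptide used by the synthetic generator.
#'
#' @slot families named list; each element is a list with fields
#'   \code{name}, \code{motifs} (named character vector of regex patterns),
#'   \code{copy_class} ("single"/"multiple"), \code{requires_amidation},
#'   \code{priority}, \code{exemplar}, \code{confidence}, \code{comment}.
#' @export
setClass("FamilyRegistry", representation(families = "list"))

setValidity("FamilyRegistry", function(object) {
  msg <- character()
  fams <- object@families
  nms <- vapply(fams, function(f) f$name, character(1))
  if (anyDuplicated(nms)) msg <- c(msg, "duplicate family names")
  if (!identical(names(fams), unname(nms)))
    msg <- c(msg, "list names must equal family names")
  for (f in fams) {
    if (length(f$motifs) < 1)
      msg <- c(msg, paste0("family ", f$name, " has no motifs"))
    if (!f$copy_class %in% c("single", "multiple"))
      msg <- c(msg, paste0("family ", f$name, ": bad copy_class"))
  }
  if (length(msg)) msg else TRUE
})

#' AnnotatedPrecursor: a fully annotated precursor protein
#'
#' Produced by \code{\link{annotatePrecursor}}: the signal-peptide call, all
#' candidate convertase cleavage sites (accepted or not, with reasons), the
#' excised mature peptides with amidation/pyroglutamate calls, and the family
#' assignment with paracopy count and ligand-type counts for capa/pk-complex
#' precursors.
#'
#' @slot id,species,taxon_group character scalars.
#' @slot residues the precursor amino-acid string.
#' @slot n_complete,c_complete,partial logical scalars.
#' @slot signal list(present, cleavage_after, score, reason).
#' @slot sites data.frame of candidate cleavage sites
#'   (p1_index, site_class, accepted, reason).
#' @slot peptides data.frame of mature peptides
#'   (start, end, raw, processed, amidated, pyroglu, copy_index).
#' @slot family character; assigned family or "unassigned".
#' @slot paracopy_count integer.
#' @slot ligand_counts named integer vector (PVK, trypto_PK, PK) for
#'   capa/pk-complex precursors, otherwise zero-length.
#' @export
setClass("AnnotatedPrecursor",
  representation(id = "character", species = "character",
    taxon_group = "character", residues = "character",
    n_complete = "logical", c_complete = "logical", partial = "logical",
    signal = "list", sites = "data.frame", peptides = "data.frame",
    family = "character", paracopy_count = "integer",
    ligand_counts = "integer"))

setValidity("AnnotatedPrecursor", function(object) {
  msg <- character()
  if (nchar(object@residues) == 0) msg <- c(msg, "empty precursor")
  if (nrow(object@peptides)) {
    bad <- object@peptides$end > nchar(object@residues) |
      object@peptides$start < 1
    if (any(bad)) msg <- c(msg, "peptide span outside precursor")
    raws <- substring(object@residues, object@peptides$start,
                      object@peptides$end)
    if (!identical(raws, object@peptides$raw))
      msg <- c(msg, "raw peptide does not equal precursor substring")
  }
  if (length(msg)) msg else TRUE
})

#' GeneComplement: a species' capa/pk-related gene products
#'
#' Each gene is a list of transcripts; each transcript is a character vector
#' (a multiset) of ligand types over \code{PVK}, \code{trypto_PK}, \code{PK}.
#' Transcripts of one gene are splice variants of each other.
#'
#' @slot species,taxon_group character scalars.
#' @slot genes named list of lists of character vectors.
#' @export
setClass("GeneComplement",
  representation(species = "character", taxon_group = "character",
                 genes = "list"))

setValidity("GeneComplement", function(object) {
  msg <- character()
  if (length(object@genes) < 1) msg <- c(msg, "complement must have >= 1 gene")
  for (g in object@genes) {
    if (!length(g)) msg <- c(msg, "gene with no transcripts")
    for (tr in g) {
      if (!length(tr)) msg <- c(msg, "empty transcript composition")
      if (!all(tr %in% c("PVK", "trypto_PK", "PK")))
        msg <- c(msg, "transcript composition restricted to PVK/trypto_PK/PK")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---- constructors -------------------------------------------------------

#' Construct a PrecursorSet
#'
#' @param residues character vector (or \code{AAStringSet}) of amino-acid
#'   sequences.
#' @param id,species,taxon_group character vectors recycled to length.
#' @param n_complete,c_complete,corrected logical vectors.
#' @param source_transcript optional character vector.
#' @return a \code{PrecursorSet}.
#' @export
PrecursorSet <- function(residues, id = names(residues), species = "unknown",
                         taxon_group = "other", n_complete = TRUE,
                         c_complete = TRUE, corrected = FALSE,
                         source_transcript = NA_character_) {
  if (!is(residues, "AAStringSet"))
    residues <- Biostrings::AAStringSet(as.character(residues))
  n <- length(residues)
  if (is.null(id)) id <- paste0("prec", seq_len(n))
  taxon_group <- ifelse(taxon_group %in% TAXON_GROUPS, taxon_group, "other")
  info <- DataFrame(id = rep_len(as.character(id), n),
                    species = rep_len(as.character(species), n),
                    taxon_group = rep_len(as.character(taxon_group), n),
                    n_complete = rep_len(as.logical(n_complete), n),
                    c_complete = rep_len(as.logical(c_complete), n),
                    corrected = rep_len(as.logical(corrected), n),
                    source_transcript =
                      rep_len(as.character(source_transcript), n))
  names(residues) <- info$id
  new("PrecursorSet", sequences = residues, info = info)
}

#' Construct a TranscriptSet
#'
#' @param sequences character vector (or \code{DNAStringSet}).
#' @param id,species,taxon_group metadata vectors recycled to length.
#' @return a \code{TranscriptSet}.
#' @export
TranscriptSet <- function(sequences, id = names(sequences),
                          species = "unknown", taxon_group = "other") {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(as.character(sequences))
  n <- length(sequences)
  if (is.null(id)) id <- paste0("tx", seq_len(n))
  taxon_group <- ifelse(taxon_group %in% TAXON_GROUPS, taxon_group, "other")
  info <- DataFrame(id = rep_len(as.character(id), n),
                    species = rep_len(as.character(species), n),
                    taxon_group = rep_len(as.character(taxon_group), n))
  names(sequences) <- info$id
  new("TranscriptSet", sequences = sequences, info = info)
}

#' Construct a GeneComplement
#'
#' @param species,taxon_group character scalars.
#' @param genes list of genes, each a list of transcript ligand-type vectors.
#'   A bare character vector is promoted to a single-transcript gene.
#' @return a \code{GeneComplement}.
#' @export
GeneComplement <- function(species, taxon_group, genes) {
  genes <- lapply(genes, function(g) if (is.character(g)) list(g) else g)
  if (is.null(names(genes)) || any(names(genes) == ""))
    names(genes) <- paste0("gene", seq_along(genes))
  new("GeneComplement", species = as.character(species),
      taxon_group = as.character(taxon_group), genes = genes)
}

## ---- generics & accessors ----------------------------------------------

#' @rdname PrecursorSet-class
#' @param x a PrecursorSet or TranscriptSet.
#' @export
setGeneric("seqInfo", function(x) standardGeneric("seqInfo"))

#' @rdname PrecursorSet-class
#' @export
setMethod("seqInfo", "PrecursorSet", function(x) x@info)

#' @rdname TranscriptSet-class
#' @export
setMethod("seqInfo", "TranscriptSet", function(x) x@info)

#' @rdname PrecursorSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname PrecursorSet-class
#' @export
setMethod("sequences", "PrecursorSet", function(x) x@sequences)

#' @rdname TranscriptSet-class
#' @export
setMethod("sequences", "TranscriptSet", function(x) x@sequences)

#' @export
setMethod("length", "PrecursorSet", function(x) length(x@sequences))

#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @export
setMethod("[", "PrecursorSet", function(x, i, j, ..., drop = TRUE) {
  new("PrecursorSet", sequences = x@sequences[i], info = x@info[i, ])
})

#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  new("TranscriptSet", sequences = x@sequences[i], info = x@info[i, ])
})

#' @rdname FamilyRegistry-class
#' @param x a FamilyRegistry.
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))

#' @rdname FamilyRegistry-class
#' @export
setMethod("familyNames", "FamilyRegistry",
          function(x) unname(vapply(x@families, `[[`, character(1), "name")))

#' @export
setMethod("length", "FamilyRegistry", function(x) length(x@families))

#' Look up one family definition
#' @param registry a FamilyRegistry.
#' @param name family name.
#' @return the definition list.
#' @export
getFamily <- function(registry, name) {
  stopifnot(is(registry, "FamilyRegistry"))
  f <- registry@families[[name]]
  if (is.null(f)) stop("unknown family: ", name)
  f
}

#' Mature-peptide table of an annotated precursor
#' @param x an AnnotatedPrecursor.
#' @export
setGeneric("maturePeptides", function(x) standardGeneric("maturePeptides"))

#' @rdname maturePeptides
#' @export
setMethod("maturePeptides", "AnnotatedPrecursor", function(x) x@peptides)

#' Cleavage-site audit table of an annotated precursor
#' @param x an AnnotatedPrecursor.
#' @export
setGeneric("cleavageSites", function(x) standardGeneric("cleavageSites"))

#' @rdname cleavageSites
#' @export
setMethod("cleavageSites", "AnnotatedPrecursor", function(x) x@sites)

#' @rdname AnnotatedPrecursor-class
#' @param x an AnnotatedPrecursor.
#' @export
setGeneric("assignedFamily", function(x) standardGeneric("assignedFamily"))

#' @rdname AnnotatedPrecursor-class
#' @export
setMethod("assignedFamily", "AnnotatedPrecursor", function(x) x@family)

#' @rdname AnnotatedPrecursor-class
#' @export
setGeneric("paracopyCount", function(x) standardGeneric("paracopyCount"))

#' @rdname AnnotatedPrecursor-class
#' @export
setMethod("paracopyCount", "AnnotatedPrecursor", function(x) x@paracopy_count)

## ---- show methods -------------------------------------------------------

setMethod("show", "PrecursorSet", function(object) {
  cat("PrecursorSet with", length(object), "precursors\n")
  if (length(object)) {
    tg <- table(object@info$taxon_group)
    cat("  taxa:", paste(names(tg), tg, sep = ":", collapse = " "), "\n")
    inc <- sum(!object@info$n_complete | !object@info$c_complete)
    if (inc) cat("  incomplete records:", inc, "\n")
  }
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
})

setMethod("show", "FamilyRegistry", function(object) {
  cat("FamilyRegistry with", length(object), "families\n")
  cat(" ", paste(familyNames(object), collapse = ", "), "\n")
})

setMethod("show", "AnnotatedPrecursor", function(object) {
  cat("AnnotatedPrecursor", object@id, sprintf("(%s, %s)\n", object@species,
      object@taxon_group))
  sig <- if (object@signal$present)
    sprintf("signal 1-%d", object@signal$cleavage_after) else "no signal"
  cat(" ", nchar(object@residues), "aa;", sig, ";",
      nrow(object@peptides), "mature peptides; family:", object@family,
      sprintf("(n=%d)%s\n", object@paracopy_count,
              if (object@partial) " [partial]" else ""))
})

setMethod("show", "GeneComplement", function(object) {
  cat("GeneComplement for", object@species, sprintf("(%s): %d gene(s)\n",
      object@taxon_group, length(object@genes)))
  for (nm in names(object@genes)) {
    comps <- vapply(object@genes[[nm]], function(tr)
      paste(names(table(tr)), table(tr), sep = "x", collapse = "+"),
      character(1))
    cat("  ", nm, ": ", paste(comps, collapse = " | "), "\n", sep = "")
  }
})
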