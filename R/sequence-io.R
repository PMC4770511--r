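#' @importFrom Biostrings readBStringSet AAStringSet DNAStringSet width
#' @importFrom utils read.delim write.table
NULL

## Header convention "id|species|taxon"; a sidecar TSV (id, species,
## taxon_group) takes precedence, conflicts are warned about.

.parseHeader <- function(h) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  list(id = trimws(parts[1]),
       species = if (length(parts) >= 2) trimws(parts[2]) else NA_character_,
       taxon = if (length(parts) >= 3) trimws(parts[3]) else NA_character_)
}

.guessAlphabet <- function(x) {
  ## composition-based: nucleotide sequences are almost entirely ACGTNU
  chars <- strsplit(toupper(x), "")
  frac <- vapply(chars, function(ch) {
    ch <- ch[ch != "-" & ch != "."]
    if (!length(ch)) return(1)
    mean(ch %in% c("A", "C", "G", "T", "U", "N"))
  }, numeric(1))
  ifelse(frac >= 0.95, "nt", "aa")
}

#' Read sequences with species/taxon metadata
#'
#' Reads a FASTA file (nucleotide or amino acid, auto-detected from residue
#' composition) and attaches species and taxon-group metadata from a sidecar
#' TSV (columns \code{id}, \code{species}, \code{taxon_group}) or from the
#' header convention \code{"id|species|taxon"}. For protein input,
#' incompleteness markers -- a literal \code{"..."} or a terminal run of
#' \code{X} -- are stripped and recorded in the \code{n_complete} /
#' \code{c_complete} flags, mirroring the "..." convention used in published
#' precursor listings. Unknown taxa are mapped to \code{"other"}; no record
#' is silently dropped.
#'
#' @param path FASTA file.
#' @param metadata optional TSV file; overrides header metadata.
#' @return a \code{PrecursorSet} (protein input) or \code{TranscriptSet}
#'   (nucleotide input).
#' @export
readSequences <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0)
    return(PrecursorSet(character(0), id = character(0)))
  headers <- names(raw)
  seqs <- as.character(raw)
  hmeta <- lapply(headers, .parseHeader)
  ids <- vapply(hmeta, `[[`, character(1), "id")
  species <- vapply(hmeta, `[[`, character(1), "species")
  taxon <- vapply(hmeta, `[[`, character(1), "taxon")
  if (!is.null(metadata)) {
    md <- read.delim(metadata, stringsAsFactors = FALSE)
    if (!all(c("id", "species", "taxon_group") %in% colnames(md)))
      stop("metadata TSV needs columns id, species, taxon_group")
    m <- match(ids, md$id)
    conflict <- !is.na(m) & !is.na(species) & species != md$species[m]
    if (any(conflict))
      warning("metadata TSV overrides header species for: ",
              paste(ids[conflict], collapse = ", "))
    species <- ifelse(is.na(m), species, md$species[m])
    taxon <- ifelse(is.na(m), taxon, md$taxon_group[m])
  }
  species[is.na(species)] <- "unknown"
  taxon[is.na(taxon) | !(taxon %in% TAXON_GROUPS)] <- "other"
  kinds <- .guessAlphabet(gsub("\\.", "", seqs))
  if (length(unique(kinds)) > 1)
    stop("mixed-alphabet input; records look ", kinds[1], " and ",
         kinds[kinds != kinds[1]][1], " (first offender: ",
         ids[which(kinds != kinds[1])[1]], ")")
  if (kinds[1] == "nt") {
    seqs <- toupper(gsub("U", "T", seqs))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-IUPAC nucleotide characters in record ", ids[which(bad)[1]])
    return(TranscriptSet(seqs, id = ids, species = species,
                         taxon_group = taxon))
  }
  ## protein: strip "..." / terminal X runs, set completeness flags
  n_complete <- rep(TRUE, length(seqs))
  c_complete <- rep(TRUE, length(seqs))
  s <- toupper(seqs)
  lead <- grepl("^(\\.\\.\\.|X{3,})", s)
  trail <- grepl("(\\.\\.\\.|X{3,})$", s)
  n_complete[lead] <- FALSE
  c_complete[trail] <- FALSE
  s <- gsub("^(\\.\\.\\.|X{3,})", "", s)
  s <- gsub("(\\.\\.\\.|X{3,})$", "", s)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", s)
  if (any(bad))
    stop("non-amino-acid characters in record ", ids[which(bad)[1]])
  PrecursorSet(s, id = ids, species = species, taxon_group = taxon,
               n_complete = n_complete, c_complete = c_complete)
}

#' Write sequences to FASTA
#'
#' Writes a \code{PrecursorSet} or \code{TranscriptSet} with headers in the
#' \code{"id|species|taxon"} convention, so that
#' \code{readSequences(writeSequences(x))} round-trips sequence payloads and
#' metadata exactly.
#'
#' @param x a PrecursorSet or TranscriptSet.
#' @param path output file.
#' @export
writeSequences <- function(x, path) {
  info <- seqInfo(x)
  headers <- paste(info$id, info$species, info$taxon_group, sep = "|")
  out <- sequences(x)
  names(out) <- headers
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

.annotationTable <- function(annotated) {
  rows <- lapply(annotated, function(a) {
    pep <- maturePeptides(a)
    if (!nrow(pep)) return(NULL)
    data.frame(precursor_id = a@id, family = a@family,
               start = pep$start, end = pep$end,
               processed = pep$processed, amidated = pep$amidated,
               pyroglu = pep$pyroglu, copy_index = pep$copy_index,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(precursor_id = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      processed = character(0), amidated = logical(0),
                      pyroglu = logical(0), copy_index = integer(0))
  out
}

#' Write precursor annotations to TSV or GFF3
#'
#' TSV output has one row per mature peptide. GFF3 output places
#' \code{sig_peptide}, \code{propeptide} and \code{mature_peptide} features
#' on the precursor protein with 1-based inclusive coordinates (standard
#' GFF3 convention).
#'
#' @param annotated list of \code{AnnotatedPrecursor}.
#' @param path output file.
#' @param format \code{"TSV"} or \code{"GFF3"}.
#' @export
writeAnnotations <- function(annotated, path, format = c("TSV", "GFF3")) {
  format <- match.arg(format)
  for (a in annotated) {
    pep <- maturePeptides(a)
    if (nrow(pep) && any(pep$end > nchar(a@residues)))
      stop("annotation span outside precursor length for ", a@id)
  }
  if (format == "TSV") {
    write.table(.annotationTable(annotated), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  feats <- list()
  for (a in annotated) {
    if (a@signal$present)
      feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
        seqnames = a@id,
        ranges = IRanges::IRanges(1L, a@signal$cleavage_after),
        type = "sig_peptide", ID = paste0(a@id, ":sig"))
    propep_start <- if (a@signal$present) a@signal$cleavage_after + 1L else 1L
    if (propep_start <= nchar(a@residues))
      feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
        seqnames = a@id,
        ranges = IRanges::IRanges(propep_start, nchar(a@residues)),
        type = "propeptide", ID = paste0(a@id, ":pro"))
    pep <- maturePeptides(a)
    if (nrow(pep))
      feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
        seqnames = a@id,
        ranges = IRanges::IRanges(pep$start, pep$end),
        type = "mature_peptide",
        ID = paste0(a@id, ":pep", pep$copy_index))
  }
  gr <- if (length(feats)) suppressWarnings(do.call(c, feats))
        else GenomicRanges::GRanges()
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 annotation file back as a GRanges
#'
#' Convenience wrapper around \code{rtracklayer::import} for round-tripping
#' annotation output.
#' @param path GFF3 file written by \code{\link{writeAnnotations}}.
#' @return a \code{GRanges}.
#' @export
readAnnotations <- function(path) {
  rtracklayer::import(path, format = "gff3")
}
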