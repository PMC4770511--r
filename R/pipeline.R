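#' Assemble a run configuration
#'
#' @param input FASTA path (nucleotide or protein).
#' @param metadata optional metadata TSV.
#' @param registry registry YAML path (NULL = packaged default).
#' @param out_dir output directory.
#' @param signal_threshold,allow_KK,min_orf_len,splice_prefix_len pipeline
#'   thresholds.
#' @param seed RNG seed recorded in the config.
#' @return a RunConfig list.
#' @export
runConfig <- function(input, metadata = NULL, registry = NULL,
                      out_dir = tempfile("npmine_run_"),
                      signal_threshold = 2, allow_KK = TRUE,
                      min_orf_len = 40, splice_prefix_len = 30, seed = 1) {
  list(input = input, metadata = metadata, registry = registry,
       out_dir = out_dir, signal_threshold = signal_threshold,
       allow_KK = allow_KK, min_orf_len = min_orf_len,
       splice_prefix_len = splice_prefix_len, seed = seed)
}

#' Load a run configuration from YAML
#' @param path YAML config file.
#' @return a RunConfig list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}

.stageLog <- function(log, stage, event, n) {
  rbind(log, data.frame(stage = stage, event = event, n = n,
                        stringsAsFactors = FALSE))
}

#' Run the annotation pipeline end to end
#'
#' read -> (six-frame translation and ORF extraction when the input is
#' nucleotide) -> signal peptide -> cleavage sites -> excision -> family
#' assignment -> splice grouping; writes annotation TSV and GFF3, the
#' family-assignment table, a per-stage count log, and the resolved
#' configuration (so a rerun from the written config is identical).
#'
#' @param config from \code{\link{runConfig}} or \code{\link{readRunConfig}}.
#' @return invisibly, list(annotated, assignments, splice_groups, log,
#'   out_dir).
#' @export
runAnnotate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(config$out_dir, "run_config.yaml"))
  registry <- loadRegistry(config$registry)
  log <- data.frame(stage = character(0), event = character(0),
                    n = integer(0))
  set.seed(config$seed)
  x <- readSequences(config$input, config$metadata)
  log <- .stageLog(log, "read", "records", length(x))
  if (is(x, "TranscriptSet")) {
    ## keep, per transcript, the longest ORF candidate
    precs <- list()
    for (i in seq_len(length(x))) {
      orfs <- findOrfs(x[i], min_len = config$min_orf_len)
      if (!nrow(orfs)) next
      ## prefer complete (Met-initiated, stop-terminated) ORFs over longer
      ## edge artifacts, then longer over shorter
      orfs <- orfs[order(-(orfs$has_start & orfs$has_stop),
                         -nchar(orfs$protein)), , drop = FALSE]
      best <- orfs[1, ]
      info <- seqInfo(x)[i, ]
      precs[[length(precs) + 1L]] <- PrecursorSet(
        gsub("\\*$", "", best$protein), id = info$id,
        species = info$species, taxon_group = info$taxon_group,
        n_complete = best$has_start, c_complete = best$has_stop,
        source_transcript = info$id)
    }
    log <- .stageLog(log, "orf", "precursors", length(precs))
    log <- .stageLog(log, "orf", "rejected_no_orf",
                     length(x) - length(precs))
    if (!length(precs)) {
      x <- PrecursorSet(character(0), id = character(0))
    } else {
      seqs <- unlist(lapply(precs, function(p) as.character(sequences(p))))
      infos <- do.call(rbind, lapply(precs, seqInfo))
      x <- PrecursorSet(seqs, id = infos$id, species = infos$species,
                        taxon_group = infos$taxon_group,
                        n_complete = infos$n_complete,
                        c_complete = infos$c_complete,
                        source_transcript = infos$source_transcript)
    }
  }
  if (length(x) == 0) {
    warning("no records to annotate; writing empty outputs")
    annotated <- list()
  } else {
    annotated <- annotatePrecursorSet(
      x, registry, signal_threshold = config$signal_threshold,
      allow_KK = config$allow_KK)
  }
  log <- .stageLog(log, "annotate", "annotated", length(annotated))
  assignments <- if (length(annotated)) familyAssignments(annotated) else
    data.frame(precursor_id = character(0), species = character(0),
               taxon_group = character(0), family = character(0),
               paracopy_count = integer(0), partial = logical(0))
  splice_groups <- if (length(annotated) >= 2)
    groupSpliceVariants(annotated, prefix_len = config$splice_prefix_len)
  else list()
  log <- .stageLog(log, "splice", "groups", length(splice_groups))
  writeAnnotations(annotated, file.path(config$out_dir, "annotations.tsv"),
                   "TSV")
  writeAnnotations(annotated, file.path(config$out_dir, "annotations.gff3"),
                   "GFF3")
  utils::write.table(assignments,
                     file.path(config$out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(log, file.path(config$out_dir, "stage_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(annotated = annotated, assignments = assignments,
                 splice_groups = splice_groups, log = log,
                 out_dir = config$out_dir))
}

#' Build the comparative reports from an annotation run
#'
#' Produces the paracopy summary table (mean with uncorrected S_N per
#' family and taxon, lower-bound rendering for partial-only cells), the
#' family-by-taxon presence matrix, and the capa/pk architecture-pattern
#' report.
#'
#' @param run result of \code{\link{runAnnotate}} (or a config list, in
#'   which case the annotation stage is run first).
#' @param logo_families optionally, families for which a C-terminally
#'   padded sequence logo matrix of the mature peptides is computed.
#' @return list(paracopies, presence, patterns, logos).
#' @export
runReport <- function(run, logo_families = character(0)) {
  if (is.null(run$annotated)) run <- runAnnotate(run)
  if (!length(run$annotated))
    return(list(paracopies = renderParacopyTable(
                  summarizeParacopies(run$assignments)),
                presence = presenceMatrix(run$assignments),
                patterns = NULL, logos = list()))
  summaries <- summarizeParacopies(run$assignments)
  rendered <- renderParacopyTable(summaries)
  presence <- presenceMatrix(run$assignments)
  complements <- buildGeneComplements(run$annotated)
  patterns <- if (length(complements)) summarizePatterns(complements)
              else NULL
  logos <- list()
  for (fam in logo_families) {
    peps <- unlist(lapply(run$annotated, function(a) {
      if (a@family != fam) return(character(0))
      tab <- .classifyPeptideTable(a@peptides, defaultRegistry())
      a@peptides$processed[a@peptides$copy_index %in%
                             tab$copy_index[tab$family == fam]]
    }))
    if (length(peps) >= 2)
      logos[[fam]] <- buildLogo(padAlignC(peps))
  }
  if (!is.null(run$out_dir)) {
    utils::write.table(rendered, file.path(run$out_dir, "paracopies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(patterns))
      utils::write.table(patterns$patterns,
                         file.path(run$out_dir, "capa_pk_patterns.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(paracopies = rendered, presence = presence, patterns = patterns,
       logos = logos)
}
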