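#' Uncorrected sample standard deviation
#'
#' The population-style dispersion statistic with denominator N (not N-1):
#' \code{sqrt(mean((x - mean(x))^2))}. For the sample \{3, 4\} this gives
#' 0.5, which distinguishes it from the corrected standard deviation
#' (0.707...).
#'
#' @param x numeric vector.
#' @return a scalar.
#' @export
uncorrectedSD <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

#' Summarize paracopy counts per family and taxon
#'
#' Mirrors the reporting convention of comparative paracopy tables: only
#' full-length precursors enter the mean and uncorrected standard deviation
#' S_N; a single full-length precursor yields a mean without S_N; a
#' family/taxon cell with only partial precursors reports the maximum
#' observed count as a lower bound; cells with no evidence are omitted.
#'
#' @param assignments data.frame from \code{\link{familyAssignments}}
#'   (columns family, taxon_group, paracopy_count, partial).
#' @param families restrict to these families (default: all present).
#' @return data.frame(family, taxon, n_full, mean, s_n, max_partial).
#' @export
summarizeParacopies <- function(assignments, families = NULL) {
  df <- assignments[assignments$family != "unassigned", , drop = FALSE]
  if (!is.null(families)) df <- df[df$family %in% families, , drop = FALSE]
  rows <- list()
  for (fam in unique(df$family)) {
    for (tax in unique(df$taxon_group[df$family == fam])) {
      sub <- df[df$family == fam & df$taxon_group == tax, , drop = FALSE]
      full <- sub$paracopy_count[!sub$partial]
      part <- sub$paracopy_count[sub$partial]
      if (!length(full) && !length(part)) next
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, taxon = tax, n_full = length(full),
        mean = if (length(full)) mean(full) else NA_real_,
        s_n = if (length(full) >= 2) uncorrectedSD(full) else NA_real_,
        max_partial = if (!length(full) && length(part)) max(part)
                      else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), taxon = character(0),
               n_full = integer(0), mean = numeric(0), s_n = numeric(0),
               max_partial = integer(0))
}

#' Family-by-taxon presence matrix
#'
#' Counts, per family and taxon, the number of species with at least one
#' assigned precursor. A zero cell is a genuine observed absence within the
#' screened taxa; taxa that were never screened simply do not appear as
#' columns (absence of data, not absence of the gene).
#'
#' @param assignments data.frame from \code{\link{familyAssignments}}.
#' @param taxa column order; defaults to taxa present in the data.
#' @param families row order; defaults to families present in the data.
#' @return integer matrix, families x taxa.
#' @export
presenceMatrix <- function(assignments, taxa = NULL, families = NULL) {
  df <- assignments[assignments$family != "unassigned", , drop = FALSE]
  if (is.null(taxa)) taxa <- unique(df$taxon_group)
  if (is.null(families)) families <- unique(df$family)
  m <- matrix(0L, nrow = length(families), ncol = length(taxa),
              dimnames = list(families, taxa))
  for (fam in families) for (tax in taxa) {
    sub <- df[df$family == fam & df$taxon_group == tax, , drop = FALSE]
    m[fam, tax] <- length(unique(sub$species))
  }
  m
}

LOGO_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a sequence-logo matrix from aligned peptides
#'
#' Computes per-position residue frequencies, information content and letter
#' heights for a set of pre-aligned equal-length peptide strings (the
#' alignment is an input, not computed). The information content at position
#' i is \code{log2(20) - H_i} bits, where H_i is the Shannon entropy of the
#' observed residue distribution, optionally minus the small-sample
#' correction \code{e_n = (1/ln 2) * (20 - 1) / (2 n)}. Letter heights are
#' \code{freq * info}, so each column's heights sum to its information
#' content. Gap characters (\code{"-"}) and the no-residue marker \code{"X"}
#' are, under the default \code{ignore_gaps} policy, excluded and the
#' frequencies renormalized over the non-gap observations of the column.
#'
#' @param peptides character vector of aligned, equal-length sequences.
#' @param small_sample_correction apply the e_n correction (default FALSE).
#' @param gap_policy \code{"ignore_gaps"} (renormalize over non-gap counts)
#'   or \code{"count_gaps"} (gaps dilute the column: frequencies are over
#'   all sequences, entropy over observed residues).
#' @return list(length, freqs [position x 20], info, heights, n_seqs,
#'   gap_policy).
#' @export
buildLogo <- function(peptides, small_sample_correction = FALSE,
                      gap_policy = c("ignore_gaps", "count_gaps")) {
  gap_policy <- match.arg(gap_policy)
  peptides <- toupper(as.character(peptides))
  if (length(unique(nchar(peptides))) != 1)
    stop("aligned peptides must all have the same length")
  L <- nchar(peptides[1])
  n <- length(peptides)
  mat <- do.call(rbind, strsplit(peptides, ""))
  freqs <- matrix(0, nrow = L, ncol = 20,
                  dimnames = list(NULL, LOGO_RESIDUES))
  info <- numeric(L)
  s <- 20
  e_n <- if (small_sample_correction) (1 / log(2)) * (s - 1) / (2 * n) else 0
  for (i in seq_len(L)) {
    col <- mat[, i]
    obs <- col[col %in% LOGO_RESIDUES]
    denom <- if (gap_policy == "ignore_gaps") length(obs) else n
    if (length(obs) == 0) { info[i] <- 0; next }
    counts <- table(factor(obs, levels = LOGO_RESIDUES))
    freqs[i, ] <- as.numeric(counts) / denom
    p <- as.numeric(counts) / length(obs)
    p <- p[p > 0]
    H <- -sum(p * log2(p))
    info[i] <- max(0, log2(s) - H - e_n)
  }
  heights <- freqs * info
  list(length = L, freqs = freqs, info = info, heights = heights,
       n_seqs = n, gap_policy = gap_policy)
}

#' C-terminally anchored padding helper for logo input
#'
#' Pads peptides of unequal length on the left with \code{"-"} so their
#' C-termini align -- the natural frame for C-terminally anchored
#' neuropeptide motifs. A convenience only; curated alignments should be
#' supplied directly.
#'
#' @param peptides character vector.
#' @return character vector of equal-length strings.
#' @export
padAlignC <- function(peptides) {
  peptides <- as.character(peptides)
  L <- max(nchar(peptides))
  vapply(peptides, function(p)
    paste0(strrep("-", L - nchar(p)), p), character(1), USE.NAMES = FALSE)
}

.fmt1 <- function(x) {
  ## 1 decimal, trailing ".0" dropped ("4 ± 0" / "3.5 ± 0.5" style)
  s <- formatC(round(x, 1), format = "f", digits = 1)
  sub("\\.0$", "", s)
}

#' Render a paracopy summary as display strings
#'
#' Formats each row of \code{\link{summarizeParacopies}} output in the
#' conventional style: \code{"mean ± S_N"} with one decimal place and
#' trailing ".0" dropped; a single full-length precursor renders as the bare
#' mean; partial-only cells render as \code{"(≥k)"}.
#'
#' @param summaries data.frame from \code{\link{summarizeParacopies}}.
#' @param family_order optional family ordering for the output rows.
#' @return the input with a \code{rendered} column appended.
#' @export
renderParacopyTable <- function(summaries, family_order = NULL) {
  rendered <- character(nrow(summaries))
  for (k in seq_len(nrow(summaries))) {
    r <- summaries[k, ]
    rendered[k] <- if (r$n_full >= 2) {
      paste0(.fmt1(r$mean), " ± ", .fmt1(r$s_n))
    } else if (r$n_full == 1) {
      .fmt1(r$mean)
    } else if (!is.na(r$max_partial)) {
      paste0("(≥", r$max_partial, ")")
    } else ""
  }
  out <- cbind(summaries, rendered = rendered, stringsAsFactors = FALSE)
  if (!is.null(family_order))
    out <- out[order(match(out$family, family_order), out$taxon), ,
               drop = FALSE]
  out
}
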