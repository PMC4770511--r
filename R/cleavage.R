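#' Predict prohormone-convertase cleavage sites
#'
#' Scans a precursor for candidate basic cleavage sites and applies the
#' classical processing rules used for insect prohormones: dibasic KR and RR
#' sites are accepted; KK and RK are accepted at reduced confidence (can be
#' disabled); a monobasic R is accepted only when another basic residue
#' occupies P4, P6 or P8; monobasic K is rejected; any site with proline at
#' P1' is rejected; a cysteine within two residues downstream rejects the
#' site (disulfide protection); sites within the signal peptide are
#' rejected. Contiguous basic runs are treated as one site whose P1 is the
#' downstream-most basic residue and whose whole run is consumed as cleavage
#' signal; furin-like R-X-(K/R)-R contexts additionally consume the P4
#' arginine, except when P3 is a glycine (an amide donor belonging to the
#' upstream peptide). A monobasic R is only licensed by a lone basic residue
#' at P4/P6/P8 -- basics that are part of a dibasic cleavage signal do not
#' license cleavage across a peptide boundary.
#'
#' Every candidate basic position is returned, accepted or not, with the
#' decisive rule in \code{reason}, so that individual calls can be audited.
#'
#' @param residues precursor amino-acid string.
#' @param signal_end last residue of the signal peptide (0 if none).
#' @param allow_KK accept KK/RK dibasics (default TRUE).
#' @param mono_R_basic_positions positions upstream of P1 at which a basic
#'   residue licenses a monobasic R site (default P4, P6, P8).
#' @return data.frame with columns p1_index, site_class, accepted, reason,
#'   consumed_start (first residue consumed as cleavage signal).
#' @export
predictCleavageSites <- function(residues, signal_end = 0, allow_KK = TRUE,
                                 mono_R_basic_positions = c(4, 6, 8)) {
  res <- toupper(as.character(residues))
  n <- nchar(res)
  ch <- strsplit(res, "")[[1]]
  basic <- ch %in% c("K", "R")
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (!basic[i]) { i <- i + 1L; next }
    ## extend the basic run; P1 is its downstream-most residue
    run_start <- i
    while (i < n && basic[i + 1L]) i <- i + 1L
    p1 <- i
    run_len <- p1 - run_start + 1L
    consumed_start <- run_start
    if (run_len >= 2L) {
      site_class <- paste0(ch[p1 - 1L], ch[p1])
      ## furin-like R-X-(K/R)-R: consume the P4 arginine too -- unless P3
      ## is a glycine, which is an amide donor belonging to the upstream
      ## peptide, not part of the cleavage signal
      if (ch[p1] == "R" && run_len == 2L && p1 >= 4L &&
          ch[p1 - 3L] == "R" && !basic[p1 - 2L] && ch[p1 - 2L] != "G")
        consumed_start <- p1 - 3L
    } else {
      site_class <- if (ch[p1] == "R") "mono_R" else "mono_K"
    }
    accepted <- FALSE
    reason <- ""
    if (p1 <= signal_end) {
      reason <- "within signal peptide"
    } else if (p1 < n && ch[p1 + 1L] == "P") {
      reason <- "proline at P1'"
    } else if (p1 < n && any(ch[seq(p1 + 1L, min(n, p1 + 2L))] == "C")) {
      reason <- "cysteine within 2 residues downstream"
    } else if (site_class %in% c("KR", "RR")) {
      accepted <- TRUE
      reason <- paste("dibasic", site_class)
      if (consumed_start == p1 - 3L) reason <- "furin-like R-X-K/R-R"
    } else if (site_class %in% c("KK", "RK")) {
      if (allow_KK) {
        accepted <- TRUE
        reason <- paste("dibasic", site_class, "(reduced confidence)")
      } else reason <- paste("dibasic", site_class, "disallowed by config")
    } else if (site_class == "mono_R") {
      ## the licensing basic at P4/P6/P8 must be a lone basic residue:
      ## members of a dibasic cleavage signal do not license a monobasic
      ## site across a peptide boundary
      lone_basic <- basic &
        !(c(FALSE, basic[-n]) | c(basic[-1], FALSE))
      up <- p1 - (mono_R_basic_positions - 1L)
      keep <- up >= 1L
      hits <- mono_R_basic_positions[keep][lone_basic[up[keep]]]
      if (length(hits)) {
        accepted <- TRUE
        reason <- sprintf("monobasic R with basic at P%d", hits[1])
      } else reason <- "monobasic R without supporting upstream basic"
    } else {
      reason <- "monobasic K"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      p1_index = p1, site_class = site_class, accepted = accepted,
      reason = reason, consumed_start = consumed_start,
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(p1_index = integer(0), site_class = character(0),
               accepted = logical(0), reason = character(0),
               consumed_start = integer(0))
}

#' Excise mature peptides from a precursor
#'
#' Partitions the precursor at the accepted cleavage sites. Basic residues
#' of a site (and a furin P4 arginine) are consumed as cleavage signal, not
#' peptide. A segment ending in glycine immediately before an accepted site
#' is called amidated (the amide-donor G is dropped in the processed display
#' string, which carries a trailing \code{"a"}); this includes the common
#' precursor-terminal G-K-R-stop arrangement, where the terminal KR is
#' itself an accepted site. An N-terminal glutamine is displayed as
#' pyroglutamate (\code{"pQ"} prefix). Concatenating the signal peptide, the
#' raw segments and the consumed cleavage residues reconstructs the
#' precursor exactly.
#'
#' @param residues precursor amino-acid string.
#' @param signal_end last residue of the signal peptide (0 if none).
#' @param sites data.frame from \code{\link{predictCleavageSites}}.
#' @return data.frame with columns start, end, raw, processed, amidated,
#'   pyroglu, copy_index, followed_by_site.
#' @export
excisePeptides <- function(residues, signal_end = 0, sites) {
  res <- toupper(as.character(residues))
  n <- nchar(res)
  acc <- sites[sites$accepted, , drop = FALSE]
  acc <- acc[order(acc$p1_index), , drop = FALSE]
  if (nrow(acc) > 1 &&
      any(diff(acc$p1_index) <= 0 |
          acc$consumed_start[-1] <= acc$p1_index[-nrow(acc)]))
    stop("overlapping or out-of-order cleavage sites")
  prev_end <- signal_end
  rows <- list()
  bounds <- rbind(acc[, c("consumed_start", "p1_index")],
                  data.frame(consumed_start = n + 1L, p1_index = n))
  for (k in seq_len(nrow(bounds))) {
    seg_start <- prev_end + 1L
    seg_end <- bounds$consumed_start[k] - 1L
    prev_end <- bounds$p1_index[k]
    followed_by_site <- k <= nrow(acc)
    if (seg_end < seg_start) next
    raw <- substr(res, seg_start, seg_end)
    amidated <- followed_by_site && endsWith(raw, "G")
    core <- if (amidated) substr(raw, 1L, nchar(raw) - 1L) else raw
    pyroglu <- startsWith(core, "Q")
    display <- if (pyroglu) paste0("pQ", substr(core, 2L, nchar(core)))
               else core
    if (amidated) display <- paste0(display, "a")
    rows[[length(rows) + 1L]] <- data.frame(
      start = seg_start, end = seg_end, raw = raw, processed = display,
      amidated = amidated, pyroglu = pyroglu,
      copy_index = length(rows) + 1L, followed_by_site = followed_by_site,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), raw = character(0),
               processed = character(0), amidated = logical(0),
               pyroglu = logical(0), copy_index = integer(0),
               followed_by_site = logical(0))
}
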