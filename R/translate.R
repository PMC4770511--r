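#' @importFrom Biostrings DNAString reverseComplement subseq
NULL

FRAME_NAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stops are rendered \code{"*"}; codons made
#' ambiguous by \code{N} translate to \code{X} (unambiguous fuzzy codons such
#' as \code{GGN} are resolved). Frames -1..-3 translate the reverse
#' complement. Sequences shorter than one codon yield six empty strings.
#'
#' @param nt a nucleotide string (ACGTN).
#' @return named character vector of length 6 ("+1".."-3").
#' @export
translateFrames <- function(nt) {
  nt <- toupper(as.character(nt))
  out <- setNames(character(6), FRAME_NAMES)
  if (nchar(nt) < 3) return(out)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  for (k in 1:3) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      n <- length(s) - (k - 1)
      n <- n - n %% 3
      key <- paste0(strand, k)
      if (n < 3) { out[key] <- ""; next }
      sub <- Biostrings::subseq(s, start = k, width = n)
      out[key] <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "solve",
                              no.init.codon = TRUE)))
    }
  }
  out
}

## nt coordinates (forward strand, 1-based inclusive) of codons a..b of the
## translation of frame `frame` ("+1".."-3") of a transcript of length L.
.codonSpan <- function(frame, L, a, b, include_stop = FALSE) {
  k <- as.integer(substr(frame, 2, 2))
  off <- k - 1L
  extra <- if (include_stop) 3L else 0L
  if (substr(frame, 1, 1) == "+") {
    c(off + 3L * (a - 1L) + 1L, off + 3L * b + extra)
  } else {
    c(L - off - 3L * b - extra + 1L, L - off - 3L * (a - 1L))
  }
}

#' Extract candidate precursor ORFs from a transcript
#'
#' Returns Met-initiated, stop-terminated ORFs in all six frames, plus
#' edge-truncated ORFs (reading frames running off a transcript end without
#' start and/or stop), so that N-/C-terminally incomplete precursors are
#' representable. \code{nt_start}/\code{nt_end} are 1-based inclusive on the
#' forward strand and include the stop codon when \code{has_stop} is true.
#'
#' @param transcript a \code{TranscriptSet} of length 1, or a nucleotide
#'   string.
#' @param min_len minimum protein length in residues (default 40; the
#'   shortest precursor families run around 60 residues, leaving margin for
#'   truncation).
#' @return data.frame with columns transcript_id, frame, nt_start, nt_end,
#'   protein, has_start, has_stop, sorted by decreasing protein length.
#' @export
findOrfs <- function(transcript, min_len = 40) {
  if (is(transcript, "TranscriptSet")) {
    stopifnot(length(transcript) == 1)
    nt <- as.character(sequences(transcript))[[1]]
    id <- seqInfo(transcript)$id[1]
  } else {
    nt <- as.character(transcript)
    id <- "transcript"
  }
  L <- nchar(nt)
  prots <- translateFrames(nt)
  rows <- list()
  for (fr in FRAME_NAMES) {
    p <- prots[[fr]]
    if (!nchar(p)) next
    ## segment the frame translation at stops
    stops <- gregexpr("*", p, fixed = TRUE)[[1]]
    stops <- stops[stops > 0]
    bounds <- c(0L, stops, nchar(p) + 1L)
    for (si in seq_len(length(bounds) - 1L)) {
      seg_start <- bounds[si] + 1L          # first residue of segment
      seg_end <- bounds[si + 1L] - 1L       # last residue before stop/end
      if (seg_end < seg_start) next
      seg <- substr(p, seg_start, seg_end)
      has_stop <- bounds[si + 1L] <= nchar(p)  # terminated by a real stop
      first_in_frame <- si == 1L
      mpos <- regexpr("M", seg, fixed = TRUE)
      cands <- list()
      if (mpos > 0) {
        a <- seg_start + as.integer(mpos) - 1L
        cands[[length(cands) + 1L]] <-
          list(a = a, b = seg_end, has_start = TRUE, has_stop = has_stop)
      }
      if (first_in_frame && (mpos != 1L)) {
        ## runs off the 5' end of the reading frame without an initiator
        cands[[length(cands) + 1L]] <-
          list(a = seg_start, b = seg_end, has_start = FALSE,
               has_stop = has_stop)
      }
      for (cd in cands) {
        prot <- substr(p, cd$a, cd$b)
        if (nchar(prot) < min_len) next
        sp <- .codonSpan(fr, L, cd$a, cd$b, include_stop = cd$has_stop)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, frame = fr, nt_start = sp[1], nt_end = sp[2],
          protein = prot, has_start = cd$has_start, has_stop = cd$has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), frame = character(0),
               nt_start = integer(0), nt_end = integer(0),
               protein = character(0), has_start = logical(0),
               has_stop = logical(0))
  out[order(-nchar(out$protein)), , drop = FALSE]
}

## Unanchored amino-acid "core" of a registry motif: drop ^/$ anchors, the
## amide mark and the pyroGlu mark, so the pattern can be scanned inside raw
## frame translations.
## number of residue positions a core pattern spans (literal characters,
## character classes and wildcards each count one; quantifiers ignored)
.corePositions <- function(core) {
  core <- gsub("\\{[0-9,]+\\}", "", core)
  core <- gsub("\\[[^]]*\\]", "#", core)
  nchar(gsub("[?*+]", "", core))
}

.motifCores <- function(registry, min_positions = 5L) {
  out <- list()
  for (f in registry@families) {
    for (mi in seq_along(f$motifs)) {
      pat <- f$motifs[[mi]]
      pat <- sub("^\\^", "", pat)
      pat <- sub("\\$$", "", pat)
      pat <- sub("a$", "", pat)
      pat <- sub("^pQ", "Q", pat)
      if (.corePositions(pat) < min_positions) next  # too unspecific to scan
      out[[length(out) + 1L]] <- list(
        family = f$name, motif_id = names(f$motifs)[mi], core = pat)
    }
  }
  out
}

#' Flag likely sequencing artifacts in an ORF candidate
#'
#' Two advisory flag kinds, neither of which mutates the input:
#' \describe{
#'   \item{in_frame_stop}{a stop codon interrupts a region that matches a
#'     family motif once the stop is masked (all 20 substitutions at the stop
#'     position are tried).}
#'   \item{frameshift_suspect}{a family motif that the candidate itself does
#'     not contain is completed in a different same-strand frame within
#'     \code{window} nucleotides of the candidate span.}
#' }
#'
#' @param candidate one row of \code{\link{findOrfs}} output.
#' @param transcript the \code{TranscriptSet} (length 1) or nucleotide string
#'   the candidate came from.
#' @param registry a \code{FamilyRegistry}.
#' @param window search window in nucleotides (default 60).
#' @return data.frame with columns transcript_id, kind, position, evidence.
#' @export
flagArtifacts <- function(candidate, transcript, registry, window = 60) {
  if (is(transcript, "TranscriptSet"))
    nt <- as.character(sequences(transcript))[[1]]
  else nt <- as.character(transcript)
  L <- nchar(nt)
  prots <- translateFrames(nt)
  fr <- candidate$frame
  p <- prots[[fr]]
  cores <- .motifCores(registry)
  flags <- list()
  emit <- function(kind, position, evidence)
    flags[[length(flags) + 1L]] <<- data.frame(
      transcript_id = candidate$transcript_id, kind = kind,
      position = position, evidence = evidence, stringsAsFactors = FALSE)

  ## --- in-frame stops: examine stops at/near the candidate within `window`
  sp <- .codonSpan(fr, L, 1L, nchar(p))
  stop_pos <- gregexpr("*", p, fixed = TRUE)[[1]]
  stop_pos <- stop_pos[stop_pos > 0]
  ## candidate codon range within the frame translation
  cand_codons <- .frameCodonRange(candidate, fr, L)
  near <- stop_pos[stop_pos >= cand_codons[1] - window %/% 3 &
                   stop_pos <= cand_codons[2] + 1L + window %/% 3]
  maxlen <- 40L
  for (s in near) {
    ctx_start <- max(1L, s - maxlen)
    ctx_end <- min(nchar(p), s + maxlen)
    ctx <- substr(p, ctx_start, ctx_end)
    srel <- s - ctx_start + 1L
    hit <- NULL
    for (aa in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
      masked <- ctx
      substr(masked, srel, srel) <- aa
      for (mc in cores) {
        m <- gregexpr(mc$core, masked)[[1]]
        if (m[1] == -1) next
        lens <- attr(m, "match.length")
        if (any(m <= srel & (m + lens - 1L) >= srel)) {
          hit <- mc; break
        }
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) {
      ntpos <- .codonSpan(fr, L, s, s)[1]
      emit("in_frame_stop", ntpos, paste0(hit$family, ":", hit$motif_id))
    }
  }

  ## --- frameshift suspects: motifs completed in a sibling frame
  strand <- substr(fr, 1, 1)
  sibs <- setdiff(FRAME_NAMES[startsWith(FRAME_NAMES, strand)], fr)
  lo <- max(1L, candidate$nt_start - window)
  hi <- min(L, candidate$nt_end + window)
  for (mc in cores) {
    if (gregexpr(mc$core, p)[[1]][1] != -1) next  # present in own frame
    for (sib in sibs) {
      q <- prots[[sib]]
      if (!nchar(q)) next
      m <- gregexpr(mc$core, q)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (j in seq_along(m)) {
        msp <- .codonSpan(sib, L, m[j], m[j] + lens[j] - 1L)
        if (msp[2] >= lo && msp[1] <= hi) {
          emit("frameshift_suspect", msp[1],
               paste0(mc$family, ":", mc$motif_id))
        }
      }
    }
  }
  out <- if (length(flags)) do.call(rbind, flags) else
    data.frame(transcript_id = character(0), kind = character(0),
               position = integer(0), evidence = character(0))
  unique(out)
}

## codon indices (within the frame translation) covered by a candidate
.frameCodonRange <- function(candidate, fr, L) {
  k <- as.integer(substr(fr, 2, 2))
  off <- k - 1L
  if (substr(fr, 1, 1) == "+") {
    a <- (candidate$nt_start - off - 1L) %/% 3L + 1L
  } else {
    a <- (L - candidate$nt_end - off) %/% 3L + 1L
  }
  nres <- nchar(candidate$protein)
  c(a, a + nres - 1L)
}

#' Attempt a single-nucleotide frameshift repair
#'
#' For a \code{frameshift_suspect} flag, tries single-nucleotide insertions
#' (of \code{N}) and deletions within a small window upstream of the flagged
#' position and accepts the first edit after which the evidence motif is
#' completed in the candidate's own frame. The input is never modified; the
#' repaired copy and a correction-log row are returned. Advisory flags are
#' only ever turned into edits through this explicit call.
#'
#' @param nt nucleotide string.
#' @param flag one row of \code{\link{flagArtifacts}} output with kind
#'   \code{frameshift_suspect}.
#' @param frame the frame of the candidate being repaired.
#' @param registry a \code{FamilyRegistry}.
#' @param window nt window upstream of the flag position to edit in.
#' @return list(nt = repaired string or NULL, log = data.frame).
#' @export
repairFrameshift <- function(nt, flag, frame, registry, window = 60) {
  nt <- as.character(nt)
  cores <- .motifCores(registry)
  ev <- strsplit(flag$evidence, ":", fixed = TRUE)[[1]][1]
  core <- NULL
  for (mc in cores) if (mc$family == ev) { core <- mc$core; break }
  if (is.null(core)) stop("evidence family not in registry: ", ev)
  positions <- seq(max(1L, flag$position - window), flag$position)
  tryEdit <- function(cand_nt, action, pos) {
    p <- translateFrames(cand_nt)[[frame]]
    if (gregexpr(core, p)[[1]][1] != -1)
      list(nt = cand_nt,
           log = data.frame(transcript_id = flag$transcript_id,
                            kind = flag$kind, position = pos,
                            action = action, stringsAsFactors = FALSE))
    else NULL
  }
  for (pos in positions) {
    del <- paste0(substr(nt, 1, pos - 1L), substr(nt, pos + 1L, nchar(nt)))
    r <- tryEdit(del, "delete_1nt", pos)
    if (!is.null(r)) return(r)
    ins <- paste0(substr(nt, 1, pos), "N", substr(nt, pos + 1L, nchar(nt)))
    r <- tryEdit(ins, "insert_1nt", pos)
    if (!is.null(r)) return(r)
  }
  list(nt = NULL, log = data.frame(transcript_id = character(0),
       kind = character(0), position = integer(0), action = character(0)))
}
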