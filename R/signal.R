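## Kyte-Doolittle hydropathy scale (J Mol Biol 157:105-132, 1982).
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

## residues tolerated at the signal-peptidase -3/-1 positions; the -1
## position strongly prefers the smallest residues (Ala-X-Ala rule)
SMALL_PREFERRED <- c("A", "G", "S")
SMALL_TOLERATED <- c("C", "T", "V")
.smallBonus <- function(res, w_pref, w_tol) {
  if (res %in% SMALL_PREFERRED) w_pref
  else if (res %in% SMALL_TOLERATED) w_tol
  else 0
}

.kd <- function(chars) unname(KD_SCALE[chars])

#' Heuristic signal-peptide prediction
#'
#' A transparent, deterministic stand-in for neural-network predictors,
#' scoring every candidate cleavage position p (signal peptide = residues
#' 1..p) for p in 10..45:
#' \itemize{
#'   \item n-region charge: net positive charge over residues 1-5, capped
#'     at 2;
#'   \item h-region: mean Kyte-Doolittle hydropathy of the best 8-residue
#'     window ending 3 to 7 residues upstream of p, so that the
#'     hydrophobic core sits a realistic c-region away from the cleavage
#'     point;
#'   \item c-region: a graded bonus for small apolar residues at positions
#'     p and p-2 (the classical -1/-3 positions of the signal-peptidase
#'     site), weighting the -1 position more and the smallest residues
#'     (A, G, S) over the merely tolerated ones (C, T, V).
#' }
#' The prediction is the highest-scoring position (ties broken towards the
#' C-terminus); \code{present} requires the best score to reach
#' \code{threshold}. Precomputed external predictions can be supplied
#' instead via \code{external}.
#'
#' @param residues precursor amino-acid string, or a list with fields
#'   \code{residues} and \code{n_complete}.
#' @param n_complete is the N-terminus complete? Signal peptides are not
#'   predicted on N-terminally truncated records.
#' @param threshold decision threshold on the position score (default 2).
#' @param external optional data.frame (id, cleavage_after, score) of
#'   precomputed predictions plus an \code{id} to look up.
#' @param id record id used with \code{external}.
#' @return list(present, cleavage_after, score, reason).
#' @export
predictSignalPeptide <- function(residues, n_complete = TRUE, threshold = 2,
                                 external = NULL, id = NULL) {
  if (!is.null(external) && !is.null(id)) {
    hit <- external[external$id == id, , drop = FALSE]
    if (nrow(hit) == 1)
      return(list(present = TRUE,
                  cleavage_after = as.integer(hit$cleavage_after),
                  score = as.numeric(hit$score), reason = "external"))
  }
  res <- toupper(as.character(residues))
  if (!n_complete)
    return(list(present = FALSE, cleavage_after = NA_integer_,
                score = NA_real_, reason = "N-terminally incomplete"))
  n <- nchar(res)
  if (n < 25)
    return(list(present = FALSE, cleavage_after = NA_integer_,
                score = NA_real_, reason = "too short"))
  ch <- strsplit(res, "")[[1]]
  ncharge <- min(2, sum(ch[1:5] %in% c("K", "R")) - sum(ch[1:5] %in% c("D", "E")))
  kd <- .kd(ch)
  kd[is.na(kd)] <- 0
  best_score <- -Inf
  best_p <- NA_integer_
  for (p in 10:min(45, n - 1)) {
    ## h-region: best 8-residue window ending within the 2-6 residues
    ## before the -3 position, i.e. a c-region of realistic length
    starts <- seq(max(2, p - 14), p - 10)
    if (!length(starts) || p - 10 < 2) next
    win <- vapply(starts, function(s) mean(kd[s:(s + 7)]), numeric(1))
    hyd <- max(win)
    bonus <- .smallBonus(ch[p], 0.7, 0.2) + .smallBonus(ch[p - 2], 0.3, 0.1)
    sc <- ncharge + hyd + bonus
    if (sc >= best_score) {  # >= : ties resolved towards the C-terminus
      best_score <- sc
      best_p <- p
    }
  }
  if (!is.finite(best_score))
    return(list(present = FALSE, cleavage_after = NA_integer_,
                score = NA_real_, reason = "too short"))
  present <- best_score >= threshold
  list(present = present,
       cleavage_after = if (present) best_p else NA_integer_,
       score = best_score,
       reason = if (present) "ok" else "below threshold")
}
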