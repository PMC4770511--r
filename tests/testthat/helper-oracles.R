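## Independent oracles used across the suite. These deliberately do not
## share code with the package: brute-force lookups and literal rule
## transcriptions against which the implementation is checked.

## ---- codon-table translation oracle ------------------------------------

ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  ## codons enumerated first-base-major: TTT TTC TTA TTG TCT ...
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
})

oracleTranslate <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  out <- character(n / 3)
  for (i in seq_len(n / 3)) {
    cod <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", cod)) {
      ## resolve only if all substitutions agree
      subs <- unique(vapply(c("A", "C", "G", "T"), function(b)
        ORACLE_CODONS[[gsub("N", b, cod)]], character(1)))
      if (length(subs) == 1) subs else "X"
    } else ORACLE_CODONS[[cod]]
  }
  paste(out, collapse = "")
}

oracleRevComp <- function(nt) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(nt), "")[[1]]]), collapse = "")
}

oracleSixFrames <- function(nt) {
  rc <- oracleRevComp(nt)
  c("+1" = oracleTranslate(nt),
    "+2" = oracleTranslate(substr(nt, 2, nchar(nt))),
    "+3" = oracleTranslate(substr(nt, 3, nchar(nt))),
    "-1" = oracleTranslate(rc),
    "-2" = oracleTranslate(substr(rc, 2, nchar(rc))),
    "-3" = oracleTranslate(substr(rc, 3, nchar(rc))))
}

## ---- literal cleavage rule-table oracle --------------------------------

## Decides acceptance for the basic residue at position p1 of `res`
## (assumed the downstream-most residue of its basic run), given the last
## signal residue. A direct transcription of the documented rule table.
oracleCleavageAccept <- function(res, p1, signal_end = 0) {
  ch <- strsplit(res, "")[[1]]
  n <- length(ch)
  isB <- function(i) i >= 1 && i <= n && ch[i] %in% c("K", "R")
  if (p1 <= signal_end) return(FALSE)
  if (p1 < n && ch[p1 + 1] == "P") return(FALSE)
  if ((p1 + 1 <= n && ch[p1 + 1] == "C") ||
      (p1 + 2 <= n && ch[p1 + 2] == "C")) return(FALSE)
  if (isB(p1 - 1)) return(TRUE)              # dibasic (KR/RR/KK/RK)
  if (ch[p1] == "K") return(FALSE)           # monobasic K
  loneB <- function(i) isB(i) && !isB(i - 1) && !isB(i + 1)
  loneB(p1 - 3) || loneB(p1 - 5) || loneB(p1 - 7)
}

## ---- literal capa/pk decision-table oracle -----------------------------

oracleArchitecture <- function(genes) {
  ## genes: list of lists of ligand-type character vectors
  pres <- function(tr) sort(unique(tr))
  gp <- lapply(genes, function(g) sort(unique(unlist(g))))
  trypto_anywhere <- any(vapply(gp, function(p) "trypto_PK" %in% p,
                                logical(1)))
  eq <- function(a, b) setequal(a, b)
  if (length(genes) == 1) {
    trs <- lapply(genes[[1]], pres)
    if (length(trs) == 1) {
      p <- trs[[1]]
      if (eq(p, c("PVK", "PK")) && !trypto_anywhere) return("A")
      if (eq(p, c("PVK", "trypto_PK", "PK"))) return("B")
      return("unresolved")
    }
    if (length(trs) == 2) {
      full <- vapply(trs, eq, logical(1), c("PVK", "trypto_PK", "PK"))
      part <- vapply(trs, eq, logical(1), c("PVK", "trypto_PK"))
      if (sum(full) >= 1 && sum(part) >= 1 && sum(full) + sum(part) == 2)
        return("B1")
      return("unresolved")
    }
    return("unresolved")
  }
  if (length(genes) == 2) {
    haspvk <- vapply(gp, function(p) "PVK" %in% p, logical(1))
    if (sum(haspvk) != 1) return("unresolved")
    capa <- gp[[which(haspvk)]]
    pk <- gp[[which(!haspvk)]]
    if (eq(capa, c("PVK", "trypto_PK")) && eq(pk, "PK")) return("C1")
    if (eq(capa, c("PVK", "trypto_PK")) && eq(pk, c("trypto_PK", "PK")))
      return("C2")
    if (eq(capa, c("PVK", "trypto_PK", "PK")) &&
        eq(pk, c("trypto_PK", "PK"))) return("C3")
    return("unresolved")
  }
  "unresolved"
}

## ---- misc --------------------------------------------------------------

oracleSN <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

## pick the reading-frame candidate carrying the generator's planted ORF
truthCandidate <- function(orfs) {
  orfs <- orfs[orfs$frame == "+1" & orfs$has_start, , drop = FALSE]
  orfs[1, ]
}

randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
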