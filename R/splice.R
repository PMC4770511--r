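.commonPrefixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d)) d[1] - 1L else n
}

#' Group splice variants of one gene
#'
#' Two precursors of the same species are splice variants of one gene when
#' they are identical over at least \code{prefix_len} N-terminal residues
#' (which exceeds any signal peptide) and then diverge -- i.e. neither is a
#' plain prefix of the other, which would more likely be an incomplete
#' assembly of the same transcript. Byte-identical duplicates are collapsed
#' to a single record and never form a group. Variant tags a, b, c, ... are
#' assigned by decreasing precursor length, matching the convention used for
#' ITP/ITPL and orcokinin A/B listings.
#'
#' @param precursors list of \code{AnnotatedPrecursor}, or a data.frame with
#'   columns id, species, residues.
#' @param prefix_len minimum shared N-terminal identity (default 30).
#' @return list of groups; each has gene_label, species, variants
#'   (data.frame id, variant_tag) and shared_prefix_len.
#' @export
groupSpliceVariants <- function(precursors, prefix_len = 30) {
  if (is.list(precursors) && length(precursors) &&
      is(precursors[[1]], "AnnotatedPrecursor")) {
    df <- data.frame(
      id = vapply(precursors, function(x) x@id, character(1)),
      species = vapply(precursors, function(x) x@species, character(1)),
      residues = vapply(precursors, function(x) x@residues, character(1)),
      stringsAsFactors = FALSE)
  } else df <- as.data.frame(precursors, stringsAsFactors = FALSE)
  ## collapse exact duplicates within a species
  df <- df[!duplicated(df[, c("species", "residues")]), , drop = FALSE]
  groups <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    ## adjacency under the shared-prefix-then-diverge rule
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    cpl <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cp <- .commonPrefixLen(sub$residues[i], sub$residues[j])
      cpl[i, j] <- cp
      diverge <- cp < min(nchar(sub$residues[i]), nchar(sub$residues[j]))
      if (cp >= prefix_len && diverge)
        parent[max(find(i), find(j))] <- min(find(i), find(j))
    }
    comp <- vapply(seq_len(n), find, integer(1))
    gi <- 0L
    for (root in unique(comp)) {
      members <- which(comp == root)
      if (length(members) < 2) next
      gi <- gi + 1L
      ord <- members[order(-nchar(sub$residues[members]))]
      shared <- min(cpl[t(utils::combn(sort(members), 2))])
      groups[[length(groups) + 1L]] <- list(
        gene_label = paste0(sp, "_splice", gi),
        species = sp,
        variants = data.frame(id = sub$id[ord],
                              variant_tag = letters[seq_along(ord)],
                              stringsAsFactors = FALSE),
        shared_prefix_len = as.integer(shared))
    }
  }
  groups
}
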