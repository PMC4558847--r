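#' Homology-pair statements of an alignment
#'
#' Decomposes an alignment into elementary homology statements, one per
#' (ordered taxon pair, residue of the first taxon): either an aligned pair
#' "residue i of x is homologous to residue j of y" (residue indices
#' 0-based in the degapped sequences) or a gap event "residue i of x sits
#' in a gap of y", labeled by the number of y residues preceding the shared
#' column (so the label is invariant to padding columns).  The symmetric
#' difference of these statement sets underlies the alignment distance, and
#' the aligned-pair subset underlies the true/false-positive homology
#' scores.
#'
#' @param msa an \code{msa}.
#' @return data frame with columns \code{x}, \code{y} (taxon labels),
#'   \code{i} (residue of x), \code{kind} ("pair" or "gap"), \code{j}
#'   (residue of y for pairs, preceding-residue count for gaps).
#' @export
homology_pairs <- function(msa) {
  A <- msa$aln
  taxa <- rownames(A)
  n <- length(taxa)
  resind <- lapply(seq_len(n), function(r) {
    ng <- A[r, ] != "-"
    ifelse(ng, cumsum(ng) - 1L, NA_integer_)  # 0-based residue index
  })
  prevres <- lapply(seq_len(n), function(r) {
    ng <- A[r, ] != "-"
    cumsum(ng)  # residues of r at or before each column
  })
  out <- vector("list", n * (n - 1L))
  k <- 0L
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    cols <- which(!is.na(resind[[x]]))
    i <- resind[[x]][cols]
    j <- resind[[y]][cols]
    gap <- is.na(j)
    k <- k + 1L
    out[[k]] <- data.frame(
      x = taxa[x], y = taxa[y], i = i,
      kind = ifelse(gap, "gap", "pair"),
      j = ifelse(gap, prevres[[y]][cols], j))
  }
  do.call(rbind, out)
}

statement_keys <- function(hp) {
  paste(hp$x, hp$y, hp$i, hp$kind, hp$j, sep = "|")
}

#' Homology-pair distance between two alignments
#'
#' Size of the symmetric difference of the two alignments' homology
#' statement sets divided by the size of their union: 0 iff the alignments
#' make identical homology statements, 1 if they share none.  A symmetric
#' pseudo-metric in the spirit of published alignment-distance metrics
#' (a "d_ssp-style" symmetric-difference distance with gap events labeled
#' by their flanking residue).
#'
#' @param a,b \code{msa} objects over the same taxa whose rows degap to the
#'   same sequences.
#' @return a number in [0, 1].
#' @export
msa_distance <- function(a, b) {
  check_same_sequences(a, b)
  ka <- statement_keys(homology_pairs(a))
  kb <- statement_keys(homology_pairs(b))
  sym <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  sym / length(union(ka, kb))
}

check_same_sequences <- function(a, b) {
  ta <- sort(rownames(a$aln))
  if (!identical(ta, sort(rownames(b$aln))))
    stop("alignments are over different taxa")
  da <- degap(a); db <- degap(b)
  for (t in ta)
    if (!identical(da[[t]], db[[t]]))
      stop("degapped sequences differ for taxon ", t)
  invisible(TRUE)
}

#' Homology true/false-positive scores against the true alignment
#'
#' Compares the aligned-pair statements (unordered residue pairs) of a test
#' alignment with those of the true alignment: tp = shared pairs, fp =
#' pairs asserted only by the test alignment, fn = pairs asserted only by
#' the truth.  \code{spfn = fn / (tp + fn)} and \code{spfp = fp / (tp + fp)}
#' are the sum-of-pairs false-negative and false-positive rates.
#'
#' @param test,truth \code{msa} objects on the same sequences.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{spfn},
#'   \code{spfp}.
#' @export
homology_scores <- function(test, truth) {
  check_same_sequences(test, truth)
  kt <- aligned_pair_keys(test)
  kr <- aligned_pair_keys(truth)
  tp <- length(intersect(kt, kr))
  fp <- length(setdiff(kt, kr))
  fn <- length(setdiff(kr, kt))
  list(tp = tp, fp = fp, fn = fn,
       spfn = if (tp + fn > 0) fn / (tp + fn) else 0,
       spfp = if (tp + fp > 0) fp / (tp + fp) else 0)
}

# unordered aligned residue pairs of an alignment
aligned_pair_keys <- function(msa) {
  hp <- homology_pairs(msa)
  hp <- hp[hp$kind == "pair", ]
  first <- hp$x < hp$y
  unique(paste(ifelse(first, hp$x, hp$y), ifelse(first, hp$y, hp$x),
               ifelse(first, hp$i, hp$j), ifelse(first, hp$j, hp$i),
               sep = "|"))
}
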