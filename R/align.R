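#' Configuration of the built-in progressive aligner
#'
#' The package ships a self-contained progressive multiple-sequence
#' aligner (k-mer distances, neighbor-joining guide tree, profile-profile
#' global alignment with affine gaps) so the two-step
#' alignment-then-inference pipeline runs without external binaries.  It is
#' an explicit stand-in for guide-tree based progressive alignment tools,
#' not a replica of any published program.
#'
#' @param k k-mer size for the distance estimation; default 3 for amino
#'   acids and 6 for nucleotides.
#' @param gap_open,gap_extend affine gap scores (both <= 0), on the scale
#'   of the integer log-odds substitution scores (x10).
#' @param ref_distance evolutionary distance at which the log-odds
#'   substitution scores are taken (expected substitutions per site).
#' @param guide_method \code{"nj"} (default) or \code{"upgma"}.
#' @return an object of class \code{aligner_config}.
#' @export
aligner_config <- function(k = NULL, gap_open = -20, gap_extend = -1,
                           ref_distance = 1.0, guide_method = c("nj", "upgma")) {
  stopifnot(gap_open <= 0, gap_extend <= 0, is.null(k) || k >= 1)
  structure(list(k = k, gap_open = gap_open, gap_extend = gap_extend,
                 ref_distance = ref_distance,
                 guide_method = match.arg(guide_method)),
            class = "aligner_config")
}

#' k-mer distance matrix
#'
#' d(x, y) = 1 - (number of shared k-mers) / (min sequence length - k + 1),
#' where the shared count sums, over distinct k-mers, the smaller of the two
#' occurrence counts.  A fast alignment-free distance of the kind
#' progressive aligners use to build guide trees.
#'
#' @param seqs named list of sequence strings or character vectors.
#' @param k word size; every sequence must have length >= k.
#' @return symmetric matrix of distances in [0, 1] with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k) {
  seqs <- lapply(seqs, function(s) if (length(s) > 1L) paste(s, collapse = "") else s)
  len <- vapply(seqs, nchar, integer(1))
  if (any(len < k)) stop("all sequences must have length >= k")
  counts <- lapply(seqs, function(s) {
    km <- substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))
    table(km)
  })
  nseq <- length(seqs)
  D <- matrix(0, nseq, nseq, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(nseq - 1L)) {
    for (j in (i + 1L):nseq) {
      shared <- intersect(names(counts[[i]]), names(counts[[j]]))
      common <- sum(pmin(as.integer(counts[[i]][shared]),
                         as.integer(counts[[j]][shared])))
      D[i, j] <- D[j, i] <- 1 - common / (min(len[i], len[j]) - k + 1L)
    }
  }
  D
}

#' Build a guide tree from a distance matrix
#'
#' Neighbor-joining (default; negative branch lengths clamped to zero) or
#' UPGMA on a symmetric distance matrix.  Deterministic for a given input.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param method \code{"nj"} or \code{"upgma"}.
#' @return a \code{phylo} guide tree (rooted for UPGMA, unrooted for NJ).
#' @export
build_guide_tree <- function(D, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (method == "nj") {
    t0 <- ape::nj(stats::as.dist(D))
    t0$edge.length[t0$edge.length < 0] <- 0
    t0
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    ape::as.phylo(hc)
  }
}

# integer log-odds substitution scores (x10) at the reference distance:
# s(x,y) = 10 * log(P_xy(d) / pi_y), symmetric for reversible models
score_matrix <- function(model, ref_distance = 1.0) {
  P <- transition_probs(model, ref_distance)
  S <- 10 * log(sweep(P, 2, model$freq, "/"))
  S <- (S + t(S)) / 2
  round(S)
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive alignment: a guide tree is estimated from k-mer
#' distances (unless supplied), then profiles are merged leaves-to-root by
#' global profile-profile alignment with affine gap costs and sum-of-pairs
#' scoring of column pairs; once introduced, gaps are never removed.
#'
#' @param seqs named list of >= 2 unaligned sequence strings or character
#'   vectors.
#' @param model a \code{subst_model} matching the sequence alphabet; used
#'   to derive the log-odds substitution scores.
#' @param config an \code{aligner_config}.
#' @param guide_tree optional \code{phylo} to use instead of estimating one.
#' @return list with \code{msa} (source \code{"builtin"}, rows in input
#'   order) and \code{guide_tree} (the tree actually used).
#' @export
progressive_align <- function(seqs, model, config = aligner_config(),
                              guide_tree = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  seqs <- lapply(seqs, function(s) if (length(s) == 1L && nchar(s) > 1L)
    strsplit(s, "")[[1]] else as.character(s))
  if (is.null(names(seqs))) stop("sequences must be named")
  k <- if (is.null(config$k)) (if (model$type == "aa") 3L else 6L) else config$k

  if (is.null(guide_tree)) {
    if (length(seqs) == 2L) {
      d <- kmer_distance_matrix(seqs, k)[1, 2]
      guide_tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                                  names(seqs)[1], d / 2,
                                                  names(seqs)[2], d / 2))
    } else {
      D <- kmer_distance_matrix(seqs, k)
      guide_tree <- build_guide_tree(D, config$guide_method)
    }
  }
  merge_tree <- if (ape::Ntip(guide_tree) == 2L) guide_tree
                else rooted_merge_tree(guide_tree)

  Smat <- score_matrix(model, config$ref_distance)
  states <- model$states

  # per-node alignments as character matrices, merged in postorder
  ntip <- ape::Ntip(merge_tree)
  sub_aln <- vector("list", ntip + merge_tree$Nnode)
  for (i in seq_len(ntip)) {
    lab <- merge_tree$tip.label[i]
    sub_aln[[i]] <- matrix(seqs[[lab]], nrow = 1,
                           dimnames = list(lab, NULL))
  }
  eo <- stats::reorder(merge_tree, "postorder")
  done <- logical(ntip + merge_tree$Nnode)
  done[seq_len(ntip)] <- TRUE
  for (i in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[i, 1]
    if (done[parent]) next
    kids <- eo$edge[eo$edge[, 1] == parent, 2]
    if (!all(done[kids])) next  # postorder guarantees children first
    acc <- sub_aln[[kids[1]]]
    for (kk in kids[-1])
      acc <- merge_profiles(acc, sub_aln[[kk]], states, Smat, config)
    sub_aln[[parent]] <- acc
    done[parent] <- TRUE
    sub_aln[kids] <- list(NULL)  # free merged children
  }
  root <- ntip + 1L
  aln <- sub_aln[[root]]
  aln <- aln[match(names(seqs), rownames(aln)), , drop = FALSE]
  list(msa = new_msa(aln, type = model$type, source = "builtin"),
       guide_tree = guide_tree)
}

# root an NJ (unrooted) guide tree for progressive merging; midpoint
# rooting, falling back to an arbitrary resolved rooting on failure
rooted_merge_tree <- function(tr) {
  if (ape::is.rooted(tr) && ape::is.binary(tr)) return(tr)
  out <- tryCatch(phangorn::midpoint(tr), error = function(e) NULL)
  if (is.null(out) || !ape::is.rooted(out))
    out <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  ape::multi2di(out)
}

# align alignment B to alignment A with the affine-gap profile DP and
# return the merged character matrix
merge_profiles <- function(A, B, states, Smat, config) {
  FA <- profile_freqs(A, states)
  FB <- profile_freqs(B, states)
  gA <- FA$gap; gB <- FB$gap
  pair <- FA$res %*% Smat %*% t(FB$res)
  pair <- pair + (outer(gA, 1 - gB) + outer(1 - gA, gB)) * config$gap_extend
  path <- align_profiles_dp(pair, config$gap_open, config$gap_extend)
  L <- length(path$a)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = L,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- path$a > 0
  out[seq_len(nrow(A)), ia] <- A[, path$a[ia], drop = FALSE]
  ib <- path$b > 0
  out[nrow(A) + seq_len(nrow(B)), ib] <- B[, path$b[ib], drop = FALSE]
  out
}

# residue frequency profile of an alignment: columns x states (gap mass
# separate), frequencies normalized over all rows
profile_freqs <- function(A, states) {
  L <- ncol(A)
  res <- matrix(0, L, length(states))
  for (s in seq_along(states)) res[, s] <- colMeans(A == states[s])
  list(res = res, gap = colMeans(A == "-"))
}

#' Run an external alignment tool
#'
#' Adapter for external MSA programs: writes the sequences to a temporary
#' FASTA file, substitutes \code{{input}} and \code{{output}} in the command
#' template, runs it through the shell, and parses the resulting aligned
#' FASTA.  The aligned rows must degap to the input sequences.
#'
#' @param seqs named list of unaligned sequence strings.
#' @param template shell command containing \code{{input}} and
#'   \code{{output}} placeholders.
#' @param type alphabet, \code{"nt"} or \code{"aa"}.
#' @param name tool name recorded in the MSA source tag.
#' @return an \code{msa} with source \code{"external:<name>"}.
#' @export
external_align <- function(seqs, template, type = c("nt", "aa"),
                           name = "tool") {
  type <- match.arg(type)
  if (!grepl("{input}", template, fixed = TRUE) ||
      !grepl("{output}", template, fixed = TRUE))
    stop("template must contain {input} and {output} placeholders")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(seqs, fin)
  cmd <- gsub("{output}", fout, gsub("{input}", fin, template, fixed = TRUE),
              fixed = TRUE)
  status <- suppressWarnings(system(cmd, ignore.stdout = TRUE,
                                    ignore.stderr = TRUE))
  if (status != 0) stop("external aligner failed (exit ", status, "): ", cmd)
  if (!file.exists(fout)) stop("external aligner produced no output: ", cmd)
  out <- read_msa(fout, type = type, source = paste0("external:", name))
  dg <- vapply(degap(out)[names(seqs)], paste, character(1), collapse = "")
  ref <- toupper(vapply(seqs, paste, character(1), collapse = ""))
  if (!identical(toupper(dg), ref))
    stop("external alignment rows do not degap to the input sequences")
  out
}
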