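#' Multiple sequence alignment container
#'
#' A rectangular gapped alignment: a character matrix with one row per
#' taxon (rownames are taxon labels) over the model alphabet plus the gap
#' character \code{"-"}.  Columns consisting only of gaps are disallowed.
#'
#' @param aln character matrix (rows = taxa, with rownames).
#' @param type \code{"nt"} or \code{"aa"}.
#' @param source provenance tag: \code{"true"}, \code{"builtin"} or
#'   \code{"external:<tool>"}.
#' @return an object of class \code{msa}.
#' @export
new_msa <- function(aln, type = c("nt", "aa"), source = "unknown") {
  type <- match.arg(type)
  if (!is.matrix(aln) || is.null(rownames(aln)))
    stop("alignment must be a character matrix with taxon rownames")
  if (anyDuplicated(rownames(aln))) stop("duplicate taxon labels")
  if (ncol(aln) > 0 && any(colSums(aln != "-") == 0))
    stop("alignment contains an all-gap column")
  structure(list(aln = aln, type = type, source = source), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d taxa x %d columns (%s, source: %s)\n",
              nrow(x$aln), ncol(x$aln), x$type, x$source))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$aln)

#' Number of columns of an alignment
#' @param msa an \code{msa}.
#' @return integer column count.
#' @export
alignment_length <- function(msa) ncol(msa$aln)

#' Remove gaps from alignment rows
#' @param msa an \code{msa}.
#' @return named list of ungapped character vectors, one per taxon.
#' @export
degap <- function(msa) {
  out <- lapply(seq_len(nrow(msa$aln)), function(i) {
    r <- msa$aln[i, ]
    r[r != "-"]
  })
  names(out) <- rownames(msa$aln)
  out
}

#' Restrict an alignment to a taxon subset
#'
#' Keeps the rows of the given taxa and drops columns that become all-gap,
#' so the result is again a valid alignment whose rows degap to the same
#' unaligned sequences.
#'
#' @param msa an \code{msa}.
#' @param taxa subset of the alignment's taxon labels.
#' @return an \code{msa} on \code{taxa}.
#' @export
extract_subalignment <- function(msa, taxa) {
  missing <- setdiff(taxa, rownames(msa$aln))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  sub <- msa$aln[taxa, , drop = FALSE]
  keep <- colSums(sub != "-") > 0
  new_msa(sub[, keep, drop = FALSE], type = msa$type, source = msa$source)
}

#' Read and write FASTA
#'
#' Minimal-surface FASTA I/O used throughout the package; sequences may
#' contain gap characters (aligned FASTA).
#'
#' @param x named list/vector of sequence strings.
#' @param file path.
#' @param msa an \code{msa} object.
#' @param type alphabet of the file being read, \code{"nt"} or \code{"aa"}.
#' @param source source tag to attach to the alignment read.
#' @return \code{read_fasta}: named character vector of sequences;
#'   \code{read_msa}: an \code{msa}.
#' @export
write_fasta <- function(x, file) {
  stopifnot(!is.null(names(x)))
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(x))
    writeLines(c(paste0(">", nm), as.character(x[[nm]])), con)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  ln <- readLines(file)
  hdr <- grep("^>", ln)
  if (!length(hdr)) stop("not a FASTA file: ", file)
  nm <- sub("^>\\s*", "", ln[hdr])
  nm <- sub("\\s.*$", "", nm)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(ln))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(ln[starts[i]:ends[i]], collapse = "")
  }, character(1))
  setNames(gsub("\\s", "", seqs), nm)
}

#' @rdname write_fasta
#' @export
write_msa <- function(msa, file) {
  write_fasta(setNames(apply(msa$aln, 1, paste, collapse = ""),
                       rownames(msa$aln)), file)
}

#' @rdname write_fasta
#' @export
read_msa <- function(file, type = c("nt", "aa"), source = "external") {
  type <- match.arg(type)
  seqs <- read_fasta(file)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("rows of an aligned FASTA must have equal length")
  aln <- do.call(rbind, strsplit(seqs, ""))
  rownames(aln) <- names(seqs)
  new_msa(aln, type = type, source = source)
}
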