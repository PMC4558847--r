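#' @importFrom ape read.tree write.tree keep.tip drop.tip cophenetic.phylo
#'   nj as.phylo unroot is.binary Ntip Nnode di2multi
NULL

#' Eight-taxon balanced study tree
#'
#' The balanced divergence-study tree: two four-leaf balanced halves joined
#' by one central branch, 13 branches in all (8 external, 4 middle, 1
#' central "root" branch), every branch of equal length, the whole tree
#' scaled to the requested total tree length.  Branch classes are attached
#' as a per-edge factor in \code{attr(tree, "branch_class")}.
#'
#' @param tree_length total sum of branch lengths (> 0), in expected
#'   substitutions per site.
#' @return an unrooted \code{phylo} with 8 tips t1..t8 and a
#'   \code{branch_class} attribute (\code{"external"}, \code{"middle"},
#'   \code{"root"}) aligned with the edge matrix.
#' @examples
#' tr <- make_balanced_tree(6)
#' sum(tr$edge.length)   # 6
#' @export
make_balanced_tree <- function(tree_length) {
  stopifnot(is.numeric(tree_length), tree_length > 0)
  b <- tree_length / 13
  txt <- "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,(t5:1,t6:1):1,(t7:1,t8:1):1);"
  tr <- ape::read.tree(text = txt)
  tr$edge.length <- rep(b, nrow(tr$edge))  # exact equality, no printf rounding
  attr(tr, "branch_class") <- classify_balanced_edges(tr)
  attr(tr, "tree_scale") <- tree_length
  tr
}

# external = edge to a tip; root = the central edge (both endpoints are
# internal nodes of degree 3 whose removal splits tips 4|4); middle = rest.
classify_balanced_edges <- function(tr) {
  ntip <- ape::Ntip(tr)
  cls <- rep("middle", nrow(tr$edge))
  cls[tr$edge[, 2] <= ntip] <- "external"
  for (i in seq_len(nrow(tr$edge))) {
    if (tr$edge[i, 2] > ntip) {
      nt <- length(tips_below(tr, tr$edge[i, 2]))
      if (nt == 4) cls[i] <- "root"
    }
  }
  cls
}

tips_below <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tr = tr))
}

#' Eight-taxon tree with a central four-way multifurcation
#'
#' The polytomy study tree: a degree-4 root carrying four two-leaf cherry
#' subtrees, two "short" (all three branches of length \code{short_branch})
#' and two "long" (all three of length \code{long_branch}).  With the
#' defaults 0.06 / 0.7, root-to-tip distances are 0.12 within the short
#' subtrees and 1.4 within the long ones.
#'
#' @param short_branch branch length within short subtrees (default 0.06).
#' @param long_branch branch length within long subtrees (default 0.7).
#' @return a \code{phylo} with 8 tips; tips t5..t8 sit on the long
#'   subtrees; attribute \code{long_taxa} names them.
#' @export
make_polytomy_tree <- function(short_branch = 0.06, long_branch = 0.7) {
  stopifnot(short_branch > 0, long_branch > 0)
  s <- short_branch; l <- long_branch
  txt <- sprintf(
    "((t1:%g,t2:%g):%g,(t3:%g,t4:%g):%g,(t5:%g,t6:%g):%g,(t7:%g,t8:%g):%g);",
    s, s, s, s, s, s, l, l, l, l, l, l)
  tr <- ape::read.tree(text = txt)
  # exact lengths (avoid printf rounding): long subtrees carry t5..t8
  tr$edge.length <- ifelse(edge_is_long(tr), l, s)
  attr(tr, "long_taxa") <- c("t5", "t6", "t7", "t8")
  tr
}

edge_is_long <- function(tr) {
  long <- c("t5", "t6", "t7", "t8")
  vapply(seq_len(nrow(tr$edge)), function(i) {
    tp <- tr$tip.label[tips_below(tr, tr$edge[i, 2])]
    all(tp %in% long)
  }, logical(1))
}

#' Enumerate the three resolutions of a four-way multifurcation
#'
#' For a tree with a single degree-4 node, returns the three bifurcating
#' trees obtained by joining the four attached subtrees pairwise across a
#' new internal branch of length 0 (the starting value for subsequent
#' branch-length optimization).  The candidate grouping the two long
#' subtrees (largest subtree depths) is tagged as the long-branch-attraction
#' resolution.
#'
#' @param tree a \code{phylo} with exactly one degree-4 multifurcation at
#'   its root node.
#' @return list of three \code{phylo} objects; attribute \code{lba} is the
#'   index of the candidate grouping the two deepest subtrees, and each
#'   candidate carries a logical attribute \code{is_lba}.
#' @export
resolve_polytomy <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- which(tree$edge[, 1] == root)
  if (length(kids) != 4L || !all(tabulate(tree$edge[, 1])[-root] %in% c(0L, 2L)))
    stop("tree must have exactly one degree-4 multifurcation (at the root)")
  subs <- lapply(kids, function(i) {
    tips <- tree$tip.label[tips_below(tree, tree$edge[i, 2])]
    list(tips = tips, newick = subtree_newick(tree, tree$edge[i, 2]),
         stem = tree$edge.length[i],
         depth = max(node_depths(tree, tree$edge[i, 2])) + tree$edge.length[i])
  })
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  depths <- vapply(subs, `[[`, numeric(1), "depth")
  longpair <- order(depths, decreasing = TRUE)[1:2]
  out <- vector("list", 3L)
  lba_idx <- NA_integer_
  for (k in 1:3) {
    p <- pairings[[k]]
    txt <- sprintf("((%s:%g,%s:%g):0,%s:%g,%s:%g);",
                   subs[[p[1]]]$newick, subs[[p[1]]]$stem,
                   subs[[p[2]]]$newick, subs[[p[2]]]$stem,
                   subs[[p[3]]]$newick, subs[[p[3]]]$stem,
                   subs[[p[4]]]$newick, subs[[p[4]]]$stem)
    cand <- ape::read.tree(text = txt)
    is_lba <- setequal(p[1:2], longpair) || setequal(p[3:4], longpair)
    attr(cand, "is_lba") <- is_lba
    if (is_lba) lba_idx <- k
    out[[k]] <- cand
  }
  attr(out, "lba") <- lba_idx
  out
}

# Newick text (no trailing ';', no root length) for the clade under `node`.
subtree_newick <- function(tr, node) {
  if (node <= ape::Ntip(tr)) return(tr$tip.label[node])
  ki <- which(tr$edge[, 1] == node)
  parts <- vapply(ki, function(i)
    sprintf("%s:%g", subtree_newick(tr, tr$edge[i, 2]), tr$edge.length[i]),
    character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

# depths of all tips below `node`, measured from `node`
node_depths <- function(tr, node) {
  if (node <= ape::Ntip(tr)) return(0)
  ki <- which(tr$edge[, 1] == node)
  unlist(lapply(ki, function(i) tr$edge.length[i] + node_depths(tr, tr$edge[i, 2])))
}

#' Felsenstein-zone study tree
#'
#' Four balanced subtrees -- two of root-to-tip depth \code{long_depth}
#' (beta) and two of depth \code{short_depth} (alpha) -- separated by a
#' single internal branch, with one long and one short subtree on each side
#' (the generating, "correct" topology).  Each subtree has 2 leaves
#' (\code{ntaxa = 8}) or 8 leaves (\code{ntaxa = 32}) and all its branches
#' (stem included) equal, summing to the requested depth along every
#' root-to-tip path.
#'
#' @param short_depth alpha: root-to-tip depth of the short subtrees.
#' @param long_depth beta: root-to-tip depth of the long subtrees.
#' @param internal_branch length of the single internal branch separating
#'   the two (long, short) pairs; defaults to \code{short_depth}.
#' @param ntaxa total leaves, 8 or 32.
#' @return a \code{phylo}; attribute \code{long_taxa} names the tips of the
#'   two long subtrees.
#' @export
make_felsenstein_tree <- function(short_depth, long_depth,
                                  internal_branch = short_depth, ntaxa = 8L) {
  stopifnot(short_depth > 0, long_depth > 0, internal_branch > 0)
  if (!ntaxa %in% c(8L, 32L)) stop("ntaxa must be 8 or 32")
  nl <- ntaxa / 4L                       # leaves per subtree: 2 or 8
  nlev <- as.integer(log2(nl)) + 1L      # edges on a root-to-tip path incl. stem
  sub <- function(labels, depth) {
    b <- depth / nlev
    bal <- function(lab) {
      if (length(lab) == 1L) return(lab)
      h <- length(lab) / 2
      sprintf("(%s:%g,%s:%g)", bal(lab[1:h]), b, bal(lab[(h + 1):length(lab)]), b)
    }
    list(newick = bal(labels), stem = b)
  }
  labs <- split(paste0("t", seq_len(ntaxa)), rep(1:4, each = nl))
  # subtrees 1,3 long; 2,4 short; correct tree pairs (1,2) vs (3,4):
  # the two long subtrees are separated by the internal branch.
  s1 <- sub(labs[[1]], long_depth);  s2 <- sub(labs[[2]], short_depth)
  s3 <- sub(labs[[3]], long_depth);  s4 <- sub(labs[[4]], short_depth)
  txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
                 s1$newick, s1$stem, s2$newick, s2$stem, internal_branch,
                 s3$newick, s3$stem, s4$newick, s4$stem)
  tr <- ape::read.tree(text = txt)
  attr(tr, "long_taxa") <- c(labs[[1]], labs[[3]])
  attr(tr, "subtree_taxa") <- labs
  tr
}

#' The three arrangements of four subtrees around an internal branch
#'
#' Given the generating Felsenstein-zone tree, returns the three candidate
#' topologies obtained by re-pairing its four subtrees across the internal
#' branch (the generating arrangement first).  Candidate attributes flag the
#' correct tree and the long-branch-attraction tree (long subtrees joined).
#'
#' @param tree a tree from \code{make_felsenstein_tree}.
#' @return list of three \code{phylo} candidates with attributes
#'   \code{correct} (index 1) and \code{lba}.
#' @export
felsenstein_candidates <- function(tree) {
  labs <- attr(tree, "subtree_taxa")
  if (is.null(labs)) stop("tree must come from make_felsenstein_tree")
  long <- attr(tree, "long_taxa")
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  ib <- internal_branch_length(tree, labs)
  nwk <- lapply(labs, function(tp) stem_and_newick(tree, tp))
  out <- vector("list", 3L)
  lba_idx <- NA_integer_
  for (k in 1:3) {
    p <- pairings[[k]]
    txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
                   nwk[[p[1]]]$newick, nwk[[p[1]]]$stem,
                   nwk[[p[2]]]$newick, nwk[[p[2]]]$stem, ib,
                   nwk[[p[3]]]$newick, nwk[[p[3]]]$stem,
                   nwk[[p[4]]]$newick, nwk[[p[4]]]$stem)
    cand <- ape::read.tree(text = txt)
    grouped_long <- all(unlist(labs[p[1:2]]) %in% long) ||
      all(unlist(labs[p[3:4]]) %in% long)
    attr(cand, "is_lba") <- grouped_long
    if (grouped_long) lba_idx <- k
    out[[k]] <- cand
  }
  attr(out, "correct") <- 1L
  attr(out, "lba") <- lba_idx
  out
}

stem_and_newick <- function(tr, tips) {
  node <- subtree_root(tr, tips)
  stem_edge <- which(tr$edge[, 2] == node)
  list(newick = subtree_newick(tr, node),
       stem = tr$edge.length[stem_edge])
}

subtree_root <- function(tr, tips) {
  idx <- match(tips, tr$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tr, idx)
}

internal_branch_length <- function(tr, labs) {
  n1 <- subtree_root(tr, labs[[1]])
  # internal branch = the edge below the node joining subtrees 1 and 2
  join <- tr$edge[tr$edge[, 2] == n1, 1]
  e <- which(tr$edge[, 2] == join)
  if (length(e) == 0) return(tr$edge.length[tr$edge[, 2] == n1] * 0)
  tr$edge.length[e]
}

#' Embed the balanced core tree in a larger supertree
#'
#' Adds extra taxa to the 8-taxon balanced tree by repeatedly attaching new
#' leaves at random points along branches lying on paths between core taxa,
#' so the induced subtree on the core taxa (suppressing degree-2 nodes and
#' summing path lengths) reproduces the core tree exactly.  Pendant branch
#' lengths of the added leaves are drawn uniformly on (0.05, 0.5 * core
#' branch length).
#'
#' @param core the 8-taxon balanced tree from \code{make_balanced_tree}.
#' @param n_total total number of leaves, 64 or 512.
#' @param seed integer seed; the result is a deterministic function of it.
#' @return a \code{phylo} with \code{n_total} leaves; the 8 core taxa keep
#'   their labels, extra taxa are x1, x2, ...; attribute \code{core_taxa}.
#' @export
embed_in_supertree <- function(core, n_total, seed = 1L) {
  if (!n_total %in% c(64L, 512L)) stop("n_total must be 64 or 512")
  if (ape::Ntip(core) != 8L) stop("core must be the 8-taxon balanced tree")
  core_b <- attr(core, "tree_scale") / 13
  if (is.null(core_b)) core_b <- mean(core$edge.length)
  set.seed(as.integer(seed))
  tr <- core
  n_extra <- n_total - 8L
  for (i in seq_len(n_extra)) {
    # candidate attachment edges: any edge on a path between two core taxa,
    # i.e. any edge whose removal leaves core taxa on both sides
    ncb <- core_counts_below(tr, core$tip.label)
    on_core_path <- ncb >= 1 & ncb <= 7
    e <- sample(which(on_core_path), 1L)
    pos <- runif(1, 0, tr$edge.length[e])
    pend <- runif(1, 0.05, 0.5 * core_b)
    tr <- phytools::bind.tip(tr, paste0("x", i), edge.length = pend,
                             where = tr$edge[e, 2], position = pos)
  }
  attr(tr, "core_taxa") <- core$tip.label
  tr
}

#' Branch lengths split by subtree membership
#'
#' Partitions a tree's branch lengths into those lying within the subtrees
#' spanned by \code{long_taxa} (stems and internal branches whose tip set
#' is a nonempty strict subset of the long taxa) and the rest; internal
#' branches joining whole subtrees (e.g. a resolution's new branch) fall in
#' \code{other}.
#'
#' @param tree a \code{phylo}.
#' @param long_taxa tip labels of the long subtrees.
#' @return list with numeric vectors \code{long} and \code{other}.
#' @export
branch_lengths_by_subtree <- function(tree, long_taxa) {
  half <- length(long_taxa) / 2
  is_long <- vapply(seq_len(nrow(tree$edge)), function(e) {
    tp <- tree$tip.label[tips_below(tree, tree$edge[e, 2])]
    length(tp) >= 1 && length(tp) <= half && all(tp %in% long_taxa)
  }, logical(1))
  list(long = tree$edge.length[is_long],
       other = tree$edge.length[!is_long])
}

# per-edge count of core tips in the clade below each edge (postorder pass)
core_counts_below <- function(tr, core) {
  ntip <- ape::Ntip(tr)
  cnt <- numeric(ntip + tr$Nnode)
  cnt[seq_len(ntip)] <- as.numeric(tr$tip.label %in% core)
  eo <- stats::reorder(tr, "postorder")
  for (i in seq_len(nrow(eo$edge)))
    cnt[eo$edge[i, 1]] <- cnt[eo$edge[i, 1]] + cnt[eo$edge[i, 2]]
  cnt[tr$edge[, 2]]
}

#' Induced subtree on a taxon subset
#'
#' Restriction of a tree to a subset of its taxa, suppressing degree-2
#' nodes and summing branch lengths along the collapsed paths.
#'
#' @param tree a \code{phylo}.
#' @param taxa tip labels to keep.
#' @return the induced \code{phylo}.
#' @export
induced_subtree <- function(tree, taxa) {
  ape::keep.tip(tree, taxa)
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of the two unrooted trees.
#'
#' @param t1,t2 \code{phylo} objects on the same leaf set.
#' @return nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Read and write Newick
#'
#' Thin wrappers around the standard Newick parser/serializer, kept as the
#' package's single tree I/O surface.
#'
#' @param text Newick string (or \code{file} a path).
#' @param file path to read/write; for \code{read_newick} give either.
#' @param tree a \code{phylo}.
#' @return \code{read_newick}: a \code{phylo}; \code{write_newick}: the
#'   Newick string, invisibly if written to a file.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file = file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
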