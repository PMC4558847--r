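#' Indel process parameters
#'
#' The reversible insertion/deletion process used by the simulator:
#' insertions and deletions each occur at \code{rel_rate} times the
#' substitution rate (per site), with lengths drawn from a truncated
#' power-law (Zipf) distribution P(L = k) proportional to k^-shape on
#' 1..max_length.
#'
#' @param rel_rate indel rate relative to the substitution rate, applied
#'   separately to insertions and to deletions (default 0.05).
#' @param length_shape Zipf exponent (> 1; default 1.7).
#' @param max_length truncation of the length distribution; conventionally
#'   20 for amino acids and 60 for nucleotides.
#' @return an object of class \code{indel_params}.
#' @export
indel_params <- function(rel_rate = 0.05, length_shape = 1.7,
                         max_length = 20L) {
  stopifnot(rel_rate >= 0, length_shape > 1, max_length >= 1)
  structure(list(rel_rate = rel_rate, length_shape = length_shape,
                 max_length = as.integer(max_length)),
            class = "indel_params")
}

#' Draw indel lengths from the truncated Zipf distribution
#'
#' @param params an \code{indel_params} object.
#' @param n number of draws.
#' @return integer vector in [1, max_length], P(k) proportional to
#'   k^-length_shape.
#' @export
sample_indel_length <- function(params, n = 1L) {
  k <- seq_len(params$max_length)
  w <- k^(-params$length_shape)
  sample.int(params$max_length, n, replace = TRUE, prob = w)
}

#' Evolve a sequence along one branch
#'
#' Substitutions and indels are interleaved exactly: indel event times come
#' from a Gillespie walk (total rate \code{2 * rel_rate * L} per unit branch
#' length, L the current length), and between events every site is evolved
#' by the matrix exponential of the substitution process over the elapsed
#' time, scaled by its Gamma rate category.  Insertion positions are uniform
#' over the L+1 slots; inserted residues are drawn from the stationary
#' distribution with fresh rate categories; deletion start sites are uniform
#' and overhanging deletions are truncated at the sequence end.
#'
#' @param node a list with integer \code{states}, integer \code{cats}
#'   (Gamma category per site) and integer \code{ids} (site homology
#'   identifiers).
#' @param t branch length (>= 0).
#' @param model a \code{subst_model}.
#' @param gamma a \code{gamma_rates} object.
#' @param indels an \code{indel_params} object (rel_rate 0 disables indels).
#' @param registry an environment holding the global ordered column registry
#'   (\code{cols}) and id counter (\code{next_id}); \code{NULL} runs the
#'   branch without recording new columns (ids of insertions still unique).
#' @return a node list of the same shape for the child.
#' @export
evolve_branch <- function(node, t, model, gamma, indels, registry = NULL) {
  stopifnot(t >= 0)
  states <- node$states; cats <- node$cats; ids <- node$ids
  nstate <- length(model$states)
  Plist_cache <- new.env(parent = emptyenv())

  apply_subs <- function(states, cats, dt) {
    if (dt <= 0 || length(states) == 0L) return(states)
    for (c in seq_len(gamma$ncat)) {
      idx <- which(cats == c)
      if (!length(idx)) next
      P <- transition_probs(model, dt, gamma$rates[c])
      parent <- states[idx]  # snapshot: each site evolves from its parent state once
      for (x in unique(parent)) {
        ii <- idx[parent == x]
        states[ii] <- sample.int(nstate, length(ii), replace = TRUE,
                                 prob = P[x, ])
      }
    }
    states
  }

  remaining <- t
  repeat {
    L <- length(states)
    rate <- 2 * indels$rel_rate * L
    if (rate <= 0) {
      states <- apply_subs(states, cats, remaining)
      break
    }
    dt <- rexp(1, rate)
    if (dt >= remaining) {
      states <- apply_subs(states, cats, remaining)
      break
    }
    states <- apply_subs(states, cats, dt)
    remaining <- remaining - dt
    if (runif(1) < 0.5) {
      # insertion after slot p in 0..L
      k <- sample_indel_length(indels, 1L)
      p <- sample.int(L + 1L, 1L) - 1L
      new_states <- sample.int(nstate, k, replace = TRUE, prob = model$freq)
      new_cats <- sample.int(gamma$ncat, k, replace = TRUE, prob = gamma$probs)
      new_ids <- new_column_ids(registry, k,
                                anchor = if (p > 0L) ids[p] else NA_integer_,
                                before = if (p == 0L && L > 0L) ids[1L] else NA_integer_)
      states <- append(states, new_states, after = p)
      cats <- append(cats, new_cats, after = p)
      ids <- append(ids, new_ids, after = p)
    } else if (L > 0L) {
      k <- sample_indel_length(indels, 1L)
      u <- sample.int(L, 1L)
      del <- u:min(u + k - 1L, L)
      states <- states[-del]; cats <- cats[-del]; ids <- ids[-del]
    }
  }
  list(states = states, cats = cats, ids = ids)
}

# allocate k fresh homology ids and splice them into the global ordered
# column registry right after `anchor` (or before `before` for insertions at
# the sequence start)
new_column_ids <- function(registry, k, anchor = NA_integer_,
                           before = NA_integer_) {
  if (is.null(registry)) {
    registry <- new.env(parent = emptyenv())
    registry$cols <- integer(0)
    registry$next_id <- 1L
  }
  ids <- registry$next_id + seq_len(k) - 1L
  registry$next_id <- registry$next_id + k
  pos <- if (!is.na(anchor)) match(anchor, registry$cols)
         else if (!is.na(before)) match(before, registry$cols) - 1L
         else length(registry$cols)
  registry$cols <- append(registry$cols, ids, after = pos)
  ids
}

#' Simulate sequences with substitutions and indels on a tree
#'
#' Draws a root sequence from the stationary distribution, assigns each
#' site a discrete-Gamma rate category, and evolves it recursively down the
#' tree with \code{\link{evolve_branch}}, tracking the descent of every
#' site.  The true multiple sequence alignment is assembled from the global
#' homology structure: each site that ever existed is one column, ordered
#' consistently with every lineage, and columns surviving in no leaf are
#' dropped.
#'
#' @param tree a \code{phylo} with branch lengths (any rooting; the start
#'   node is the tree's root and, for reversible models, rooting does not
#'   affect the distribution of the data).
#' @param model a \code{subst_model}.
#' @param gamma a \code{gamma_rates}; default shape 1.8, 4 categories.
#' @param indels an \code{indel_params}; defaults depend on \code{model}
#'   type: max indel length 20 (amino acids) or 60 (nucleotides).
#' @param root_length number of sites in the root sequence; conventionally
#'   408 amino acids or 1224 nucleotides.
#' @param seed integer seed; output is a deterministic function of it.
#' @return object of class \code{phylo_sim}: \code{seqs} (list of unaligned
#'   character vectors per taxon), \code{alignment} (an \code{msa} object,
#'   the true alignment, source \code{"true"}), \code{column_ids} (homology
#'   identifier per alignment column), \code{column_cats} (Gamma category
#'   per column), \code{tree}, \code{seed}.
#' @examples
#' sim <- simulate_sequences(make_balanced_tree(1), build_gtr(),
#'                           root_length = 60, seed = 1)
#' sim$alignment
#' @export
simulate_sequences <- function(tree, model, gamma = discretize_gamma(1.8, 4),
                               indels = NULL, root_length = NULL, seed = 1L) {
  if (is.null(indels))
    indels <- indel_params(max_length = if (model$type == "aa") 20L else 60L)
  if (is.null(root_length))
    root_length <- if (model$type == "aa") 408L else 1224L
  stopifnot(root_length >= 1)
  set.seed(as.integer(seed))
  nstate <- length(model$states)

  registry <- new.env(parent = emptyenv())
  registry$cols <- seq_len(root_length)
  registry$next_id <- root_length + 1L
  id2cat <- new.env(parent = emptyenv())

  root_node <- list(
    states = sample.int(nstate, root_length, replace = TRUE, prob = model$freq),
    cats = sample.int(gamma$ncat, root_length, replace = TRUE,
                      prob = gamma$probs),
    ids = seq_len(root_length))

  ntip <- ape::Ntip(tree)
  leaves <- vector("list", ntip)
  recurse <- function(node_idx, node) {
    kids <- which(tree$edge[, 1] == node_idx)
    if (!length(kids)) {
      leaves[[node_idx]] <<- node
      return(invisible())
    }
    for (i in kids) {
      child <- evolve_branch(node, tree$edge.length[i], model, gamma,
                             indels, registry)
      recurse(tree$edge[i, 2], child)
    }
  }
  recurse(ntip + 1L, root_node)

  # assemble the true alignment over columns surviving in >= 1 leaf
  leaf_ids <- lapply(leaves, `[[`, "ids")
  alive <- registry$cols[registry$cols %in% unique(unlist(leaf_ids))]
  aln <- matrix("-", nrow = ntip, ncol = length(alive),
                dimnames = list(tree$tip.label, NULL))
  cats_by_col <- integer(length(alive))
  for (i in seq_len(ntip)) {
    pos <- match(leaves[[i]]$ids, alive)
    aln[i, pos] <- model$states[leaves[[i]]$states]
    cats_by_col[pos] <- leaves[[i]]$cats
  }
  seqs <- lapply(seq_len(ntip), function(i) model$states[leaves[[i]]$states])
  names(seqs) <- tree$tip.label

  structure(list(seqs = seqs,
                 alignment = new_msa(aln, type = model$type, source = "true"),
                 column_ids = alive,
                 column_cats = cats_by_col,
                 tree = tree,
                 seed = as.integer(seed)),
            class = "phylo_sim")
}

#' @export
print.phylo_sim <- function(x, ...) {
  cat(sprintf("Simulated sequences: %d taxa, true alignment %d columns (%s)\n",
              length(x$seqs), ncol(x$alignment$aln),
              x$alignment$type))
  cat(sprintf("  unaligned lengths %d..%d; seed %d\n",
              min(lengths(x$seqs)), max(lengths(x$seqs)), x$seed))
  invisible(x)
}

#' Write simulation output to files
#'
#' Writes the unaligned sequences (FASTA), true alignment (gapped FASTA),
#' generating tree (Newick) and per-column homology identifiers (TSV).
#'
#' @param sim a \code{phylo_sim}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of paths written.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    seqs = file.path(dir, paste0(prefix, "_seqs.fasta")),
    truemsa = file.path(dir, paste0(prefix, "_true.fasta")),
    tree = file.path(dir, paste0(prefix, "_tree.nwk")),
    homology = file.path(dir, paste0(prefix, "_columns.tsv")))
  write_fasta(lapply(sim$seqs, paste, collapse = ""), paths["seqs"])
  write_msa(sim$alignment, paths["truemsa"])
  write_newick(sim$tree, paths["tree"])
  utils::write.table(
    data.frame(column = seq_along(sim$column_ids),
               homology_id = sim$column_ids,
               gamma_category = sim$column_cats),
    paths["homology"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
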