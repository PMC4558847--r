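# shared fixtures and a cross-test cache for expensive simulation runs

paper_gtr <- function() build_gtr()   # default parameterization of the study
study_gamma <- function() discretize_gamma(1.8, 4)

# Jukes-Cantor-form model: all exchangeabilities equal, uniform frequencies
jc_model <- function() build_gtr(exch = rep(1, 6), freq = rep(0.25, 4))

# brute-force quadrature oracle for discrete-Gamma category rates
gamma_rates_oracle <- function(shape, ncat) {
  q <- qgamma(seq(0, 1, length.out = ncat + 1), shape = shape, rate = shape)
  vapply(seq_len(ncat), function(i) {
    ncat * integrate(function(x) x * dgamma(x, shape = shape, rate = shape),
                     q[i], q[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
}

# exhaustive-enumeration likelihood oracle: sums over all internal-node
# state assignments of a (small, rooted or trifurcating) tree, one rate
# category mixture
loglik_oracle <- function(msa, tree, model, gamma) {
  states <- model$states
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1L):nnode
  idx <- match(tolower(msa$aln[tree$tip.label, , drop = FALSE]),
               tolower(states))
  idx <- matrix(idx, nrow = ntip)
  total <- 0
  for (site in seq_len(ncol(idx))) {
    lik <- 0
    for (c in seq_len(gamma$ncat)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_probs(model, tree$edge.length[e], gamma$rates[c]))
      grid <- do.call(expand.grid,
                      rep(list(seq_along(states)), length(internal)))
      sl <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(nd) {
          if (nd <= ntip) idx[nd, site] else grid[g, nd - ntip]
        }
        pr <- model$freq[[assign_state(ntip + 1L)]]
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          a <- assign_state(tree$edge[e, 1]); b <- assign_state(tree$edge[e, 2])
          if (is.na(b)) next  # gap at tip: marginalized, i.e. factor 1 summed
          pr <- pr * Ps[[e]][a, b]
        }
        sl <- sl + pr
      }
      lik <- lik + gamma$probs[c] * sl
    }
    total <- total + log(lik)
  }
  total
}

# brute-force affine-gap global pairwise alignment score by recursion with
# memoization over (i, j, previous-move)
pairwise_align_oracle <- function(s1, s2, S, gap_open, gap_extend) {
  n <- length(s1); m <- length(s2)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1, "m") + S[s1[i], s2[j]])
    if (i > 0)
      best <- max(best, rec(i - 1, j, "x") +
                    if (prev == "x") gap_extend else gap_open)
    if (j > 0)
      best <- max(best, rec(i, j - 1, "y") +
                    if (prev == "y") gap_extend else gap_open)
    memo[[key]] <- best
    best
  }
  rec(n, m, "m")  # sentinel: a trailing gap run still pays its gap_open
}

# naive, independent RELL SH re-implementation sharing the seed stream
sh_test_oracle <- function(site_lnl, B, seed) {
  K <- nrow(site_lnl); S <- ncol(site_lnl)
  obs <- rowSums(site_lnl)
  delta <- max(obs) - obs
  set.seed(as.integer(seed))
  R <- matrix(0, K, B)
  for (b in seq_len(B)) {
    ii <- sample.int(S, S, replace = TRUE)
    for (k in seq_len(K)) R[k, b] <- sum(site_lnl[k, ii])
  }
  for (k in seq_len(K)) R[k, ] <- R[k, ] - mean(R[k, ])
  p <- numeric(K)
  for (k in seq_len(K)) {
    nulldelta <- apply(R, 2, max) - R[k, ]
    p[k] <- mean(nulldelta >= delta[k])
  }
  p
}

msa_from_strings <- function(rows, type = "nt", source = "true") {
  aln <- do.call(rbind, strsplit(unname(unlist(rows)), ""))
  rownames(aln) <- names(rows)
  new_msa(aln, type = type, source = source)
}

# root-to-tip path lengths measured from the tree's base node
node_depths_to_tips <- function(tr, node = ape::Ntip(tr) + 1L) {
  if (node <= ape::Ntip(tr)) return(0)
  ki <- which(tr$edge[, 1] == node)
  unlist(lapply(ki, function(i)
    tr$edge.length[i] + node_depths_to_tips(tr, tr$edge[i, 2])))
}

tips_below_oracle <- function(tr, node) {
  if (node <= ape::Ntip(tr)) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below_oracle, tr = tr))
}

# cross-file cache so the acceptance criteria sharing one simulation run
# compute it only once
.acc_cache <- new.env(parent = emptyenv())
acc_cached <- function(key, expr) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- force(expr)
  .acc_cache[[key]]
}
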