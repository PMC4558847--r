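#' Observed-count frequency estimates
#'
#' Stationary frequencies estimated from the observed residue counts of an
#' alignment (gaps excluded); zero counts are floored at 1e-6 before
#' renormalization so every state keeps positive mass.
#'
#' @param msa an \code{msa}.
#' @return named frequency vector over the alphabet of \code{msa$type}.
#' @export
observed_frequencies <- function(msa) {
  states <- if (msa$type == "aa") AA_STATES else NT_STATES
  cnt <- vapply(states, function(s) sum(msa$aln == s), numeric(1))
  if (sum(cnt) == 0) stop("empty alignment")
  f <- cnt / sum(cnt)
  f <- pmax(f, 1e-6)
  f / sum(f)
}

# msa -> phangorn phyDat (gap "-" is fully ambiguous = missing data)
as_phydat <- function(msa) {
  phangorn::phyDat(msa$aln, type = if (msa$type == "aa") "AA" else "DNA")
}

# exchangeabilities of a subst_model as the lower-triangle vector order
# used throughout (for nucleotides: AC, AG, AT, CG, CT, GT)
exch_vector <- function(model) {
  v <- model$exch[lower.tri(model$exch)]
  v / v[length(v)]  # reference pair (last) = 1
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Felsenstein pruning over alignment columns under a reversible
#' substitution model with discrete-Gamma rate mixing (equal-weight
#' categories).  Gaps and unrecognized characters contribute a partial
#' likelihood vector of ones (missing data).  This is the package's own
#' reference implementation; it performs no optimization.
#'
#' @param msa an \code{msa} whose taxa equal the tree's tip labels.
#' @param tree a \code{phylo} with branch lengths.
#' @param model a \code{subst_model}.
#' @param gamma a \code{gamma_rates}.
#' @param freq root/stationary frequencies to use; default the model's.
#' @return object of class \code{phylo_fit} with \code{logLik},
#'   \code{site_lnl} (per alignment column), \code{tree}, \code{shape},
#'   \code{exch}, \code{freq}, and \code{optimized = FALSE}.
#' @export
phylo_loglik <- function(msa, tree, model, gamma = discretize_gamma(1.8, 4),
                         freq = NULL) {
  if (!setequal(rownames(msa$aln), tree$tip.label))
    stop("alignment taxa do not match tree tips")
  if (is.null(freq)) freq <- model$freq
  states <- model$states
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  nstate <- length(states)

  idx <- match(tolower(msa$aln[tree$tip.label, , drop = FALSE]),
               tolower(states))
  idx <- matrix(idx, nrow = ntip)      # NA = gap/ambiguous
  key <- apply(idx, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_of_site <- match(key, key[upat])
  pat <- idx[, upat, drop = FALSE]
  npat <- ncol(pat)

  eo <- stats::reorder(tree, "postorder")
  lik_pat <- numeric(npat)
  for (c in seq_len(gamma$ncat)) {
    lv <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      m <- matrix(0, npat, nstate)
      s <- pat[i, ]
      known <- !is.na(s)
      m[cbind(which(known), s[known])] <- 1
      m[!known, ] <- 1
      lv[[i]] <- m
    }
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
      P <- transition_probs(model, eo$edge.length[e], gamma$rates[c])
      contrib <- lv[[chd]] %*% t(P)
      lv[[par]] <- if (is.null(lv[[par]])) contrib else lv[[par]] * contrib
    }
    root <- ntip + 1L
    lik_pat <- lik_pat + gamma$probs[c] * as.numeric(lv[[root]] %*% freq)
  }
  site_lnl <- log(lik_pat)[pat_of_site]
  new_phylo_fit(logLik = sum(site_lnl), site_lnl = site_lnl, tree = tree,
                shape = gamma$shape, exch = exch_vector(model), freq = freq,
                model_type = model$type, optimized = FALSE)
}

new_phylo_fit <- function(logLik, site_lnl, tree, shape, exch, freq,
                          model_type, optimized, converged = NA,
                          pml_fit = NULL) {
  structure(list(logLik = logLik, site_lnl = site_lnl, tree = tree,
                 shape = shape, exch = exch, freq = freq,
                 model_type = model_type, optimized = optimized,
                 converged = converged, pml_fit = pml_fit),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("ML phylogenetic fit (%s%s): lnL = %.4f\n",
              x$model_type, if (x$optimized) ", optimized" else "",
              x$logLik))
  cat(sprintf("  tree length = %.4f over %d branches; Gamma shape = %.4g\n",
              sum(x$tree$edge.length), nrow(x$tree$edge), x$shape))
  invisible(x)
}

#' @export
logLik.phylo_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
            df = nrow(object$tree$edge))
}

#' @export
coef.phylo_fit <- function(object, ...) {
  c(setNames(object$tree$edge.length,
             paste0("edge_", object$tree$edge[, 1], "_", object$tree$edge[, 2])),
    shape = object$shape)
}

#' Optimize branch lengths (and model parameters) on a fixed topology
#'
#' Maximum-likelihood estimation on a fixed tree topology under GTR+Gamma
#' (nucleotides) or an empirical amino-acid model +Gamma, with gaps as
#' missing data.  Frequencies are fixed at their observed counts; branch
#' lengths are always optimized; the Gamma shape and (for nucleotides) the
#' exchangeabilities are optimized when requested.  Optimization is
#' delegated to the pruning-based ML machinery of \pkg{phangorn}; per-site
#' log-likelihoods at the optimum are returned.
#'
#' @param msa an \code{msa}; taxa must equal the topology's tip labels.
#' @param topology a \code{phylo}; branch lengths, if present, are used as
#'   starting values (zeros are lifted to a small positive floor).
#' @param model a \code{subst_model} giving the starting (or fixed)
#'   exchangeabilities.
#' @param gamma a \code{gamma_rates} giving the starting (or fixed) shape
#'   and the category count.
#' @param estimate_shape optimize the Gamma shape (default TRUE).
#' @param estimate_rates optimize the exchangeabilities (default TRUE for
#'   nucleotide models, unavailable for empirical amino-acid models).
#' @param frequencies \code{"observed"} (default) or \code{"model"}.
#' @param control a \code{phangorn::pml.control} list.
#' @return a \code{phylo_fit} with \code{optimized = TRUE}; \code{exch} is
#'   reported relative to the model's last state pair (GT for nucleotides).
#' @export
fit_branch_lengths <- function(msa, topology, model,
                               gamma = discretize_gamma(1.8, 4),
                               estimate_shape = TRUE,
                               estimate_rates = (model$type == "nt"),
                               frequencies = c("observed", "model"),
                               control = phangorn::pml.control(trace = 0)) {
  frequencies <- match.arg(frequencies)
  if (!setequal(rownames(msa$aln), topology$tip.label))
    stop("alignment taxa do not match tree tips")
  dat <- as_phydat(msa)
  bf <- if (frequencies == "observed") observed_frequencies(msa)
        else model$freq
  tr <- topology
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  fit0 <- phangorn::pml(tr, dat, bf = unname(bf), Q = unname(exch_vector(model)),
                        shape = gamma$shape, k = gamma$ncat)
  fit <- phangorn::optim.pml(fit0, optEdge = TRUE,
                             optGamma = estimate_shape,
                             optQ = isTRUE(estimate_rates) && model$type == "nt",
                             optBf = FALSE, control = control)
  site_lnl <- pml_site_lnl(fit)
  new_phylo_fit(logLik = as.numeric(fit$logLik), site_lnl = site_lnl,
                tree = fit$tree, shape = fit$shape,
                exch = fit$Q / fit$Q[length(fit$Q)],
                freq = setNames(fit$bf, model$states),
                model_type = model$type, optimized = TRUE,
                converged = TRUE, pml_fit = fit)
}

# expand phangorn's per-pattern site log-likelihoods to alignment columns
pml_site_lnl <- function(fit) {
  sl <- fit$siteLik
  index <- attr(fit$data, "index")
  as.numeric(sl[index])
}

#' Relative exchangeabilities of a fit, normalized to a reference pair
#'
#' @param fit a \code{phylo_fit} on nucleotide data.
#' @param ref reference pair, default \code{"ag"}.
#' @return named vector (ac, ag, at, cg, ct, gt) with \code{ref} = 1.
#' @export
relative_exch <- function(fit, ref = "ag") {
  nm <- c("ac", "ag", "at", "cg", "ct", "gt")
  v <- setNames(fit$exch, nm)
  v / v[[ref]]
}

#' Select the best topology among candidates
#'
#' Optimizes each candidate topology with \code{\link{fit_branch_lengths}}
#' and assigns weights: candidates whose maximized log-likelihood is within
#' \code{eps} of the best share weight equally (the tie rule), all others
#' get weight zero.
#'
#' @param msa an \code{msa}.
#' @param candidates list of \code{phylo} topologies on the same leaf set.
#' @param model,gamma,... passed to \code{\link{fit_branch_lengths}}.
#' @param eps log-likelihood tie tolerance (default 1e-2).
#' @return object of class \code{topology_choice}: \code{weights} (sum 1),
#'   \code{winners}, \code{logLik} per candidate, \code{fits}, \code{eps}.
#' @export
select_topology <- function(msa, candidates, model,
                            gamma = discretize_gamma(1.8, 4),
                            eps = 1e-2, ...) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  fits <- lapply(candidates, function(tr)
    fit_branch_lengths(msa, tr, model, gamma, ...))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  top <- ll >= max(ll) - eps
  w <- as.numeric(top) / sum(top)
  structure(list(weights = w, winners = which(top), logLik = ll,
                 fits = fits, eps = eps),
            class = "topology_choice")
}

#' @export
print.topology_choice <- function(x, ...) {
  cat("Topology selection over", length(x$weights), "candidates\n")
  for (i in seq_along(x$weights))
    cat(sprintf("  [%d] lnL = %.4f  weight = %.3f\n",
                i, x$logLik[i], x$weights[i]))
  invisible(x)
}

#' Fitch parsimony score
#'
#' Minimum number of state changes on the (unrooted) topology under Fitch
#' parsimony; gaps count as missing data (compatible with any state).
#'
#' @param msa an \code{msa}.
#' @param topology a \code{phylo} on the alignment's taxa.
#' @return integer parsimony score.
#' @export
fitch_parsimony <- function(msa, topology) {
  if (!setequal(rownames(msa$aln), topology$tip.label))
    stop("alignment taxa do not match tree tips")
  dat <- as_phydat(msa)
  as.integer(phangorn::fitch(topology, dat))
}

#' Select topologies by maximum parsimony
#'
#' @param msa an \code{msa}.
#' @param candidates list of \code{phylo} topologies.
#' @return a \code{topology_choice} whose \code{logLik} field holds the
#'   negated parsimony scores; exact score ties share weight equally.
#' @export
mp_select <- function(msa, candidates) {
  sc <- vapply(candidates, function(tr) fitch_parsimony(msa, tr), integer(1))
  top <- sc == min(sc)
  w <- as.numeric(top) / sum(top)
  structure(list(weights = w, winners = which(top), logLik = -as.numeric(sc),
                 fits = NULL, eps = 0),
            class = "topology_choice")
}
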