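#' RELL-based Shimodaira-Hasegawa test
#'
#' Multiple-topology test on a matrix of per-site log-likelihoods (one row
#' per candidate topology at its ML branch lengths, one column per
#' alignment site).  The observed statistic for candidate k is
#' delta_k = max_j lnL_j - lnL_k.  The null distribution is built by RELL
#' resampling: B bootstrap replicates resample site indices with
#' replacement, each candidate's replicate sums are centered by that
#' candidate's own replicate mean, and the null delta for each candidate in
#' each replicate is the centered maximum minus its centered score.
#' p_k is the fraction of replicates whose null delta is >= the observed
#' delta_k (ties counted as exceedances, so the ML candidate always has
#' p = 1 and can never be rejected).
#'
#' @param site_lnl numeric matrix, candidates x sites, of per-site
#'   log-likelihoods on the same columns.
#' @param n_bootstrap number of RELL replicates B (default 1000).
#' @param seed integer seed for the resampling.
#' @param alpha rejection level (default 0.05).
#' @return object of class \code{sh_result}: \code{p} (per candidate),
#'   \code{rejected}, \code{delta}, \code{n_bootstrap}, \code{alpha},
#'   \code{seed}.
#' @export
sh_test <- function(site_lnl, n_bootstrap = 1000L, seed = 1L, alpha = 0.05) {
  if (!is.matrix(site_lnl) || nrow(site_lnl) < 2L || ncol(site_lnl) < 1L)
    stop("site_lnl must be a candidates x sites matrix with >= 2 rows")
  K <- nrow(site_lnl); S <- ncol(site_lnl)
  obs <- rowSums(site_lnl)
  delta <- max(obs) - obs

  set.seed(as.integer(seed))
  idx <- matrix(sample.int(S, S * n_bootstrap, replace = TRUE),
                nrow = S, ncol = n_bootstrap)
  # replicate sums per candidate: K x B
  R <- matrix(apply(idx, 2, function(ii)
    rowSums(site_lnl[, ii, drop = FALSE])), nrow = K)
  Rc <- R - rowMeans(R)
  nullmax <- apply(Rc, 2, max)
  p <- vapply(seq_len(K), function(k)
    mean(nullmax - Rc[k, ] >= delta[k]), numeric(1))
  structure(list(p = p, rejected = p < alpha, delta = delta,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 seed = as.integer(seed)),
            class = "sh_result")
}

#' @export
print.sh_result <- function(x, ...) {
  cat(sprintf("SH test (RELL, B = %d, alpha = %.3g)\n",
              x$n_bootstrap, x$alpha))
  for (k in seq_along(x$p))
    cat(sprintf("  candidate %d: delta = %.4f, p = %.4f%s\n",
                k, x$delta[k], x$p[k],
                if (x$rejected[k]) "  [rejected]" else ""))
  invisible(x)
}

#' Per-class rejection frequencies across many SH results
#'
#' @param results list of \code{sh_result} objects.
#' @param labels character vector (or list of vectors, one per result)
#'   labeling each candidate, e.g. \code{"LBA"} / \code{"non-LBA"}.
#' @return named vector: per label, the fraction of candidate instances
#'   rejected.
#' @export
rejection_frequency <- function(results, labels) {
  if (!length(results)) stop("no results")
  if (!is.list(labels)) labels <- rep(list(labels), length(results))
  rej <- unlist(lapply(results, `[[`, "rejected"))
  lab <- unlist(labels)
  if (length(rej) != length(lab)) stop("labels do not match candidates")
  tapply(rej, lab, mean)
}
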