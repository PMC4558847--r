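#' @useDynLib msabias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qgamma pgamma runif rexp setNames median quantile
#'   integrate optimize chisq.test p.adjust sd
#' @importFrom utils head tail
NULL

NT_STATES <- c("a", "c", "g", "t")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Default nucleotide simulation parameters: GTR exchangeabilities
## (AC, AG, AT, CG, CT, GT order, relative to AG = 1) and base frequencies
## (A, C, G, T) representative of mammalian nuclear genes.
GTR_EXCH_DEFAULT <- c(ac = 0.30, ag = 1.0, at = 0.20,
                      cg = 0.25, ct = 1.39, gt = 0.22)
NT_FREQ_DEFAULT <- c(a = 0.25, c = 0.26, g = 0.27, t = 0.22)

#' Build a reversible substitution model
#'
#' Constructs the scaled instantaneous rate matrix Q of a general
#' time-reversible model from exchangeabilities r and stationary frequencies
#' pi: Q[x,y] = r[xy] * pi[y] for x != y, diagonal chosen so rows sum to
#' zero, and the whole matrix scaled so the expected substitution rate at
#' stationarity, -sum(pi * diag(Q)), equals 1.  Branch lengths used with the
#' model are then in expected substitutions per site.
#'
#' @param exch numeric vector of exchangeabilities for the unordered state
#'   pairs in column-major lower-triangle order (for nucleotides:
#'   AC, AG, AT, CG, CT, GT).  All must be positive.
#' @param freq stationary frequencies; positive, summing to 1 within 1e-6
#'   (renormalized internally).
#' @param states ordered character vector of states (default the nucleotide
#'   alphabet a, c, g, t).
#' @return an object of class \code{subst_model}: list with \code{states},
#'   \code{exch} (full symmetric matrix), \code{freq}, \code{Q}, a cached
#'   symmetric eigendecomposition, and \code{type} ("nt" or "aa").
#' @examples
#' m <- build_gtr()           # default mammalian-gene-like parameterization
#' rowSums(m$Q)               # ~0
#' @export
build_gtr <- function(exch = GTR_EXCH_DEFAULT, freq = NT_FREQ_DEFAULT,
                      states = NT_STATES) {
  n <- length(states)
  npair <- n * (n - 1L) / 2L
  if (length(exch) != npair)
    stop("need ", npair, " exchangeabilities for ", n, " states")
  if (any(exch <= 0)) stop("exchangeabilities must be positive")
  if (length(freq) != n) stop("need ", n, " frequencies")
  if (any(freq <= 0)) stop("frequencies must be positive")
  if (abs(sum(freq) - 1) > 1e-6) stop("frequencies must sum to 1")
  freq <- freq / sum(freq)

  R <- matrix(0, n, n, dimnames = list(states, states))
  R[lower.tri(R)] <- exch
  R <- R + t(R)
  Q <- R %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  R <- R / mu
  dimnames(Q) <- list(states, states)

  # symmetric similarity transform for a stable matrix exponential
  sq <- sqrt(freq)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  ei <- eigen(B, symmetric = TRUE)

  structure(list(states = states,
                 exch = R,
                 freq = setNames(as.numeric(freq), states),
                 Q = Q,
                 eig = list(values = ei$values,
                            right = diag(1 / sq) %*% ei$vectors,
                            left = t(ei$vectors) %*% diag(sq)),
                 type = if (n == 4L) "nt" else "aa"),
            class = "subst_model")
}

#' Build an empirical amino-acid substitution model
#'
#' Loads a bundled empirical exchangeability matrix (currently only the
#' Whelan-Goldman "WAG" model) and assembles the scaled reversible rate
#' matrix over the 20 amino-acid states.  Supplying \code{freq} gives the
#' "+F" variant where observed frequencies replace the model's published
#' stationary distribution.
#'
#' @param name model identifier; only \code{"WAG"} is bundled.
#' @param freq optional 20-vector of stationary frequencies (e.g. observed
#'   counts); default uses the model's published frequencies.
#' @return a \code{subst_model} over the 20-state amino-acid alphabet.
#' @export
build_empirical_aa <- function(name = "WAG", freq = NULL) {
  if (!identical(toupper(name), "WAG"))
    stop("unsupported empirical model: ", name)
  dat <- read_paml_dat(system.file("extdata", "wag.dat", package = "msabias"))
  if (is.null(freq)) freq <- dat$freq
  build_gtr(exch = dat$exch, freq = freq, states = AA_STATES)
}

# Parse a PAML-style .dat file: 19 lower-triangle exchangeability rows
# followed by one line of 20 frequencies; '#' comments allowed.
read_paml_dat <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))])
  vals <- lapply(strsplit(ln, "\\s+"), as.numeric)
  if (length(vals) != 20L) stop("malformed empirical-model file: ", path)
  M <- matrix(0, 20, 20)
  for (i in 2:20) {
    if (length(vals[[i - 1L]]) != i - 1L)
      stop("malformed exchangeability row ", i, " in ", path)
    M[i, 1:(i - 1L)] <- vals[[i - 1L]]
  }
  freq <- vals[[20L]]
  if (length(freq) != 20L) stop("malformed frequency line in ", path)
  list(exch = M[lower.tri(M)], freq = freq / sum(freq))
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("Reversible substitution model (%d states, %s)\n",
              length(x$states), x$type))
  cat("  expected rate at stationarity:",
      format(-sum(x$freq * diag(x$Q))), "\n")
  cat("  frequencies:", paste(sprintf("%s=%.3f", x$states, x$freq),
                              collapse = " "), "\n")
  invisible(x)
}

#' Discretize a Gamma rate distribution
#'
#' Equal-probability discretization of the mean-one Gamma(shape, shape)
#' distribution of among-site rate variation: the rate of each of the
#' \code{ncat} categories is the conditional mean of the distribution over
#' that quantile interval, so the discrete distribution keeps mean 1 exactly.
#'
#' @param shape Gamma shape alpha (> 0); small values = strong rate
#'   heterogeneity.
#' @param ncat number of categories (default 4).
#' @return object of class \code{gamma_rates}: \code{shape}, \code{ncat},
#'   \code{rates} (increasing, mean 1), \code{probs} (all 1/ncat).
#' @examples
#' discretize_gamma(1.8, 4)$rates
#' @export
discretize_gamma <- function(shape, ncat = 4L) {
  if (!is.numeric(shape) || shape <= 0) stop("shape must be positive")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("ncat must be >= 1")
  if (ncat == 1L) {
    rates <- 1
  } else {
    q <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = shape, rate = shape)
    # conditional mean over [q_i, q_{i+1}] via the incomplete-gamma identity
    cm <- pgamma(q, shape = shape + 1, rate = shape)
    rates <- ncat * diff(cm)
    rates <- rates / sum(rates / ncat)  # exact mean-1 against quantile rounding
  }
  structure(list(shape = shape, ncat = ncat,
                 rates = rates, probs = rep(1 / ncat, ncat)),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat(sprintf("Discrete Gamma rates: shape=%.4g, %d categories\n",
              x$shape, x$ncat))
  cat("  rates:", paste(sprintf("%.4f", x$rates), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' P(t * rate) = exp(Q * t * rate) via the cached symmetric
#' eigendecomposition of the reversible rate matrix.
#'
#' @param model a \code{subst_model}.
#' @param t branch length (expected substitutions per site at rate 1); >= 0.
#' @param rate relative site rate multiplier (default 1).
#' @return row-stochastic matrix of state transition probabilities.
#' @export
transition_probs <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("branch length must be a nonnegative number")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}
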