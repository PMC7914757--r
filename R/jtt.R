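## The JTT amino-acid replacement model: the standard published
## exchangeability values and equilibrium frequencies (lower triangle,
## amino-acid order ARNDCQEGHILKMFPSTWYV). A unit test cross-checks these
## constants against an independent copy shipped with phangorn.

.JTT_S_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQS <- c(
  A = 0.076748, R = 0.051691, N = 0.042645, D = 0.051544, C = 0.019803,
  Q = 0.040752, E = 0.061830, G = 0.073152, H = 0.022944, I = 0.053761,
  L = 0.091904, K = 0.058676, M = 0.023826, F = 0.040126, P = 0.050901,
  S = 0.068765, T = 0.058565, W = 0.014261, Y = 0.032102, V = 0.066005)

#' JTT instantaneous rate matrix
#'
#' Assembles the 20x20 JTT rate matrix from the published exchangeabilities
#' and equilibrium frequencies, normalized so the expected number of
#' substitutions per site per unit time is 1.
#'
#' @return 20x20 numeric matrix, rows/columns in order
#'   \code{ARNDCQEGHILKMFPSTWYV}, rows summing to zero.
#' @export
jttRateMatrix <- function() {
  S <- matrix(0, 20, 20, dimnames = list(.aaOrderJTT, .aaOrderJTT))
  S[lower.tri(S)] <- .JTT_S_LOWER
  S <- S + t(S)
  pi <- .JTT_FREQS / sum(.JTT_FREQS)
  Q <- S * rep(pi, each = 20)          # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## Spectral decomposition of the (reversible) JTT generator via the
## pi-symmetrized form. Returns eigenvalues and the weights c_k such that the
## expected proportion of identical sites after time t is sum_k c_k exp(l_k t).
.jttSpectral <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    Q <- jttRateMatrix()
    pi <- .JTT_FREQS / sum(.JTT_FREQS)
    sp <- sqrt(pi)
    B <- diag(sp) %*% Q %*% diag(1 / sp)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    ## pi_i P_ii(t) = pi_i [ (1/sp_i) sum_k V_ik^2 e^{l_k t} sp_i ]
    cw <- colSums(pi * e$vectors^2)
    cache <<- list(lambda = e$values, w = cw, pi = pi,
                   V = e$vectors, sp = sp)
    cache
  }
})

#' JTT transition probability matrix
#'
#' \code{P(t) = exp(Qt)} for the normalized JTT generator, optionally under a
#' site-rate multiplier. Used by the simulation-based tests as the generating
#' model and by the distance estimator's expected-difference curve.
#'
#' @param t Divergence time in expected substitutions per site.
#' @param rate Optional rate multiplier.
#' @return 20x20 transition probability matrix.
#' @export
jttTransitionMatrix <- function(t, rate = 1) {
  s <- .jttSpectral()
  E <- s$V %*% (exp(s$lambda * t * rate) * t(s$V))
  P <- (1 / s$sp) * E * rep(s$sp, each = 20)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(.aaOrderJTT, .aaOrderJTT)
  P
}

#' Discrete-gamma rate categories
#'
#' Mean rates of \code{k} equal-probability categories of a Gamma(shape =
#' alpha, rate = alpha) distribution (mean 1), the standard discretization
#' for among-site rate heterogeneity.
#'
#' @param alpha Gamma shape (> 0); smaller alpha = more rate variation.
#' @param k Number of categories (>= 1).
#' @return Numeric vector of k rates with mean 1.
#' @export
#' @examples
#' discreteGammaRates(1, 4)
discreteGammaRates <- function(alpha, k = 8L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- k * diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

## Expected proportion of DIFFERING sites between two sequences separated by
## total divergence t under JTT with discrete-gamma rates. Vectorized in t.
.jttExpectedP <- function(t, rates) {
  s <- .jttSpectral()
  acc <- numeric(length(t))
  for (r in rates) acc <- acc + drop(exp(outer(t * r, s$lambda)) %*% s$w)
  1 - acc / length(rates)
}

## Asymptotic (t -> Inf) expected proportion of differences: 1 - sum pi^2.
.jttPMax <- function() {
  pi <- .JTT_FREQS / sum(.JTT_FREQS)
  1 - sum(pi^2)
}
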