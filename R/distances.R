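#' Distance model specification
#'
#' @param kind One of \code{"p_distance"} (raw proportion of differing
#'   comparable sites), \code{"poisson_gamma"} (Poisson correction with
#'   gamma-distributed site rates, \code{d = alpha * ((1-p)^(-1/alpha) - 1)}),
#'   or \code{"jtt_gamma"} (divergence time inverting the JTT
#'   expected-difference curve under a k-category discrete gamma).
#' @param alpha Gamma shape (> 0); ignored for \code{p_distance}.
#' @param deletion \code{"pairwise"} (default; each pair uses the columns
#'   where both rows are ungapped) or \code{"complete"} (only columns ungapped
#'   in every row).
#' @param rate_categories Number of discrete-gamma categories for
#'   \code{jtt_gamma} (default 8).
#' @return A list of class \code{DistanceModel}.
#' @export
distanceModel <- function(kind = c("jtt_gamma", "poisson_gamma", "p_distance"),
                          alpha = 1, deletion = c("pairwise", "complete"),
                          rate_categories = 8L) {
  kind <- match.arg(kind)
  deletion <- match.arg(deletion)
  if (kind != "p_distance" && alpha <= 0) stop("alpha must be > 0")
  if (rate_categories < 1) stop("rate_categories must be >= 1")
  structure(list(kind = kind, alpha = alpha, deletion = deletion,
                 rate_categories = as.integer(rate_categories)),
            class = "DistanceModel")
}

#' Poisson+Gamma distance from a proportion of differences
#'
#' The closed-form gamma-corrected Poisson distance
#' \code{d = alpha * ((1 - p)^(-1/alpha) - 1)}. Strictly decreasing in alpha
#' for fixed p, with limit \code{-log(1 - p)} as alpha grows.
#'
#' @param p Proportion of differing comparable sites, in \[0, 1).
#' @param alpha Gamma shape (> 0).
#' @return Numeric distance(s).
#' @export
#' @examples
#' poissonGammaDistance(0.5, 1)     # 1
#' poissonGammaDistance(0.19, 2)    # 2 * ((0.81)^(-1/2) - 1)
poissonGammaDistance <- function(p, alpha) {
  stopifnot(alpha > 0, all(p >= 0 & p < 1))
  alpha * ((1 - p)^(-1 / alpha) - 1)
}

#' JTT+Gamma divergence from proportions of differences
#'
#' Inverts the expected-difference curve \code{E[p | t, alpha]} of the
#' normalized JTT model averaged over k discrete-gamma rate categories, by
#' monotone bisection on \code{t} in \[0, 20\]. Values of p at or beyond 99%
#' of the model's asymptote are returned as NA (saturated).
#'
#' @param p Numeric vector of proportions of differing comparable sites.
#' @param alpha Gamma shape.
#' @param k Number of discrete-gamma categories.
#' @return Numeric vector of divergence times (expected substitutions/site).
#' @export
jttGammaDistance <- function(p, alpha = 1, k = 8L) {
  rates <- discreteGammaRates(alpha, k)
  ceiling_p <- 0.99 * .jttPMax()
  out <- rep(NA_real_, length(p))
  solve <- p < ceiling_p & p >= 0
  out[solve & p == 0] <- 0
  todo <- which(solve & p > 0)
  if (length(todo)) {
    lo <- rep(0, length(todo)); hi <- rep(20, length(todo))
    target <- p[todo]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      pm <- .jttExpectedP(mid, rates)
      up <- pm < target
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    out[todo] <- (lo + hi) / 2
  }
  out
}

#' Pairwise evolutionary distances from an alignment
#'
#' Computes, for every pair of rows, the proportion p of differing sites over
#' the columns where both rows are ungapped (pairwise deletion), and the
#' model-corrected distance. Pairs with zero comparable sites are flagged
#' \code{incomparable}; pairs whose p reaches the model's saturation ceiling
#' (99% of the asymptote) are flagged \code{saturated}; both get NA distances
#' rather than silently truncated values.
#'
#' @param alignment A [DomainAlignment], a character matrix of residues and
#'   \code{"-"} gaps, or an \code{AAStringSet} of equal-length aligned
#'   sequences.
#' @param model A [distanceModel()].
#' @return A [PairwiseDistances].
#' @export
pairwiseDistances <- function(alignment, model = distanceModel()) {
  M <- .asAlnMatrix(alignment)
  ids <- rownames(M)
  n <- nrow(M)
  if (n < 2) stop("need at least two rows")
  if (model$deletion == "complete") {
    keep <- colSums(M == "-") == 0
    M <- M[, keep, drop = FALSE]
  }
  X <- matrix(match(M, c(LETTERS, letters)), nrow = n)  # gaps/unknown -> NA
  X[M == "-"] <- NA_integer_

  P <- matrix(0, n, n); S <- matrix(0L, n, n)
  flags <- matrix("ok", n, n)
  for (i in seq_len(n - 1)) {
    xi <- X[i, ]
    for (j in (i + 1):n) {
      xj <- X[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      m <- sum(ok)
      S[i, j] <- S[j, i] <- m
      if (m == 0) {
        flags[i, j] <- flags[j, i] <- "incomparable"
        P[i, j] <- P[j, i] <- NA_real_
      } else {
        P[i, j] <- P[j, i] <- sum(xi[ok] != xj[ok]) / m
      }
    }
  }

  D <- P
  pv <- P[upper.tri(P)]
  ceiling_p <- switch(model$kind,
                      p_distance = 1.01,          # never saturates
                      poisson_gamma = 0.99,
                      jtt_gamma = 0.99 * .jttPMax())
  sat <- !is.na(P) & P >= ceiling_p & row(P) != col(P)
  if (model$kind == "poisson_gamma") {
    ok <- !is.na(P) & !sat
    D[ok] <- poissonGammaDistance(P[ok], model$alpha)
  } else if (model$kind == "jtt_gamma") {
    ut <- upper.tri(P)
    vals <- jttGammaDistance(ifelse(is.na(pv) | pv >= ceiling_p, 0, pv),
                             model$alpha, model$rate_categories)
    D[ut] <- vals
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    diag(D) <- 0
  }
  D[sat] <- NA_real_
  flags[sat] <- "saturated"
  D[flags == "incomparable"] <- NA_real_

  new("PairwiseDistances", ids = ids, d = D, sites = S, flags = flags,
      model = unclass(model))
}

.asAlnMatrix <- function(alignment) {
  if (is(alignment, "DomainAlignment")) return(alignment@aa)
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment)))
      rownames(alignment) <- paste0("seq", seq_len(nrow(alignment)))
    return(alignment)
  }
  if (is(alignment, "XStringSet") || is.character(alignment)) {
    ch <- as.character(alignment)
    if (length(unique(nchar(ch))) != 1)
      stop("aligned sequences must have equal length")
    M <- do.call(rbind, strsplit(ch, ""))
    rownames(M) <- if (!is.null(names(ch))) names(ch)
                   else paste0("seq", seq_along(ch))
    return(M)
  }
  stop("unsupported alignment type")
}
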