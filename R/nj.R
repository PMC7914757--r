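#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' \code{Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)} is joined, with
#' deterministic tie-breaking (lexicographically smallest index pair in the
#' current ordering). Branch lengths use the standard split formula; by
#' default negative lengths are clamped to zero with the overflow added to
#' the sibling edge so path lengths between the joined pair are preserved.
#'
#' @param D A [PairwiseDistances] or a symmetric numeric matrix with
#'   dimnames. Must contain no NA among the used entries.
#' @param clampNegative If TRUE (default), apply the zero-clamp convention;
#'   if FALSE, keep negative branch lengths.
#' @return An unrooted \code{ape::phylo} tree with the input ids as tips.
#' @export
#' @examples
#' D <- matrix(c(0,5,9,9, 5,0,10,10, 9,10,0,8, 9,10,8,0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' tr <- neighborJoining(D)
neighborJoining <- function(D, clampNegative = TRUE) {
  if (is(D, "PairwiseDistances")) {
    bad <- which(D@flags != "ok" & upper.tri(D@flags), arr.ind = TRUE)
    if (nrow(bad))
      stop("distance matrix contains flagged pairs, e.g. ",
           D@ids[bad[1, 1]], " vs ", D@ids[bad[1, 2]])
    M <- distMatrix(D)
  } else M <- D
  if (anyNA(M) || any(!is.finite(M))) stop("NA/non-finite in distance matrix")
  n <- nrow(M)
  if (n < 3) stop("need at least 3 taxa")
  ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  frag <- ids            # newick fragment per active node
  active <- seq_len(n)

  while (length(active) > 3) {
    m <- length(active)
    sub <- M[active, active]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- sub[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clampNegative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
      li <- max(li, 0); lj <- max(lj, 0)
    }
    ai <- active[i]; aj <- active[j]
    newdist <- (M[ai, active] + M[aj, active] - dij) / 2
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[ai], li, frag[aj], lj)
    ## reuse slot ai for the merged node
    M[ai, active] <- newdist; M[active, ai] <- newdist; M[ai, ai] <- 0
    frag[ai] <- newfrag
    active <- active[-j]
  }

  a <- active[1]; b <- active[2]; c <- active[3]
  la <- (M[a, b] + M[a, c] - M[b, c]) / 2
  lb <- (M[a, b] + M[b, c] - M[a, c]) / 2
  lc <- (M[a, c] + M[b, c] - M[a, b]) / 2
  if (clampNegative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[a], la, frag[b], lb, frag[c], lc)
  ape::read.tree(text = nwk)
}

#' Path-length (patristic) matrix of a tree
#'
#' @param tree An \code{ape::phylo}.
#' @return Symmetric matrix of tip-to-tip path lengths, ordered by tip label.
#' @export
pathLengthMatrix <- function(tree) {
  M <- ape::cophenetic.phylo(tree)
  M[order(rownames(M)), order(colnames(M))]
}
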