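#' Neighbor-Joining tree with bootstrap clade support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement B times (amino-acid columns; for a
#' codon-position-1+2 nucleotide matrix the two positions of a codon are
#' resampled together), rebuilds the tree for each replicate, and annotates
#' each internal edge of the original tree with the percentage of replicate
#' trees containing the same bipartition (rounded to integer, stored in
#' \code{node.label}). Reproducible given \code{seed}: replicate b draws its
#' columns from a stream seeded with \code{seed + b}.
#'
#' Saturated or incomparable pairs arising in a replicate are capped at the
#' model ceiling distance instead of aborting the replicate, so supports
#' remain defined for alignments near saturation.
#'
#' @param alignment A [DomainAlignment] or character matrix (see
#'   [pairwiseDistances()]).
#' @param model A [distanceModel()].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param codonPairs If TRUE, treat consecutive column pairs as units
#'   (for nt12 matrices).
#' @return An \code{ape::phylo} with integer \code{node.label} supports in
#'   \[0, 100\] (root label empty).
#' @export
bootstrapSupport <- function(alignment, model = distanceModel(), B = 100L,
                             seed = 1L, codonPairs = FALSE) {
  stopifnot(B >= 1)
  M <- .asAlnMatrix(alignment)
  tree <- neighborJoining(.capped(pairwiseDistances(M, model)))
  L <- ncol(M)
  units <- if (codonPairs) L %/% 2L else L
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    u <- sample.int(units, units, replace = TRUE)
    cols <- if (codonPairs) as.vector(rbind(2L * u - 1L, 2L * u)) else u
    Db <- .capped(pairwiseDistances(M[, cols, drop = FALSE], model))
    reps[[b]] <- neighborJoining(Db)
  }
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  lab <- as.character(as.integer(round(100 * cnt / B)))
  lab[1] <- ""                       # the root of an unrooted tree is not an edge
  tree$node.label <- lab
  tree
}

## Replace flagged pair distances with the model ceiling so NJ stays defined.
.capped <- function(D) {
  bad <- D@flags != "ok"
  if (!any(bad)) return(D)
  cap <- switch(D@model$kind,
                p_distance = 1,
                poisson_gamma = poissonGammaDistance(0.99, D@model$alpha),
                jtt_gamma = 20)
  mx <- suppressWarnings(max(D@d[D@flags == "ok"], na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0
  D@d[bad] <- max(cap, mx * 1.05)
  diag(D@d) <- 0
  D@flags[bad] <- "ok"
  D
}

#' Serialize a tree with a support rendering threshold
#'
#' Writes Newick with supports as internal node labels, blanking supports
#' below \code{threshold} (the conventional "values below 30 are not shown").
#'
#' @param tree An \code{ape::phylo} with \code{node.label} supports.
#' @param path Output file, or NULL to return the string.
#' @param threshold Minimum support to render (default 30).
#' @return The Newick string, invisibly when written to a file.
#' @export
writeTreeWithSupports <- function(tree, path = NULL, threshold = 30) {
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(v) & v < threshold] <- ""
  }
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
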