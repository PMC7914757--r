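#' Minimal clade cover of a tip set
#'
#' The minimum number of clades of an unrooted tree needed to cover exactly a
#' given set of tips: 1 if the set is a clade (forms one side of a
#' bipartition), otherwise the number of maximal subtrees whose tips all
#' belong to the set. The tree is rooted at a tip outside the set for the
#' computation; if the set contains all tips the answer is 1.
#'
#' @param tree An \code{ape::phylo}.
#' @param tips Character vector of tip labels.
#' @return Integer clade count (>= 1 for a non-empty set).
#' @export
cladeCover <- function(tree, tips) {
  tips <- intersect(tips, tree$tip.label)
  if (!length(tips)) return(0L)
  out <- setdiff(tree$tip.label, tips)
  if (!length(out)) return(1L)
  rt <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  n <- length(rt$tip.label)
  inset <- rt$tip.label %in% tips
  ## postorder: does every tip under this node belong to the set?
  allin <- c(inset, rep(NA, rt$Nnode))
  po <- ape::reorder.phylo(rt, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    v <- allin[ch]
    allin[p] <- if (is.na(allin[p])) v else allin[p] && v
  }
  ## maximal all-in nodes: all-in, parent not all-in
  parent <- integer(n + rt$Nnode)
  parent[po$edge[, 2]] <- po$edge[, 1]
  root <- n + 1L
  cnt <- 0L
  for (v in which(allin)) {
    if (v == root) next
    if (!isTRUE(allin[parent[v]])) cnt <- cnt + 1L
  }
  if (isTRUE(allin[root])) cnt <- 1L
  max(cnt, 1L)
}

#' Gamma sensitivity sweep
#'
#' Rebuilds the tree for each gamma shape value and reports, per orthogroup,
#' the cohesion: 1 if the orthogroup's sequences form a clade, otherwise the
#' minimum number of clades covering them. Low shape values (strong rate
#' heterogeneity) tend to fragment fast-evolving orthogroups; shapes at or
#' above 1 keep them united.
#'
#' @param alignment A [DomainAlignment] or character matrix.
#' @param model A [distanceModel()]; its alpha is overridden per sweep value.
#' @param alphas Numeric vector of gamma shapes to test (the conventional
#'   comparison set is \code{c(0.8, 1.0, 1.1)}).
#' @param labels Named character vector: orthogroup per sequence id.
#' @return data.frame with columns \code{alpha}, \code{orthogroup},
#'   \code{cohesion}, \code{n_members}.
#' @export
gammaSweep <- function(alignment, model = distanceModel(),
                       alphas = c(0.8, 1.0, 1.1), labels) {
  M <- .asAlnMatrix(alignment)
  ids <- rownames(M)
  if (is.null(names(labels)) || !all(ids %in% names(labels)))
    stop("labels must be named by sequence id and cover the alignment")
  labels <- labels[ids]
  res <- list()
  for (a in alphas) {
    m <- model; m$alpha <- a
    tr <- neighborJoining(.capped(pairwiseDistances(M, m)))
    for (og in unique(labels)) {
      memb <- ids[labels == og]
      res[[length(res) + 1L]] <- data.frame(
        alpha = a, orthogroup = og,
        cohesion = cladeCover(tr, memb), n_members = length(memb))
    }
  }
  do.call(rbind, res)
}
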