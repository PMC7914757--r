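## Shared fixtures and independent oracles, built in code.

## reference analysis settings: wide alignment window (approximates the
## ~200-position conserved-domain alignment used for the main trees)
refSignature <- function() signatureConfig(extension_nt = 60)

## small constructed records: template-derived CDS with controlled defects
templateCDS <- function() makeDomainTemplate()$cds

## mutate one codon of a CDS (1-based codon index) to a given codon
swapCodon <- function(cds, codonIdx, newCodon) {
  x <- strsplit(cds, "")[[1]]
  x[(3 * codonIdx - 2):(3 * codonIdx)] <- strsplit(newCodon, "")[[1]]
  paste(x, collapse = "")
}

## a GeneRecordSet from named cds strings + optional locations data.frame
recordsFromCDS <- function(cds, loc = NULL) {
  readGeneRecords(Biostrings::DNAStringSet(unlist(cds)), loc)
}

simpleLocations <- function(ids, species = "Xx", group = "A",
                            unit = "chr1", start = 101, end = NULL,
                            strand = "+") {
  n <- length(ids)
  if (is.null(end)) end <- start + 999
  data.frame(record_id = ids, species = rep_len(species, n),
             group = rep_len(group, n), assembly_unit = rep_len(unit, n),
             start = rep_len(start, n), end = rep_len(end, n),
             strand = rep_len(strand, n))
}

## quick reference simulation -> list(records, truth, history)
quickSim <- function(seed, n_og = 8L, ...) {
  cfg <- simulationConfig(seed = seed, n_root_orthogroups = n_og, ...)
  h <- simulateHistory(cfg)
  rec <- evolveSequences(h, cfg)
  tr <- as.data.frame(historyTruth(h))
  list(cfg = cfg, history = h, records = rec,
       truth = stats::setNames(tr$orthogroup, tr$record_id),
       truthTable = tr)
}

## ---- independent NJ oracle: brute-force topology enumeration --------------

## all unrooted binary topologies on taxa 1..n as edge lists, built by
## sequential insertion of each taxon into every edge of every smaller tree
enumTopologies <- function(n) {
  stopifnot(n >= 3, n <= 6)
  ## represent: edge matrix over node ids; tips 1..n, internals n+1, ...
  base <- list(list(edge = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    nextNode = n + 2))
  trees <- base
  for (tip in seq(4, length.out = max(0, n - 3))) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        newInt <- tr$nextNode
        ed <- tr$edge
        a <- ed[e, 1]; b <- ed[e, 2]
        ed[e, ] <- c(a, newInt)
        ed <- rbind(ed, c(newInt, b), c(newInt, tip))
        out[[length(out) + 1]] <- list(edge = ed, nextNode = newInt + 1)
      }
    }
    trees <- out
  }
  trees
}

## least-squares branch lengths for a fixed topology; returns max abs
## residual between the tree's path lengths and D
lsFitResidual <- function(edge, D) {
  n <- nrow(D)
  nodes <- sort(unique(as.vector(edge)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer(0))
  eid <- matrix(0L, max(nodes), max(nodes))
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    eid[a, b] <- eid[b, a] <- k
  }
  pathEdges <- function(from, to) {
    ## BFS
    prev <- rep(0L, max(nodes)); prev[from] <- from
    q <- from
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (v == to) break
      for (w in adj[[v]]) if (prev[w] == 0L) { prev[w] <- v; q <- c(q, w) }
    }
    out <- integer(0); v <- to
    while (v != from) { out <- c(out, eid[v, prev[v]]); v <- prev[v] }
    out
  }
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), nrow(edge))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    X[k, pathEdges(i, j)] <- 1
    y[k] <- D[i, j]
  }
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  max(abs(X %*% beta - y))
}

## brute-force: the (unique) topology reproducing an additive matrix exactly
bruteForceTopology <- function(D, tol = 1e-8) {
  n <- nrow(D)
  tps <- enumTopologies(n)
  fits <- vapply(tps, function(t) lsFitResidual(t$edge, D), 0)
  hit <- which(fits < tol)
  if (length(hit) != 1) return(NULL)
  tps[[hit]]$edge
}

## unrooted split set of a tree over tip labels 1..n (for topology comparison)
splitSet <- function(edge, n) {
  nodes <- max(edge)
  adj <- lapply(seq_len(nodes), function(i) integer(0))
  for (k in seq_len(nrow(edge))) {
    adj[[edge[k, 1]]] <- c(adj[[edge[k, 1]]], edge[k, 2])
    adj[[edge[k, 2]]] <- c(adj[[edge[k, 2]]], edge[k, 1])
  }
  tipsBelow <- function(v, parent) {
    if (v <= n) return(v)
    out <- integer(0)
    for (w in adj[[v]]) if (w != parent) out <- c(out, tipsBelow(w, v))
    out
  }
  sp <- character(0)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    side <- sort(tipsBelow(b, a))
    if (length(side) >= 2 && length(side) <= n - 2) {
      if (!(1 %in% side)) side <- sort(setdiff(seq_len(n), side))
      sp <- c(sp, paste(side, collapse = ","))
    }
  }
  sort(unique(sp))
}

## splits of an ape tree whose tips are "1".."n"
apeSplitSet <- function(tree) {
  n <- length(tree$tip.label)
  relab <- as.integer(tree$tip.label)
  edge <- tree$edge
  ## renumber: ape tips 1..n correspond to labels; map node ids directly
  ## (tips first, internals after, same convention as splitSet)
  m <- max(edge)
  map <- seq_len(m)
  map[seq_len(n)] <- relab
  e2 <- cbind(map[edge[, 1]], map[edge[, 2]])
  splitSet(e2, n)
}

## random additive matrix from a random binary tree; returns list(D)
randomAdditive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr$tip.label <- as.character(sample(n))
  D <- ape::cophenetic.phylo(tr)
  ord <- order(as.integer(rownames(D)))
  D <- D[ord, ord]
  dimnames(D) <- list(as.character(1:n), as.character(1:n))
  list(D = D, tree = tr)
}
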