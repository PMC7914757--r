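#' Name lineage genes lacking confident orthogroup affinity
#'
#' Implements the naming rules used for cyclostome-style lineages whose genes
#' only partly follow the orthogroup structure of the jawed vertebrates.
#' Lineage genes are first clustered into maximal clades containing only
#' lineage leaves; each cluster is then named by mean conserved-domain
#' amino-acid identity to the orthogroups:
#' \enumerate{
#'   \item Identity to the nearest orthogroup exceeds the runner-up by at
#'     least \code{margin} percentage points: the cluster takes that
#'     orthogroup's (lower-case) name.
#'   \item Two orthogroups are approximately equidistant but jointly stand
#'     out from the rest: a combined name (\code{gjd1/2} style).
#'   \item No clear affinity: the subfamily prefix of the nearest orthogroup
#'     plus \code{-genN}, numbered per subfamily.
#' }
#' Within a multi-gene cluster with a (possibly combined) base name, members
#' located on the same assembly unit within \code{window} bp receive
#' \code{.1}, \code{.2}, ... suffixes (tandem duplicates), members on
#' different units receive \code{a}, \code{b}, ... (possible products of
#' genome duplication or rearrangement); if locations are missing the tandem
#' versus dispersed distinction is undecidable and the cluster falls back to
#' \code{-genN} with a warning.
#'
#' @param assignments Output of [incrementalHarmonize()] /
#'   [assignOrthogroupNames()] covering the non-lineage records.
#' @param tree \code{ape::phylo} containing both lineage and reference leaves.
#' @param alignment A [DomainAlignment] or character matrix for identity
#'   computation.
#' @param records A [GeneRecordSet] providing locations.
#' @param lineageIds Character vector of lineage record ids.
#' @param margin Percentage-point margin for "clearly higher identity"
#'   (default 3).
#' @param window Linkage window in bp for the tandem suffix (default 1 Mb).
#' @param subfamilyOf Function mapping an orthogroup name to its subfamily
#'   prefix (default: first three characters, e.g. \code{"gjc"}).
#' @return DataFrame: \code{record_id}, \code{name}, \code{rule},
#'   \code{nearest}, \code{nearest_identity}, \code{runnerup_identity}.
#' @export
nameUnplacedLineageGenes <- function(assignments, tree, alignment, records,
                                     lineageIds, margin = 3, window = 1e6,
                                     subfamilyOf = function(x) tolower(substr(x, 1, 3))) {
  M <- .asAlnMatrix(alignment)
  ids <- rownames(M)
  lineageIds <- intersect(lineageIds, ids)
  if (!length(lineageIds)) return(DataFrame(record_id = character(0)))
  lab <- stats::setNames(assignments$orthogroup, assignments$record_id)
  refIds <- setdiff(ids, lineageIds)
  refIds <- refIds[!is.na(lab[refIds])]
  ogs <- unique(lab[refIds])

  ## mean aa identity (pairwise-deletion columns) lineage gene x orthogroup
  pident <- function(a, b) {
    ok <- M[a, ] != "-" & M[b, ] != "-"
    if (!any(ok)) return(NA_real_)
    100 * mean(M[a, ok] == M[b, ok])
  }
  idmat <- matrix(NA_real_, length(lineageIds), length(ogs),
                  dimnames = list(lineageIds, ogs))
  for (g in ogs) {
    memb <- refIds[lab[refIds] == g]
    for (q in lineageIds)
      idmat[q, g] <- mean(vapply(memb, function(r) pident(q, r), 0))
  }

  ## clusters: maximal lineage-only clades in the tree
  cl <- .lineageClusters(tree, lineageIds)

  info <- recordInfo(records)
  genCounter <- new.env(parent = emptyenv())
  rows <- list()
  for (cluster in cl) {
    prof <- colMeans(idmat[cluster, , drop = FALSE])
    ord <- order(prof, decreasing = TRUE)
    top <- ogs[ord]; val <- prof[ord]
    rule <- NULL; base <- NULL
    if (length(val) >= 2 && (val[1] - val[2]) >= margin) {
      rule <- "nearest"; base <- tolower(top[1])
    } else if (length(val) == 1) {
      rule <- "nearest"; base <- tolower(top[1])
    } else if (length(val) == 2 || (val[2] - val[3]) >= margin) {
      rule <- "combined"
      nm <- c(tolower(top[1]), tolower(top[2]))
      num <- suppressWarnings(as.numeric(sub("^[a-z]+", "", nm)))
      o <- order(sub("[0-9].*$", "", nm), num, nm)
      n1 <- nm[o[1]]; n2 <- nm[o[2]]
      pre <- .commonPrefix(n1, n2)
      base <- paste0(n1, "/", substring(n2, nchar(pre) + 1L))
    } else {
      rule <- "gen"
    }

    if (identical(rule, "gen")) {
      sf <- subfamilyOf(top[1])
      for (q in cluster) {
        k <- (if (is.null(genCounter[[sf]])) 0L else genCounter[[sf]]) + 1L
        genCounter[[sf]] <- k
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = q, name = sprintf("%s-gen%d", sf, k), rule = "gen",
          nearest = top[1], nearest_identity = val[1],
          runnerup_identity = if (length(val) > 1) val[2] else NA_real_)
      }
      next
    }

    suffixes <- .clusterSuffixes(cluster, info, window)
    if (is.null(suffixes)) {
      warning("missing locations for cluster {",
              paste(cluster, collapse = ","),
              "}: tandem/dispersed undecidable, using -genN")
      sf <- subfamilyOf(top[1])
      for (q in cluster) {
        k <- (if (is.null(genCounter[[sf]])) 0L else genCounter[[sf]]) + 1L
        genCounter[[sf]] <- k
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = q, name = sprintf("%s-gen%d", sf, k),
          rule = "gen_fallback", nearest = top[1], nearest_identity = val[1],
          runnerup_identity = val[2])
      }
      next
    }
    for (i in seq_along(cluster)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = cluster[i], name = paste0(base, suffixes[i]), rule = rule,
        nearest = top[1], nearest_identity = val[1],
        runnerup_identity = if (length(val) > 1) val[2] else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  DataFrame(out[match(lineageIds, out$record_id), , drop = FALSE],
            row.names = NULL)
}

## maximal clades containing only lineage leaves (clusters); singletons allowed
.lineageClusters <- function(tree, lineageIds) {
  inTree <- intersect(lineageIds, tree$tip.label)
  out <- setdiff(tree$tip.label, inTree)
  if (!length(out)) return(list(inTree))
  rt <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  n <- length(rt$tip.label)
  po <- ape::reorder.phylo(rt, "postorder")
  allin <- c(rt$tip.label %in% inTree, rep(NA, rt$Nnode))
  desc <- vector("list", n + rt$Nnode)
  for (v in seq_len(n)) desc[[v]] <- v
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    allin[p] <- if (is.na(allin[p])) allin[ch] else allin[p] && allin[ch]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  parent <- integer(n + rt$Nnode)
  parent[po$edge[, 2]] <- po$edge[, 1]
  clusters <- list()
  for (v in which(allin)) {
    if (v == n + 1L) next
    if (!isTRUE(allin[parent[v]]))
      clusters[[length(clusters) + 1L]] <- rt$tip.label[desc[[v]]]
  }
  clusters
}

## suffixes within a named cluster: "" for singletons; ".1",".2" for linked
## same-unit members; "a","b" for different units; NULL if undecidable.
.clusterSuffixes <- function(cluster, info, window) {
  if (length(cluster) == 1L) return("")
  m <- match(cluster, info$record_id)
  if (anyNA(m) || any(!info$placed[m])) return(NULL)
  units <- info$assembly_unit[m]; starts <- info$start[m]
  if (length(unique(units)) == 1L &&
      (max(starts) - min(starts)) <= window) {
    ord <- order(starts)
    suff <- character(length(cluster))
    suff[ord] <- paste0(".", seq_along(cluster))
    return(suff)
  }
  if (length(unique(units)) == length(units)) {
    ord <- order(cluster)
    suff <- character(length(cluster))
    suff[ord] <- letters[seq_along(cluster)]
    return(suff)
  }
  ## mixed case: same unit but distant, or repeated units among >2 members;
  ## fall back to the dispersed convention ordered by unit then position
  ord <- order(units, starts)
  suff <- character(length(cluster))
  suff[ord] <- letters[seq_along(cluster)]
  suff
}
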