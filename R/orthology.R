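#' Canonical incremental build orders
#'
#' The three group-addition orders used by the harmonization protocol:
#' \describe{
#'   \item{mammal_down}{seed with mammals (A, B, C), add the remaining
#'     tetrapods downwards, then the lobe-finned fish, then the non-teleost
#'     ray-finned fishes, then Chondrichthyes, and teleosts last.}
#'   \item{teleost_out}{seed with teleosts (M), add the other actinopterygians,
#'     then Chondrichthyes, then build upwards to mammals.}
#'   \item{chondrichthyes_up}{seed with Chondrichthyes (N), build upwards,
#'     teleosts added last.}
#' }
#' Together the step sets of each order partition the full group set A-N.
#'
#' @param groups Optional character vector of group codes present in the
#'   data; steps are restricted to these (empty steps dropped).
#' @return Named list of build orders, each a list with \code{order_id} and
#'   \code{steps} (list of character vectors).
#' @export
canonicalBuildOrders <- function(groups = NULL) {
  orders <- list(
    mammal_down = list(
      order_id = "mammal_down",
      steps = list(c("A", "B", "C"), c("D", "E", "F", "G"), "H", "I",
                   c("J", "K", "L"), "N", "M")),
    teleost_out = list(
      order_id = "teleost_out",
      steps = list("M", c("L", "K", "J"), "N", "I", "H",
                   c("D", "E", "F", "G"), c("A", "B", "C"))),
    chondrichthyes_up = list(
      order_id = "chondrichthyes_up",
      steps = list("N", c("J", "K", "L"), "I", "H", c("D", "E", "F", "G"),
                   c("A", "B", "C"), "M")))
  if (!is.null(groups)) {
    orders <- lapply(orders, function(o) {
      o$steps <- Filter(length, lapply(o$steps, intersect, y = groups))
      o
    })
  }
  orders
}

## Assign labels to unlabeled leaves: midpoint-root the tree, then for each
## query walk up from its parent and take the first ancestor with labeled
## descendants (other than the query); majority label wins, ties -> NA.
.propagateLabels <- function(tree, fixed) {
  tr <- tryCatch(phangorn::midpoint(tree), error = function(e) tree)
  n <- length(tr$tip.label)
  parent <- integer(n + tr$Nnode)
  po <- ape::reorder.phylo(tr, "postorder")
  parent[po$edge[, 2]] <- po$edge[, 1]
  ## descendant tips per node
  desc <- vector("list", n + tr$Nnode)
  for (v in seq_len(n)) desc[[v]] <- v
  for (k in seq_len(nrow(po$edge)))
    desc[[po$edge[k, 1]]] <- c(desc[[po$edge[k, 1]]], desc[[po$edge[k, 2]]])
  lab <- fixed[tr$tip.label]        # NA where unlabeled
  out <- stats::setNames(rep(NA_character_, n), tr$tip.label)
  for (q in seq_len(n)) {
    v <- parent[q]
    while (v != 0L) {
      cand <- lab[setdiff(desc[[v]], q)]
      cand <- cand[!is.na(cand)]
      if (length(cand)) {
        tb <- sort(table(cand), decreasing = TRUE)
        if (length(tb) == 1L || tb[1] > tb[2]) out[q] <- names(tb)[1]
        break
      }
      v <- parent[v]
    }
  }
  out
}

#' Incremental orthology harmonization across build orders
#'
#' The first order in the list is the naming pass: its seed labels (the
#' anchor names) propagate outwards as groups are added. The remaining
#' orders are consistency checks: each starts from its own seed group
#' carrying the names assigned by the naming pass (anchors stay fixed
#' everywhere), and re-derives every other label from its own tree sequence.
#'
#' Within an order: at every step the next group's sequences are added, the
#' NJ tree of the enlarged set is rebuilt (distances are computed once on the
#' full alignment and subset per step, which is exact under pairwise
#' deletion), and every non-seed sequence receives the induced label of its
#' smallest enclosing clade that contains reference-labeled leaves (majority
#' vote; ties leave it unplaced at that step). The step trees are consistency
#' probes, not label sources: a sequence is internally consistent for an
#' order if every step's induced label equals its first induction (unplaced
#' steps are skipped), and the order's label is the induction in the final,
#' complete tree. The final flag is \code{consistent} when all orders agree
#' on the same label and each is internally consistent, \code{inconsistent}
#' when labels conflict or wobbled mid-protocol, \code{unplaced} when no
#' order could place it.
#'
#' @param alignment A [DomainAlignment] or character matrix.
#' @param groups Named character vector: group code per sequence id.
#' @param seedLabels Named character vector of fixed labels (typically the
#'   committee names of the anchor sequences; at minimum the seed group of
#'   each order should be covered).
#' @param buildOrders List from [canonicalBuildOrders()].
#' @param model A [distanceModel()] (the protocol default is JTT, alpha = 1,
#'   pairwise deletion, no bootstrap).
#' @return \code{DataFrame}: \code{record_id}, \code{label}, per-order label
#'   and consistency, \code{final_flag}, \code{candidates}.
#' @export
incrementalHarmonize <- function(alignment, groups, seedLabels,
                                 buildOrders = NULL,
                                 model = distanceModel("jtt_gamma", alpha = 1)) {
  M <- .asAlnMatrix(alignment)
  ids <- rownames(M)
  if (!all(ids %in% names(groups)))
    stop("groups must cover every aligned sequence")
  groups <- groups[ids]
  if (is.null(buildOrders)) buildOrders <- canonicalBuildOrders(unique(groups))
  for (o in buildOrders) {
    missing <- setdiff(unlist(o$steps), groups)
    if (length(missing))
      stop("build order ", o$order_id, " references groups absent from the ",
           "data: ", paste(missing, collapse = ", "))
  }
  Dfull <- pairwiseDistances(M, model)
  Dm <- distMatrix(.capped(Dfull))

  orderLabel <- orderConsistent <- list()
  firstPass <- NULL       # labels from the first (naming) order
  for (o in buildOrders) {
    fixed <- stats::setNames(rep(NA_character_, length(ids)), ids)
    ## anchors are always fixed; later orders additionally seed their start
    ## group with the names assigned by the first (naming) pass
    seeded <- intersect(ids, names(seedLabels))
    fixed[seeded] <- seedLabels[seeded]
    if (!is.null(firstPass)) {
      sg <- setdiff(ids[groups %in% o$steps[[1]]], seeded)
      carry <- sg[!is.na(firstPass[sg])]
      fixed[carry] <- firstPass[carry]
      seeded <- c(seeded, carry)
    }
    consistent <- stats::setNames(rep(TRUE, length(ids)), ids)
    firstInd <- lastInd <- stats::setNames(rep(NA_character_, length(ids)), ids)
    present <- ids[groups %in% o$steps[[1]]]
    for (s in seq_along(o$steps)[-1]) {
      present <- c(present, ids[groups %in% o$steps[[s]]])
      if (length(present) < 3) next
      tr <- neighborJoining(Dm[present, present])
      induced <- .propagateLabels(tr, fixed)
      for (q in names(induced)) {
        if (q %in% seeded) next
        v <- induced[[q]]
        if (is.na(v)) next
        if (is.na(firstInd[q])) firstInd[q] <- v
        else if (firstInd[q] != v) consistent[q] <- FALSE
        lastInd[q] <- v
      }
    }
    lab <- fixed
    lab[is.na(lab)] <- lastInd[is.na(lab)]
    orderLabel[[o$order_id]] <- lab
    orderConsistent[[o$order_id]] <- consistent
    if (is.null(firstPass)) firstPass <- lab
  }

  labmat <- do.call(cbind, orderLabel)
  conmat <- do.call(cbind, orderConsistent)
  final <- character(length(ids)); label <- rep(NA_character_, length(ids))
  candidates <- character(length(ids))
  for (i in seq_along(ids)) {
    ls <- labmat[i, ]; got <- ls[!is.na(ls)]
    if (!length(got)) { final[i] <- "unplaced"; next }
    uq <- unique(got)
    candidates[i] <- paste(sort(uq), collapse = ";")
    if (length(uq) == 1L && length(got) == ncol(labmat) && all(conmat[i, ])) {
      final[i] <- "consistent"; label[i] <- uq
    } else if (length(uq) == 1L) {
      final[i] <- "inconsistent"; label[i] <- uq
    } else {
      final[i] <- "inconsistent"
    }
  }
  res <- DataFrame(record_id = ids, label = label, final_flag = final,
                   candidates = candidates)
  for (nm in colnames(labmat)) {
    res[[paste0("label_", nm)]] <- unname(labmat[, nm])
    res[[paste0("consistent_", nm)]] <- unname(conmat[, nm])
  }
  res
}

#' Assign final orthogroup names with case conventions
#'
#' Orthogroups (groups of records sharing a harmonized label) containing at
#' least one mammalian anchor take that anchor's committee name in upper
#' case; orthogroups without mammalian members take the configured lower-case
#' name, or the lower-cased label as placeholder. An orthogroup whose members
#' carry two conflicting committee names is flagged for manual resolution and
#' never auto-merged.
#'
#' @param assignments Output of [incrementalHarmonize()].
#' @param groups Named character vector: group code per record id.
#' @param anchors Named character vector: committee name per anchor record id
#'   (e.g. \code{c(rec1 = "GJA1")}).
#' @param lowercaseNames Optional named character vector mapping a harmonized
#'   label to its configured non-mammalian name.
#' @return \code{assignments} with added columns \code{orthogroup} (final
#'   name), \code{is_mammal_anchored}, \code{name_conflict}.
#' @export
assignOrthogroupNames <- function(assignments, groups, anchors,
                                  lowercaseNames = NULL) {
  lab <- assignments$label
  orth <- rep(NA_character_, nrow(assignments))
  mam <- rep(FALSE, nrow(assignments))
  confl <- rep(FALSE, nrow(assignments))
  for (g in unique(lab[!is.na(lab)])) {
    memb <- which(!is.na(lab) & lab == g)
    rid <- assignments$record_id[memb]
    isMammal <- any(groups[rid] %in% .MAMMAL_GROUPS, na.rm = TRUE)
    anc <- unique(stats::na.omit(anchors[rid]))
    if (length(anc) > 1) {
      confl[memb] <- TRUE
      orth[memb] <- paste(sort(toupper(anc)), collapse = "|")
    } else if (length(anc) == 1 && isMammal) {
      orth[memb] <- toupper(anc)
    } else if (isMammal) {
      orth[memb] <- toupper(g)
    } else {
      nm <- if (!is.null(lowercaseNames) && g %in% names(lowercaseNames))
        lowercaseNames[[g]] else tolower(g)
      orth[memb] <- nm
    }
    mam[memb] <- isMammal
  }
  assignments$orthogroup <- orth
  assignments$is_mammal_anchored <- mam
  assignments$name_conflict <- confl
  assignments
}

#' Compress a tree to one tip per orthogroup
#'
#' Collapses each orthogroup clade to a single tip and tabulates, per
#' orthogroup, the sorted letters of the vertebrate groups present, the
#' absent groups, and whether the orthogroup is fragmented (not a single
#' clade) together with its clade count.
#'
#' @param tree An \code{ape::phylo} whose tips are record ids.
#' @param assignments DataFrame with \code{record_id} and \code{orthogroup}.
#' @param groups Named character vector: group letter per record id.
#' @param allGroups Character vector of the full group letter set (default
#'   A-N).
#' @return List with \code{table} (data.frame: orthogroup, letters,
#'   absent, n_members, n_clades, fragmented) and \code{tree} (the
#'   compressed \code{phylo}).
#' @export
compressTree <- function(tree, assignments, groups, allGroups = LETTERS[1:14]) {
  ids <- tree$tip.label
  lab <- stats::setNames(assignments$orthogroup, assignments$record_id)[ids]
  if (anyNA(lab)) stop("every leaf must have an orthogroup assignment")
  rows <- list(); keep <- character(); newname <- character()
  for (og in unique(lab)) {
    memb <- ids[lab == og]
    gl <- sort(unique(stats::na.omit(groups[memb])))
    gl <- intersect(allGroups, gl)
    k <- cladeCover(tree, memb)
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup = og, letters = paste(gl, collapse = ""),
      absent = paste(setdiff(allGroups, gl), collapse = ""),
      n_members = length(memb), n_clades = k, fragmented = k > 1L)
    keep <- c(keep, memb[1])
    newname <- c(newname, if (k > 1L) paste0(og, "*") else og)
  }
  ctree <- ape::keep.tip(tree, keep)
  ctree$tip.label <- newname[match(ctree$tip.label, keep)]
  list(table = do.call(rbind, rows), tree = ctree)
}
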