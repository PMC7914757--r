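#' Detect within-species duplicate pairs and classify them
#'
#' Within each orthogroup, same-species leaves that form a cherry in the
#' tree, or that are reciprocal nearest neighbors by patristic distance
#' (among the species' leaves in that orthogroup), become a duplicate pair.
#' Pairs are classified by their genomic locations: different assembly units
#' give \code{ohnolog} (the whole-genome-duplication signature), the same
#' unit within the linkage window gives \code{tandem}, the same unit beyond
#' the window or a missing location gives \code{unresolved}. Groups of more
#' than two same-species genes are emitted as all within-group pairs with a
#' multiplet flag, since such "pairs" may reflect either reality or assembly
#' error.
#'
#' @param tree \code{ape::phylo} whose tips are record ids.
#' @param assignments DataFrame with \code{record_id} and \code{orthogroup}
#'   (or \code{label}).
#' @param records A [GeneRecordSet] providing species, locations and
#'   sequences.
#' @param annotations Optional [locateConservedDomains()] output; when given,
#'   the conserved-domain amino-acid identity of each pair is computed.
#' @param species Optional character vector restricting to some species.
#' @param window Linkage window in bp (default 1 Mb; tandem partners
#'   typically lie tens of kilobases apart).
#' @param useRNN Also pair reciprocal nearest neighbors that are not cherries
#'   (default TRUE; assembly fragmentation can break cherries).
#' @return DataFrame: \code{species}, \code{record_a}, \code{record_b},
#'   \code{orthogroup}, \code{class}, \code{genomic_relation},
#'   \code{nt_identity_fulllength}, \code{aa_identity_domains},
#'   \code{multiplet}.
#' @export
detectDuplicatePairs <- function(tree, assignments, records,
                                 annotations = NULL, species = NULL,
                                 window = 1e6, useRNN = TRUE) {
  lab <- if ("orthogroup" %in% colnames(assignments) &&
             !all(is.na(assignments$orthogroup)))
    stats::setNames(assignments$orthogroup, assignments$record_id)
  else stats::setNames(assignments$label, assignments$record_id)
  info <- recordInfo(records)
  sp <- stats::setNames(info$species, info$record_id)
  pat <- ape::cophenetic.phylo(tree)
  cherrySets <- .cherryPairs(tree)

  rows <- list()
  for (og in unique(stats::na.omit(lab[tree$tip.label]))) {
    memb <- tree$tip.label[!is.na(lab[tree$tip.label]) &
                           lab[tree$tip.label] == og]
    for (s in unique(stats::na.omit(sp[memb]))) {
      if (!is.null(species) && !(s %in% species)) next
      mine <- memb[!is.na(sp[memb]) & sp[memb] == s]
      if (length(mine) < 2) next
      if (length(mine) == 2) {
        pairs <- matrix(mine, ncol = 2)
        multiplet <- FALSE
      } else {
        pairs <- t(utils::combn(mine, 2))
        multiplet <- TRUE
      }
      for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        if (!multiplet) {
          isCherry <- paste(sort(c(a, b)), collapse = "\r") %in% cherrySets
          isRNN <- useRNN && .reciprocalNN(a, b, mine, memb, pat)
          if (!isCherry && !isRNN) next
        }
        rows[[length(rows) + 1L]] <-
          .pairRow(a, b, s, og, records, annotations, info, window, multiplet)
      }
    }
  }
  if (!length(rows))
    return(DataFrame(species = character(0), record_a = character(0),
                     record_b = character(0), orthogroup = character(0),
                     class = character(0), genomic_relation = character(0),
                     nt_identity_fulllength = numeric(0),
                     aa_identity_domains = numeric(0), multiplet = logical(0)))
  DataFrame(do.call(rbind, rows), row.names = NULL)
}

.cherryPairs <- function(tree) {
  n <- length(tree$tip.label)
  par <- tree$edge[match(seq_len(n), tree$edge[, 2]), 1]
  out <- character(0)
  for (p in unique(par)) {
    kids <- which(par == p)
    if (length(kids) == 2)
      out <- c(out, paste(sort(tree$tip.label[kids]), collapse = "\r"))
  }
  out
}

.reciprocalNN <- function(a, b, mine, memb, pat) {
  others <- setdiff(memb, c(a, b))
  ## nearest neighbor among the orthogroup's leaves of this species
  nn <- function(x) {
    cand <- setdiff(mine, x)
    cand[which.min(pat[x, cand])]
  }
  identical(nn(a), b) && identical(nn(b), a)
}

.pairRow <- function(a, b, s, og, records, annotations, info, window,
                     multiplet) {
  ia <- match(a, info$record_id); ib <- match(b, info$record_id)
  rel <- "unknown"
  if (isTRUE(info$placed[ia]) && isTRUE(info$placed[ib])) {
    if (info$assembly_unit[ia] != info$assembly_unit[ib]) rel <- "different_units"
    else if (abs(info$start[ia] - info$start[ib]) <= window) rel <- "same_unit_linked"
    else rel <- "same_unit_distant"
  }
  cls <- switch(rel, different_units = "ohnolog",
                same_unit_linked = "tandem", "unresolved")
  ntid <- pairwiseIdentitySeq(as.character(recordCDS(records)[[ia]]),
                              as.character(recordCDS(records)[[ib]]), "nt")
  aaid <- NA_real_
  if (!is.null(annotations)) {
    ok <- annotations$valid_d1 & annotations$valid_d2
    if (all(c(a, b) %in% annotations$record_id[ok])) {
      ba <- extractDomainBlocks(records, annotations, a)
      bb <- extractDomainBlocks(records, annotations, b)
      aaid <- pairwiseIdentitySeq(paste0(ba$aa1, ba$aa2),
                                  paste0(bb$aa1, bb$aa2), "aa")
    }
  }
  data.frame(species = s, record_a = a, record_b = b, orthogroup = og,
             class = cls, genomic_relation = rel,
             nt_identity_fulllength = ntid, aa_identity_domains = aaid,
             multiplet = multiplet)
}

#' Per-species identity summaries of ohnolog pairs
#'
#' Count, mean, minimum and maximum full-length nucleotide identity of
#' ohnolog-class pairs per species (the summary that contrasts young and old
#' genome duplications: a recent duplication leaves near-identical pairs, an
#' old one pairs around 70-80% identity).
#'
#' @param pairs Output of [detectDuplicatePairs()].
#' @return DataFrame: \code{species}, \code{n_pairs}, \code{mean_identity},
#'   \code{min_identity}, \code{max_identity}.
#' @export
summarizeIdentities <- function(pairs) {
  pairs <- pairs[pairs$class == "ohnolog", , drop = FALSE]
  if (!nrow(pairs))
    return(DataFrame(species = character(0), n_pairs = integer(0),
                     mean_identity = numeric(0), min_identity = numeric(0),
                     max_identity = numeric(0)))
  rows <- lapply(split(seq_len(nrow(pairs)), pairs$species), function(ix) {
    v <- pairs$nt_identity_fulllength[ix]
    data.frame(species = pairs$species[ix[1]], n_pairs = length(ix),
               mean_identity = mean(v), min_identity = min(v),
               max_identity = max(v))
  })
  DataFrame(do.call(rbind, rows), row.names = NULL)
}
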