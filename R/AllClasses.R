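#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet AAStringSet XStringSet
#' @importFrom stats setNames
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))

#' GeneRecordSet: candidate gene records with sequences and genomic locations
#'
#' Container for a set of candidate gene-family members. Holds the coding
#' nucleotide sequences, their translations and a per-record metadata table
#' (species, vertebrate group, genomic location, provisional name, accession,
#' translation validity). Genomic coordinates are stored 0-based half-open
#' internally and converted to 1-based inclusive on output; minus-strand
#' records are reverse-complemented on ingest so \code{cds} is always the
#' coding strand.
#'
#' @slot cds \code{DNAStringSet} of coding sequences, one per record.
#' @slot protein \code{AAStringSet} of translations (empty string where the
#'   translation is invalid).
#' @slot info \code{DataFrame} with columns \code{record_id}, \code{species},
#'   \code{group}, \code{assembly_unit}, \code{start}, \code{end},
#'   \code{strand}, \code{placed}, \code{provisional_name}, \code{accession},
#'   \code{valid_translation}, \code{translation_note}.
#'
#' @export
setClass("GeneRecordSet",
  representation(cds = "DNAStringSet", protein = "AAStringSet",
                 info = "DataFrame"))

setValidity("GeneRecordSet", function(object) {
  n <- length(object@cds)
  msgs <- character()
  if (length(object@protein) != n)
    msgs <- c(msgs, "protein and cds must have equal length")
  if (nrow(object@info) != n)
    msgs <- c(msgs, "info must have one row per record")
  need <- c("record_id", "species", "group", "assembly_unit", "start", "end",
            "strand", "placed", "provisional_name", "accession",
            "valid_translation", "translation_note")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    msgs <- c(msgs, paste("info lacks columns:", paste(miss, collapse = ", ")))
  if (!length(msgs) && anyDuplicated(object@info$record_id))
    msgs <- c(msgs, "record ids must be unique")
  if (!length(msgs)) {
    ok <- !object@info$placed | (object@info$start < object@info$end)
    if (!all(ok)) msgs <- c(msgs, "placed records must have start < end")
  }
  if (length(msgs)) msgs else TRUE
})

#' DomainAlignment: concatenated conserved-domain multiple alignment
#'
#' The two conserved extracellular-loop domains aligned independently with
#' their cysteine motifs constrained to shared anchor columns, then
#' concatenated. Carries the amino-acid view, a per-row residue index map
#' (for the round-trip guarantee and the codon-position-1+2 nucleotide view),
#' the unaligned domain blocks, the anchor columns and the column separating
#' domain 1 from domain 2.
#'
#' @slot ids Character vector of row (record) ids.
#' @slot aa Character matrix of residues and \code{"-"} gaps
#'   (rows = records, columns = alignment positions).
#' @slot idx Integer matrix, same shape as \code{aa}; for non-gap cells the
#'   1-based index of the residue within that record's concatenated domain
#'   blocks, 0 for gaps.
#' @slot blockAA Named character vector: per record, the concatenated
#'   (unaligned) domain residues.
#' @slot blockNT Named character vector: per record, the in-frame nucleotides
#'   of the concatenated blocks (3x the residue count).
#' @slot anchors Integer vector of cysteine anchor column indices.
#' @slot boundary Integer; the last column belonging to domain 1.
#'
#' @export
setClass("DomainAlignment",
  representation(ids = "character", aa = "matrix", idx = "matrix",
                 blockAA = "character", blockNT = "character",
                 anchors = "integer", boundary = "integer"))

setValidity("DomainAlignment", function(object) {
  msgs <- character()
  if (nrow(object@aa) != length(object@ids))
    msgs <- c(msgs, "aa must have one row per id")
  if (!identical(dim(object@aa), dim(object@idx)))
    msgs <- c(msgs, "aa and idx must have identical dimensions")
  if (length(object@anchors) &&
      (min(object@anchors) < 1 || max(object@anchors) > ncol(object@aa)))
    msgs <- c(msgs, "anchor columns out of range")
  if (length(object@anchors)) {
    anc <- object@aa[, object@anchors, drop = FALSE]
    if (!all(anc %in% c("C", "-")))
      msgs <- c(msgs, "anchor columns must contain cysteine or gap")
  }
  for (i in seq_along(object@ids)) {
    got <- paste(object@aa[i, object@aa[i, ] != "-"], collapse = "")
    if (!identical(got, unname(object@blockAA[object@ids[i]]))) {
      msgs <- c(msgs, "ungapped rows must reproduce the extracted blocks")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PairwiseDistances: evolutionary distance matrix with bookkeeping
#'
#' Symmetric pairwise distances between aligned sequences, the per-pair count
#' of comparable (both ungapped) sites used under pairwise deletion, and
#' per-pair status flags (\code{"ok"}, \code{"saturated"},
#' \code{"incomparable"}).
#'
#' @slot ids Character vector of sequence ids.
#' @slot d Numeric symmetric matrix of distances (NA where flagged).
#' @slot sites Integer matrix of comparable-site counts.
#' @slot flags Character matrix of per-pair status.
#' @slot model List echoing the distance model used.
#'
#' @export
setClass("PairwiseDistances",
  representation(ids = "character", d = "matrix", sites = "matrix",
                 flags = "matrix", model = "list"))

setValidity("PairwiseDistances", function(object) {
  msgs <- character()
  n <- length(object@ids)
  if (!all(dim(object@d) == n)) msgs <- c(msgs, "d must be n x n")
  ok <- object@flags == "ok"
  if (n && any(object@d[ok] < 0, na.rm = TRUE))
    msgs <- c(msgs, "distances must be non-negative")
  if (n && !isTRUE(all.equal(object@d[ok & t(ok)],
                             t(object@d)[ok & t(ok)], tolerance = 1e-12)))
    msgs <- c(msgs, "d must be symmetric")
  if (n && any(abs(diag(object@d)) > 1e-12))
    msgs <- c(msgs, "diagonal must be zero")
  if (length(msgs)) msgs else TRUE
})

#' GeneFamilyHistory: simulated gene-family history with truth labels
#'
#' The event log and gene lineage forest produced by [simulateHistory()],
#' together with per-extant-gene truth (species, orthogroup, locus, ohnolog
#' and tandem partners).
#'
#' @slot speciesTree \code{ape::phylo} species tree used.
#' @slot nodes data.frame of gene-lineage nodes (id, time before present,
#'   species-tree context, event type, orthogroup, locus).
#' @slot edges data.frame of gene-lineage edges (parent, child, length).
#' @slot events data.frame event log.
#' @slot truth \code{DataFrame} with one row per extant gene.
#' @slot config List; the simulation configuration used.
#'
#' @export
setClass("GeneFamilyHistory",
  representation(speciesTree = "ANY", nodes = "data.frame",
                 edges = "data.frame", events = "data.frame",
                 truth = "DataFrame", config = "list"))

setValidity("GeneFamilyHistory", function(object) {
  msgs <- character()
  tr <- object@truth
  if (nrow(tr)) {
    if (anyNA(tr$orthogroup))
      msgs <- c(msgs, "every extant gene must carry a root orthogroup")
    oh <- !is.na(tr$ohnolog_partner)
    if (any(oh)) {
      p <- match(tr$ohnolog_partner[oh], tr$record_id)
      if (anyNA(p) ||
          any(tr$assembly_unit[oh] == tr$assembly_unit[p], na.rm = TRUE))
        msgs <- c(msgs, "ohnolog partners must lie on different assembly units")
    }
    td <- !is.na(tr$tandem_partner)
    if (any(td)) {
      p <- match(tr$tandem_partner[td], tr$record_id)
      if (anyNA(p) || any(tr$assembly_unit[td] != tr$assembly_unit[p]))
        msgs <- c(msgs, "tandem partners must share an assembly unit")
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---- basic accessors and show methods --------------------------------------

#' @describeIn GeneRecordSet Number of records.
#' @param x,object A \code{GeneRecordSet}.
#' @export
setMethod("length", "GeneRecordSet", function(x) length(x@cds))

#' Accessors for GeneRecordSet
#'
#' @param x A \code{GeneRecordSet}.
#' @return \code{recordInfo} returns the metadata \code{DataFrame};
#'   \code{recordCDS} the \code{DNAStringSet}; \code{recordProtein} the
#'   \code{AAStringSet}; \code{recordIds} the character ids.
#' @export
recordInfo <- function(x) x@info

#' @rdname recordInfo
#' @export
recordCDS <- function(x) x@cds

#' @rdname recordInfo
#' @export
recordProtein <- function(x) x@protein

#' @rdname recordInfo
#' @export
recordIds <- function(x) x@info$record_id

#' @describeIn GeneRecordSet Subset records by index, logical or id.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GeneRecordSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$record_id)
  initialize(x, cds = x@cds[i], protein = x@protein[i],
             info = x@info[i, , drop = FALSE])
})

setMethod("show", "GeneRecordSet", function(object) {
  cat("GeneRecordSet with", length(object), "records;",
      length(unique(object@info$species)), "species;",
      sum(!object@info$valid_translation), "invalid translation(s)\n")
})

#' Accessors for DomainAlignment
#'
#' @param x A \code{DomainAlignment}.
#' @return \code{alignedAA} returns the amino-acid alignment as a character
#'   matrix; \code{anchorColumns} the cysteine anchor column indices;
#'   \code{domainBoundary} the last column of domain 1;
#'   \code{alignmentIds} the row ids.
#' @export
alignedAA <- function(x) x@aa

#' @rdname alignedAA
#' @export
anchorColumns <- function(x) x@anchors

#' @rdname alignedAA
#' @export
domainBoundary <- function(x) x@boundary

#' @rdname alignedAA
#' @export
alignmentIds <- function(x) x@ids

setMethod("show", "DomainAlignment", function(object) {
  cat("DomainAlignment:", nrow(object@aa), "rows x", ncol(object@aa),
      "aa columns;", length(object@anchors), "cysteine anchors; domain 1 ends",
      "at column", object@boundary, "\n")
})

#' Accessors for PairwiseDistances
#'
#' @param x A \code{PairwiseDistances}.
#' @return \code{distMatrix} returns the numeric distance matrix (dimnames =
#'   ids); \code{comparableSites} the per-pair comparable-site counts;
#'   \code{pairFlags} the per-pair status flags.
#' @export
distMatrix <- function(x) {
  d <- x@d
  dimnames(d) <- list(x@ids, x@ids)
  d
}

#' @rdname distMatrix
#' @export
comparableSites <- function(x) {
  s <- x@sites
  dimnames(s) <- list(x@ids, x@ids)
  s
}

#' @rdname distMatrix
#' @export
pairFlags <- function(x) {
  f <- x@flags
  dimnames(f) <- list(x@ids, x@ids)
  f
}

setMethod("show", "PairwiseDistances", function(object) {
  cat("PairwiseDistances (", object@model$kind, "): ",
      length(object@ids), " sequences; ",
      sum(object@flags[upper.tri(object@flags)] != "ok"),
      " flagged pair(s)\n", sep = "")
})

#' Accessors for GeneFamilyHistory
#'
#' @param x A \code{GeneFamilyHistory}.
#' @return \code{historyTruth} returns the per-extant-gene truth table;
#'   \code{historyEvents} the event log; \code{geneLineageEdges} the gene
#'   lineage forest edge table.
#' @export
historyTruth <- function(x) x@truth

#' @rdname historyTruth
#' @export
historyEvents <- function(x) x@events

#' @rdname historyTruth
#' @export
geneLineageEdges <- function(x) x@edges

setMethod("show", "GeneFamilyHistory", function(object) {
  cat("GeneFamilyHistory:", nrow(object@truth), "extant genes in",
      length(unique(object@truth$orthogroup)), "orthogroups across",
      length(unique(object@truth$species)), "species;",
      sum(object@events$type == "wgd_retention"), "WGD retention(s),",
      sum(object@events$type == "duplication"), "duplication(s),",
      sum(object@events$type == "loss"), "loss(es)\n")
})
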