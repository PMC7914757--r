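#' Extract the conserved-domain blocks of a record
#'
#' Returns the amino-acid substrings of the two validated domain spans and
#' the corresponding in-frame nucleotide substrings (3x the residue count per
#' block). Refuses records whose domains are invalid; such records should
#' have been excluded upstream.
#'
#' @param records A [GeneRecordSet].
#' @param annotations Output of [locateConservedDomains()].
#' @param id A single record id.
#' @return List with \code{aa1}, \code{aa2}, \code{nt1}, \code{nt2} and the
#'   0-based motif cysteine offsets within each block (\code{cys1},
#'   \code{cys2}).
#' @export
extractDomainBlocks <- function(records, annotations, id) {
  i <- match(id, annotations$record_id)
  if (is.na(i)) stop("unknown record id: ", id)
  if (!annotations$valid_d1[i] || !annotations$valid_d2[i])
    stop("record ", id, " does not have two valid domains")
  p <- as.character(recordProtein(records)[[match(id, recordIds(records))]])
  nt <- as.character(recordCDS(records)[[match(id, recordIds(records))]])
  span <- function(s, e) substr(p, s + 1L, e)
  ntspan <- function(s, e) substr(nt, 3L * s + 1L, 3L * e)
  cys <- as.integer(strsplit(annotations$cys_positions[i], ",")[[1]])
  list(aa1 = span(annotations$d1_start[i], annotations$d1_end[i]),
       aa2 = span(annotations$d2_start[i], annotations$d2_end[i]),
       nt1 = ntspan(annotations$d1_start[i], annotations$d1_end[i]),
       nt2 = ntspan(annotations$d2_start[i], annotations$d2_end[i]),
       cys1 = cys[1:3] - annotations$d1_start[i],
       cys2 = cys[4:6] - annotations$d2_start[i])
}

## Center-star alignment of short segments: pick the longest segment as the
## center (ties -> first), align every other segment to it globally, and
## merge the centers' insertion runs into a common column layout. Returns a
## character matrix (rows in input order) whose columns are the aligned
## positions; empty segments become all-gap rows.
.starAlign <- function(segs) {
  n <- length(segs)
  lens <- nchar(segs)
  if (all(lens == 0)) return(matrix(character(), nrow = n, ncol = 0))
  ctr <- which.max(lens)
  C <- segs[[ctr]]; Lc <- nchar(C)
  ## per-sequence: map to center coordinates. rows: list of list(chars,
  ## centerPos) where centerPos 0 means insertion before center position 1.
  placements <- vector("list", n)
  ins <- integer(Lc + 1L)            # max insertion length after center pos k
  for (i in seq_len(n)) {
    if (lens[i] == 0) { placements[[i]] <- NULL; next }
    if (i == ctr || lens[i] == Lc) {
      ## equal length: positional (gap-free) placement; segments only differ
      ## in length through end clipping or indels
      placements[[i]] <- list(chars = strsplit(segs[[i]], "")[[1]],
                              at = seq_len(Lc), insAfter = integer(Lc + 1L))
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(segs[[i]]), Biostrings::AAString(C),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    cpos <- 0L
    at <- integer(0); chars <- character(0)
    insAfter <- integer(Lc + 1L)
    for (k in seq_along(pa)) {
      if (su[k] != "-") {
        cpos <- cpos + 1L
        if (pa[k] != "-") { at <- c(at, cpos); chars <- c(chars, pa[k]) }
      } else if (pa[k] != "-") {
        insAfter[cpos + 1L] <- insAfter[cpos + 1L] + 1L
        at <- c(at, -(cpos + 1L)); chars <- c(chars, pa[k])
      }
    }
    placements[[i]] <- list(chars = chars, at = at, insAfter = insAfter)
    ins <- pmax(ins, insAfter)
  }
  ## column layout: for center pos 0..Lc, ins[k+1] insertion columns after it,
  ## then (for k >= 1) the center column itself precedes its trailing
  ## insertions. Layout: [ins before 1][c1][ins after 1][c2]...
  width <- Lc + sum(ins)
  colOfCenter <- integer(Lc)         # column index of center position k
  insStart <- integer(Lc + 1L)       # first column of insertion block k
  col <- 0L
  insStart[1L] <- col + 1L; col <- col + ins[1L]
  for (k in seq_len(Lc)) {
    col <- col + 1L; colOfCenter[k] <- col
    insStart[k + 1L] <- col + 1L; col <- col + ins[k + 1L]
  }
  M <- matrix("-", nrow = n, ncol = width)
  for (i in seq_len(n)) {
    pl <- placements[[i]]
    if (is.null(pl)) next
    insUsed <- integer(Lc + 1L)
    for (k in seq_along(pl$chars)) {
      a <- pl$at[k]
      if (a > 0) M[i, colOfCenter[a]] <- pl$chars[k]
      else {
        slot <- -a
        M[i, insStart[slot] + insUsed[slot]] <- pl$chars[k]
        insUsed[slot] <- insUsed[slot] + 1L
      }
    }
  }
  M
}

#' Align the conserved domains across records
#'
#' Builds the concatenated conserved-domain multiple alignment with the motif
#' cysteines constrained to shared anchor columns. Each domain is decomposed
#' at its three motif cysteines into four segments (left flank, two
#' inter-cysteine segments, right flank); homologous segments are aligned
#' across records by a deterministic center-star procedure (longest segment
#' as center, global pairwise alignment with affine gaps, merged gap
#' columns), the cysteines become single gap-free anchor columns, and the two
#' domains are aligned independently and concatenated. Records lacking two
#' valid domains are dropped with a warning.
#'
#' @param records A [GeneRecordSet].
#' @param annotations Output of [locateConservedDomains()].
#' @param ids Optional subset of record ids (default: all with two valid
#'   domains).
#' @return A [DomainAlignment].
#' @export
alignDomains <- function(records, annotations, ids = NULL) {
  ok <- annotations$valid_d1 & annotations$valid_d2
  usable <- intersect(annotations$record_id[ok], recordIds(records))
  if (is.null(ids)) ids <- usable
  drop <- setdiff(ids, usable)
  if (length(drop)) {
    warning("dropping records without two valid domains: ",
            paste(drop, collapse = ", "))
    ids <- intersect(ids, usable)
  }
  if (length(ids) < 2) stop("need at least two records to align")

  blocks <- lapply(ids, function(id) extractDomainBlocks(records, annotations, id))
  names(blocks) <- ids

  ## segment decomposition per domain: flank1 | C | seg2 | C | seg3 | C | flank4
  segOf <- function(b, dom) {
    aa <- if (dom == 1) b$aa1 else b$aa2
    cys <- if (dom == 1) b$cys1 else b$cys2
    L <- nchar(aa)
    list(substr(aa, 1L, cys[1]),
         substr(aa, cys[1] + 2L, cys[2]),
         substr(aa, cys[2] + 2L, cys[3]),
         substr(aa, cys[3] + 2L, L))
  }
  alignDom <- function(dom) {
    segsets <- lapply(blocks, segOf, dom = dom)
    parts <- list(); anchors <- integer(); col <- 0L
    for (s in 1:4) {
      M <- .starAlign(vapply(segsets, function(x) x[[s]], ""))
      parts[[length(parts) + 1L]] <- M
      col <- col + ncol(M)
      if (s < 4) {
        parts[[length(parts) + 1L]] <- matrix("C", nrow = length(ids), ncol = 1)
        col <- col + 1L
        anchors <- c(anchors, col)
      }
    }
    list(M = do.call(cbind, parts), anchors = anchors)
  }
  d1 <- alignDom(1); d2 <- alignDom(2)
  aa <- cbind(d1$M, d2$M)
  rownames(aa) <- ids
  anchors <- c(d1$anchors, ncol(d1$M) + d2$anchors)

  ## residue index map: non-gap cells numbered left-to-right per row
  idx <- matrix(0L, nrow = nrow(aa), ncol = ncol(aa))
  for (i in seq_len(nrow(aa))) {
    ng <- which(aa[i, ] != "-")
    idx[i, ng] <- seq_along(ng)
  }
  blockAA <- vapply(blocks, function(b) paste0(b$aa1, b$aa2), "")
  blockNT <- vapply(blocks, function(b) paste0(b$nt1, b$nt2), "")
  new("DomainAlignment", ids = ids, aa = aa, idx = idx,
      blockAA = blockAA, blockNT = blockNT,
      anchors = as.integer(anchors), boundary = ncol(d1$M))
}

#' Codon-position-1+2 nucleotide view of a domain alignment
#'
#' For every amino-acid column, emits the first and second codon positions of
#' the underlying codon; gaps propagate as double gaps. The result has twice
#' as many columns as the amino-acid alignment.
#'
#' @param alignment A [DomainAlignment].
#' @return Character matrix (rows = records, 2L columns).
#' @export
nt12View <- function(alignment) {
  aa <- alignment@aa; idx <- alignment@idx
  n <- nrow(aa); L <- ncol(aa)
  out <- matrix("-", nrow = n, ncol = 2L * L,
                dimnames = list(alignment@ids, NULL))
  for (i in seq_len(n)) {
    nt <- strsplit(alignment@blockNT[alignment@ids[i]], "")[[1]]
    ng <- which(idx[i, ] > 0)
    k <- idx[i, ng]
    out[i, 2L * ng - 1L] <- nt[3L * (k - 1L) + 1L]
    out[i, 2L * ng] <- nt[3L * (k - 1L) + 2L]
  }
  out
}

#' Write a domain alignment as aligned FASTA with an anchor sidecar
#'
#' @param alignment A [DomainAlignment].
#' @param aa_path Path for the aligned amino-acid FASTA.
#' @param nt12_path Optional path for the codon-position-1+2 view.
#' @param anchors_path Optional path for the anchor-column TSV.
#' @return Invisibly, the paths written.
#' @export
writeAlignment <- function(alignment, aa_path, nt12_path = NULL,
                           anchors_path = NULL) {
  aa <- apply(alignment@aa, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(aa, alignment@ids)), aa_path)
  written <- aa_path
  if (!is.null(nt12_path)) {
    m <- nt12View(alignment)
    nt <- apply(m, 1, paste, collapse = "")
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(stats::setNames(nt, alignment@ids)), nt12_path)
    written <- c(written, nt12_path)
  }
  if (!is.null(anchors_path)) {
    utils::write.table(
      data.frame(anchor_column = alignment@anchors,
                 domain = ifelse(alignment@anchors <= alignment@boundary, 1L, 2L)),
      anchors_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, anchors_path)
  }
  invisible(written)
}
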