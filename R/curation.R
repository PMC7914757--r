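#' Conserved-domain signature configuration
#'
#' Parameters governing how the two conserved extracellular-loop domains are
#' located and validated. The motifs are cysteine spacing patterns written as
#' \code{"C-x(n)-C-x(m)-C"}; the canonical loop spacings are
#' \code{C-x(6)-C-x(3)-C} for loop 1 (E1) and \code{C-x(4)-C-x(5)-C} for
#' loop 2 (E2). Each matched motif window is widened by
#' \code{extension_nt / 3} residues on both sides (clipped at the sequence
#' ends) to give the domain span; the default extension is 15 nucleotides,
#' i.e. 5 codons. Transmembrane validation requires the mean Kyte-Doolittle
#' hydropathy over the \code{tm_window} residues adjacent to each domain side
#' to exceed \code{tm_min_hydropathy}.
#'
#' @param e1_motif,e2_motif Cysteine spacing patterns (see above). Both are
#'   configurable because some family members (the epsilon-like genes) carry
#'   deviating loops.
#' @param extension_nt Non-negative multiple of 3; nucleotides added to each
#'   domain end.
#' @param tm_min_hydropathy Mean Kyte-Doolittle floor for a flanking window
#'   to count as transmembrane-like. Random protein averages about -0.2 on
#'   this scale; membrane-spanning helices typically exceed 1.5.
#' @param tm_window Window length in residues (default 19, the classic
#'   transmembrane helix span).
#' @return A list of class \code{SignatureConfig}.
#' @export
#' @examples
#' cfg <- signatureConfig()
#' cfg$e1_motif
signatureConfig <- function(e1_motif = "C-x(6)-C-x(3)-C",
                            e2_motif = "C-x(4)-C-x(5)-C",
                            extension_nt = 15L,
                            tm_min_hydropathy = 1.0,
                            tm_window = 19L) {
  extension_nt <- as.integer(extension_nt)
  if (extension_nt < 0L || extension_nt %% 3L != 0L)
    stop("extension_nt must be a non-negative multiple of 3")
  structure(list(e1_motif = e1_motif, e2_motif = e2_motif,
                 extension_nt = extension_nt,
                 tm_min_hydropathy = tm_min_hydropathy,
                 tm_window = as.integer(tm_window)),
            class = "SignatureConfig")
}

## Parse "C-x(6)-C-x(3)-C" into list(regex=, cysOffsets= 0-based, width=).
.parseMotif <- function(motif) {
  toks <- strsplit(motif, "-", fixed = TRUE)[[1]]
  rx <- character(); off <- integer(); w <- 0L
  for (tk in toks) {
    if (tk == "C") {
      rx <- c(rx, "C"); off <- c(off, w); w <- w + 1L
    } else if (grepl("^x\\([0-9]+\\)$", tk)) {
      k <- as.integer(sub("^x\\(([0-9]+)\\)$", "\\1", tk))
      rx <- c(rx, sprintf(".{%d}", k)); w <- w + k   # x = any residue
    } else stop("unparseable motif token: ", tk)
  }
  list(regex = paste(rx, collapse = ""), cysOffsets = off, width = w)
}

#' Read candidate gene records
#'
#' Reads a FASTA file of coding nucleotide sequences and a tab-separated
#' genomic-location table (columns \code{record_id species group
#' assembly_unit start end strand}, 1-based inclusive coordinates) into a
#' [GeneRecordSet]. Records without a location row are kept with an
#' "unplaced" location and a warning. Minus-strand sequences are
#' reverse-complemented so the stored CDS is the coding strand. Sequences
#' whose length is not a multiple of three, or whose translation contains an
#' internal stop, are flagged (\code{valid_translation = FALSE}) rather than
#' rejected.
#'
#' @param fasta_source Path to a nucleotide FASTA file, or a named
#'   \code{DNAStringSet}.
#' @param locations_table Path to the locations TSV, or a data.frame with the
#'   declared columns. May be \code{NULL} (all records unplaced).
#' @return A [GeneRecordSet].
#' @export
readGeneRecords <- function(fasta_source, locations_table = NULL) {
  cds <- if (is(fasta_source, "DNAStringSet")) fasta_source
         else Biostrings::readDNAStringSet(fasta_source)
  if (is.null(names(cds)) || any(!nzchar(names(cds))))
    stop("FASTA records must be named")
  ids <- sub("\\s.*$", "", names(cds))
  if (anyDuplicated(ids)) stop("duplicate FASTA record ids")
  names(cds) <- ids

  loc <- NULL
  if (!is.null(locations_table)) {
    loc <- if (is.character(locations_table))
      utils::read.delim(locations_table, stringsAsFactors = FALSE,
                        colClasses = "character")
    else as.data.frame(locations_table, stringsAsFactors = FALSE)
    need <- c("record_id", "species", "group", "assembly_unit",
              "start", "end", "strand")
    miss <- setdiff(need, colnames(loc))
    if (length(miss))
      stop("locations table lacks columns: ", paste(miss, collapse = ", "))
  }

  n <- length(cds)
  info <- DataFrame(record_id = ids,
                    species = NA_character_, group = NA_character_,
                    assembly_unit = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, placed = FALSE,
                    provisional_name = "", accession = "",
                    valid_translation = FALSE, translation_note = "")
  if (!is.null(loc)) {
    m <- match(ids, loc$record_id)
    hit <- !is.na(m)
    if (any(!hit))
      warning("records without a location row (kept unplaced): ",
              paste(ids[!hit], collapse = ", "))
    info$species[hit] <- loc$species[m[hit]]
    info$group[hit] <- loc$group[m[hit]]
    info$assembly_unit[hit] <- loc$assembly_unit[m[hit]]
    ## external 1-based inclusive -> internal 0-based half-open
    info$start[hit] <- as.integer(loc$start[m[hit]]) - 1L
    info$end[hit] <- as.integer(loc$end[m[hit]])
    info$strand[hit] <- loc$strand[m[hit]]
    info$placed[hit] <- TRUE
    for (opt in c("provisional_name", "accession"))
      if (opt %in% colnames(loc)) info[[opt]][hit] <- loc[[opt]][m[hit]]
    neg <- which(hit & info$strand == "-")
    if (length(neg))
      cds[neg] <- Biostrings::reverseComplement(cds[neg])
  }

  prot <- character(n); note <- character(n); valid <- logical(n)
  sq <- as.character(cds)
  for (i in seq_len(n)) {
    tr <- .translateCDS(sq[i])
    prot[i] <- tr$protein; valid[i] <- tr$valid; note[i] <- tr$note
  }
  info$valid_translation <- valid
  info$translation_note <- note
  new("GeneRecordSet", cds = cds,
      protein = Biostrings::AAStringSet(stats::setNames(prot, ids)),
      info = info)
}

#' Locate and validate the conserved domains
#'
#' Finds the first occurrence of the E1 cysteine motif and the subsequent
#' occurrence of the E2 motif in each translated record, widens each matched
#' window by \code{extension_nt / 3} residues on both sides (clipped at the
#' sequence ends), and validates the transmembrane context by mean
#' Kyte-Doolittle hydropathy of the windows adjacent to each domain side.
#' Failure to find a motif yields \code{valid_d1}/\code{valid_d2} FALSE (the
#' record becomes excludable) rather than an error.
#'
#' @param records A [GeneRecordSet].
#' @param cfg A [signatureConfig()].
#' @return A \code{DataFrame}, one row per record: \code{record_id},
#'   0-based half-open residue spans \code{d1_start,d1_end,d2_start,d2_end},
#'   \code{cys_positions} (comma-separated 0-based residue indices),
#'   \code{valid_d1}, \code{valid_d2}, \code{tm_valid}.
#' @export
locateConservedDomains <- function(records, cfg = signatureConfig()) {
  m1 <- .parseMotif(cfg$e1_motif); m2 <- .parseMotif(cfg$e2_motif)
  ext <- cfg$extension_nt %/% 3L
  prot <- as.character(recordProtein(records))
  n <- length(records)
  out <- DataFrame(record_id = recordIds(records),
                   d1_start = NA_integer_, d1_end = NA_integer_,
                   d2_start = NA_integer_, d2_end = NA_integer_,
                   cys_positions = "", valid_d1 = FALSE, valid_d2 = FALSE,
                   tm_valid = FALSE)
  for (i in seq_len(n)) {
    p <- prot[i]
    if (!nzchar(p)) next
    L <- nchar(p)
    h1 <- regexpr(m1$regex, p, perl = TRUE)
    cys <- integer()
    if (h1 > 0) {
      s1 <- as.integer(h1) - 1L                      # 0-based motif start
      out$valid_d1[i] <- TRUE
      out$d1_start[i] <- max(0L, s1 - ext)
      out$d1_end[i] <- min(L, s1 + m1$width + ext)
      cys <- c(cys, s1 + m1$cysOffsets)
      rest <- substr(p, s1 + m1$width + 1L, L)
      h2 <- regexpr(m2$regex, rest, perl = TRUE)
      if (h2 > 0) {
        s2 <- s1 + m1$width + as.integer(h2) - 1L
        out$valid_d2[i] <- TRUE
        out$d2_start[i] <- max(0L, s2 - ext)
        out$d2_end[i] <- min(L, s2 + m2$width + ext)
        cys <- c(cys, s2 + m2$cysOffsets)
        ## keep the spans disjoint if the extensions collide
        if (out$d1_end[i] > out$d2_start[i]) {
          mid <- (s1 + m1$width + s2) %/% 2L
          out$d1_end[i] <- mid
          out$d2_start[i] <- mid
        }
      }
    } else {
      ## E1 absent: still try E2 anywhere, so single-domain records are
      ## recognizable as such
      h2 <- regexpr(m2$regex, p, perl = TRUE)
      if (h2 > 0) {
        s2 <- as.integer(h2) - 1L
        out$valid_d2[i] <- TRUE
        out$d2_start[i] <- max(0L, s2 - ext)
        out$d2_end[i] <- min(L, s2 + m2$width + ext)
        cys <- c(cys, s2 + m2$cysOffsets)
      }
    }
    out$cys_positions[i] <- paste(cys, collapse = ",")
    out$tm_valid[i] <- .tmCheck(p, out[i, ], cfg)
  }
  out
}

## Mean Kyte-Doolittle over the tm_window residues adjacent to each side of
## each located domain core; all evaluable windows must reach the floor.
## The core is the motif widened by 5 residues (the canonical 15-nucleotide
## loop extension): the transmembrane helices flank the extracellular loop
## itself, so the check is anchored there regardless of how far the
## alignment extension reaches. Windows shorter than 5 residues (sequence
## edge) are skipped.
.tmCheck <- function(p, ann, cfg) {
  L <- nchar(p)
  aa <- strsplit(p, "")[[1]]
  kd <- unname(.KD[aa]); kd[is.na(kd)] <- 0
  cys <- as.integer(strsplit(ann$cys_positions, ",")[[1]])
  spans <- list()
  if (isTRUE(ann$valid_d1)) {
    cc <- cys[1:3]
    spans <- c(spans, list(c(cc[1] - 5L - cfg$tm_window, cc[1] - 5L),
                           c(cc[3] + 6L, cc[3] + 6L + cfg$tm_window)))
  }
  if (isTRUE(ann$valid_d2)) {
    cc <- if (isTRUE(ann$valid_d1)) cys[4:6] else cys[1:3]
    spans <- c(spans, list(c(cc[1] - 5L - cfg$tm_window, cc[1] - 5L),
                           c(cc[3] + 6L, cc[3] + 6L + cfg$tm_window)))
  }
  if (!length(spans)) return(FALSE)
  for (sp in spans) {
    a <- max(0L, sp[1]); b <- min(L, sp[2])
    if (b - a < 5L) next
    if (mean(kd[(a + 1L):b]) < cfg$tm_min_hydropathy) return(FALSE)
  }
  TRUE
}

#' Apply the inclusion/exclusion rules
#'
#' Partitions records into kept and excluded with machine-readable reasons:
#' \code{invalid_translation} (CDS not translatable), \code{missing_domains}
#' (neither conserved domain found), \code{single_domain} (only one found),
#' \code{transmembrane} (flanking windows fail the hydropathy check), and
#' \code{near_duplicate} (same-species full-length nucleotide identity above
#' \code{identity_threshold}; the first-listed record is kept). The kept and
#' excluded sets always partition the input.
#'
#' @param records A [GeneRecordSet].
#' @param annotations Output of [locateConservedDomains()] for `records`.
#' @param identity_threshold Percent identity above which a same-species
#'   record is a near-duplicate (default 99).
#' @return List with \code{kept} (a [GeneRecordSet]) and \code{excluded}
#'   (DataFrame \code{record_id}, \code{reason}, \code{detail}).
#' @export
applyExclusionRules <- function(records, annotations,
                                identity_threshold = 99) {
  ids <- recordIds(records)
  stopifnot(identical(ids, annotations$record_id))
  reason <- rep(NA_character_, length(ids))
  detail <- rep("", length(ids))
  info <- recordInfo(records)

  bad <- !info$valid_translation
  reason[bad] <- "invalid_translation"
  detail[bad] <- info$translation_note[bad]

  nd <- is.na(reason) & !annotations$valid_d1 & !annotations$valid_d2
  reason[nd] <- "missing_domains"
  sd <- is.na(reason) & xor(annotations$valid_d1, annotations$valid_d2)
  reason[sd] <- "single_domain"
  detail[sd] <- ifelse(annotations$valid_d1[sd], "only_domain1", "only_domain2")

  tm <- is.na(reason) & !annotations$tm_valid
  reason[tm] <- "transmembrane"

  ## near-duplicates among the survivors, per species, keep first-listed
  sq <- as.character(recordCDS(records))
  for (sp in unique(info$species[is.na(reason)])) {
    idx <- which(is.na(reason) & !is.na(info$species) & info$species == sp)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- idx[a]; j <- idx[b]
        if (!is.na(reason[i]) || !is.na(reason[j])) next
        if (abs(nchar(sq[i]) - nchar(sq[j])) >
            (1 - identity_threshold / 100) * 2 * nchar(sq[j]) + 30) next
        pid <- pairwiseIdentitySeq(sq[i], sq[j], "nt")
        if (pid > identity_threshold) {
          reason[i] <- "near_duplicate"
          detail[i] <- sprintf("kept=%s;identity=%.2f", ids[j], pid)
          break
        }
      }
    }
  }

  excl <- which(!is.na(reason))
  list(kept = records[setdiff(seq_along(ids), excl)],
       excluded = DataFrame(record_id = ids[excl],
                            reason = reason[excl], detail = detail[excl]))
}

#' Format a display name for a record
#'
#' Builds the tree/report display name from the species abbreviation, the
#' harmonized orthogroup name and whatever identifiers are available, using
#' the four schemes: with an accession,
#' \code{Sp-name-accession[-dbEntryName]}; without an accession but with a
#' database entry (transcript) name,
#' \code{Sp-name-scaffold:startStrand-dbEntryName}; otherwise
#' \code{Sp-name-scaffold:startStrand}. Names of orthogroups containing
#' mammalian sequences are upper case, all others lower case. Positions are
#' printed 1-based.
#'
#' @param records A [GeneRecordSet].
#' @param labels Character vector (recycled): harmonized orthogroup name per
#'   record.
#' @param mammalAnchored Logical vector (recycled): does the record's
#'   orthogroup contain mammalian members?
#' @return Character vector of display names.
#' @export
#' @examples
#' # "Ln-gjd5-XM_n-gjd2like" style names; see the vignette.
formatDisplayName <- function(records, labels, mammalAnchored = FALSE) {
  info <- recordInfo(records)
  n <- length(records)
  labels <- rep_len(labels, n)
  mammalAnchored <- rep_len(mammalAnchored, n)
  out <- character(n)
  for (i in seq_len(n)) {
    nm <- if (mammalAnchored[i]) toupper(labels[i]) else tolower(labels[i])
    sp <- info$species[i]
    acc <- info$accession[i]; prov <- info$provisional_name[i]
    locstr <- if (isTRUE(info$placed[i]))
      sprintf("%s:%d%s", info$assembly_unit[i], info$start[i] + 1L,
              info$strand[i])
    else "unplaced"
    if (nzchar(acc)) {
      parts <- c(sp, nm, acc)
      if (nzchar(prov) && tolower(prov) != tolower(nm)) parts <- c(parts, prov)
    } else if (nzchar(prov)) {
      parts <- c(sp, nm, locstr, prov)
    } else {
      parts <- c(sp, nm, locstr)
    }
    out[i] <- paste(parts, collapse = "-")
  }
  out
}

#' Write a curated dataset and exclusion report
#'
#' @param kept A [GeneRecordSet] of kept records.
#' @param excluded DataFrame from [applyExclusionRules()].
#' @param fasta_path,report_path Output paths.
#' @return Invisibly, the two paths.
#' @export
writeCurated <- function(kept, excluded, fasta_path, report_path) {
  Biostrings::writeXStringSet(recordCDS(kept), fasta_path)
  utils::write.table(as.data.frame(excluded), report_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, report_path))
}
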