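#' Pipeline run configuration
#'
#' Flat, validated configuration for [runPipeline()]: input paths (or
#' in-memory objects), distance model settings, bootstrap replicate count,
#' support rendering threshold, the gamma sweep values, the excluded
#' orthogroup (the deviating epsilon-like group is excluded from the main
#' tree by default to avoid long-branch artifacts), naming tables and seed.
#'
#' @param fasta,locations Input paths (or a [GeneRecordSet] via
#'   \code{records}).
#' @param records Optional pre-built [GeneRecordSet] (overrides paths).
#' @param out_dir Output directory; NULL for no files.
#' @param matrix Distance kind (see [distanceModel()]).
#' @param alpha Gamma shape for the main tree (the figure convention is 1.1;
#'   the harmonization protocol uses 1).
#' @param B Bootstrap replicates (0 disables the bootstrap stage; the figure
#'   convention is 500).
#' @param support_render_threshold Minimum support rendered (default 30).
#' @param sweep_alphas Gamma values for the sensitivity sweep.
#' @param exclude_orthogroups Seed labels excluded from the main tree.
#' @param anchors Named character vector: committee name per anchor record.
#' @param seed_labels Named character vector of initial labels for the
#'   harmonization seeds (defaults to \code{anchors}).
#' @param identity_threshold Near-duplicate exclusion threshold (percent).
#' @param signature A [signatureConfig()].
#' @param seed Integer seed.
#' @return List of class \code{RunConfig}.
#' @export
pipelineConfig <- function(fasta = NULL, locations = NULL, records = NULL,
                           out_dir = NULL, matrix = "jtt_gamma", alpha = 1.1,
                           B = 0L, support_render_threshold = 30,
                           sweep_alphas = NULL,
                           exclude_orthogroups = character(0),
                           anchors = NULL, seed_labels = NULL,
                           identity_threshold = 99,
                           signature = signatureConfig(), seed = 1L) {
  if (is.null(records)) {
    if (is.null(fasta)) stop("either records or fasta must be given")
    if (is.character(fasta) && !file.exists(fasta))
      stop("fasta not found: ", fasta)
    if (is.character(locations) && !is.null(locations) &&
        !file.exists(locations))
      stop("locations not found: ", locations)
  }
  if (alpha <= 0) stop("alpha must be > 0")
  if (B < 0) stop("B must be >= 0")
  structure(list(fasta = fasta, locations = locations, records = records,
                 out_dir = out_dir, matrix = matrix, alpha = alpha,
                 B = as.integer(B),
                 support_render_threshold = support_render_threshold,
                 sweep_alphas = sweep_alphas,
                 exclude_orthogroups = exclude_orthogroups,
                 anchors = anchors, seed_labels = seed_labels,
                 identity_threshold = identity_threshold,
                 signature = signature, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Orchestrates curate -> align -> distances -> tree (with optional
#' bootstrap) -> harmonize -> duplicate detection -> summaries, writing every
#' intermediate when \code{out_dir} is set. Stage failures abort with the
#' stage name.
#'
#' @param config A [pipelineConfig()].
#' @return A list bundle: \code{records}, \code{kept}, \code{excluded},
#'   \code{annotations}, \code{alignment}, \code{distances}, \code{tree},
#'   \code{assignments}, \code{pairs}, \code{identitySummary},
#'   \code{compressed}, \code{sweep}, \code{log}.
#' @export
runPipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logs <- c(sprintf("seed=%d", config$seed),
            sprintf("model=%s alpha=%g B=%d", config$matrix, config$alpha,
                    config$B))

  records <- stage("read", {
    if (!is.null(config$records)) config$records
    else readGeneRecords(config$fasta, config$locations)
  })
  ann <- stage("curate", locateConservedDomains(records, config$signature))
  cur <- stage("curate", applyExclusionRules(records, ann,
                                             config$identity_threshold))
  kept <- cur$kept
  ann2 <- ann[match(recordIds(kept), ann$record_id), , drop = FALSE]

  aln <- stage("align", alignDomains(kept, ann2))

  seedLabels <- config$seed_labels
  if (is.null(seedLabels)) seedLabels <- config$anchors
  if (is.null(seedLabels)) {
    pn <- recordInfo(kept)$provisional_name
    seedLabels <- stats::setNames(pn, recordIds(kept))[nzchar(pn)]
  }
  groups <- stats::setNames(recordInfo(kept)$group, recordIds(kept))

  harmModel <- distanceModel(config$matrix, alpha = 1)
  asg <- stage("harmonize",
               incrementalHarmonize(aln, groups, seedLabels,
                                    canonicalBuildOrders(unique(groups)),
                                    harmModel))
  anchors <- config$anchors
  if (is.null(anchors)) {
    mam <- recordIds(kept)[groups[recordIds(kept)] %in% .MAMMAL_GROUPS]
    anchors <- seedLabels[intersect(names(seedLabels), mam)]
  }
  asg <- stage("harmonize", assignOrthogroupNames(asg, groups, anchors))

  ## main tree, optionally without the configured (epsilon-like) orthogroups
  excl <- config$exclude_orthogroups
  treeIds <- asg$record_id[is.na(asg$label) | !(asg$label %in% excl |
                                                asg$orthogroup %in% excl)]
  M <- alignedAA(aln)[intersect(alignmentIds(aln), treeIds), , drop = FALSE]
  mainModel <- distanceModel(config$matrix, alpha = config$alpha)
  tree <- stage("tree", {
    if (config$B > 0)
      bootstrapSupport(M, mainModel, B = config$B, seed = config$seed)
    else neighborJoining(.capped(pairwiseDistances(M, mainModel)))
  })

  pairs <- stage("ohnologs",
                 detectDuplicatePairs(tree, asg, kept, annotations = ann2))
  idsum <- stage("ohnologs", summarizeIdentities(pairs))

  compressed <- stage("report", {
    a2 <- asg[!is.na(asg$orthogroup), , drop = FALSE]
    ids <- intersect(tree$tip.label, a2$record_id)
    if (length(ids) >= 3)
      compressTree(ape::keep.tip(tree, ids), a2, groups,
                   allGroups = intersect(LETTERS[1:14], unique(groups)))
    else NULL
  })

  sweep <- NULL
  if (!is.null(config$sweep_alphas)) {
    lab <- stats::setNames(asg$orthogroup, asg$record_id)
    lab <- lab[!is.na(lab)]
    keepIds <- intersect(rownames(M), names(lab))
    sweep <- stage("sweep",
                   gammaSweep(M[keepIds, , drop = FALSE],
                              distanceModel(config$matrix, alpha = 1),
                              config$sweep_alphas, lab[keepIds]))
  }

  bundle <- list(records = records, kept = kept, excluded = cur$excluded,
                 annotations = ann, alignment = aln, tree = tree,
                 assignments = asg, pairs = pairs, identitySummary = idsum,
                 compressed = compressed, sweep = sweep, log = logs)

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    writeCurated(kept, cur$excluded, file.path(d, "curated.fasta"),
                 file.path(d, "excluded.tsv"))
    writeAlignment(aln, file.path(d, "domains_aa.fasta"),
                   file.path(d, "domains_nt12.fasta"),
                   file.path(d, "anchors.tsv"))
    writeTreeWithSupports(tree, file.path(d, "tree.nwk"),
                          config$support_render_threshold)
    utils::write.table(as.data.frame(asg), file.path(d, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pairs), file.path(d, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(idsum),
                       file.path(d, "identity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(compressed)) {
      utils::write.table(compressed$table, file.path(d, "orthogroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ape::write.tree(compressed$tree, file.path(d, "tree_compressed.nwk"))
    }
    if (!is.null(sweep))
      utils::write.table(sweep, file.path(d, "gamma_sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeLines(logs, file.path(d, "run_log.txt"))
  }
  bundle
}

#' Render human-readable summary tables from a pipeline bundle
#'
#' @param bundle Output of [runPipeline()].
#' @return List of data.frames: \code{presence} (orthogroup x group-letter
#'   table, fragmented orthogroups asterisked), \code{identities},
#'   \code{sweep} (when run).
#' @export
renderSummary <- function(bundle) {
  presence <- NULL
  if (!is.null(bundle$compressed)) {
    tb <- bundle$compressed$table
    presence <- data.frame(
      orthogroup = ifelse(tb$fragmented, paste0(tb$orthogroup, "*"),
                          tb$orthogroup),
      groups_present = tb$letters, groups_absent = tb$absent,
      n_members = tb$n_members, n_clades = tb$n_clades)
    empty <- presence$n_members == 0
    if (any(empty)) {
      warning("omitting empty orthogroup rows: ",
              paste(presence$orthogroup[empty], collapse = ", "))
      presence <- presence[!empty, , drop = FALSE]
    }
  }
  list(presence = presence,
       identities = as.data.frame(bundle$identitySummary),
       sweep = bundle$sweep)
}

#' Orthogroup recovery scores against simulation truth
#'
#' Micro precision/recall/F1 of harmonized labels against truth labels,
#' evaluated over non-seed records: precision over placed records, recall
#' over all records.
#'
#' @param assignments Output of [incrementalHarmonize()].
#' @param truthLabels Named character vector: true orthogroup per record id.
#' @param seedIds Record ids excluded from scoring (the seeded anchors).
#' @return Named numeric vector: precision, recall, f1, n.
#' @export
orthogroupF1 <- function(assignments, truthLabels, seedIds = character(0)) {
  ids <- setdiff(assignments$record_id, seedIds)
  ix <- match(ids, assignments$record_id)
  lab <- assignments$label[ix]
  truth <- truthLabels[ids]
  placed <- !is.na(lab)
  correct <- placed & lab == truth
  precision <- if (any(placed)) sum(correct) / sum(placed) else 0
  recall <- sum(correct) / length(ids)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1, n = length(ids))
}
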