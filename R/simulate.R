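#' Default vertebrate-style species tree
#'
#' An ultrametric 14-species tree, one representative per vertebrate group
#' A-N, with a topology following the accepted vertebrate relationships
#' (cartilaginous fishes diverging first, then the ray-finned fish groups
#' with teleosts innermost, then the lobe-finned fish and the tetrapods).
#' Depth is 1 time unit; all times in the simulator are fractions of this
#' root age.
#'
#' @return An \code{ape::phylo} with tips \code{spA} ... \code{spN}.
#' @export
defaultSpeciesTree <- function() {
  act <- "(spJ:0.87,(spK:0.85,(spL:0.8,spM:0.8):0.05):0.02)"
  mam <- "(spC:0.45,(spA:0.25,spB:0.25):0.2)"
  rep_ <- "(spG:0.55,(spF:0.5,(spE:0.45,spD:0.45):0.05):0.05)"
  tet <- sprintf("(spH:0.75,(%s:0.2,%s:0.1):0.1)", mam, rep_)
  sar <- sprintf("(spI:0.85,%s:0.1)", tet)
  nwk <- sprintf("(spN:1,(%s:0.03,%s:0.05):0.1);", act, sar)
  ape::read.tree(text = nwk)
}

#' Conserved-domain template protein and CDS
#'
#' A deterministic root gene emulating the four-transmembrane topology of a
#' gap-junction protein: hydrophobic transmembrane helices flank two
#' extracellular loops carrying the canonical cysteine motifs
#' (\code{C-x(6)-C-x(3)-C} and \code{C-x(4)-C-x(5)-C}). Cysteines occur only
#' at the motif positions, so the curation signatures locate the domains
#' unambiguously. The returned object carries per-nucleotide relative rate
#' factors (transmembrane and domain sites conserved, loops and termini
#' fast) and a mask of invariant sites (motif cysteine codons, start codon,
#' terminal stop).
#'
#' @param domain_rate,tm_rate,other_rate Relative substitution rate factors.
#' @return List: \code{protein}, \code{cds} (character), \code{rateNT},
#'   \code{maskNT}, \code{d1_span}, \code{d2_span} (0-based half-open
#'   residue spans of the motif +/- 5-residue domains), \code{cys} (0-based
#'   motif cysteine residue positions).
#' @export
makeDomainTemplate <- function(domain_rate = 0.03, tm_rate = 0.3,
                               other_rate = 1.6) {
  segs <- list(
    c("other",  "MNWGTLQSILG"),
    c("tm",     "ILVFAILVFGAILVFAILV"),
    c("domain", "ESNPGCNTVQPGCYDRCHEVKA"),   # E1: 5 + C-x(6)-C-x(3)-C + 5
    c("tm",     "VFLIAVFLIGAVFLIAVFL"),
    c("other",  "RKEQSDGHNSRLEQTSDGKHNERT"),
    c("tm",     "LIVAFLIVGFALIVAFLIV"),
    c("domain", "PDNSVCPHRVCTSLAPCNKIEG"),   # E2: 5 + C-x(4)-C-x(5)-C + 5
    c("tm",     "FVALIFVALGIFVALIFVA"),
    c("other",  "RSDTKEQNGHSPERLTDK"))
  protein <- paste(vapply(segs, `[`, "", 2), collapse = "")
  region <- unlist(lapply(segs, function(s) rep(s[1], nchar(s[2]))))
  aa <- strsplit(protein, "")[[1]]
  stopifnot(sum(aa == "C") == 6L)
  cys <- which(aa == "C") - 1L
  cds <- paste0(paste(.CODON_OF[aa], collapse = ""), "TAA")
  L <- nchar(cds)
  rateAA <- c(other = other_rate, tm = tm_rate, domain = domain_rate)[region]
  rateNT <- c(rep(rateAA, each = 3L), 0, 0, 0)
  maskNT <- rep(FALSE, L)
  maskNT[1:3] <- TRUE                      # start codon
  maskNT[(L - 2):L] <- TRUE                # terminal stop
  for (p in cys) maskNT[(3 * p + 1):(3 * p + 3)] <- TRUE
  rateNT[maskNT] <- 0
  regionNT <- c(rep(region, each = 3L), "other", "other", "other")
  list(protein = protein, cds = cds, rateNT = rateNT, maskNT = maskNT,
       regionNT = regionNT,
       d1_span = c(cys[1] - 5L, cys[3] + 6L),
       d2_span = c(cys[4] - 5L, cys[6] + 6L),
       cys = cys)
}

#' Simulation configuration
#'
#' Defines a gene-family evolution scenario: a species tree, birth-death
#' gene duplication/loss, whole-genome duplications (WGDs) of configurable
#' age and retention, tandem versus dispersed small-scale duplications, and
#' a codon-aware substitution process. The defaults encode the reference
#' scenario used throughout the package: 14 vertebrate groups, 20 root
#' orthogroups, an old WGD on the teleost-like stem (age 0.35 of the root
#' age, echoing the teleost duplication relative to the vertebrate
#' radiation) and a young WGD on the sturgeon-like stem (age 0.035),
#' with substitution scale chosen so the old-WGD ohnolog pairs sit near
#' 72-82% full-length nucleotide identity and the young-WGD pairs near 97%.
#'
#' @param species_tree Ultrametric \code{ape::phylo}.
#' @param groups Named character vector: group letter per species tip.
#' @param n_root_orthogroups Number of ancestral family members.
#' @param dup_rate,loss_rate Per-gene per-time birth-death rates.
#' @param wgd_events data.frame with columns \code{tip} (the WGD lies on the
#'   terminal edge leading to this tip), \code{time} (age before present),
#'   \code{retention} (per-gene duplicate retention probability),
#'   \code{name}.
#' @param tandem_prob Probability that a small-scale duplication is tandem
#'   (linked locus) rather than dispersed.
#' @param tandem_offset_range Range in bp for tandem copy offsets (tandem
#'   partners typically lie tens of kilobases apart).
#' @param template Output of [makeDomainTemplate()].
#' @param site_rate_alpha Gamma shape for among-site rate variation.
#' @param subst_scale Expected nucleotide substitutions per site per unit
#'   time at relative rate 1.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @param orthogroup_stem Height (time units) of the family radiation tree
#'   above the species root (controls between-orthogroup identity).
#' @param family_min_split Fraction of the stem below which no family split
#'   occurs (floors the separation of the most closely related orthogroup
#'   pair).
#' @param orthogroup_rate_multipliers Optional numeric vector (length
#'   \code{n_root_orthogroups}): per-orthogroup substitution rate
#'   multipliers, emulating the wide conservation differences between real
#'   family members (default all 1).
#' @param seed Integer seed.
#' @param cap Maximum allowed number of extant genes (guards against
#'   explosive birth-death parameters).
#' @return List of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(species_tree = defaultSpeciesTree(),
                             groups = NULL,
                             n_root_orthogroups = 20L,
                             dup_rate = 0.04, loss_rate = 0.02,
                             wgd_events = data.frame(
                               tip = c("spM", "spK"),
                               time = c(0.35, 0.035),
                               retention = c(0.4, 0.9),
                               name = c("wgd_old", "wgd_young")),
                             tandem_prob = 0.4,
                             tandem_offset_range = c(1e4, 1e5),
                             template = makeDomainTemplate(),
                             site_rate_alpha = 1.0,
                             subst_scale = 1.0,
                             kappa = 2,
                             orthogroup_stem = 3.0,
                             family_min_split = 0.6,
                             orthogroup_rate_multipliers = NULL,
                             seed = 1L,
                             cap = 5000L) {
  if (is.null(groups)) {
    tl <- species_tree$tip.label
    groups <- stats::setNames(sub("^sp", "", tl), tl)
  }
  stopifnot(dup_rate >= 0, loss_rate >= 0, tandem_prob >= 0, tandem_prob <= 1,
            all(wgd_events$retention >= 0 & wgd_events$retention <= 1))
  structure(list(species_tree = species_tree, groups = groups,
                 n_root_orthogroups = as.integer(n_root_orthogroups),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 wgd_events = wgd_events, tandem_prob = tandem_prob,
                 tandem_offset_range = tandem_offset_range,
                 template = template, site_rate_alpha = site_rate_alpha,
                 subst_scale = subst_scale, kappa = kappa,
                 orthogroup_stem = orthogroup_stem,
                 family_min_split = family_min_split,
                 orthogroup_rate_multipliers = orthogroup_rate_multipliers,
                 seed = as.integer(seed), cap = as.integer(cap)),
            class = "SimulationConfig")
}

#' Simulate a gene-family history
#'
#' Birth-death gene evolution along the species tree: small-scale
#' duplications (tandem copies placed within the linkage window on the same
#' assembly unit, dispersed copies on fresh units) and losses occur at the
#' configured per-gene rates; at each WGD event every gene present
#' duplicates with the retention probability, the copy landing on a fresh
#' assembly unit. Every extant gene is truth-labeled with its root
#' orthogroup, locus, and ohnolog/tandem partner. Reproducible given the
#' config seed.
#'
#' @param cfg A [simulationConfig()].
#' @return A [GeneFamilyHistory].
#' @export
simulateHistory <- function(cfg) {
  set.seed(cfg$seed)
  tree <- cfg$species_tree
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  age[age < 1e-12] <- 0
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- ntip + 1L

  ## place WGDs on terminal edges by tip
  wgdOnChild <- list()
  if (nrow(cfg$wgd_events)) {
    for (k in seq_len(nrow(cfg$wgd_events))) {
      tip <- match(cfg$wgd_events$tip[k], tree$tip.label)
      if (is.na(tip)) stop("wgd tip not in species tree: ",
                           cfg$wgd_events$tip[k])
      key <- as.character(tip)
      wgdOnChild[[key]] <- rbind(wgdOnChild[[key]],
        data.frame(time = cfg$wgd_events$time[k],
                   retention = cfg$wgd_events$retention[k],
                   name = cfg$wgd_events$name[k]))
    }
  }

  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$edges <- list(); env$events <- list()
  env$extant <- list(); env$nNode <- 0L; env$uid <- 0L; env$unitCounter <- 0L
  newNode <- function(t, type, og) {
    env$nNode <- env$nNode + 1L
    env$nodes[[env$nNode]] <- data.frame(node = env$nNode, time = t,
                                         type = type, orthogroup = og)
    env$nNode
  }
  addEdge <- function(p, c, len)
    env$edges[[length(env$edges) + 1L]] <- data.frame(parent = p, child = c,
                                                      length = len)
  logEvent <- function(type, t, og, detail = "")
    env$events[[length(env$events) + 1L]] <-
      data.frame(type = type, time = t, orthogroup = og, detail = detail)
  newUnit <- function(prefix) {
    env$unitCounter <- env$unitCounter + 1L
    sprintf("%s_u%03d", prefix, env$unitCounter)
  }

  lambda <- cfg$dup_rate; mu <- cfg$loss_rate
  totRate <- lambda + mu

  processEdge <- function(parentSp, childSp, lineages, og) {
    tTop <- age[parentSp]; tBot <- age[childSp]
    wg <- wgdOnChild[[as.character(childSp)]]
    if (!is.null(wg)) wg <- wg[order(-wg$time), , drop = FALSE]
    surviving <- list()
    stack <- lapply(lineages, function(l) { l$t <- tTop; l })
    while (length(stack)) {
      lin <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      repeat {
        tBD <- if (totRate > 0) lin$t - stats::rexp(1, totRate) else -Inf
        tW <- NA_real_; wrow <- NULL
        if (!is.null(wg)) {
          cand <- which(wg$time < lin$t & wg$time > tBot)
          if (length(cand)) { tW <- wg$time[cand[1]]; wrow <- wg[cand[1], ] }
        }
        if (!is.na(tW) && tW >= tBD) {
          if (stats::runif(1) < wrow$retention) {
            nd <- newNode(tW, "wgd", og)
            addEdge(lin$node, nd, lin$t - tW)
            env$uid <- env$uid + 1L
            copy <- lin
            copy$node <- nd; copy$t <- tW
            copy$unit <- newUnit(wrow$name)
            copy$pos <- 5e6
            copy$tand <- list()   # relocated: inherited tandem links are stale
            copy$wgd <- c(lin$wgd, list(c(env$uid, "B", wrow$name)))
            lin$wgd <- c(lin$wgd, list(c(env$uid, "A", wrow$name)))
            lin$node <- nd; lin$t <- tW
            stack[[length(stack) + 1L]] <- copy
            logEvent("wgd_retention", tW, og, wrow$name)
          } else {
            lin$t <- tW
          }
        } else if (tBD > tBot) {
          if (stats::runif(1) < lambda / totRate) {
            nd <- newNode(tBD, "duplication", og)
            addEdge(lin$node, nd, lin$t - tBD)
            env$uid <- env$uid + 1L
            copy <- lin
            copy$node <- nd; copy$t <- tBD
            if (stats::runif(1) < cfg$tandem_prob) {
              off <- stats::runif(1, cfg$tandem_offset_range[1],
                                  cfg$tandem_offset_range[2])
              copy$pos <- lin$pos + round(off)
              copy$tand <- c(lin$tand, list(c(env$uid, "B")))
              lin$tand <- c(lin$tand, list(c(env$uid, "A")))
              logEvent("duplication", tBD, og, "tandem")
            } else {
              copy$unit <- newUnit("disp")
              copy$pos <- 5e6
              ## a dispersed small-scale copy is a new paralog: it inherits
              ## neither its parent's tandem link nor its ohnolog identity
              copy$tand <- list()
              copy$wgd <- list()
              logEvent("duplication", tBD, og, "dispersed")
            }
            lin$node <- nd; lin$t <- tBD
            stack[[length(stack) + 1L]] <- copy
          } else {
            nd <- newNode(tBD, "loss", og)
            addEdge(lin$node, nd, lin$t - tBD)
            logEvent("loss", tBD, og)
            break
          }
        } else {
          if (childSp <= ntip) {
            nd <- newNode(tBot, "extant", og)
            addEdge(lin$node, nd, lin$t - tBot)
            lin$node <- nd
            lin$species <- tree$tip.label[childSp]
            env$extant[[length(env$extant) + 1L]] <- lin
            if (length(env$extant) > cfg$cap)
              stop("explosive parameters: extant gene cap exceeded")
          } else {
            nd <- newNode(tBot, "speciation", og)
            addEdge(lin$node, nd, lin$t - tBot)
            lin$node <- nd
            surviving[[length(surviving) + 1L]] <- lin
          }
          break
        }
      }
    }
    if (childSp > ntip)
      for (ch in kids[[as.character(childSp)]])
        processEdge(childSp, ch, surviving, og)
    invisible(NULL)
  }

  ## family radiation: a coalescent-topology ultrametric tree over the root
  ## orthogroups spanning the stem above the species root, giving the family
  ## a nested substructure (some orthogroups are close relatives, others
  ## distant). Internal split ages are floored at family_min_split of the
  ## stem so no two orthogroups are nearly identical. No birth-death events
  ## occur on the family tree: it only carries divergence.
  nog <- cfg$n_root_orthogroups
  famNodeOf <- integer(nog)
  if (nog == 1L) {
    famRoot <- newNode(age[root] + cfg$orthogroup_stem, "family_root", 0L)
    tipNode <- newNode(age[root], "family_radiation", 1L)
    addEdge(famRoot, tipNode, cfg$orthogroup_stem)
    famNodeOf[1L] <- tipNode
  } else {
    ft <- ape::rcoal(nog)
    fd <- ape::node.depth.edgelength(ft)
    fage <- max(fd) - fd
    inn <- (nog + 1L):(nog + ft$Nnode)
    fage[inn] <- cfg$orthogroup_stem *
      (cfg$family_min_split +
       (1 - cfg$family_min_split) * fage[inn] / max(fage[inn]))
    fage[seq_len(nog)] <- 0
    gnode <- integer(nog + ft$Nnode)
    froot <- nog + 1L
    gnode[froot] <- newNode(age[root] + fage[froot], "family_root", 0L)
    po <- ape::reorder.phylo(ft, "postorder")
    for (k in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[k, 1]; ch <- po$edge[k, 2]
      typ <- if (ch <= nog) "family_radiation" else "family_split"
      gnode[ch] <- newNode(age[root] + fage[ch], typ,
                           if (ch <= nog) ch else 0L)
      addEdge(gnode[p], gnode[ch], fage[p] - fage[ch])
    }
    famNodeOf <- gnode[seq_len(nog)]
  }
  for (g in seq_len(nog)) {
    start <- list(node = famNodeOf[g], og = g,
                  unit = sprintf("chr%02d", (g - 1L) %% 25L + 1L),
                  pos = 5e6 + 3e6 * ((g - 1L) %/% 25L),
                  wgd = list(), tand = list(), species = NA_character_)
    for (ch in kids[[as.character(root)]])
      processEdge(root, ch, list(start), g)
  }

  ## assemble truth
  ex <- env$extant
  if (!length(ex)) stop("no extant genes were simulated")
  ogv <- vapply(ex, function(l) l$og, 0L)
  spv <- vapply(ex, function(l) l$species, "")
  ord <- order(ogv, spv)
  ex <- ex[ord]
  idv <- character(length(ex)); cnt <- new.env(parent = emptyenv())
  for (i in seq_along(ex)) {
    key <- paste0(ex[[i]]$species, "_og", sprintf("%02d", ex[[i]]$og))
    k <- (if (is.null(cnt[[key]])) 0L else cnt[[key]]) + 1L
    cnt[[key]] <- k
    idv[i] <- sprintf("%s_%d", key, k)
  }

  ## partner resolution: latest tag whose other side has extant descendants
  tagSides <- function(tags) vapply(tags, `[`, "", 2)
  tagIds <- function(tags) vapply(tags, `[`, "", 1)
  findPartner <- function(i, field) {
    tags <- ex[[i]][[field]]
    if (!length(tags)) return(list(NA_character_, NA_character_))
    for (k in rev(seq_along(tags))) {
      uid <- tags[[k]][1]; side <- tags[[k]][2]
      for (j in seq_along(ex)) {
        if (j == i) next
        jt <- ex[[j]][[field]]
        if (!length(jt)) next
        hit <- which(tagIds(jt) == uid & tagSides(jt) != side)
        if (length(hit))
          return(list(idv[j],
                      if (field == "wgd") tags[[k]][3] else NA_character_))
      }
    }
    list(NA_character_, NA_character_)
  }

  n <- length(ex)
  ohno <- character(n); wgdname <- character(n); tand <- character(n)
  for (i in seq_len(n)) {
    pw <- findPartner(i, "wgd")
    ohno[i] <- pw[[1]]; wgdname[i] <- pw[[2]]
    tand[i] <- findPartner(i, "tand")[[1]]
  }
  len <- nchar(cfg$template$cds)
  truth <- DataFrame(
    record_id = idv,
    species = vapply(ex, function(l) l$species, ""),
    group = unname(cfg$groups[vapply(ex, function(l) l$species, "")]),
    orthogroup = sprintf("og%02d", vapply(ex, function(l) l$og, 0L)),
    assembly_unit = vapply(ex, function(l) l$unit, ""),
    start = vapply(ex, function(l) as.integer(round(l$pos)), 0L),
    end = vapply(ex, function(l) as.integer(round(l$pos)) + len, 0L),
    strand = "+",
    node = vapply(ex, function(l) l$node, 0L),
    ohnolog_partner = ohno, wgd_name = wgdname, tandem_partner = tand)

  new("GeneFamilyHistory", speciesTree = tree,
      nodes = do.call(rbind, env$nodes), edges = do.call(rbind, env$edges),
      events = if (length(env$events)) do.call(rbind, env$events)
               else data.frame(type = character(0), time = numeric(0),
                               orthogroup = integer(0), detail = character(0)),
      truth = truth, config = unclass(cfg))
}

#' Evolve coding sequences along a simulated history
#'
#' Codon-aware substitution along the gene lineage forest: per-site
#' gamma-distributed rates multiplied by region factors (conserved domains
#' and transmembrane helices slow, loops fast), a transition-biased jump
#' process (kappa-weighted), invariant masking of the motif cysteine codons,
#' start codon and terminal stop, and rejection of substitutions creating
#' internal stop codons (the affected codon reverts to its parent). The
#' translations therefore always retain an open reading frame and the domain
#' signatures, unless ablation is requested for a directed negative control.
#'
#' @param history A [GeneFamilyHistory].
#' @param cfg The [simulationConfig()] used (defaults to the one stored in
#'   the history).
#' @param ablate Character vector of record ids whose third E1 motif
#'   cysteine codon is mutated to serine after evolution (curation negative
#'   controls).
#' @return A [GeneRecordSet] ready for the curation module.
#' @export
evolveSequences <- function(history, cfg = NULL, ablate = character(0)) {
  if (is.null(cfg)) cfg <- history@config
  set.seed(cfg$seed + 1000003L)
  tmpl <- cfg$template
  L <- nchar(tmpl$cds)
  rootSeq <- strsplit(tmpl$cds, "")[[1]]
  edges <- history@edges
  nodes <- history@nodes
  truth <- history@truth
  kidsOf <- split(seq_len(nrow(edges)), edges$parent)
  alphabet <- c("A", "C", "G", "T")
  ## transition partner lookup
  tsOf <- c(A = "G", G = "A", C = "T", T = "C")
  kap <- cfg$kappa
  pTs <- kap / (kap + 2)

  mutate <- function(seq, t, rates) {
    lam <- rates * cfg$subst_scale * t
    nsub <- stats::rpois(L, lam)
    hot <- which(nsub > 0)
    if (!length(hot)) return(seq)
    old <- seq
    for (s in hot) {
      base <- seq[s]
      for (k in seq_len(nsub[s])) {
        if (stats::runif(1) < pTs) base <- tsOf[[base]]
        else base <- sample(setdiff(alphabet, c(base, tsOf[[base]])), 1)
      }
      seq[s] <- base
    }
    ## purifying selection: internal stop codons revert, and transmembrane
    ## codons only accept hydrophobic replacements (helix maintenance)
    ncod <- L %/% 3L
    for (cd in seq_len(ncod - 1L)) {
      ix <- (3L * cd - 2L):(3L * cd)
      if (!any(ix %in% hot)) next
      codon <- paste(seq[ix], collapse = "")
      if (codon %in% .STOP_CODONS) { seq[ix] <- old[ix]; next }
      if (tmpl$regionNT[ix[1]] == "tm") {
        aa <- Biostrings::GENETIC_CODE[[codon]]
        if (!(aa %in% .TM_ALLOWED)) seq[ix] <- old[ix]
      }
    }
    seq
  }

  seqs <- new.env(parent = emptyenv())
  mult <- cfg$orthogroup_rate_multipliers
  if (is.null(mult)) mult <- rep(1, cfg$n_root_orthogroups)
  nodeType <- stats::setNames(nodes$type, as.character(nodes$node))
  nodeOg <- stats::setNames(nodes$orthogroup, as.character(nodes$node))
  walk <- function(node, seq, rates) {
    key <- as.character(node)
    seqs[[key]] <- seq
    ## the per-orthogroup rate multiplier takes effect below the family
    ## radiation tip: a fast family member is internally divergent without
    ## drifting away from the rest of the family
    below <- if (identical(nodeType[[key]], "family_radiation"))
      rates * mult[nodeOg[[key]]] else rates
    for (ei in kidsOf[[key]]) {
      child <- edges$child[ei]
      walk(child, mutate(seq, edges$length[ei], below), below)
    }
  }
  siteRates <- stats::rgamma(L, shape = cfg$site_rate_alpha,
                             rate = cfg$site_rate_alpha) * tmpl$rateNT
  for (r in nodes$node[nodes$type == "family_root"])
    walk(r, rootSeq, siteRates)

  cds <- vapply(truth$node, function(nd)
    paste(seqs[[as.character(nd)]], collapse = ""), "")
  names(cds) <- truth$record_id

  if (length(ablate)) {
    cysCodon <- (3L * tmpl$cys[3] + 1L):(3L * tmpl$cys[3] + 3L)
    for (id in intersect(ablate, names(cds))) {
      x <- strsplit(cds[[id]], "")[[1]]
      x[cysCodon] <- c("A", "G", "C")
      cds[[id]] <- paste(x, collapse = "")
    }
  }

  info <- DataFrame(record_id = truth$record_id,
                    species = truth$species, group = truth$group,
                    assembly_unit = truth$assembly_unit,
                    start = truth$start, end = truth$end,
                    strand = truth$strand, placed = TRUE,
                    provisional_name = truth$orthogroup, accession = "",
                    valid_translation = TRUE, translation_note = "")
  prot <- vapply(cds, function(s) .translateCDS(s)$protein, "")
  info$valid_translation <- nzchar(prot)
  new("GeneRecordSet",
      cds = Biostrings::DNAStringSet(cds),
      protein = Biostrings::AAStringSet(stats::setNames(prot, truth$record_id)),
      info = info)
}

#' Write a simulated dataset to disk
#'
#' Emits the pipeline inputs (CDS FASTA, locations TSV) and the truth tables
#' (orthogroups, duplicate partners). Byte-stable given the config seed.
#'
#' @param records A [GeneRecordSet] from [evolveSequences()].
#' @param history The [GeneFamilyHistory].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(records, history, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genes.fasta")
  Biostrings::writeXStringSet(recordCDS(records), fa)
  info <- recordInfo(records)
  loc <- data.frame(record_id = info$record_id, species = info$species,
                    group = info$group, assembly_unit = info$assembly_unit,
                    start = info$start + 1L, end = info$end,
                    strand = info$strand)
  locp <- file.path(out_dir, "locations.tsv")
  utils::write.table(loc, locp, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- as.data.frame(historyTruth(history))
  trp <- file.path(out_dir, "truth_orthogroups.tsv")
  utils::write.table(tr[, c("record_id", "species", "group", "orthogroup")],
                     trp, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- tr[!is.na(tr$ohnolog_partner) | !is.na(tr$tandem_partner),
           c("record_id", "ohnolog_partner", "wgd_name", "tandem_partner")]
  prp <- file.path(out_dir, "truth_pairs.tsv")
  utils::write.table(pr, prp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, locp, trp, prp))
}
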