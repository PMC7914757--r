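noWGD <- data.frame(tip = character(0), time = numeric(0),
                    retention = numeric(0), name = character(0))

test_that("without duplication, loss or WGD the family is one gene per species", {
  st <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1.5,s4:1.5):0.5);")
  cfg <- simulationConfig(species_tree = st,
                          groups = c(s1 = "A", s2 = "B", s3 = "M", s4 = "N"),
                          n_root_orthogroups = 5L, dup_rate = 0, loss_rate = 0,
                          wgd_events = noWGD, seed = 5)
  h <- simulateHistory(cfg)
  tt <- as.data.frame(historyTruth(h))
  expect_equal(nrow(tt), 20L)
  expect_equal(unname(table(tt$orthogroup)), rep(4L, 5), ignore_attr = TRUE)
  expect_equal(unname(table(tt$species)), rep(5L, 4), ignore_attr = TRUE)
  expect_true(all(is.na(tt$ohnolog_partner)))
})

test_that("a fully retained WGD doubles the lineage and labels all pairs", {
  st <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1.5,s4:1.5):0.5);")
  wgd <- data.frame(tip = "s3", time = 0.5, retention = 1, name = "wgdX")
  cfg <- simulationConfig(species_tree = st,
                          groups = c(s1 = "A", s2 = "B", s3 = "M", s4 = "N"),
                          n_root_orthogroups = 4L, dup_rate = 0, loss_rate = 0,
                          wgd_events = wgd, seed = 6)
  h <- simulateHistory(cfg)
  tt <- as.data.frame(historyTruth(h))
  s3 <- tt[tt$species == "s3", ]
  s4 <- tt[tt$species == "s4", ]
  expect_equal(nrow(s3), 2L * nrow(s4))
  expect_true(all(!is.na(s3$ohnolog_partner)))
  expect_true(all(s3$wgd_name == "wgdX"))
  ## partners are mutual and on different assembly units
  m <- match(s3$ohnolog_partner, s3$record_id)
  expect_equal(s3$ohnolog_partner[m], s3$record_id)
  expect_true(all(s3$assembly_unit != s3$assembly_unit[m]))
})

test_that("extant counts follow the birth-death expectation", {
  st <- ape::read.tree(text = "(s1:10,s2:10);")
  counts <- c()
  for (sd in 1:40) {
    cfg <- simulationConfig(species_tree = st, groups = c(s1 = "A", s2 = "B"),
                            n_root_orthogroups = 10L, dup_rate = 0.1,
                            loss_rate = 0.05, wgd_events = noWGD,
                            orthogroup_stem = 0.1, seed = 6000 + sd,
                            cap = 50000L)
    h <- simulateHistory(cfg)
    tt <- as.data.frame(historyTruth(h))
    ## extant genes per root lineage per species tip
    counts <- c(counts, as.vector(table(factor(
      paste(tt$orthogroup, tt$species),
      levels = as.vector(outer(unique(tt$orthogroup),
                               c("s1", "s2"), paste))))))
  }
  expected <- exp((0.1 - 0.05) * 10)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("explosive parameters abort before sequence evolution", {
  st <- ape::read.tree(text = "(s1:10,s2:10);")
  cfg <- simulationConfig(species_tree = st, groups = c(s1 = "A", s2 = "B"),
                          n_root_orthogroups = 5L, dup_rate = 1.5,
                          loss_rate = 0, wgd_events = noWGD, seed = 3,
                          cap = 200L)
  expect_error(simulateHistory(cfg), "cap")
})

test_that("zero substitution scale reproduces the template everywhere", {
  s <- quickSim(81, n_og = 3L, subst_scale = 0)
  cds <- as.character(recordCDS(s$records))
  expect_true(all(cds == makeDomainTemplate()$cds))
})

test_that("sequence divergence tracks the substitution-process expectation", {
  ## two species at depth t; near-constant site rates; measure the observed
  ## difference proportion at fast ('other') sites against the
  ## transition-biased jump-process closed form averaged over the path 2t
  st <- ape::read.tree(text = "(s1:0.5,s2:0.5);")
  tmpl <- makeDomainTemplate()
  fast <- which(tmpl$regionNT == "other" & !tmpl$maskNT & tmpl$rateNT > 0)
  d <- 2 * 0.5 * 1.0 * 1.6            # path x scale x region rate
  ## kappa = 2 jump process, equal frequencies: alpha' = 1/2, beta' = 1/4
  pSame <- 0.25 + 0.25 * exp(-d) + 0.5 * exp(-1.5 * d)
  obs <- c()
  for (sd in 1:25) {
    cfg <- simulationConfig(species_tree = st, groups = c(s1 = "A", s2 = "B"),
                            n_root_orthogroups = 4L, dup_rate = 0,
                            loss_rate = 0, wgd_events = noWGD,
                            site_rate_alpha = 1e6, orthogroup_stem = 0.01,
                            seed = 8000 + sd)
    h <- simulateHistory(cfg)
    rec <- evolveSequences(h, cfg)
    tt <- as.data.frame(historyTruth(h))
    for (og in unique(tt$orthogroup)) {
      pr <- tt$record_id[tt$orthogroup == og]
      x <- strsplit(as.character(recordCDS(rec)[[match(pr[1], recordIds(rec))]]), "")[[1]]
      y <- strsplit(as.character(recordCDS(rec)[[match(pr[2], recordIds(rec))]]), "")[[1]]
      obs <- c(obs, mean(x[fast] != y[fast]))
    }
  }
  se <- stats::sd(obs) / sqrt(length(obs))
  ## small upward-identity bias from stop-codon rejection is tolerated
  expect_lt(abs(mean(obs) - (1 - pSame)), 3 * se + 0.02)
})

test_that("truth labels are structurally consistent for several seeds", {
  for (sd in c(2, 14)) {
    s <- quickSim(sd, n_og = 6L)
    tt <- s$truthTable
    oh <- tt[!is.na(tt$ohnolog_partner), ]
    m <- match(oh$ohnolog_partner, tt$record_id)
    expect_false(anyNA(m))
    expect_true(all(oh$assembly_unit != tt$assembly_unit[m]))
    td <- tt[!is.na(tt$tandem_partner), ]
    if (nrow(td)) {
      m2 <- match(td$tandem_partner, tt$record_id)
      expect_true(all(td$assembly_unit == tt$assembly_unit[m2]))
      expect_true(all(abs(td$start - tt$start[m2]) <= 1e6))
    }
    ## every extant gene traces to exactly one root orthogroup
    expect_false(anyNA(tt$orthogroup))
  }
})

test_that("written datasets are byte-stable for a seed and change across seeds", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  d3 <- file.path(tempdir(), "ds3")
  s <- quickSim(91, n_og = 3L)
  writeDataset(s$records, s$history, d1)
  s2 <- quickSim(91, n_og = 3L)
  writeDataset(s2$records, s2$history, d2)
  expect_identical(readLines(file.path(d1, "genes.fasta")),
                   readLines(file.path(d2, "genes.fasta")))
  expect_identical(readLines(file.path(d1, "truth_orthogroups.tsv")),
                   readLines(file.path(d2, "truth_orthogroups.tsv")))
  s3 <- quickSim(92, n_og = 3L)
  writeDataset(s3$records, s3$history, d3)
  expect_false(identical(readLines(file.path(d1, "genes.fasta")),
                         readLines(file.path(d3, "genes.fasta"))))
  ## schema identical
  expect_identical(readLines(file.path(d1, "locations.tsv"), n = 1),
                   readLines(file.path(d3, "locations.tsv"), n = 1))
})
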