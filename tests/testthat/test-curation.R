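test_that("records are read with locations attached, unplaced rows warned, and bad CDS flagged", {
  cds <- c(g1 = templateCDS(), g2 = templateCDS(), g3 = templateCDS())
  loc <- simpleLocations(c("g1", "g2", "g3"), species = c("Aa", "Aa", "Bb"),
                         group = c("A", "A", "M"))
  rs <- readGeneRecords(Biostrings::DNAStringSet(cds), loc)
  expect_equal(length(rs), 3L)
  expect_true(all(recordInfo(rs)$placed))
  expect_equal(recordInfo(rs)$species, c("Aa", "Aa", "Bb"))
  ## 1-based inclusive input -> 0-based half-open internal
  expect_equal(recordInfo(rs)$start, rep(100L, 3))

  expect_warning(
    rs2 <- readGeneRecords(Biostrings::DNAStringSet(cds),
                           loc[1:2, , drop = FALSE]),
    "unplaced")
  expect_false(recordInfo(rs2)$placed[3])

  rs3 <- readGeneRecords(Biostrings::DNAStringSet(c(bad = "ATGGCCTTTA")))
  expect_false(recordInfo(rs3)$valid_translation[1])
  expect_equal(recordInfo(rs3)$translation_note[1], "length_not_multiple_of_3")
})

test_that("minus-strand records are reverse-complemented on ingest", {
  cds <- templateCDS()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  loc <- simpleLocations("gm", strand = "-")
  rs <- readGeneRecords(Biostrings::DNAStringSet(c(gm = rc)), loc)
  expect_equal(as.character(recordCDS(rs)[[1]]), cds)
  expect_true(recordInfo(rs)$valid_translation[1])
})

test_that("domain location finds both motifs with 5-residue extensions and flags defects", {
  tmpl <- makeDomainTemplate()
  rs <- recordsFromCDS(list(ok = tmpl$cds))
  ann <- locateConservedDomains(rs)
  expect_true(ann$valid_d1 && ann$valid_d2 && ann$tm_valid)
  expect_equal(c(ann$d1_start, ann$d1_end), tmpl$d1_span)
  expect_equal(c(ann$d2_start, ann$d2_end), tmpl$d2_span)
  expect_equal(as.integer(strsplit(ann$cys_positions, ",")[[1]]), tmpl$cys)

  ## third E1 cysteine mutated to serine: E1 signature lost
  mut <- swapCodon(tmpl$cds, tmpl$cys[3] + 1L, "AGC")
  annM <- locateConservedDomains(recordsFromCDS(list(m = mut)))
  expect_false(annM$valid_d1)
  expect_true(annM$valid_d2)

  ## E2 third cysteine mutated: E1 only
  mut2 <- swapCodon(tmpl$cds, tmpl$cys[6] + 1L, "AGC")
  ann2 <- locateConservedDomains(recordsFromCDS(list(m = mut2)))
  expect_true(ann2$valid_d1)
  expect_false(ann2$valid_d2)
})

test_that("domain location is stable under appending residues after domain 2", {
  tmpl <- makeDomainTemplate()
  base <- sub("TAA$", "", tmpl$cds)
  longer <- paste0(base, strrep("GCT", 30), "TAA")
  a1 <- locateConservedDomains(recordsFromCDS(list(a = tmpl$cds)))
  a2 <- locateConservedDomains(recordsFromCDS(list(a = longer)))
  expect_equal(a1$d1_start, a2$d1_start)
  expect_equal(a1$d2_end, a2$d2_end)
  expect_equal(a1$cys_positions, a2$cys_positions)
})

test_that("exclusion rules partition the input with machine-readable reasons", {
  tmpl <- makeDomainTemplate()
  nearDup <- swapCodon(tmpl$cds, 60L, "GCA")          # one codon off
  oneDomain <- swapCodon(tmpl$cds, tmpl$cys[5] + 1L, "AGC")
  cds <- list(k1 = tmpl$cds, k2 = nearDup, s1 = oneDomain)
  loc <- simpleLocations(c("k1", "k2", "s1"), species = "Xx")
  rs <- recordsFromCDS(cds, loc)
  ann <- locateConservedDomains(rs)
  res <- applyExclusionRules(rs, ann, identity_threshold = 99)
  ex <- as.data.frame(res$excluded)
  expect_setequal(c(recordIds(res$kept), ex$record_id), c("k1", "k2", "s1"))
  expect_equal(ex$reason[ex$record_id == "k2"], "near_duplicate")
  expect_match(ex$detail[ex$record_id == "k2"], "kept=k1")
  expect_equal(ex$reason[ex$record_id == "s1"], "single_domain")
  expect_equal(recordIds(res$kept), "k1")

  ## different species: no near-duplicate call; all-distinct valid kept
  loc2 <- simpleLocations(c("k1", "k2"), species = c("Xx", "Yy"))
  rs2 <- recordsFromCDS(cds[1:2], loc2)
  res2 <- applyExclusionRules(rs2, locateConservedDomains(rs2))
  expect_equal(length(res2$kept), 2L)
  expect_equal(nrow(res2$excluded), 0L)
})

test_that("curation accepts every simulated record and rejects ablated motifs", {
  s <- quickSim(101, n_og = 6L)
  ids <- recordIds(s$records)
  victim <- ids[10]
  rec <- evolveSequences(s$history, s$cfg, ablate = victim)
  ann <- locateConservedDomains(rec, refSignature())
  ok <- ann$valid_d1 & ann$valid_d2 & ann$tm_valid
  expect_true(all(ok[ann$record_id != victim]))
  expect_false(ann$valid_d1[ann$record_id == victim])
  res <- applyExclusionRules(rec, ann)
  expect_true(victim %in% as.data.frame(res$excluded)$record_id)
  ## partition property
  expect_setequal(c(recordIds(res$kept), as.data.frame(res$excluded)$record_id),
                  ids)
})

test_that("display names follow the four schemes and the case convention", {
  cds <- list(a = templateCDS(), b = templateCDS(), c = templateCDS())
  loc <- simpleLocations(c("a", "b", "c"),
                         species = c("Ln", "Hs", "Xx"), unit = "S",
                         start = 100, end = 1200)
  loc$accession <- c("XM_n", "NM_1", "")
  loc$provisional_name <- c("gjd2like", "", "")
  rs <- recordsFromCDS(cds, loc)
  nm <- formatDisplayName(rs, c("gjd5", "gja1", "gja1"),
                          mammalAnchored = c(FALSE, TRUE, FALSE))
  expect_equal(nm[1], "Ln-gjd5-XM_n-gjd2like")
  expect_equal(nm[2], "Hs-GJA1-NM_1")
  expect_equal(nm[3], "Xx-gja1-S:100+")
})
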