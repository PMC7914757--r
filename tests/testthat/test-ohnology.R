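test_that("pairwise identity has the expected fixed points and symmetry", {
  a <- strrep("ATGGCC", 50)
  expect_equal(pairwiseIdentitySeq(a, a, "nt"), 100)
  b <- a
  substr(b, 7, 7) <- "C"   # one substitution in 300 comparable columns
  expect_equal(pairwiseIdentitySeq(a, b, "nt"), 100 * 299 / 300)
  expect_equal(pairwiseIdentitySeq(a, b, "nt"), pairwiseIdentitySeq(b, a, "nt"))
  expect_error(pairwiseIdentitySeq("", a), "empty")
})

## constructed duplicate scenario: one orthogroup, species Zz with a cherry
## on different chromosomes (ohnolog), species Tt with a linked pair
## (tandem), species Uu with one gene, species Vv with a triple (multiplet)
dupFixture <- function() {
  tr <- ape::read.tree(text = paste0(
    "(((z1:0.02,z2:0.02):0.1,(t1:0.01,t2:0.01):0.1):0.1,",
    "(u1:0.05,(v1:0.02,(v2:0.01,v3:0.01):0.01):0.1):0.1);"))
  ids <- tr$tip.label
  cds <- makeDomainTemplate()$cds
  cdss <- stats::setNames(rep(cds, length(ids)), ids)
  cdss["z2"] <- swapCodon(cds, 20L, "GCA")
  loc <- simpleLocations(ids,
    species = c(z1 = "Zz", z2 = "Zz", t1 = "Tt", t2 = "Tt",
                u1 = "Uu", v1 = "Vv", v2 = "Vv", v3 = "Vv")[ids],
    group = "M")
  loc$assembly_unit <- c(z1 = "chr5", z2 = "chr13", t1 = "sc1", t2 = "sc1",
                         u1 = "chr2", v1 = "chr1", v2 = "chr2",
                         v3 = "chr3")[ids]
  loc$start <- c(z1 = 1e6, z2 = 2e6, t1 = 1e6, t2 = 1e6 + 5e4,
                 u1 = 1e6, v1 = 1e6, v2 = 1e6, v3 = 1e6)[ids]
  loc$end <- loc$start + 1000
  rec <- recordsFromCDS(as.list(cdss), loc)
  asg <- DataFrame(record_id = ids, orthogroup = "GJD1")
  list(tree = tr, records = rec, assignments = asg)
}

test_that("duplicate pairs are classified by tree and location", {
  fx <- dupFixture()
  pairs <- as.data.frame(detectDuplicatePairs(fx$tree, fx$assignments,
                                              fx$records))
  zz <- pairs[pairs$species == "Zz", ]
  expect_equal(nrow(zz), 1L)
  expect_equal(zz$class, "ohnolog")
  expect_equal(zz$genomic_relation, "different_units")
  tt <- pairs[pairs$species == "Tt", ]
  expect_equal(tt$class, "tandem")
  expect_equal(tt$genomic_relation, "same_unit_linked")
  expect_false(any(pairs$species == "Uu"))
  vv <- pairs[pairs$species == "Vv", ]
  expect_equal(nrow(vv), 3L)                 # all within-group pairs
  expect_true(all(vv$multiplet))
  expect_false(any(zz$multiplet, tt$multiplet))
  ## identity bookkeeping: z-pair differs by one codon swap
  expect_lt(zz$nt_identity_fulllength, 100)
  expect_gt(zz$nt_identity_fulllength, 99)
  expect_equal(tt$nt_identity_fulllength, 100)
})

test_that("classification depends only on tree and locations", {
  fx <- dupFixture()
  p1 <- as.data.frame(detectDuplicatePairs(fx$tree, fx$assignments,
                                           fx$records))
  perm <- sample(length(fx$records))
  p2 <- as.data.frame(detectDuplicatePairs(fx$tree,
                                           fx$assignments[perm, ],
                                           fx$records[perm]))
  key <- function(p) sort(paste(p$record_a, p$record_b, p$class))
  expect_equal(key(p1), key(p2))
})

test_that("identity summaries aggregate ohnolog pairs per species", {
  pairs <- DataFrame(species = c("Zz", "Zz", "Tt", "Zz"),
                     record_a = letters[1:4], record_b = LETTERS[1:4],
                     orthogroup = "x",
                     class = c("ohnolog", "ohnolog", "tandem", "unresolved"),
                     genomic_relation = "different_units",
                     nt_identity_fulllength = c(90, 94, 99, 80),
                     aa_identity_domains = NA_real_, multiplet = FALSE)
  s <- as.data.frame(summarizeIdentities(pairs))
  expect_equal(nrow(s), 1L)                   # only ohnolog-class, one species
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$mean_identity, 92)
  expect_equal(s$min_identity, 90)
  expect_equal(s$max_identity, 94)
  one <- summarizeIdentities(pairs[1, , drop = FALSE])
  expect_equal(one$mean_identity, one$min_identity)
  expect_equal(one$mean_identity, one$max_identity)
})

test_that("simulated ohnologs are recovered with high recall and little confusion", {
  s <- quickSim(71, n_og = 8L)
  ann <- locateConservedDomains(s$records, refSignature())
  aln <- alignDomains(s$records, ann)
  D <- pairwiseDistances(alignedAA(aln), distanceModel("jtt_gamma", alpha = 1))
  tr <- neighborJoining(connexo:::.capped(D))
  asg <- DataFrame(record_id = s$truthTable$record_id,
                   orthogroup = s$truthTable$orthogroup)
  pairs <- as.data.frame(detectDuplicatePairs(tr, asg, s$records))
  pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tt <- s$truthTable
  oh <- tt[!is.na(tt$ohnolog_partner), ]
  truthOh <- unique(pkey(oh$record_id, oh$ohnolog_partner))
  detOh <- pkey(pairs$record_a[pairs$class == "ohnolog"],
                pairs$record_b[pairs$class == "ohnolog"])
  expect_gte(mean(truthOh %in% detOh), 0.9)
  ## tandem truth pairs must not be called ohnologs
  td <- tt[!is.na(tt$tandem_partner), ]
  if (nrow(td)) {
    truthTd <- unique(pkey(td$record_id, td$tandem_partner))
    expect_lte(mean(truthTd %in% detOh), 0.05)
  }
})
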