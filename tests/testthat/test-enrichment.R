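## A compact scenario: 9 TICF-defined patients in 3 groups, a trusted
## protein shared beyond the seed group, a trusted linked partner
## carried by an otherwise unrelated patient.
enrichmentScenario <- function() {
  ids <- sprintf("p%d", 1:9)
  docs <- c(
    lapply(seq_along(ids), function(i)
      clinicalDoc(ids[i], stage = c(1, 1, 1, 2, 2, 2, 3, 3, 3)[i],
                  size = 10 * i, age = 40 + i, survival = 100 - 5 * i)),
    list(clinicalDoc("z", stage = NA, size = NA, age = NA, survival = 55)),
    ## MODA carried by the seed group p1-p3 plus p4, p5 (support 5 > 2)
    lapply(c("p1", "p2", "p3", "p4", "p5"), function(p)
      cnvDoc(p, list(MODA = 1))),
    ## MODB carried only by p7 (support 1: untrusted)
    list(cnvDoc("p7", list(MODB = 1)),
         ## PARTA: partner of MODA, carried by the TICF-less patient z
         ## and 2 extras to give it internal support
         cnvDoc("z", list(PARTA = 1)),
         cnvDoc("p8", list(PARTA = -1)),
         cnvDoc("p9", list(PARTA = -1))))
  scoring <- scoringConfig(trustedThreshold = 2L)
  net <- suppressMessages(buildInternalNetwork(docs, scoring = scoring))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("protein_a\tprotein_b\tscore\tprovider",
               "MODA\tPARTA\t0.9\tgo",
               "MODB\tPARTB\t0.9\tgo"), path)
  net <- addLinkedRelations(net, edksFixtureProvider(path), scoring)
  net <- pruneUntrusted(markTrusted(net, scoring))
  ticf <- suppressMessages(buildTICFTable(docs, k = 3))
  list(docs = docs, net = net, ticf = ticf)
}

test_that("ring 0 is the seed's TICF group and partitions the cohort", {
  sc <- enrichmentScenario()
  ring0 <- seedGroup("p1", sc$ticf)
  expect_identical(ring0, c("p1", "p2", "p3"))
  ## union over all seeds covers exactly the TICF-defined patients
  tab <- ticfValues(sc$ticf)
  all0 <- unique(unlist(lapply(tab$sampleId, seedGroup, ticf = sc$ticf)))
  expect_setequal(all0, tab$sampleId)
  expect_error(seedGroup("z", sc$ticf), "no defined TICF")
})

test_that("internal expansion follows trusted proteins only", {
  sc <- enrichmentScenario()
  ring0 <- seedGroup("p1", sc$ticf)
  ring1 <- expandInternal(ring0, sc$net)
  ## MODA (trusted) reaches p4, p5; MODB is untrusted and adds nothing
  expect_identical(ring1, c("p4", "p5"))
  expect_length(intersect(ring0, ring1), 0L)

  ## p7's group reaches z through trusted PARTA; untrusted MODB (carried
  ## by p7 alone) contributes nothing
  ring0c <- seedGroup("p7", sc$ticf)
  expect_identical(expandInternal(ring0c, sc$net), "z")

  ## with no trusted proteins at all, expansion is empty
  netHi <- markTrusted(sc$net, scoringConfig(trustedThreshold = 100L))
  expect_identical(expandInternal(ring0c, netHi), character())
})

test_that("linked expansion reaches carriers of trusted partner proteins", {
  sc <- enrichmentScenario()
  ring01 <- c(seedGroup("p1", sc$ticf), c("p4", "p5"))
  lk <- expandLinked(ring01, sc$net)
  ## MODA -(linked, trusted)- PARTA, carried by z, p8, p9 outside the rings
  expect_identical(lk$linkedProteins, "PARTA")
  expect_identical(lk$ring2, c("p8", "p9", "z"))

  ## MODB's link to PARTB (support 1 <= 2) was pruned away entirely
  e <- networkEdges(sc$net)
  expect_false("PARTB" %in% c(e$source, e$target))
})

test_that("rings match a brute-force two-hop traversal on random networks", {
  set.seed(17)
  for (iter in 1:20) {
    nPat <- sample(6:14, 1)
    nProt <- sample(3:8, 1)
    patients <- sprintf("p%02d", seq_len(nPat))
    prots <- sprintf("G%d", seq_len(nProt))
    carriers <- stats::setNames(lapply(prots, function(g)
      sample(patients, sample(0:nPat, 1))), prots)
    carriers <- carriers[lengths(carriers) > 0]
    thr <- sample(1:4, 1)
    scoring <- scoringConfig(trustedThreshold = thr)
    net <- toyNetwork(carriers, allPatients = patients,
                      trustedThreshold = thr)
    ## random linked relations
    if (length(carriers) >= 2) {
      pairs <- t(utils::combn(names(carriers), 2))
      keep <- sample(nrow(pairs), min(3, nrow(pairs)))
      path <- withr::local_tempfile(fileext = ".tsv")
      writeLines(c("protein_a\tprotein_b\tscore\tprovider",
                   sprintf("%s\t%s\t0.8\tgo", pairs[keep, 1],
                           pairs[keep, 2])), path)
      net <- addLinkedRelations(net, edksFixtureProvider(path), scoring)
      net <- pruneUntrusted(markTrusted(net, scoring))
    }
    ring0 <- sort(sample(patients, sample(1:3, 1)))
    ring1 <- expandInternal(ring0, net)
    ring2 <- expandLinked(c(ring0, ring1), net)$ring2
    oracle <- bruteRings(net, ring0)
    expect_identical(ring1, oracle$ring1)
    expect_identical(ring2, oracle$ring2)
    ## monotone, disjoint enrichment
    expect_length(intersect(ring0, ring1), 0L)
    expect_length(intersect(c(ring0, ring1), ring2), 0L)
  }
})

test_that("feature assembly normalizes columns and imputes missing TICF", {
  sc <- enrichmentScenario()
  cohort <- enrichCohort("p1", sc$net, sc$ticf, sc$docs)
  expect_identical(ringPatients(cohort, 0), c("p1", "p2", "p3"))
  expect_identical(ringPatients(cohort, 1), c("p4", "p5"))
  expect_identical(ringPatients(cohort, 2), c("p8", "p9", "z"))
  X <- featureMatrix(cohort)
  expect_identical(nrow(X), 8L)
  expect_true("ticf" %in% colnames(X))
  ## non-degenerate columns have mean 0, unit population variance
  for (j in seq_len(ncol(X))) {
    if (any(X[, j] != 0)) {
      expect_lt(abs(mean(X[, j])), 1e-9)
      expect_lt(abs(mean(X[, j]^2) - 1), 1e-9)
    }
  }
  ## the TICF-less patient z sits in the matrix; its clinical entry was
  ## imputed before renormalization
  expect_true("z" %in% rownames(X))
  y <- survivalTargets(cohort)
  expect_identical(y[["z"]], 55)

  ## constant indicator columns collapse to zeros
  Xc <- assembleFeatures(c("p1", "p2"), sc$ticf, sc$net, sc$docs,
                         proteins = "MODA")$featureMatrix
  expect_identical(unname(Xc[, "prot_MODA"]), c(0, 0))

  ## fewer than 2 survival targets is an insufficient cohort
  docsNoSurv <- c(sc$docs[1:2],
                  list(clinicalDoc("p9", 3, 90, 49, NA)))
  expect_error(
    assembleFeatures(c("p9"), sc$ticf, sc$net, docsNoSurv,
                     proteins = "MODA"),
    "insufficient cohort")
})

test_that("enrichment without network expansion is ring 0 only", {
  sc <- enrichmentScenario()
  cohort <- enrichCohort("p1", sc$net, sc$ticf, sc$docs, expand = FALSE)
  expect_identical(ringPatients(cohort), seedGroup("p1", sc$ticf))
  expect_identical(ncol(featureMatrix(cohort)), 1L)
})
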