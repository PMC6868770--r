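test_that("expression aberration calls follow cohort z-scores", {
  ## constant cohort: zero variance, nothing is aberrant
  docs <- lapply(1:4, function(i)
    exprDoc(paste0("p", i), list(TP53 = "1.0", EGFR = "1.0")))
  st <- cohortExpressionStats(docs)
  expect_identical(callAberrantProteins(docs[[1]], stats = st), character())

  ## one value pushed far out; verify with an independent mean/SD oracle
  vals <- c(0.1, -0.1, 0.2, -0.2, 0.05, -0.05, 0.15, -0.15, 0, 8.0)
  zOut <- (vals[10] - mean(vals)) / sd(vals)
  expect_gt(zOut, 2)  # oracle: the planted value exceeds the cutoff
  docs <- lapply(seq_along(vals), function(i)
    exprDoc(paste0("p", i), list(TP53 = as.character(vals[i]),
                                 EGFR = "0.5")))
  st <- cohortExpressionStats(docs)
  expect_identical(callAberrantProteins(docs[[10]], stats = st), "TP53")
  expect_identical(callAberrantProteins(docs[[1]], stats = st), character())

  ## non-numeric values are skipped with a warning
  bad <- exprDoc("p9", list(TP53 = "n/a"))
  expect_warning(out <- callAberrantProteins(bad, stats = st),
                 "non-numeric")
  expect_identical(out, character())
})

test_that("copy-number aberration calls respect the gain/loss cutoffs", {
  cfg <- aberrationConfig(cnGain = 0.5, cnLoss = -0.5)
  d <- cnvDoc("p1", list(A = "0", B = "0.5", C = "-0.7", D = "0.49"))
  expect_identical(callAberrantProteins(d, cfg), c("B", "C"))
  expect_identical(callAberrantProteins(cnvDoc("p2", list()), cfg),
                   character())
})

test_that("the internal network links patients through shared proteins", {
  ## two patients with disjoint aberrant proteins: no shared edges
  net <- toyNetwork(list(A = "p1", B = "p2"), trustedThreshold = 1L)
  expect_identical(sum(networkEdges(net)$kind ==
                         "patient_patient_shared"), 0L)
  ## trusted proteins with disjoint carrier pairs only link within a pair
  net2 <- toyNetwork(list(A = c("p1", "p2"), B = c("p3", "p4")),
                     trustedThreshold = 1L)
  e2 <- networkEdges(net2)
  sh <- e2[e2$kind == "patient_patient_shared", ]
  expect_identical(nrow(sh), 2L)
  expect_false(any(sh$source %in% c("p1", "p2") &
                     sh$target %in% c("p3", "p4")))

  ## 3 patients all carrying TP53 (threshold 2 makes it trusted):
  ## frequency 3 and C(3,2) = 3 shared edges
  net <- toyNetwork(list(TP53 = c("p1", "p2", "p3")),
                    trustedThreshold = 2L)
  e <- networkEdges(net)
  pp <- e[e$kind == "patient_protein_cnv", ]
  expect_identical(nrow(pp), 3L)
  expect_true(all(pp$frequency == 3L))
  expect_true(all(pp$trusted))
  expect_identical(sum(e$kind == "patient_patient_shared"), 3L)

  ## at the default strict threshold 10 the same protein is untrusted
  net10 <- toyNetwork(list(TP53 = c("p1", "p2", "p3")),
                      trustedThreshold = 10L)
  expect_false(any(networkEdges(net10)$trusted))
  expect_identical(sum(networkEdges(net10)$kind ==
                         "patient_patient_shared"), 0L)
})

test_that("orphan molecular records are kept as patient nodes", {
  docs <- list(clinicalDoc("p1", 2, 20, 50, 60),
               cnvDoc("p1", list(A = 1)),
               cnvDoc("ghost", list(A = 1)))
  expect_message(net <- buildInternalNetwork(docs), "orphan")
  expect_true("ghost" %in% patientNodes(net))
})

test_that("patientsByProtein matches a brute-force scan", {
  carriers <- list(A = c("p1", "p5"), B = c("p2", "p3", "p5"), C = "p4")
  net <- toyNetwork(carriers, trustedThreshold = 1L)
  expect_identical(patientsByProtein(net, "A"), c("p1", "p5"))
  expect_identical(patientsByProtein(net, "a"), c("p1", "p5"))
  expect_identical(patientsByProtein(net, "ABSENT"), character())
  for (p in names(carriers))
    expect_true(all(patientsByProtein(net, p) %in% patientNodes(net)))
})

test_that("frequencies, bipartiteness and shared edges obey their oracles", {
  set.seed(7)
  for (iter in 1:10) {
    patients <- paste0("p", 1:12)
    prots <- LETTERS[1:6]
    carriers <- lapply(prots, function(p)
      sample(patients, sample(0:8, 1)))
    names(carriers) <- prots
    carriers <- carriers[lengths(carriers) > 0]
    thr <- 3L
    net <- toyNetwork(carriers, allPatients = patients,
                      trustedThreshold = thr)
    e <- networkEdges(net)

    ## bipartite internal layer
    pp <- e[e$kind %in% c("patient_protein_expr", "patient_protein_cnv"), ]
    expect_true(all(pp$source %in% patients))
    expect_true(all(pp$target %in% names(carriers)))

    ## frequency oracle: distinct carriers per protein
    for (p in names(carriers)) {
      fr <- unique(pp$frequency[pp$target == p])
      expect_identical(fr, length(unique(carriers[[p]])))
    }

    ## shared-edge oracle: brute-force pairwise intersection of trusted
    ## protein sets
    trustedProts <- names(carriers)[lengths(lapply(carriers, unique)) > thr]
    expected <- 0L
    for (i in seq_along(patients)) for (j in seq_len(i - 1L)) {
      shared <- sum(vapply(trustedProts, function(p)
        all(c(patients[i], patients[j]) %in% carriers[[p]]), logical(1)))
      if (shared > 0) expected <- expected + 1L
    }
    expect_identical(sum(e$kind == "patient_patient_shared"), expected)
  }
})

test_that("adding a patient never decreases protein frequencies", {
  carriers <- list(A = c("p1", "p2"), B = c("p2", "p3"))
  net1 <- toyNetwork(carriers, trustedThreshold = 1L)
  carriers2 <- list(A = c("p1", "p2", "p4"), B = c("p2", "p3"))
  net2 <- toyNetwork(carriers2, trustedThreshold = 1L)
  for (p in c("A", "B")) {
    f1 <- unique(networkEdges(net1)$frequency[networkEdges(net1)$target == p])
    f2 <- unique(networkEdges(net2)$frequency[networkEdges(net2)$target == p])
    expect_gte(f2, f1)
  }
})

test_that("network export and import round-trip both formats", {
  net <- toyNetwork(list(A = c("p1", "p2"), B = c("p2", "p3", "p4"),
                         C = "p1"), trustedThreshold = 2L)
  sortEdges <- function(e) {
    e <- e[order(e$source, e$target, e$kind), ]
    rownames(e) <- NULL
    e
  }
  for (fmt in c("tsv", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportNetwork(net, path, fmt)
    back <- importNetwork(path, fmt)
    expect_identical(sortEdges(networkEdges(back)),
                     sortEdges(networkEdges(net)))
    expect_setequal(patientNodes(back), patientNodes(net))
    expect_setequal(proteinNodes(back), proteinNodes(net))
    expect_identical(trustedThreshold(back), trustedThreshold(net))
  }

  ## canonical edge order makes the TSV export byte-stable
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  exportNetwork(net, p1, "tsv"); exportNetwork(net, p2, "tsv")
  expect_identical(readLines(p1), readLines(p2))

  ## an empty network still exports valid GraphML
  empty <- new("IntegratedNetwork", patients = character(),
               proteins = character(), edges = TICFnet:::emptyEdgeTable(),
               trustedThreshold = 10L)
  path <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(empty, path, "graphml")
  back <- importNetwork(path, "graphml")
  expect_identical(nrow(networkEdges(back)), 0L)

  expect_error(exportNetwork(net, tempfile(), "xml"), "should be one of")
})
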