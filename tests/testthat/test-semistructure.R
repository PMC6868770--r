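test_that("delimiter discovery picks the consistent, maximal candidate", {
  expect_identical(detectDelimiter(c("a,b,c", "1,2,3")), ",")
  expect_identical(detectDelimiter(c("a\tb", "1\t2")), "\t")
  ## comma gives 3 consistent columns on both lines, tab only 2
  expect_identical(detectDelimiter(c("a,b\tc,d", "1,2\t3,4")), ",")
  ## trailing empty fields still count as columns
  expect_identical(detectDelimiter(c("a,b,", "1,,")), ",")
  expect_error(detectDelimiter(c("abc", "def"), file = "x.txt"),
               "undetectable delimiter.*x\\.txt")
  expect_error(detectDelimiter("only one line"), "at least 2")
})

test_that("header parsing extracts technology, refs and attributes", {
  meta <- parseHeader(c("#technology=RNA-Seq", "#ref=EXP001",
                        "id,stage", "r1,2"))
  expect_identical(meta@technology, "RNA-Seq")
  expect_identical(meta@referencedFileIds, "EXP001")
  expect_identical(meta@attributeNames, c("id", "stage"))
  expect_identical(meta@nDeclaredAttributes, 2L)

  ## degenerate: no commented lines at all
  meta2 <- parseHeader(c("id\tsize", "r1\t10"))
  expect_identical(meta2@technology, "")
  expect_length(meta2@referencedFileIds, 0L)
  expect_identical(meta2@attributeNames, c("id", "size"))

  expect_error(parseHeader(c("#technology=x"), file = "f"),
               "missing attribute header")
})

test_that("folding records builds field counts incrementally", {
  semi <- semiStructure("clinical")
  r1 <- rec("r1", "p1", "clinical", list(a = "1", b = "2"))
  s1 <- foldRecord(semi, r1)
  expect_identical(fieldStats(s1), c(a = 1L, b = 1L))
  expect_identical(recordCount(s1), 1L)
  ## value semantics: the input semi-structure is untouched
  expect_identical(recordCount(semi), 0L)

  ## duplication is counted, not deduplicated
  s2 <- foldRecord(s1, r1)
  expect_identical(fieldStats(s2), c(a = 2L, b = 2L))
  expect_identical(recordCount(s2), 2L)

  expect_error(foldRecord(semi, rec("r", "p", "cnv", list(x = 1))),
               "data_type mismatch")
})

test_that("semi-structure is order-invariant and matches a one-pass count", {
  recs <- list(rec("r1", "p1", "clinical", list(a = "1", b = "2")),
               rec("r2", "p2", "clinical", list(a = "1")),
               rec("r3", "p3", "clinical", list(a = "1", c = "3")))
  expected <- c(a = 3L, b = 1L, c = 1L)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (p in perms) {
    s <- buildSemiStructure(recs[p], "clinical")
    expect_identical(fieldStats(s)[order(names(fieldStats(s)))], expected)
    expect_identical(recordCount(s), 3L)
  }

  ## property: incremental folding == brute-force multiset count, and the
  ## total count is conserved, for random field sets
  set.seed(42)
  pool <- letters[1:8]
  for (i in 1:25) {
    n <- sample(1:6, 1)
    fieldSets <- lapply(seq_len(n), function(j)
      sample(pool, sample(1:5, 1)))
    recs <- lapply(seq_len(n), function(j)
      rec(paste0("r", j), paste0("p", j), "expression",
          stats::setNames(as.list(rep("0", length(fieldSets[[j]]))),
                          fieldSets[[j]])))
    s <- buildSemiStructure(recs, "expression")
    oracle <- table(unlist(fieldSets))                 # one-pass count
    expect_identical(fieldStats(s)[sort(names(fieldStats(s)))],
                     stats::setNames(as.integer(oracle), names(oracle)))
    expect_identical(sum(fieldStats(s)),
                     sum(lengths(fieldSets)))          # conservation
  }
})

test_that("the data schema keeps mandatory ids and known fields only", {
  semi <- buildSemiStructure(
    list(rec("r0", "p0", "clinical", list(stage = "1"))), "clinical")
  doc <- applySchema(rec("r1", "p1", "clinical", list(stage = "2")), semi)
  expect_identical(doc$record_id, "r1")
  expect_identical(doc$sample_id, "p1")
  expect_identical(doc$fields, list(stage = "2"))

  ## unknown fields are projected away with a warning
  expect_warning(
    doc2 <- applySchema(rec("r2", "p2", "clinical",
                            list(stage = "3", foo = "x")), semi),
    "foo")
  expect_false("foo" %in% names(doc2$fields))

  ## a record without a sample id violates the schema
  r <- rec("r3", "p3", "clinical", list(stage = "1"))
  r$sample_id <- ""
  expect_error(applySchema(r, semi), "missing ID/Sample ID")
})

test_that("the document store round-trips and is byte-stable", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  storeDocuments(list(), path)
  expect_identical(loadDocuments(path), list())

  set.seed(1)
  semi <- semiStructure("cnv")
  docs <- lapply(1:100, function(i) {
    flds <- stats::setNames(as.list(as.character(round(rnorm(3), 3))),
                            sample(LETTERS, 3))
    r <- rec(paste0("r", i), paste0("p", i), "cnv", flds)
    semi <<- foldRecord(semi, r)
    r
  })
  docs <- lapply(docs, applySchema, semi = semi)
  storeDocuments(docs, path)
  back <- loadDocuments(path)
  expect_length(back, 100L)
  for (i in seq_along(docs)) {
    expect_identical(back[[i]]$record_id, docs[[i]]$record_id)
    expect_identical(back[[i]]$fields[sort(names(back[[i]]$fields))],
                     docs[[i]]$fields[sort(names(docs[[i]]$fields))])
  }

  path2 <- withr::local_tempfile(fileext = ".ndjson")
  storeDocuments(docs, path2)
  expect_identical(readLines(path), readLines(path2))

  writeLines(c("{\"a\": 1}", "not json"), path2)
  expect_error(loadDocuments(path2), "line 2")
})

test_that("ingestion handles both study dialects end to end", {
  dir <- withr::local_tempdir()
  writeLines(c("#technology=RNA-Seq", "#ref=EXP001",
               "id,sample_id,stage,tumor_size",
               "r1,p1,2,15", "r2,p2,3,40"),
             file.path(dir, "a.csv"))
  writeLines(c("ID\tSampleID\ttumor_stage\tsize_mm",
               "r3\tp3\tIII\t22"),
             file.path(dir, "b.tsv"))
  out <- ingestStudyFiles(c(A = file.path(dir, "a.csv"),
                            B = file.path(dir, "b.tsv")),
                          "clinical", file.path(dir, "store"))
  expect_length(out$documents, 3L)
  expect_identical(recordCount(out$semiStructure), 3L)
  samples <- vapply(out$documents, function(d) d$sample_id, character(1))
  expect_setequal(samples, c("p1", "p2", "p3"))
  ## store round-trip through the written file
  expect_length(loadDocuments(out$storePath), 3L)
})
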