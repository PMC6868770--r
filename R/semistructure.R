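## Horizontal integration: heterogeneous delimited files -> typed records ->
## incrementally inferred semi-structures -> schema-validated documents in a
## line-delimited document store.

DELIMITER_CANDIDATES <- c(tab = "\t", comma = ",", semicolon = ";")

#' Discover the delimiter of a delimited text file
#'
#' Tries tab, comma and semicolon on the sampled lines and keeps the
#' candidate that splits every line into the same number (>= 2) of
#' columns; among consistent candidates the one with the most columns
#' wins, ties broken in the order tab, comma, semicolon.
#'
#' @param rawLines character vector of data lines (header lines excluded);
#'   at least 2 lines are required.
#' @param file file name used in error messages.
#' @return The delimiter character.
#' @examples
#' detectDelimiter(c("a,b,c", "1,2,3"))
#' @export
detectDelimiter <- function(rawLines, file = "<lines>") {
  rawLines <- rawLines[nzchar(rawLines)]
  if (length(rawLines) < 2L)
    stop("need at least 2 non-empty lines to detect a delimiter in ", file)
  best <- NULL
  bestCols <- 1L
  for (cand in DELIMITER_CANDIDATES) {
    ## occurrence count + 1, so trailing empty fields still count
    cols <- nchar(rawLines) - nchar(gsub(cand, "", rawLines,
                                         fixed = TRUE)) + 1L
    if (length(unique(cols)) == 1L && cols[1L] >= 2L && cols[1L] > bestCols) {
      best <- cand
      bestCols <- cols[1L]
    }
  }
  if (is.null(best))
    stop("undetectable delimiter in ", file,
         ": no candidate splits all lines into a constant column count >= 2")
  best
}

#' Parse the header block of a study file
#'
#' Header lines carry a comment prefix (default `"#"`) and hold `key=value`
#' metadata: the generating technology and references to other files. The
#' first unprefixed line is the attribute row naming the columns. Multiple
#' candidate attribute rows are resolved first-match (flagged via message).
#'
#' @param rawLines all lines of the file.
#' @param headerPrefix comment prefix marking header lines.
#' @param delimiter delimiter for the attribute row; auto-detected from the
#'   data lines when `NULL`.
#' @param file file name used in messages.
#' @return A [FileHeaderMeta-class].
#' @export
parseHeader <- function(rawLines, headerPrefix = "#", delimiter = NULL,
                        file = "<lines>") {
  isHeader <- startsWith(rawLines, headerPrefix)
  headerEnd <- match(FALSE, isHeader, nomatch = length(rawLines) + 1L) - 1L
  headerLines <- rawLines[seq_len(headerEnd)]
  body <- rawLines[seq.int(headerEnd + 1L, length.out = length(rawLines) - headerEnd)]
  body <- body[nzchar(body)]
  if (!length(body))
    stop("missing attribute header in ", file)

  technology <- character()
  refs <- character()
  nDeclared <- NA_integer_
  for (h in headerLines) {
    h <- sub(paste0("^", headerPrefix, "\\s*"), "", h)
    if (!grepl("=", h, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", h)))
    val <- trimws(sub("^[^=]*=", "", h))
    if (key == "technology") technology <- val
    else if (key %in% c("ref", "reference", "file_ref", "refs"))
      refs <- c(refs, trimws(strsplit(val, ",", fixed = TRUE)[[1L]]))
    else if (key %in% c("attributes", "n_attributes"))
      nDeclared <- suppressWarnings(as.integer(val))
  }
  if (is.null(delimiter)) {
    delimiter <- if (length(body) >= 2L) detectDelimiter(body, file = file)
                 else detectDelimiter(rep(body, 2L), file = file)
  }
  attributeNames <- trimws(strsplit(body[1L], delimiter, fixed = TRUE)[[1L]])
  if (is.na(nDeclared)) nDeclared <- length(attributeNames)
  new("FileHeaderMeta",
      technology = if (length(technology)) technology else "",
      attributeNames = attributeNames,
      referencedFileIds = refs,
      nDeclaredAttributes = nDeclared)
}

#' Construct a raw record
#'
#' One parsed record of any data type. Every record carries the mandatory
#' record id and sample id (the subject name) in addition to its fields.
#'
#' @param recordId,sampleId non-empty identifier strings.
#' @param dataType one of `"clinical"`, `"expression"`, `"cnv"`.
#' @param fields named list of field values (names unique).
#' @param sourceFile,sourceStudy provenance strings.
#' @return A list of class `RawRecord`.
#' @export
rawRecord <- function(recordId, sampleId, dataType, fields,
                      sourceFile = "", sourceStudy = "") {
  if (!nzchar(recordId)) stop("record_id must be non-empty")
  if (!nzchar(sampleId)) stop("sample_id must be non-empty")
  if (!dataType %in% DATA_TYPES)
    stop("data_type must be one of ", paste(DATA_TYPES, collapse = ", "))
  if (length(fields) && (is.null(names(fields)) ||
                         anyDuplicated(names(fields))))
    stop("field names must be present and unique within a record")
  structure(list(record_id = recordId, sample_id = sampleId,
                 data_type = dataType, fields = as.list(fields),
                 source_file = sourceFile, source_study = sourceStudy),
            class = "RawRecord")
}

#' Fold one record into a semi-structure
#'
#' Increments the record count and the occurrence count of every field name
#' in the record (inserting new names at count 1). The input semi-structure
#' is not mutated; a new object is returned.
#'
#' @param semi a [SemiStructure-class].
#' @param record a record created by [rawRecord()].
#' @return The updated `SemiStructure`.
#' @export
foldRecord <- function(semi, record) {
  if (!identical(record$data_type, semi@dataType))
    stop(sprintf("data_type mismatch: record is '%s', semi-structure is '%s'",
                 record$data_type, semi@dataType))
  stats <- semi@fieldStats
  for (nm in names(record$fields)) {
    stats[nm] <- if (nm %in% names(stats)) stats[[nm]] + 1L else 1L
  }
  new("SemiStructure", dataType = semi@dataType,
      fieldStats = stats, recordCount = semi@recordCount + 1L)
}

#' Build a semi-structure over a record collection
#'
#' @param records list of records of one data type.
#' @param dataType the collection's data type.
#' @return A [SemiStructure-class].
#' @export
buildSemiStructure <- function(records, dataType) {
  semi <- semiStructure(dataType)
  for (r in records) semi <- foldRecord(semi, r)
  semi
}

#' Validate a record against the data schema
#'
#' Applies the schema restriction derived from the semi-structure: the
#' document keeps the mandatory record and sample ids plus only fields the
#' semi-structure has seen; unknown fields are dropped (with a warning).
#' Records lacking either mandatory id are rejected.
#'
#' @param record a record from [rawRecord()].
#' @param semi the [SemiStructure-class] built over the record's data type.
#' @return A validated document (named list).
#' @export
applySchema <- function(record, semi) {
  if (is.null(record$record_id) || !nzchar(record$record_id) ||
      is.null(record$sample_id) || !nzchar(record$sample_id))
    stop("schema violation: missing ID/Sample ID")
  if (!identical(record$data_type, semi@dataType))
    stop("record data_type does not match the semi-structure")
  known <- names(record$fields) %in% names(semi@fieldStats)
  if (any(!known))
    warning(sprintf("dropping %d field(s) unknown to the %s semi-structure: %s",
                    sum(!known), semi@dataType,
                    paste(names(record$fields)[!known], collapse = ", ")))
  list(record_id = record$record_id,
       sample_id = record$sample_id,
       data_type = record$data_type,
       source_file = record$source_file,
       source_study = record$source_study,
       fields = record$fields[known])
}

canonicalizeDoc <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, canonicalizeDoc)
  } else x
}

#' Store and load validated documents
#'
#' The embedded document store is line-delimited JSON with canonically
#' sorted keys, so storing the same documents twice yields byte-identical
#' files and `loadDocuments(storeDocuments(docs))` is the identity.
#'
#' @param documents list of documents from [applySchema()].
#' @param path store file path.
#' @return `storeDocuments` returns `path` invisibly; `loadDocuments`
#'   returns the list of documents.
#' @export
storeDocuments <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    as.character(jsonlite::toJSON(canonicalizeDoc(d), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname storeDocuments
#' @export
loadDocuments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    doc <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(doc))
      stop(sprintf("malformed document at %s line %d", path, i))
    docs[[i]] <- doc
  }
  docs
}

## --- file ingestion ----------------------------------------------------

CLINICAL_ALIASES <- list(
  record_id = c("id", "record_id", "patient_id", "patientid"),
  sample_id = c("sample_id", "sampleid", "sample id", "sample", "subject"),
  stage = c("stage", "tumor_stage", "tumour_stage", "tumor stage"),
  size = c("size", "tumor_size", "tumour_size", "size_mm", "tumor_size_mm",
           "tumor size"),
  age = c("age", "age_at_diagnosis", "age at diagnosis", "age_years"),
  survival_months = c("survival_months", "os_months", "survival",
                      "overall_survival_months", "months_survival"))

matchAlias <- function(columns, aliases) {
  hit <- match(aliases, tolower(trimws(columns)))
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1L] else NA_integer_
}

#' Ingest one delimited study file into raw records
#'
#' Reads a clinical table (one row per patient) or a molecular matrix
#' (proteins x patients; first column the Hugo symbol) written in any of
#' the supported delimiter dialects, parses the commented header, and
#' returns one [rawRecord()] per patient. Clinical column names are kept
#' verbatim as field names; molecular field names are the uppercased Hugo
#' symbols.
#'
#' @param path file to read.
#' @param dataType `"clinical"`, `"expression"` or `"cnv"`.
#' @param study study label recorded in each record.
#' @param headerPrefix comment prefix of the header block.
#' @return list with elements `records` and `header`
#'   (a [FileHeaderMeta-class]).
#' @export
ingestFile <- function(path, dataType, study, headerPrefix = "#") {
  stopifnot(dataType %in% DATA_TYPES)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  isHeader <- startsWith(lines, headerPrefix)
  headerEnd <- match(FALSE, isHeader, nomatch = length(lines) + 1L) - 1L
  body <- lines[seq.int(headerEnd + 1L, length.out = length(lines) - headerEnd)]
  if (length(body) < 2L)
    stop("no data rows in ", path)
  delim <- detectDelimiter(body, file = path)
  header <- parseHeader(lines, headerPrefix = headerPrefix,
                        delimiter = delim, file = path)
  cells <- strsplit(body, delim, fixed = TRUE)
  columns <- trimws(cells[[1L]])
  rows <- cells[-1L]

  records <- if (dataType == "clinical") {
    idCol <- matchAlias(columns, CLINICAL_ALIASES$record_id)
    sampleCol <- matchAlias(columns, CLINICAL_ALIASES$sample_id)
    if (is.na(sampleCol))
      stop("no sample-id column recognised in ", path)
    lapply(seq_along(rows), function(i) {
      vals <- trimws(rows[[i]])
      length(vals) <- length(columns)
      vals[is.na(vals)] <- ""
      sampleId <- vals[sampleCol]
      recId <- if (!is.na(idCol) && nzchar(vals[idCol])) vals[idCol]
               else sprintf("%s:%s:row%d", study, basename(path), i)
      keep <- setdiff(seq_along(columns), c(idCol, sampleCol))
      keep <- keep[nzchar(vals[keep])]
      rawRecord(recId, sampleId, "clinical",
                stats::setNames(as.list(vals[keep]), columns[keep]),
                sourceFile = basename(path), sourceStudy = study)
    })
  } else {
    ## molecular matrix: column 1 = protein symbol, remaining = patients
    sampleIds <- columns[-1L]
    proteins <- toupper(vapply(rows, `[[`, character(1L), 1L))
    valueMat <- do.call(rbind, lapply(rows, function(v) {
      length(v) <- length(columns)
      v[-1L]
    }))
    lapply(seq_along(sampleIds), function(j) {
      vals <- trimws(valueMat[, j])
      keep <- nzchar(vals) & !is.na(vals)
      rawRecord(sprintf("%s:%s:%s", study, dataType, sampleIds[j]),
                sampleIds[j], dataType,
                stats::setNames(as.list(vals[keep]), proteins[keep]),
                sourceFile = basename(path), sourceStudy = study)
    })
  }
  list(records = records, header = header)
}

#' Ingest study files into a document store
#'
#' Runs the full horizontal-integration path for one data type: ingest
#' every file, infer the semi-structure incrementally over all records,
#' validate each record against the resulting data schema, and write the
#' surviving documents to a line-delimited store under `storeDir`.
#'
#' @param files named character vector of file paths; names are study
#'   labels (unnamed files fall back to `study`).
#' @param dataType `"clinical"`, `"expression"` or `"cnv"`.
#' @param storeDir directory of the document store (created if needed).
#' @param study fallback study label.
#' @param headerPrefix header comment prefix.
#' @return list with `documents`, `semiStructure` and `storePath`.
#' @export
ingestStudyFiles <- function(files, dataType, storeDir, study = "study",
                             headerPrefix = "#") {
  studies <- names(files)
  if (is.null(studies)) studies <- rep(study, length(files))
  studies[!nzchar(studies)] <- study
  records <- list()
  for (i in seq_along(files)) {
    ing <- ingestFile(files[[i]], dataType, studies[[i]],
                      headerPrefix = headerPrefix)
    records <- c(records, ing$records)
  }
  semi <- buildSemiStructure(records, dataType)
  documents <- lapply(records, applySchema, semi = semi)
  if (!dir.exists(storeDir)) dir.create(storeDir, recursive = TRUE)
  storePath <- file.path(storeDir, paste0(dataType, ".ndjson"))
  storeDocuments(documents, storePath)
  summaryPath <- file.path(storeDir, paste0(dataType, "_semistructure.json"))
  jsonlite::write_json(
    list(data_type = dataType,
         record_count = semi@recordCount,
         field_stats = as.list(semi@fieldStats)),
    summaryPath, auto_unbox = TRUE, digits = NA)
  list(documents = documents, semiStructure = semi, storePath = storePath)
}
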