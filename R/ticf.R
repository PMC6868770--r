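## The Tumor Integrated Clinical Feature (TICF): fixed-order numeric
## concatenation of tumor stage, tumor size and age at diagnosis, its
## normalization, quantile stratification and nearest-neighbour queries.

#' Build the TICF composite
#'
#' Concatenates tumor stage, tumor size (mm) and age at diagnosis
#' (years), in this exact order, as fixed-width zero-padded digits, so
#' the numeric order of composites equals the lexicographic order of
#' (stage, size, age): stage dominates, then size, then age. With the
#' default widths (1, 3, 3) the composite is
#' `stage * 10^6 + size * 10^3 + age`.
#'
#' @param stage tumor stage, integer 1-4 (vectorized).
#' @param size tumor size in mm, `0 < size < 10^widths[2]`.
#' @param age age at diagnosis in years, `0 < age < 10^widths[3]`.
#' @param widths digit widths of the three components.
#' @return numeric composite(s).
#' @examples
#' buildTICF(2, 15, 47)   # 2015047
#' @export
buildTICF <- function(stage, size, age, widths = c(1L, 3L, 3L)) {
  if (anyNA(stage) || anyNA(size) || anyNA(age))
    stop("TICF undefined for patient: missing stage, size or age")
  stage <- as.integer(stage); size <- as.integer(size); age <- as.integer(age)
  if (any(stage < 1L | stage > 4L))
    stop("tumor stage must be an integer in 1..4")
  if (any(size < 1L | size >= 10^widths[2L]))
    stop(sprintf("tumor size must lie in 1..%d mm (width overflow)",
                 10^widths[2L] - 1L))
  if (any(age < 1L | age >= 10^widths[3L]))
    stop(sprintf("age must lie in 1..%d years (width overflow)",
                 10^widths[3L] - 1L))
  stage * 10^(widths[2L] + widths[3L]) + size * 10^widths[3L] + age
}

#' Decompose a TICF composite
#'
#' Exact inverse of [buildTICF()] under the same widths.
#'
#' @param composite composite value(s).
#' @param widths digit widths used to build the composite.
#' @return list with integer vectors `stage`, `size`, `age`.
#' @export
decomposeTICF <- function(composite, widths = c(1L, 3L, 3L)) {
  m2 <- 10^widths[3L]
  m1 <- 10^(widths[2L] + widths[3L])
  stage <- composite %/% m1
  rest <- composite %% m1
  list(stage = as.integer(stage),
       size = as.integer(rest %/% m2),
       age = as.integer(rest %% m2))
}

#' Normalize values by removing the mean and scaling to unit variance
#'
#' Population mean/SD normalization with the state stored for later
#' patients. A constant input is degenerate: it maps to zeros and the
#' state is flagged, rather than dividing by zero.
#'
#' @param values numeric vector (length >= 1).
#' @return list with `normalized` and `state`
#'   (a [NormalizationState-class]).
#' @export
normalizeValues <- function(values) {
  if (!length(values)) stop("cannot normalize an empty vector")
  mu <- mean(values)
  sdv <- sqrt(mean((values - mu)^2))
  if (sdv == 0) {
    list(normalized = rep(0, length(values)),
         state = new("NormalizationState", mean = mu, sd = 0,
                     degenerate = TRUE))
  } else {
    list(normalized = (values - mu) / sdv,
         state = new("NormalizationState", mean = mu, sd = sdv,
                     degenerate = FALSE))
  }
}

#' Transform new values with a stored normalization state
#'
#' @param values numeric vector.
#' @param state a [NormalizationState-class] from [normalizeValues()].
#' @return normalized values (zeros under a degenerate state).
#' @export
applyNormalization <- function(values, state) {
  if (state@degenerate) rep(0, length(values))
  else (values - state@mean) / state@sd
}

#' Stratify patients into near-equal groups by normalized TICF
#'
#' Patients are sorted by normalized TICF (ties broken by sample id) and
#' cut into `k` contiguous groups whose sizes differ by at most one
#' (earlier groups take the remainder). Deterministic.
#'
#' @param normalized normalized TICF values.
#' @param sampleIds patient ids aligned with `normalized`.
#' @param k number of groups (default 5).
#' @return named integer vector: group index (1..k) per patient, in the
#'   input order of `sampleIds`.
#' @export
stratifyPatients <- function(normalized, sampleIds, k = 5L) {
  n <- length(normalized)
  stopifnot(length(sampleIds) == n)
  if (n < k)
    stop(sprintf("cannot split %d patients into %d groups; use a smaller k",
                 n, k))
  ord <- order(normalized, sampleIds)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  groupSorted <- rep(seq_len(k), times = sizes)
  groups <- integer(n)
  groups[ord] <- groupSorted
  stats::setNames(groups, sampleIds)
}

#' Nearest patients by TICF distance
#'
#' The `m` patients whose normalized TICF is closest (in absolute
#' difference) to the query patient's, ties broken by sample id; the
#' query itself is excluded.
#'
#' @param querySampleId the studied patient (must have a defined TICF).
#' @param ticf a [TICFTable-class].
#' @param m number of neighbours.
#' @return character vector of sample ids, nearest first.
#' @export
nearestPatients <- function(querySampleId, ticf, m) {
  tab <- ticf@table
  qi <- match(querySampleId, tab$sampleId)
  if (is.na(qi))
    stop("patient '", querySampleId, "' has no defined TICF")
  others <- tab[-qi, , drop = FALSE]
  d <- abs(others$normalized - tab$normalized[qi])
  others$sampleId[order(d, others$sampleId)][seq_len(min(m, nrow(others)))]
}

## --- clinical field extraction ----------------------------------------

ROMAN_STAGES <- c(i = 1L, ii = 2L, iii = 3L, iv = 4L)

#' Normalize a tumor-stage annotation to an integer
#'
#' Accepts plain integers ("3"), roman numerals ("III"), and prefixed
#' forms ("stage 3", "Stage III"). Unmappable annotations yield NA (the
#' patient's TICF is then undefined).
#'
#' @param stage character or numeric vector of stage annotations.
#' @return integer vector with NA for unmappable values.
#' @export
normalizeStage <- function(stage) {
  s <- tolower(trimws(as.character(stage)))
  s <- sub("^stage[ _]*", "", s)
  out <- suppressWarnings(as.integer(s))
  roman <- !is.na(match(s, names(ROMAN_STAGES)))
  out[roman] <- ROMAN_STAGES[s[roman]]
  out[!is.na(out) & (out < 1L | out > 4L)] <- NA_integer_
  out
}

normalizeSizeMm <- function(size) {
  v <- suppressWarnings(as.numeric(as.character(size)))
  ## heuristic: small values written with a decimal point are centimetres
  cm <- !is.na(v) & v < 10 & grepl("\\.", as.character(size))
  if (any(cm))
    message(sprintf("%d tumor size value(s) interpreted as cm and converted to mm",
                    sum(cm)))
  v[cm] <- v[cm] * 10
  out <- as.integer(round(v))
  out[!is.na(out) & out < 1L] <- NA_integer_
  out
}

clinicalField <- function(doc, aliases) {
  nm <- names(doc$fields)
  hit <- match(aliases, tolower(trimws(nm)))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(NA_character_)
  v <- doc$fields[[hit[1L]]]
  if (is.null(v) || !nzchar(as.character(v)[1L])) NA_character_
  else as.character(v)[1L]
}

#' Extract canonical clinical variables from clinical documents
#'
#' Maps study-specific field aliases to the canonical variables stage,
#' size (mm), age (years) and survival months, normalizing stage strings
#' and size units. Duplicate sample ids keep the first document in
#' canonical (record id) order.
#'
#' @param documents clinical documents.
#' @return data.frame(sampleId, stage, size, age, survivalMonths).
#' @export
clinicalVariables <- function(documents) {
  documents <- Filter(function(d) identical(d$data_type, "clinical"),
                      documents)
  if (!length(documents))
    return(data.frame(sampleId = character(), stage = integer(),
                      size = integer(), age = integer(),
                      survivalMonths = numeric()))
  out <- data.frame(
    sampleId = vapply(documents, function(d) as.character(d$sample_id),
                      character(1L)),
    recordId = vapply(documents, function(d) as.character(d$record_id),
                      character(1L)),
    stage = normalizeStage(vapply(documents, clinicalField, character(1L),
                                  CLINICAL_ALIASES$stage)),
    size = normalizeSizeMm(vapply(documents, clinicalField, character(1L),
                                  CLINICAL_ALIASES$size)),
    age = as.integer(round(suppressWarnings(as.numeric(
      vapply(documents, clinicalField, character(1L),
             CLINICAL_ALIASES$age))))),
    survivalMonths = suppressWarnings(as.numeric(
      vapply(documents, clinicalField, character(1L),
             CLINICAL_ALIASES$survival_months))),
    stringsAsFactors = FALSE)
  out <- out[order(out$recordId), , drop = FALSE]
  dup <- duplicated(out$sampleId)
  if (any(dup))
    message(sprintf("%d duplicate clinical record(s) dropped (first kept)",
                    sum(dup)))
  out <- out[!dup, , drop = FALSE]
  out$recordId <- NULL
  rownames(out) <- NULL
  out
}

#' Build the cohort TICF table
#'
#' Computes the TICF composite for every patient with complete stage,
#' size and age, normalizes the composites (mean/SD stored), and
#' stratifies the patients into `k` near-equal groups. Patients with any
#' missing component have no TICF and are excluded (reported via
#' message).
#'
#' @param documents clinical documents.
#' @param k number of stratification groups (default 5).
#' @param widths digit widths of the composite.
#' @return A [TICFTable-class].
#' @export
buildTICFTable <- function(documents, k = 5L, widths = c(1L, 3L, 3L)) {
  cl <- clinicalVariables(documents)
  defined <- !is.na(cl$stage) & !is.na(cl$size) & !is.na(cl$age)
  if (any(!defined))
    message(sprintf("%d patient(s) lack a defined TICF and are excluded",
                    sum(!defined)))
  cl <- cl[defined, , drop = FALSE]
  if (!nrow(cl)) stop("no patient has a defined TICF")
  composite <- buildTICF(cl$stage, cl$size, cl$age, widths = widths)
  nz <- normalizeValues(composite)
  groups <- stratifyPatients(nz$normalized, cl$sampleId, k = k)
  tab <- data.frame(sampleId = cl$sampleId, stage = cl$stage,
                    size = cl$size, age = cl$age,
                    composite = composite, normalized = nz$normalized,
                    group = as.integer(groups),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$sampleId), , drop = FALSE]
  rownames(tab) <- NULL
  new("TICFTable", table = tab, state = nz$state,
      widths = as.integer(widths), k = as.integer(k))
}
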