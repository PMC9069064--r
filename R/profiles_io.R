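# Readers/writers for the package's tabular formats. All files are
# tab-delimited UTF-8 with '.' decimal; floats are serialised at 15
# significant digits so that write-then-read round-trips are stable well
# below 1e-12 relative error and re-serialisation is byte-stable; missing
# values are written as "NA" and propagated as missing, never imputed.

.FLOAT_DIGITS <- 15L

#' Read / write a relative-abundance matrix
#'
#' The on-disk layout is a TSV whose header row holds feature ids, whose
#' first column (`sample_id`) holds sample ids and whose body holds
#' non-negative relative abundances. Row order is preserved.
#'
#' @param path file path.
#' @return `readAbundance()`: a samples x features numeric matrix with
#'   dimnames. `writeAbundance()`: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' writeAbundance(m, f)
#' stopifnot(all.equal(readAbundance(f), m))
#' @export
readAbundance <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("abundance file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nc <- length(header)
  featureIds <- header[-1L]
  if (anyDuplicated(featureIds)) stop("duplicate feature ids in ", path)
  body <- fields[-1L]
  ragged <- which(lengths(body) != nc)
  if (length(ragged))
    stop(sprintf("ragged row %d in %s (expected %d fields, got %d)",
                 ragged[1L] + 1L, path, nc, lengths(body)[ragged[1L]]))
  sampleIds <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id '",
         sampleIds[duplicated(sampleIds)][1L], "' in ", path)
  vals <- matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
                 nrow = length(body), ncol = nc - 1L, byrow = TRUE,
                 dimnames = list(sampleIds, featureIds))
  bad <- which(is.na(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid abundance at sample '%s', feature '%s' in %s",
                 sampleIds[bad[1L, 1L]], featureIds[bad[1L, 2L]], path))
  if (any(rowSums(vals) > 1 + 1e-9))
    stop("per-sample abundance sums exceed 1 in ", path)
  vals
}

#' @param mat samples x features matrix with dimnames.
#' @rdname readAbundance
#' @export
writeAbundance <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(formatC(r, digits = .FLOAT_DIGITS, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write per-sample clinical metadata
#'
#' TSV with one row per sample carrying patient id, timepoint label and week
#' offset, RECIST response group, antibiotics flag, BMI, TMB, HLA-E level
#' and (censored) progression-free survival. Missing entries are "NA".
#'
#' @param path file path.
#' @return `readSampleMeta()`: a data.frame. `writeSampleMeta()`: the path,
#'   invisibly.
#' @export
readSampleMeta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  miss <- setdiff(.META_COLS, colnames(df))
  if (length(miss))
    stop("metadata file missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  if (any(!is.na(df$week) & df$week < 0)) stop("negative week offset in ", path)
  if (any(!is.na(df$pfs_months) & df$pfs_months <= 0))
    stop("pfs_months must be > 0 in ", path)
  df$atb <- as.logical(df$atb)
  df$pfs_event <- as.logical(df$pfs_event)
  df
}

#' @param meta data.frame as returned by [sampleMeta()].
#' @rdname readSampleMeta
#' @export
writeSampleMeta <- function(meta, path) {
  out <- meta
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], formatC, digits = .FLOAT_DIGITS, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' TSV with columns `mgs_id`, `class`, `genus`, `species`
#' ("unclassified" where no species was assigned).
#'
#' @param path file path.
#' @return `readTaxonomy()`: a data.frame. `writeTaxonomy()`: the path,
#'   invisibly.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  need <- c("mgs_id", "class", "genus", "species")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("taxonomy file missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.na(df$species) & df$species != "unclassified" &
    (is.na(df$genus) | df$genus == "")
  if (any(bad))
    stop("taxonomy rows with species but empty genus: ",
         paste(utils::head(df$mgs_id[bad], 3), collapse = ", "))
  df
}

#' @param taxonomy data.frame as returned by [taxonomyMap()].
#' @rdname readTaxonomy
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a GMT pathway-membership file
#'
#' Standard GMT: one pathway per line, tab-separated as
#' `pathway_id<TAB>description<TAB>KO1<TAB>KO2...`. The description field
#' carries `name; category` so the level-1 KEGG category round-trips.
#'
#' @param path file path.
#' @return `readGMT()`: a list with `map` (named list pathway -> KO ids) and
#'   `info` (data.frame pathway_id, name, category). `writeGMT()`: the path,
#'   invisibly.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line without members: line ", which(short)[1L], " in ", path)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in ", path)
  desc <- vapply(fields, `[[`, "", 2L)
  map <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(map) <- ids
  parts <- strsplit(desc, "; ", fixed = TRUE)
  info <- data.frame(
    pathway_id = ids,
    name = vapply(parts, `[[`, "", 1L),
    category = vapply(parts, function(p)
      if (length(p) > 1L) p[[2L]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  list(map = map, info = info)
}

#' @param map named list, pathway id -> character vector of KO ids.
#' @param info optional data.frame (pathway_id, name, category).
#' @rdname readGMT
#' @export
writeGMT <- function(map, path, info = NULL) {
  stopifnot(length(map) > 0, !is.null(names(map)))
  if (any(!lengths(map))) stop("empty pathway in map")
  desc <- if (is.null(info)) names(map) else {
    i <- match(names(map), info$pathway_id)
    ifelse(is.na(info$category[i]), info$name[i],
           paste(info$name[i], info$category[i], sep = "; "))
  }
  writeLines(vapply(seq_along(map), function(k)
    paste(c(names(map)[k], desc[k], map[[k]]), collapse = "\t"), ""),
    con = path, useBytes = FALSE)
  invisible(path)
}

#' Write / read a whole cohort directory
#'
#' Serialises an [ICTCohort-class] to a directory of plain-text files
#' (`mgs_abundance.tsv`, `ko_abundance.tsv`, `meta.tsv`, `taxonomy.tsv`,
#' `pathways.gmt`) and reads it back. The planted-truth record of a
#' synthetic cohort is not serialised.
#'
#' @param cohort an ICTCohort.
#' @param dir directory (created if needed).
#' @return `writeCohort()`: `dir`, invisibly; `readCohort()`: an ICTCohort.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "ICTCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAbundance(mgsAbundance(cohort), file.path(dir, "mgs_abundance.tsv"))
  writeAbundance(koAbundance(cohort), file.path(dir, "ko_abundance.tsv"))
  writeSampleMeta(sampleMeta(cohort), file.path(dir, "meta.tsv"))
  writeTaxonomy(taxonomyMap(cohort), file.path(dir, "taxonomy.tsv"))
  writeGMT(pathwayMap(cohort), file.path(dir, "pathways.gmt"),
           info = pathwayInfo(cohort))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  gmt <- readGMT(file.path(dir, "pathways.gmt"))
  ICTCohort(readAbundance(file.path(dir, "mgs_abundance.tsv")),
            readAbundance(file.path(dir, "ko_abundance.tsv")),
            readSampleMeta(file.path(dir, "meta.tsv")),
            pathways = gmt$map, pathwayInfo = gmt$info,
            taxonomy = readTaxonomy(file.path(dir, "taxonomy.tsv")))
}

#' Cross-validate abundance samples against metadata
#'
#' Reports samples missing metadata, metadata rows without a matching sample
#' ("orphan metadata") and the samples flagged for exclusion because the
#' patient received antibiotics during therapy. When `excludeATB = TRUE`
#' the returned sample view drops the antibiotics-exposed patients, the
#' exclusion applied in the study design this package follows.
#'
#' @param abund samples x features abundance matrix, or an
#'   [ICTCohort-class] (its MGS table is used).
#' @param meta per-sample metadata data.frame; taken from the cohort when
#'   `abund` is an ICTCohort.
#' @param excludeATB drop antibiotics-exposed patients from the validated
#'   view (default TRUE).
#' @return A list with `validSamples` (character vector defining the
#'   validated view), `orphanSamples`, `orphanMeta`, `atbExcluded`
#'   (sample ids dropped for antibiotics exposure), `nPatients`
#'   (patients in the validated view) and `issues` (character log; empty
#'   for fully consistent inputs).
#' @examples
#' ch <- generateCohort(cohortConfig(nPatients = 20, nMGS = 40, nKO = 60,
#'                                   nPathways = 6, seed = 3))
#' rep <- validateCohort(ch)
#' rep$nPatients
#' @export
validateCohort <- function(abund, meta = NULL, excludeATB = TRUE) {
  if (is(abund, "ICTCohort")) {
    meta <- sampleMeta(abund)
    abund <- mgsAbundance(abund)
  }
  stopifnot(is.matrix(abund), is.data.frame(meta))
  samples <- rownames(abund)
  orphanSamples <- setdiff(samples, meta$sample_id)
  orphanMeta <- setdiff(meta$sample_id, samples)
  common <- intersect(samples, meta$sample_id)
  if (!length(common))
    stop("no overlap between abundance samples and metadata")
  issues <- character()
  if (length(orphanSamples))
    issues <- c(issues, sprintf("%d sample(s) missing metadata",
                                length(orphanSamples)))
  if (length(orphanMeta))
    issues <- c(issues, sprintf("%d orphan metadata row(s)",
                                length(orphanMeta)))
  m <- meta[match(common, meta$sample_id), ]
  atbSamples <- m$sample_id[isTRUE(excludeATB) & m$atb %in% TRUE]
  valid <- setdiff(common, atbSamples)
  list(validSamples = valid,
       orphanSamples = orphanSamples,
       orphanMeta = orphanMeta,
       atbExcluded = atbSamples,
       nPatients = length(unique(m$patient_id[m$sample_id %in% valid])),
       issues = issues)
}

#' Summarise cohort composition
#'
#' Tallies patients by response group and by responder status (progression-
#' free survival strictly beyond `cutoff` months) and reports integer-rounded
#' percentages, the headline arithmetic of a cohort report.
#'
#' @param meta per-sample metadata data.frame or an [ICTCohort-class].
#' @param cutoff responder PFS cutoff in months (default 3).
#' @return A list with `nPatients`, `groupCounts`, `groupPercent`
#'   (integer-rounded), `nResponders`, `nNonResponders`, `responderPercent`
#'   and `nonResponderPercent`.
#' @export
summarizeResponse <- function(meta, cutoff = 3) {
  if (is(meta, "ICTCohort")) meta <- sampleMeta(meta)
  pat <- meta[!duplicated(meta$patient_id), ]
  n <- nrow(pat)
  cnt <- table(factor(pat$response, levels = .GROUP_ORDER))
  lab <- classifyResponders(pat$pfs_months, pat$pfs_event, cutoff)
  nR <- sum(lab == "R", na.rm = TRUE)
  nNR <- sum(lab == "NR", na.rm = TRUE)
  list(nPatients = n,
       groupCounts = cnt,
       groupPercent = round(100 * as.numeric(cnt) / n) |>
         stats::setNames(names(cnt)),
       nResponders = nR, nNonResponders = nNR,
       responderPercent = round(100 * nR / n),
       nonResponderPercent = round(100 * nNR / n))
}
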