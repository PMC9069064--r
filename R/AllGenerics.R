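#' Accessors for ICTCohort objects
#'
#' `mgsAbundance()` and `koAbundance()` return samples x features matrices of
#' relative abundances (the transpose of the internal feature-by-sample
#' storage, matching the on-disk TSV layout). `sampleMeta()` returns the
#' per-sample clinical table as a data.frame, `pathwayMap()` the pathway ->
#' KO membership list, `pathwayInfo()` the pathway annotation table,
#' `taxonomyMap()` the MGS taxonomy and `cohortTruth()` the planted-structure
#' record of a synthetic cohort (an empty list for real data).
#'
#' @param x an [ICTCohort-class] object.
#' @return See individual descriptions.
#' @aliases mgsAbundance koAbundance sampleMeta pathwayMap pathwayInfo
#'   taxonomyMap cohortTruth
#' @name cohort-accessors
#' @examples
#' cfg <- cohortConfig(nPatients = 12, nMGS = 40, nKO = 60, nPathways = 6,
#'                     seed = 1)
#' ch <- generateCohort(cfg)
#' dim(mgsAbundance(ch))
#' head(sampleMeta(ch))
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("mgsAbundance", function(x) standardGeneric("mgsAbundance"))
#' @rdname cohort-accessors
#' @export
setGeneric("koAbundance", function(x) standardGeneric("koAbundance"))
#' @rdname cohort-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname cohort-accessors
#' @export
setGeneric("pathwayMap", function(x) standardGeneric("pathwayMap"))
#' @rdname cohort-accessors
#' @export
setGeneric("pathwayInfo", function(x) standardGeneric("pathwayInfo"))
#' @rdname cohort-accessors
#' @export
setGeneric("taxonomyMap", function(x) standardGeneric("taxonomyMap"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
setMethod("mgsAbundance", "ICTCohort", function(x)
  t(SummarizedExperiment::assay(x@mgs)))
#' @rdname cohort-accessors
setMethod("koAbundance", "ICTCohort", function(x)
  t(SummarizedExperiment::assay(x@ko)))
#' @rdname cohort-accessors
setMethod("sampleMeta", "ICTCohort", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x@mgs))
  rownames(df) <- NULL
  df
})
#' @rdname cohort-accessors
setMethod("pathwayMap", "ICTCohort", function(x) x@pathways)
#' @rdname cohort-accessors
setMethod("pathwayInfo", "ICTCohort", function(x) x@pathwayInfo)
#' @rdname cohort-accessors
setMethod("taxonomyMap", "ICTCohort", function(x) x@taxonomy)
#' @rdname cohort-accessors
setMethod("cohortTruth", "ICTCohort", function(x) x@truth)

#' Subset a cohort by sample id
#'
#' Returns a new [ICTCohort-class] restricted to `sampleIds` (order
#' preserved as given). Pathways, taxonomy and truth are carried over.
#'
#' @param x an ICTCohort.
#' @param sampleIds character vector of sample ids to keep.
#' @return An ICTCohort.
#' @export
subsetSamples <- function(x, sampleIds) {
  stopifnot(is(x, "ICTCohort"))
  missing <- setdiff(sampleIds, colnames(x@mgs))
  if (length(missing))
    stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
  initialize(x, mgs = x@mgs[, sampleIds], ko = x@ko[, sampleIds])
}

setMethod("show", "ICTCohort", function(object) {
  meta <- sampleMeta(object)
  cat("ICTCohort:", nrow(meta), "samples /",
      length(unique(meta$patient_id)), "patients\n")
  cat("  MGS features:", nrow(object@mgs),
      "| KO features:", nrow(object@ko),
      "| pathways:", length(object@pathways), "\n")
  tb <- table(meta$response[!duplicated(meta$patient_id)])
  cat("  patients by response:",
      paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  cat("  timepoints:", paste(unique(meta$timepoint), collapse = " "), "\n")
  if (length(object@truth)) cat("  synthetic (truth record attached)\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      length(object@timepoints), "visits,",
      object@nMGS, "MGS /", object@nKO, "KO /",
      object@nPathways, "pathways\n")
  cat("  planted: ", object@nDifferentialMGS, " MGS (effect ",
      object@mgsEffectSize, "), ", object@nDifferentialPathways,
      " pathways; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "DMMFit", function(object) {
  cat("DMMFit: K =", object@K, "| logLik =", round(object@logLik, 2),
      "| log evidence =", round(object@logEvidence, 2),
      if (object@converged) "(converged)" else "(max iterations)", "\n")
  cat("  weights:", paste(round(object@weights, 3), collapse = " "), "\n")
})

setMethod("show", "TieredModel", function(object) {
  cat("TieredModel (two-tiered random forest)\n")
  cat("  stage A (PR vs PD):", length(object@featuresA), "features\n")
  cat("  stage B (SD vs non-SD):", length(object@featuresB), "features\n")
  cat("  training samples:", length(object@trainingSampleIds),
      "| held out:", length(object@testSampleIds), "\n")
})
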