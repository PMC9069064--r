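#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# Columns every per-sample clinical metadata table must carry.
.META_COLS <- c("sample_id", "patient_id", "timepoint", "week", "response",
                "atb", "bmi", "tmb", "hla_e", "pfs_months", "pfs_event")

#' Cohort configuration for the synthetic generator
#'
#' Holds every tunable of [generateCohort()]: cohort composition, sampling
#' grid, feature-space sizes, planted effects, confounding and outcome
#' parameters. Construct with [cohortConfig()].
#'
#' @slot nPatients integer, number of patients.
#' @slot groupProportions named numeric, response-group fractions (sum 1).
#' @slot timepoints named integer, visit label -> week offset.
#' @slot dropoutRate numeric in \[0,1), per-visit dropout probability after
#'   baseline.
#' @slot nMGS,nKO,nPathways integer feature-space sizes.
#' @slot pathwaySizeRange integer length-2, min/max KOs per pathway.
#' @slot nDifferentialMGS integer, number of planted differential species.
#' @slot mgsEffectSize numeric >= 0, natural-log latent mean shift of a
#'   planted species in its enriched group.
#' @slot nDifferentialPathways integer, number of planted pathways whose
#'   member KOs are shifted toward the PR group.
#' @slot bmiConfounderStrength numeric >= 0, regression coefficient of
#'   (centred) BMI on latent log-abundance for the confounded feature subset.
#' @slot enterotypeCount integer >= 1, number of community types.
#' @slot hazardModifiers named numeric hazard ratios (ATB, TMBhigh, HLAEhigh).
#' @slot censorRate numeric in \[0,1), probability a PFS time is censored.
#' @slot atbRate numeric in \[0,1\], fraction of patients on antibiotics.
#' @slot zeroInflation numeric in \[0,1), marginal below-detection zero
#'   fraction of an unshifted feature (detection-limit truncation of the
#'   latent log-abundance).
#' @slot seed integer master seed.
#' @export
setClass("CohortConfig", representation(
  nPatients = "integer",
  groupProportions = "numeric",
  timepoints = "integer",
  dropoutRate = "numeric",
  nMGS = "integer",
  nKO = "integer",
  nPathways = "integer",
  pathwaySizeRange = "integer",
  nDifferentialMGS = "integer",
  mgsEffectSize = "numeric",
  nDifferentialPathways = "integer",
  bmiConfounderStrength = "numeric",
  enterotypeCount = "integer",
  hazardModifiers = "numeric",
  censorRate = "numeric",
  atbRate = "numeric",
  zeroInflation = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be > 0")
  gp <- object@groupProportions
  if (is.null(names(gp)) || !all(names(gp) %in% .GROUP_ORDER))
    msg <- c(msg, "groupProportions must be named with PR/SD/PD/FD")
  if (abs(sum(gp) - 1) > 1e-9) msg <- c(msg, "groupProportions must sum to 1")
  if (any(gp < 0)) msg <- c(msg, "groupProportions must be non-negative")
  if (length(object@timepoints) < 1L || any(object@timepoints < 0L) ||
      is.null(names(object@timepoints)))
    msg <- c(msg, "timepoints must be a named vector of non-negative weeks")
  for (f in c("dropoutRate", "censorRate", "zeroInflation"))
    if (slot(object, f) < 0 || slot(object, f) >= 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1)", f))
  if (object@atbRate < 0 || object@atbRate > 1)
    msg <- c(msg, "atbRate must lie in [0, 1]")
  for (f in c("nMGS", "nKO", "nPathways"))
    if (slot(object, f) < 1L) msg <- c(msg, sprintf("%s must be > 0", f))
  if (object@nDifferentialMGS < 0L || object@nDifferentialMGS > object@nMGS)
    msg <- c(msg, "nDifferentialMGS must lie in [0, nMGS]")
  if (object@nDifferentialPathways < 0L ||
      object@nDifferentialPathways > object@nPathways)
    msg <- c(msg, "nDifferentialPathways must lie in [0, nPathways]")
  if (object@mgsEffectSize < 0) msg <- c(msg, "mgsEffectSize must be >= 0")
  if (object@bmiConfounderStrength < 0)
    msg <- c(msg, "bmiConfounderStrength must be >= 0")
  if (object@enterotypeCount < 1L) msg <- c(msg, "enterotypeCount must be >= 1")
  if (length(object@pathwaySizeRange) != 2L ||
      object@pathwaySizeRange[1] < 1L ||
      object@pathwaySizeRange[2] < object@pathwaySizeRange[1])
    msg <- c(msg, "pathwaySizeRange must be (min, max) with 1 <= min <= max")
  if (any(object@hazardModifiers <= 0))
    msg <- c(msg, "hazardModifiers must be positive hazard ratios")
  if (length(msg)) msg else TRUE
})

#' A longitudinal immunotherapy microbiome cohort
#'
#' Container bundling the species-level (MGS) and KEGG-orthology (KO)
#' relative-abundance profiles of a cohort, its per-sample clinical
#' metadata, the KO-to-pathway membership map, the species taxonomy and --
#' for synthetic cohorts -- the ground-truth record of planted structure.
#' The two abundance tables are stored as
#' [SummarizedExperiment::SummarizedExperiment] objects (features in rows,
#' samples in columns) sharing identical column data.
#'
#' @slot mgs SummarizedExperiment of MGS relative abundances.
#' @slot ko SummarizedExperiment of KO relative abundances.
#' @slot pathways named list, pathway id -> character vector of KO ids.
#' @slot pathwayInfo data.frame with columns pathway_id, name, category.
#' @slot taxonomy data.frame with columns mgs_id, class, genus, species.
#' @slot truth list recording planted structure (empty for real data).
#' @export
setClass("ICTCohort", representation(
  mgs = "SummarizedExperiment",
  ko = "SummarizedExperiment",
  pathways = "list",
  pathwayInfo = "data.frame",
  taxonomy = "data.frame",
  truth = "list"
))

.checkAbundanceValues <- function(m, what) {
  msg <- character()
  if (anyNA(m) || any(m < 0))
    msg <- c(msg, sprintf("%s abundances must be non-negative and non-missing",
                          what))
  else if (any(colSums(m) > 1 + 1e-9))
    msg <- c(msg, sprintf("per-sample %s abundance sums exceed 1", what))
  msg
}

setValidity("ICTCohort", function(object) {
  msg <- character()
  mgs <- object@mgs; ko <- object@ko
  if (!identical(colnames(mgs), colnames(ko)))
    msg <- c(msg, "MGS and KO tables must cover the same samples in order")
  if (anyDuplicated(colnames(mgs))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(mgs))) msg <- c(msg, "duplicate MGS ids")
  if (anyDuplicated(rownames(ko))) msg <- c(msg, "duplicate KO ids")
  msg <- c(msg, .checkAbundanceValues(SummarizedExperiment::assay(mgs), "MGS"),
           .checkAbundanceValues(SummarizedExperiment::assay(ko), "KO"))
  cd <- SummarizedExperiment::colData(mgs)
  miss <- setdiff(.META_COLS, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("metadata missing columns:",
                        paste(miss, collapse = ", ")))
  if (nrow(object@taxonomy) &&
      !all(rownames(mgs) %in% object@taxonomy$mgs_id))
    msg <- c(msg, "taxonomy does not cover all MGS features")
  if (length(object@pathways)) {
    if (any(!lengths(object@pathways)))
      msg <- c(msg, "empty pathway in pathway map")
    if (any(vapply(object@pathways, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "duplicated KO ids within a pathway")
  }
  if (length(msg)) msg else TRUE
})

#' Dirichlet-multinomial mixture fit
#'
#' Result of [fitDMM()]: a K-component Dirichlet-multinomial mixture fitted
#' by expectation-maximisation to genus-level count profiles.
#'
#' @slot K integer, number of mixture components.
#' @slot weights numeric, mixture proportions (sum 1).
#' @slot alpha K x G matrix of positive Dirichlet parameters.
#' @slot responsibilities N x K posterior membership matrix (rows sum to 1).
#' @slot logLik numeric, observed-data log-likelihood at convergence.
#' @slot logEvidence numeric, Laplace-approximated log model evidence
#'   (or BIC-based score, see [fitDMM()]).
#' @slot converged logical.
#' @slot iterations integer, EM iterations used.
#' @export
setClass("DMMFit", representation(
  K = "integer", weights = "numeric", alpha = "matrix",
  responsibilities = "matrix", logLik = "numeric", logEvidence = "numeric",
  converged = "logical", iterations = "integer"
))

setValidity("DMMFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be positive")
  if (nrow(object@responsibilities) &&
      max(abs(rowSums(object@responsibilities) - 1)) > 1e-6)
    msg <- c(msg, "responsibility rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Two-tiered random-forest response model
#'
#' Result of [trainTiered()]. Stage A is a forest separating partial
#' response (PR) from progressive disease (PD); stage B separates stable
#' disease (SD) from non-SD. Per-sample three-class probabilities are
#' obtained with [predictTiered()] via [combineProbabilities()].
#'
#' @slot modelA,modelB fitted randomForest objects.
#' @slot featuresA,featuresB character, selected feature ids per stage.
#' @slot trainingSampleIds character, samples used for training (stage B's
#'   training set; stage A's is its PR/PD subset).
#' @slot testSampleIds character, held-out samples.
#' @slot seed integer seed the training was run under.
#' @slot selectionTrace list with per-stage feature contribution tables and
#'   the out-of-fold AUC grid used to pick the feature-count k.
#' @export
setClass("TieredModel", representation(
  modelA = "ANY", modelB = "ANY",
  featuresA = "character", featuresB = "character",
  trainingSampleIds = "character", testSampleIds = "character",
  seed = "integer", selectionTrace = "list"
))

setValidity("TieredModel", function(object) {
  msg <- character()
  if (!length(object@featuresA)) msg <- c(msg, "featuresA must be non-empty")
  if (!length(object@featuresB)) msg <- c(msg, "featuresB must be non-empty")
  if (length(msg)) msg else TRUE
})
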