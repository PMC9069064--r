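#' Construct a cohort configuration
#'
#' Builds and validates a [CohortConfig-class] describing a synthetic
#' longitudinal anti-PD-1 cohort. Defaults mirror the structure of the study
#' cohort this package emulates: 85 patients split 13 PR / 24 SD / 43 PD /
#' 5 FD, sampled at baseline (M0) and then at weeks 1, 2, 4, 8, 12 and 16,
#' with a 12/85 antibiotics fraction. Feature-space sizes default to a
#' desk-scale cohort; raise them (e.g. `nMGS = 1507`) for full-size runs.
#'
#' @param nPatients number of patients.
#' @param groupProportions named fractions over PR, SD, PD, FD (sum to 1).
#'   Realised counts are obtained by deterministic largest-remainder
#'   apportionment, so the default reproduces exactly 13/24/43/5 patients.
#' @param timepoints named integer vector, visit label -> week offset.
#' @param dropoutRate per-visit probability (after M0) that a patient drops
#'   out of sampling; dropout is monotone (a patient who misses a visit
#'   contributes no later samples). FD patients contribute only M0.
#' @param nMGS,nKO,nPathways feature-space sizes.
#' @param pathwaySizeRange integer (min, max) KOs per pathway.
#' @param nDifferentialMGS number of planted differential species. Each is
#'   assigned an enriched response group (cycling PR, SD, PD) and its latent
#'   log-mean is raised by `mgsEffectSize` in that group.
#' @param mgsEffectSize natural-log latent mean shift (0 = null cohort).
#' @param nDifferentialPathways planted pathways whose KOs are carried by
#'   PR-enriched planted species, so the pathway signal points toward PR.
#' @param bmiConfounderStrength coefficient of centred BMI on the latent
#'   log-abundance of a random 20% feature subset (0 = no confounding).
#' @param enterotypeCount number of community types; each is driven by a
#'   block of genera whose members get a latent log boost in that type.
#' @param hazardModifiers named hazard ratios applied multiplicatively to
#'   the group-specific exponential PFS hazard: `ATB` (antibiotics),
#'   `TMBhigh` (tumour mutational burden > 5.6 /Mb), `HLAEhigh`.
#' @param censorRate probability that a PFS time is right-censored.
#' @param atbRate fraction of patients flagged as antibiotics-exposed
#'   (count realised as `round(nPatients * atbRate)`).
#' @param zeroInflation marginal zero fraction of an unshifted feature.
#'   Zeros follow a detection-limit model: a feature is zeroed in a sample
#'   when its latent log-abundance falls below the feature's own
#'   `zeroInflation` quantile under no group/BMI/enterotype shift, so
#'   enriched groups show both higher abundance and higher occurrence, as
#'   real below-detection zeros do.
#' @param seed master seed; every random draw derives from it.
#' @return A validated [CohortConfig-class].
#' @seealso [generateCohort()]
#' @export
cohortConfig <- function(nPatients = 85L,
                         groupProportions = c(PR = 13 / 85, SD = 24 / 85,
                                              PD = 43 / 85, FD = 5 / 85),
                         timepoints = c(M0 = 0L, W1 = 1L, W2 = 2L, M1 = 4L,
                                        M2 = 8L, M3 = 12L, M4 = 16L),
                         dropoutRate = 0.1,
                         nMGS = 300L, nKO = 400L, nPathways = 25L,
                         pathwaySizeRange = c(5L, 20L),
                         nDifferentialMGS = 30L, mgsEffectSize = 1.0,
                         nDifferentialPathways = 5L,
                         bmiConfounderStrength = 0,
                         enterotypeCount = 3L,
                         hazardModifiers = c(ATB = 2.5, TMBhigh = 0.5,
                                             HLAEhigh = 1.8),
                         censorRate = 0.15,
                         atbRate = 12 / 85,
                         zeroInflation = 0.3,
                         seed = 1L) {
  gp <- groupProportions[intersect(.GROUP_ORDER, names(groupProportions))]
  if (length(gp) != length(groupProportions))
    stop("groupProportions must be named with groups among PR, SD, PD, FD")
  new("CohortConfig",
      nPatients = as.integer(nPatients), groupProportions = gp,
      timepoints = stats::setNames(as.integer(timepoints), names(timepoints)),
      dropoutRate = dropoutRate, nMGS = as.integer(nMGS),
      nKO = as.integer(nKO), nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      nDifferentialMGS = as.integer(nDifferentialMGS),
      mgsEffectSize = mgsEffectSize,
      nDifferentialPathways = as.integer(nDifferentialPathways),
      bmiConfounderStrength = bmiConfounderStrength,
      enterotypeCount = as.integer(enterotypeCount),
      hazardModifiers = hazardModifiers, censorRate = censorRate,
      atbRate = atbRate, zeroInflation = zeroInflation,
      seed = as.integer(seed))
}

# Genus pool with class annotations; enterotype drivers are assigned from
# the head of this table (Bacteroides-, Faecalibacterium/Eubacterium/
# Clostridium-, Prevotella-driven types first, matching the canonical
# enterotype literature).
.GENUS_POOL <- data.frame(
  genus = c("Bacteroides", "Faecalibacterium", "Eubacterium", "Clostridium",
            "Prevotella", "Alistipes", "Roseburia", "Blautia",
            "Enterocloster", "Collinsella", "Holdemanella", "Akkermansia"),
  class = c("Bacteroidia", "Clostridia", "Clostridia", "Clostridia",
            "Bacteroidia", "Bacteroidia", "Clostridia", "Clostridia",
            "Clostridia", "Coriobacteriia", "Erysipelotrichia",
            "Verrucomicrobiae"),
  stringsAsFactors = FALSE
)

# Driver genus indices per enterotype (1-based into .GENUS_POOL).
.enterotypeDrivers <- function(k) {
  base <- list(1L, c(2L, 3L, 4L), 5L)
  if (k <= 3L) return(base[seq_len(k)])
  c(base, as.list(5L + seq_len(k - 3L)))
}

#' Construct an ICTCohort from its components
#'
#' Low-level constructor used by [generateCohort()] and the file readers.
#' Abundance matrices are supplied samples x features (the on-disk layout)
#' and stored internally feature-by-sample inside
#' [SummarizedExperiment::SummarizedExperiment] objects.
#'
#' @param mgsAbund,koAbund samples x features relative-abundance matrices
#'   with row names (sample ids) and column names (feature ids).
#' @param meta per-sample clinical data.frame; must contain one row per
#'   sample in the abundance matrices (matched on `sample_id`).
#' @param pathways named list: pathway id -> character vector of KO ids.
#' @param pathwayInfo data.frame (pathway_id, name, category); generated
#'   from `pathways` names when omitted.
#' @param taxonomy data.frame (mgs_id, class, genus, species).
#' @param truth list of planted ground truth; empty for real data.
#' @return An [ICTCohort-class].
#' @export
ICTCohort <- function(mgsAbund, koAbund, meta, pathways = list(),
                      pathwayInfo = NULL, taxonomy = data.frame(),
                      truth = list()) {
  stopifnot(is.matrix(mgsAbund), is.matrix(koAbund), is.data.frame(meta))
  if (!all(rownames(mgsAbund) %in% meta$sample_id))
    stop("every sample in the abundance matrices needs a metadata row")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta <- meta[match(rownames(mgsAbund), meta$sample_id), , drop = FALSE]
  if (is.null(pathwayInfo))
    pathwayInfo <- data.frame(pathway_id = names(pathways),
                              name = names(pathways),
                              category = NA_character_,
                              stringsAsFactors = FALSE)
  attr(koAbund, "zeroKOs") <- NULL
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  mgsSE <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = t(mgsAbund)), colData = cd)
  koSE <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = t(koAbund)), colData = cd)
  new("ICTCohort", mgs = mgsSE, ko = koSE, pathways = pathways,
      pathwayInfo = pathwayInfo, taxonomy = taxonomy, truth = truth)
}

#' Generate a synthetic longitudinal anti-PD-1 cohort
#'
#' Draws a complete synthetic cohort with the statistical structure the
#' downstream analyses assume: per-patient response groups realised by
#' largest-remainder apportionment; zero-inflated log-normal compositional
#' species (MGS) abundances with planted group effects, BMI confounding and
#' enterotype structure; a KO functional profile derived from the species
#' profile through a binary species-by-KO incidence matrix; a GMT-style
#' pathway map with planted differential pathways; clinical covariates
#' (antibiotics, BMI, TMB, HLA-E) and exponentially distributed, censored
#' progression-free survival scaled by covariate hazard ratios.
#'
#' All randomness derives from `config@seed` through per-patient sub-streams,
#' so the same config yields a bit-identical cohort, and dropout draws never
#' perturb abundance draws.
#'
#' @param config a [CohortConfig-class] from [cohortConfig()].
#' @return An [ICTCohort-class] whose `cohortTruth()` records the planted
#'   differential MGS ids (with their enriched group), planted pathway ids,
#'   per-patient enterotype assignments and the true hazard structure.
#' @examples
#' ch <- generateCohort(cohortConfig(nPatients = 20, nMGS = 50, nKO = 80,
#'                                   nPathways = 8, seed = 42))
#' ch
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  seed <- config@seed
  nP <- config@nPatients
  groups <- names(config@groupProportions)
  counts <- .apportion(nP, config@groupProportions)
  warnings <- character()
  for (g in c("PR", "SD", "PD")) {
    if (!g %in% groups || counts[g] == 0L) {
      w <- sprintf("group %s has zero patients; downstream contrasts involving it will fail", g)
      warning(w, call. = FALSE)
      warnings <- c(warnings, w)
    }
  }
  patientGroup <- rep(groups, counts)
  patientIds <- sprintf("P%03d", seq_len(nP))

  # -- feature-level parameters (one sub-stream) ---------------------------
  feat <- .withSeed(.subSeed(seed, 0L, 1L), {
    mu <- stats::rnorm(config@nMGS, mean = 0, sd = 1.5)
    genusIdx <- sample.int(nrow(.GENUS_POOL), config@nMGS, replace = TRUE)
    planted <- if (config@nDifferentialMGS > 0L)
      sort(sample.int(config@nMGS, config@nDifferentialMGS)) else integer()
    plantedGroup <- rep_len(c("PR", "SD", "PD"), length(planted))
    confounded <- sort(sample.int(config@nMGS, max(1L, round(0.2 * config@nMGS))))
    unclassified <- stats::runif(config@nMGS) < 0.3
    list(mu = mu, genusIdx = genusIdx, planted = planted,
         plantedGroup = plantedGroup, confounded = confounded,
         unclassified = unclassified)
  })
  mgsIds <- sprintf("igc%04d", seq_len(config@nMGS))
  taxonomy <- data.frame(
    mgs_id = mgsIds,
    class = .GENUS_POOL$class[feat$genusIdx],
    genus = .GENUS_POOL$genus[feat$genusIdx],
    species = ifelse(feat$unclassified, "unclassified",
                     paste(.GENUS_POOL$genus[feat$genusIdx], "sp.",
                           seq_len(config@nMGS))),
    stringsAsFactors = FALSE
  )

  # -- pathway map and MGS x KO incidence (one sub-stream) -----------------
  koIds <- sprintf("K%05d", seq_len(config@nKO))
  prCarriers <- feat$planted[feat$plantedGroup == "PR"]
  pw <- .withSeed(.subSeed(seed, 0L, 2L), {
    .buildPathways(config, prCarriers)
  })
  if (!is.null(pw$warning)) warnings <- c(warnings, pw$warning)

  # -- patient-level covariates (one sub-stream) ---------------------------
  cov <- .withSeed(.subSeed(seed, 0L, 3L), {
    nATB <- round(config@atbRate * nP)
    atb <- rep(FALSE, nP)
    if (nATB > 0) atb[sample.int(nP, nATB)] <- TRUE
    bmi <- round(stats::rnorm(nP, 22.5, 3), 1)
    tmb <- round(stats::rlnorm(nP, log(3.5), 0.8), 2)
    hla <- ifelse(stats::runif(nP) < 0.3, "high", "low")
    etProbs <- c(0.5, 0.3, 0.2, rep(0.1, max(0, config@enterotypeCount - 3L)))
    etProbs <- etProbs[seq_len(config@enterotypeCount)]
    enterotype <- sample.int(config@enterotypeCount, nP, replace = TRUE,
                             prob = etProbs / sum(etProbs))
    list(atb = atb, bmi = bmi, tmb = tmb, hla = hla, enterotype = enterotype)
  })

  # per-enterotype log-boost on driver-genus members
  drivers <- .enterotypeDrivers(config@enterotypeCount)
  etOffset <- matrix(0, config@enterotypeCount, config@nMGS)
  for (e in seq_len(config@enterotypeCount)) {
    d <- drivers[[e]]
    d <- d[d <= nrow(.GENUS_POOL)]
    etOffset[e, feat$genusIdx %in% d] <- 1.5
  }
  groupShift <- matrix(0, length(groups), config@nMGS,
                       dimnames = list(groups, NULL))
  if (length(feat$planted))
    for (i in seq_along(feat$planted)) {
      g <- feat$plantedGroup[i]
      if (g %in% groups)
        groupShift[g, feat$planted[i]] <- config@mgsEffectSize
    }

  tp <- config@timepoints
  tpLabels <- names(tp)

  # -- per-patient sampling ------------------------------------------------
  metaRows <- vector("list", nP)
  abundRows <- vector("list", nP)
  baseHazard <- c(PR = log(2) / 12, SD = log(2) / 5, PD = log(2) / 2,
                  FD = log(2) / 0.7)
  for (i in seq_len(nP)) {
    g <- patientGroup[i]
    nT <- length(tp)
    # abundance sub-stream: draws for every scheduled visit, kept or not
    eps <- .withSeed(.subSeed(seed, i, 1L),
                     matrix(stats::rnorm(nT * config@nMGS), nT, config@nMGS))
    logAb <- sweep(eps, 2, feat$mu, "+")
    logAb <- sweep(logAb, 2, groupShift[g, ], "+")
    logAb <- sweep(logAb, 2, etOffset[cov$enterotype[i], ], "+")
    bmiEff <- numeric(config@nMGS)
    bmiEff[feat$confounded] <- config@bmiConfounderStrength * (cov$bmi[i] - 22.5)
    logAb <- sweep(logAb, 2, bmiEff, "+")
    # detection-limit zeros: a feature drops out when its latent
    # log-abundance falls below its own null pi0-quantile, so the marginal
    # zero rate of an unshifted feature is zeroInflation while enriched
    # groups show both higher abundance and higher occurrence
    detThr <- feat$mu + stats::qnorm(config@zeroInflation)
    ab <- exp(logAb) * sweep(logAb, 2, detThr, ">=")
    # guard: a fully zeroed visit keeps its single largest latent feature
    dead <- rowSums(ab) == 0
    if (any(dead))
      for (r in which(dead)) ab[r, which.max(logAb[r, ])] <- exp(max(logAb[r, ]))
    ab <- ab / rowSums(ab)

    # dropout sub-stream: monotone after baseline; FD contributes only M0
    keepVisit <- .withSeed(.subSeed(seed, i, 2L), {
      kv <- rep(TRUE, nT)
      if (g == "FD") {
        kv[-1L] <- FALSE
      } else if (nT > 1L) {
        drop <- stats::runif(nT - 1L) < config@dropoutRate
        if (any(drop)) kv[-1L][seq(from = which(drop)[1L], to = nT - 1L)] <- FALSE
      }
      kv
    })

    # outcome sub-stream
    outc <- .withSeed(.subSeed(seed, i, 3L), {
      hr <- 1
      hm <- config@hazardModifiers
      if (cov$atb[i] && "ATB" %in% names(hm)) hr <- hr * hm[["ATB"]]
      if (cov$tmb[i] > 5.6 && "TMBhigh" %in% names(hm)) hr <- hr * hm[["TMBhigh"]]
      if (cov$hla[i] == "high" && "HLAEhigh" %in% names(hm))
        hr <- hr * hm[["HLAEhigh"]]
      t0 <- stats::rexp(1, rate = baseHazard[[g]] * hr)
      censored <- stats::runif(1) < config@censorRate
      if (censored) t0 <- stats::runif(1, 0, t0)
      list(pfs = max(round(t0, 2), 0.03), event = !censored, hr = hr)
    })

    kept <- which(keepVisit)
    sid <- paste(patientIds[i], tpLabels[kept], sep = "_")
    metaRows[[i]] <- data.frame(
      sample_id = sid, patient_id = patientIds[i],
      timepoint = tpLabels[kept], week = unname(tp[kept]),
      response = g, atb = cov$atb[i], bmi = cov$bmi[i], tmb = cov$tmb[i],
      hla_e = cov$hla[i], pfs_months = outc$pfs, pfs_event = outc$event,
      enterotype = cov$enterotype[i], true_hr = outc$hr,
      stringsAsFactors = FALSE
    )
    abundRows[[i]] <- ab[kept, , drop = FALSE]
  }
  meta <- do.call(rbind, metaRows)
  mgsAbund <- do.call(rbind, abundRows)
  dimnames(mgsAbund) <- list(meta$sample_id, mgsIds)

  koAbund <- mgsToKO(mgsAbund, pw$incidence)

  truth <- list(
    differentialMGS = data.frame(mgs_id = mgsIds[feat$planted],
                                 enriched_group = feat$plantedGroup,
                                 stringsAsFactors = FALSE),
    differentialPathways = pw$plantedIds,
    confoundedMGS = mgsIds[feat$confounded],
    enterotype = stats::setNames(cov$enterotype, patientIds),
    hazardModifiers = config@hazardModifiers,
    baseHazard = baseHazard,
    zeroKOs = attr(koAbund, "zeroKOs"),
    warnings = warnings,
    config = config
  )
  ICTCohort(mgsAbund, koAbund, meta, pathways = pw$map,
            pathwayInfo = pw$info, taxonomy = taxonomy, truth = truth)
}

# Builds the pathway map, its annotation table and the MGS x KO incidence.
# Planted pathways receive dedicated KOs carried only by PR-enriched planted
# species, so the functional signal tracks the taxonomic one. Runs inside a
# seeded sub-stream.
.buildPathways <- function(config, prCarriers) {
  koIds <- sprintf("K%05d", seq_len(config@nKO))
  mgsIds <- sprintf("igc%04d", seq_len(config@nMGS))
  sz <- config@pathwaySizeRange
  nPlant <- config@nDifferentialPathways
  warn <- NULL

  sizes <- if (sz[1] == sz[2]) rep(sz[1], config@nPathways) else
    sample(seq(sz[1], sz[2]), config@nPathways, replace = TRUE)
  sizes <- pmin(sizes, config@nKO)

  plantedIds <- character()
  map <- vector("list", config@nPathways)
  names(map) <- sprintf("map%05d", seq_len(config@nPathways))
  usedPlantedKO <- integer()
  if (nPlant > 0L) {
    plantedIds <- names(map)[seq_len(nPlant)]
    need <- sum(sizes[seq_len(nPlant)])
    if (need > config@nKO)
      stop("not enough KOs for the requested planted pathways")
    pool <- sample.int(config@nKO, need)
    off <- 0L
    for (p in seq_len(nPlant)) {
      map[[p]] <- koIds[pool[off + seq_len(sizes[p])]]
      off <- off + sizes[p]
    }
    usedPlantedKO <- pool
  }
  rest <- setdiff(seq_len(config@nKO), usedPlantedKO)
  for (p in seq_len(config@nPathways)) {
    if (nPlant > 0L && p <= nPlant) next
    take <- min(sizes[p], length(rest))
    map[[p]] <- koIds[sample(rest, take)]
  }
  map <- map[lengths(map) > 0L]

  # incidence: sparse random carriage, then rewire planted-pathway KOs
  incidence <- matrix(stats::runif(config@nMGS * config@nKO) < 0.05,
                      config@nMGS, config@nKO,
                      dimnames = list(mgsIds, koIds))
  noCarrier <- which(colSums(incidence) == 0L)
  if (length(noCarrier))
    for (j in noCarrier) incidence[sample.int(config@nMGS, 1L), j] <- TRUE
  if (nPlant > 0L) {
    if (!length(prCarriers)) {
      warn <- "planted pathways requested without PR-enriched planted MGSs; pathway signal will be null"
      prCarriers <- sample.int(config@nMGS, min(3L, config@nMGS))
    }
    for (p in seq_len(nPlant)) {
      cols <- match(map[[p]], koIds)
      incidence[, cols] <- FALSE
      carriers <- prCarriers[((seq_along(cols) - 1L) %% length(prCarriers)) + 1L]
      # each planted KO carried by up to 3 PR-enriched species
      for (ci in seq_along(cols)) {
        pick <- unique(c(carriers[ci],
                         sample(prCarriers, min(2L, length(prCarriers)))))
        incidence[pick, cols[ci]] <- TRUE
      }
    }
  }
  info <- data.frame(
    pathway_id = names(map),
    name = paste("pathway", names(map)),
    category = rep_len(c("Metabolism", "Genetic Information Processing",
                         "Environmental Information Processing",
                         "Cellular Processes"), length(map)),
    stringsAsFactors = FALSE
  )
  list(map = map, info = info, incidence = incidence,
       plantedIds = plantedIds, warning = warn)
}

#' Derive a KO profile from an MGS profile
#'
#' Projects a species-level relative-abundance matrix onto KEGG-orthology
#' space through a binary carriage (incidence) matrix: each KO's abundance
#' is the summed abundance of the species carrying it, renormalised per
#' sample. The map is linear in the species profile before renormalisation.
#'
#' @param mgsAbund samples x MGS relative-abundance matrix.
#' @param incidence binary MGS x KO matrix; its rows must cover every MGS
#'   column of `mgsAbund`.
#' @return samples x KO relative-abundance matrix; KOs carried by no species
#'   (all-zero columns) are retained and listed in the `"zeroKOs"` attribute.
#' @examples
#' m <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("s1", c("m1", "m2")))
#' inc <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(c("m1", "m2"),
#'                                                    c("k1", "k2")))
#' mgsToKO(m, inc)  # m1 carries both KOs: each gets 0.5 after closure
#' @export
mgsToKO <- function(mgsAbund, incidence) {
  stopifnot(is.matrix(mgsAbund), is.matrix(incidence))
  if (!all(colnames(mgsAbund) %in% rownames(incidence)))
    stop("incidence rows must cover all MGS features")
  inc <- incidence[colnames(mgsAbund), , drop = FALSE]
  storage.mode(inc) <- "double"
  if (any(rowSums(mgsAbund) == 0)) stop("empty sample")
  ko <- mgsAbund %*% inc
  zero <- colnames(ko)[colSums(ko) == 0]
  rs <- rowSums(ko)
  rs[rs == 0] <- 1  # a sample hitting no KO stays all-zero rather than NaN
  ko <- ko / rs
  attr(ko, "zeroKOs") <- zero
  ko
}
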