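#' Default design of the synthetic paired cohort
#'
#' Three diet/exposure arms (RC-Air, HFHC-Air, HFHC-IHC) sampled
#' longitudinally: 8 mice per group, 20 timepoints over 10 weeks of study
#' (host age 10 to 19.5 weeks), 150 microbial features with family labels,
#' 250 metabolite features, expected library size 12,000 with lognormal
#' spread (so rarefaction at 10,200 drops some samples), 30% zero-inflation
#' and 2 shared latent factors. The planted group effect reaches
#' `effectSize` natural-log units at the final timepoint, ramping linearly
#' from zero: Muribaculaceae-like features are depleted and
#' Akkermansiaceae-like features enriched under HFHC (fully so under
#' HFHC-IHC), with matching RC- and HFHC-IHC-associated metabolite sets.
#'
#' @param groups group labels.
#' @param micePerGroup mice per group.
#' @param timepoints host ages in weeks.
#' @param nMicrobes,nMetabolites feature counts.
#' @param depthMean expected library size.
#' @param depthSdlog lognormal sd of library size.
#' @param dropout zero-inflation probability for counts.
#' @param effectSize planted effect at the final timepoint (ln units).
#' @param rank number of shared latent factors.
#' @param latentSD,subjectSD,noiseSD latent score, subject intercept and
#'   metabolite noise scales (log scale).
#' @return a [CohortDesign-class].
#' @export
cohortDesign <- function(groups = c("RC-Air", "HFHC-Air", "HFHC-IHC"),
                         micePerGroup = 8, timepoints = seq(10, 19.5, by = 0.5),
                         nMicrobes = 150, nMetabolites = 250,
                         depthMean = 12000, depthSdlog = 0.3, dropout = 0.3,
                         effectSize = 2, rank = 2, latentSD = 1,
                         subjectSD = 0.3, noiseSD = 0.5) {
  new("CohortDesign", groups = groups,
      micePerGroup = as.integer(micePerGroup), timepoints = timepoints,
      nMicrobes = as.integer(nMicrobes),
      nMetabolites = as.integer(nMetabolites), depthMean = depthMean,
      depthSdlog = depthSdlog, dropout = dropout, effectSize = effectSize,
      rank = as.integer(rank), latentSD = latentSD, subjectSD = subjectSD,
      noiseSD = noiseSD)
}

# Group multiplier on the planted effect ramp: RC-Air none, HFHC-Air
# partial (diet only), HFHC-IHC full (diet + exposure).
.groupMultiplier <- function(groups) {
  m <- c("RC-Air" = 0, "HFHC-Air" = 0.6, "HFHC-IHC" = 1)
  out <- m[groups]
  out[is.na(out)] <- 0
  unname(out)
}

#' Simulate a paired longitudinal microbiome-metabolome cohort
#'
#' Generates paired count and intensity tables with known ground truth.
#' Counts are drawn per sample from a multinomial whose log-probabilities
#' are a low-rank term (shared latent factors times microbe loadings) plus
#' group-by-time effects and a per-subject random intercept, with
#' zero-inflation dropout. Metabolite log-intensities use the *same* latent
#' sample factors with their own loadings, group effects and Gaussian
#' noise. Opposing family enrichments (Muribaculaceae-like down,
#' Akkermansiaceae-like up under HFHC-IHC, ramping linearly with time) and
#' a handful of noiseless microbe-metabolite pairs (a metabolite that is an
#' exact linear function of one microbe's latent contribution) are planted
#' and recorded in the returned [SyntheticTruth-class].
#'
#' All randomness flows from the single `seed`, split into named streams;
#' the same seed reproduces the tables exactly.
#'
#' @param design a [CohortDesign-class]; see [cohortDesign()].
#' @param seed master seed.
#' @return list with `microbes` and `metabolites` ([FeatureTable-class]),
#'   `metadata` (data.frame) and `truth` ([SyntheticTruth-class]).
#' @export
simulateCohort <- function(design = cohortDesign(), seed = 1) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  groups <- design@groups
  tps <- design@timepoints
  nT <- length(tps)
  nMice <- length(groups) * design@micePerGroup
  mouseGroup <- rep(groups, each = design@micePerGroup)
  mouseID <- paste0("mouse", sprintf("%02d", seq_len(nMice)))
  n <- nMice * nT
  meta <- data.frame(
    sample_id = paste0(rep(mouseID, each = nT), ".wk",
                       sprintf("%04.1f", rep(tps, nMice))),
    host_subject_id = rep(mouseID, each = nT),
    host_age = rep(tps, nMice),
    diet = sub("-.*", "", rep(mouseGroup, each = nT)),
    exposure = sub(".*-", "", rep(mouseGroup, each = nT)),
    stringsAsFactors = FALSE)
  meta <- validateSampleMetadata(meta)

  p1 <- design@nMicrobes
  p2 <- design@nMetabolites
  r <- design@rank
  micIDs <- paste0("asv", sprintf("%03d", seq_len(p1)))
  metIDs <- paste0("mtb", sprintf("%03d", seq_len(p2)))

  nFam <- max(4L, round(p1 / 6))
  familyMap <- rep("OtherFamily", p1)
  familyMap[seq_len(nFam)] <- "MuribaculaceaeLike"
  familyMap[nFam + seq_len(nFam)] <- "AkkermansiaceaeLike"
  names(familyMap) <- micIDs
  famDir <- c(MuribaculaceaeLike = -1, AkkermansiaceaeLike = 1,
              OtherFamily = 0)[familyMap]

  nCls <- max(4L, round(p2 / 6))
  metClass <- rep("none", p2)
  metClass[seq_len(nCls)] <- "rcAssoc"
  metClass[nCls + seq_len(nCls)] <- "hfhcIhcAssoc"
  names(metClass) <- metIDs
  metDir <- c(rcAssoc = -1, hfhcIhcAssoc = 1, none = 0)[metClass]

  U <- .withSeed(.streamSeed(seed, "latent"), function()
    matrix(stats::rnorm(n * r, sd = design@latentSD), n, r))
  Wmic <- .withSeed(.streamSeed(seed, "microbeLoadings"), function()
    matrix(stats::rnorm(p1 * r), p1, r))
  Wmet <- .withSeed(.streamSeed(seed, "metaboliteLoadings"), function()
    matrix(stats::rnorm(p2 * r), p2, r))
  # The opposing families and metabolite classes share latent axis 1 (a
  # community-state factor loading them in opposite directions), so the
  # cross-omic family/class log-ratio correlation is carried by the shared
  # factors as well as by the group effect ramp.
  Wmic[, 1] <- Wmic[, 1] - 0.5 * famDir
  Wmet[, 1] <- Wmet[, 1] - 0.5 * metDir
  aMic <- .withSeed(.streamSeed(seed, "microbeIntercepts"), function()
    stats::rnorm(p1, mean = 0, sd = 1))
  aMet <- .withSeed(.streamSeed(seed, "metaboliteIntercepts"), function()
    stats::rnorm(p2, mean = 8, sd = 1))
  subjMic <- .withSeed(.streamSeed(seed, "subjectMicrobe"), function()
    matrix(stats::rnorm(nMice * p1, sd = design@subjectSD), nMice, p1))
  subjMet <- .withSeed(.streamSeed(seed, "subjectMetabolite"), function()
    matrix(stats::rnorm(nMice * p2, sd = design@subjectSD), nMice, p2))

  # Noiseless planted microbe-metabolite pairs, taken outside the planted
  # differential families / metabolite classes. Pair microbes are made
  # abundant with strong latent loadings: an identifiable pair needs its
  # microbe member to be well estimated from counts.
  nPairs <- 5L
  pairMic <- which(familyMap == "OtherFamily")[seq_len(nPairs)]
  pairMet <- which(metClass == "none")[seq_len(nPairs)]
  aMic[pairMic] <- aMic[pairMic] + 2
  # fixed strong loading norm (3 ln units), random direction
  nw <- sqrt(rowSums(Wmic[pairMic, , drop = FALSE]^2))
  Wmic[pairMic, ] <- 3 * Wmic[pairMic, , drop = FALSE] / nw
  Wmet[pairMet, ] <- Wmic[pairMic, , drop = FALSE]

  ramp <- (meta$host_age - tps[1]) / (tps[nT] - tps[1])
  gm <- .groupMultiplier(paste(meta$diet, meta$exposure, sep = "-"))
  effRow <- design@effectSize * ramp * gm              # per sample
  subjIdx <- match(meta$host_subject_id, mouseID)

  etaMic <- matrix(aMic, n, p1, byrow = TRUE) + U %*% t(Wmic) +
    outer(effRow, famDir) + subjMic[subjIdx, , drop = FALSE]

  keepMask <- .withSeed(.streamSeed(seed, "dropout"), function()
    matrix(stats::runif(n * p1) >= design@dropout, n, p1))
  # Pair microbes are consistently detected (no zero-inflation): the pair
  # contract is a measurable microbe driving a metabolite.
  keepMask[, pairMic] <- TRUE
  # Guarantee at least one retained feature per sample.
  none <- rowSums(keepMask) == 0L
  keepMask[cbind(which(none), max.col(etaMic[none, , drop = FALSE]))] <- TRUE

  depths <- .withSeed(.streamSeed(seed, "depth"), function()
    pmax(1, round(stats::rlnorm(n, meanlog = log(design@depthMean) -
                                  design@depthSdlog^2 / 2,
                                sdlog = design@depthSdlog))))
  counts <- .withSeed(.streamSeed(seed, "counts"), function() {
    out <- matrix(0, n, p1)
    for (i in seq_len(n)) {
      pr <- exp(etaMic[i, ] - max(etaMic[i, ])) * keepMask[i, ]
      out[i, ] <- stats::rmultinom(1, depths[i], pr / sum(pr))
    }
    out
  })
  dimnames(counts) <- list(meta$sample_id, micIDs)

  logMet <- matrix(aMet, n, p2, byrow = TRUE) + U %*% t(Wmet) +
    outer(effRow, metDir) + subjMet[subjIdx, , drop = FALSE] +
    .withSeed(.streamSeed(seed, "noise"), function()
      matrix(stats::rnorm(n * p2, sd = design@noiseSD), n, p2))
  # Planted pairs: each metabolite is an exact (noiseless) linear function
  # of its partner microbe's log abundance, as for a metabolite produced
  # by that microbe.
  logMet[, pairMet] <- matrix(aMet[pairMet] - aMic[pairMic], n, nPairs,
                              byrow = TRUE) + etaMic[, pairMic, drop = FALSE]
  intensities <- exp(logMet)
  dimnames(intensities) <- list(meta$sample_id, metIDs)

  rownames(U) <- meta$sample_id
  rownames(Wmic) <- micIDs
  rownames(Wmet) <- metIDs
  truth <- new("SyntheticTruth",
    latentFactors = U, microbeLoadings = Wmic, metaboliteLoadings = Wmet,
    groupEffects = stats::setNames(design@effectSize *
                                     .groupMultiplier(groups), groups),
    familyMap = familyMap, metaboliteClass = metClass,
    plantedPairs = data.frame(microbe = micIDs[pairMic],
                              metabolite = metIDs[pairMet],
                              stringsAsFactors = FALSE),
    differentialMicrobes = list(
      numerator = micIDs[familyMap == "MuribaculaceaeLike"],
      denominator = micIDs[familyMap == "AkkermansiaceaeLike"]),
    metaboliteSets = list(rc = metIDs[metClass == "rcAssoc"],
                          hfhcIhc = metIDs[metClass == "hfhcIhcAssoc"]),
    seed = seed)

  list(microbes = FeatureTable(counts, "counts"),
       metabolites = FeatureTable(intensities, "intensities"),
       metadata = meta,
       truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the microbe and metabolite tables (TSV, features as rows, or BIOM
#' JSON), the sample metadata, a feature-family table, a metabolite-class
#' table and the ground truth as JSON, all under one directory.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"biom"` for the feature tables.
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(sim, dir, format = c("tsv", "biom")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tsv") ".tsv" else ".biom"
  writeFeatureTable(sim$microbes, file.path(dir, paste0("microbes", ext)),
                    format = format)
  # Intensities rounded to one decimal keep the fixture compact; ratio and
  # rclr statistics are insensitive to this quantization.
  met <- sim$metabolites
  metR <- FeatureTable(round(tableValues(met), 1), "intensities")
  writeFeatureTable(metR, file.path(dir, paste0("metabolites", ext)),
                    format = format, digits = 12)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  utils::write.table(
    data.frame(feature_id = names(tr@familyMap), family = tr@familyMap),
    file.path(dir, "feature_families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(tr@metaboliteClass),
               class = tr@metaboliteClass),
    file.path(dir, "metabolite_classes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truthList <- list(
    seed = tr@seed,
    latent_factors = signif(unname(tr@latentFactors), 6),
    microbe_loadings = signif(unname(tr@microbeLoadings), 6),
    metabolite_loadings = signif(unname(tr@metaboliteLoadings), 6),
    sample_ids = rownames(tr@latentFactors),
    microbe_ids = rownames(tr@microbeLoadings),
    metabolite_ids = rownames(tr@metaboliteLoadings),
    group_effects = as.list(tr@groupEffects),
    family_map = as.list(tr@familyMap),
    metabolite_class = as.list(tr@metaboliteClass),
    planted_pairs = tr@plantedPairs,
    differential_microbes = tr@differentialMicrobes,
    metabolite_sets = tr@metaboliteSets)
  jsonlite::write_json(truthList, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the ground truth JSON written by [writeFixture()]
#'
#' @param path path to `truth.json`.
#' @return a [SyntheticTruth-class].
#' @export
readTruth <- function(path) {
  tl <- jsonlite::read_json(path, simplifyVector = TRUE)
  U <- matrix(unlist(tl$latent_factors), nrow = length(tl$sample_ids),
              byrow = FALSE)
  Wmic <- matrix(unlist(tl$microbe_loadings), nrow = length(tl$microbe_ids))
  Wmet <- matrix(unlist(tl$metabolite_loadings),
                 nrow = length(tl$metabolite_ids))
  rownames(U) <- tl$sample_ids
  rownames(Wmic) <- tl$microbe_ids
  rownames(Wmet) <- tl$metabolite_ids
  new("SyntheticTruth",
      latentFactors = U, microbeLoadings = Wmic, metaboliteLoadings = Wmet,
      groupEffects = unlist(tl$group_effects),
      familyMap = unlist(tl$family_map),
      metaboliteClass = unlist(tl$metabolite_class),
      plantedPairs = as.data.frame(tl$planted_pairs),
      differentialMicrobes = lapply(tl$differential_microbes, unlist),
      metaboliteSets = lapply(tl$metabolite_sets, unlist),
      seed = tl$seed)
}
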