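#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. Inputs may be file
#' paths (TSV/BIOM tables, metadata TSV, feature-family TSV) or in-memory
#' objects. Every stochastic stage draws its seed from the single master
#' `seed`, and all seeds and parameters are echoed into the provenance
#' JSON.
#'
#' @param microbeTable,metaboliteTable paths or [FeatureTable-class]s.
#' @param metadata path or data.frame (see [validateSampleMetadata()]).
#' @param featureFamilies path or data.frame with columns `feature_id`,
#'   `family`, used for the family log ratio.
#' @param outputDir output directory.
#' @param tableFormat `"tsv"` or `"biom"`.
#' @param orientation TSV orientation (see [readFeatureTable()]).
#' @param depth rarefaction depth (default 10200).
#' @param rank,maxIter,tol factorization controls for the per-table RPCA
#'   ordination.
#' @param jointRank rank of the joint integration stage (default 5; the
#'   feature-correlation geometry needs axes beyond the dominant
#'   ordination structure).
#' @param seed master seed.
#' @param trainFraction,nSplits joint-factorization CV settings.
#' @param featureQuantile per-tail fraction of microbes kept (by axis-1
#'   loading) before integration.
#' @param vipThreshold PLS-DA VIP selection cutoff.
#' @param permutations PERMANOVA permutations.
#' @param numeratorFamily,denominatorFamily family labels forming the
#'   microbial log ratio.
#' @param plsdaComparison the two group labels compared by PLS-DA.
#' @param excludeFirstTimepoint drop the earliest timepoint before PLS-DA
#'   (all animals still share the baseline diet there).
#' @param lastTimepoints number of final timepoints entering the pairwise
#'   group tests.
#' @return a validated config list of class `"crossOmicsConfig"`.
#' @export
pipelineConfig <- function(microbeTable, metaboliteTable, metadata,
                           featureFamilies, outputDir,
                           tableFormat = "tsv", orientation = "features",
                           depth = 10200, rank = 3, jointRank = 5,
                           maxIter = 200,
                           tol = 1e-6, seed = 1, trainFraction = 0.8,
                           nSplits = 5, featureQuantile = 0.1,
                           vipThreshold = 1, permutations = 999,
                           numeratorFamily = "MuribaculaceaeLike",
                           denominatorFamily = "AkkermansiaceaeLike",
                           plsdaComparison = c("RC-Air", "HFHC-IHC"),
                           excludeFirstTimepoint = TRUE,
                           lastTimepoints = 2) {
  cfg <- list(microbeTable = microbeTable,
              metaboliteTable = metaboliteTable, metadata = metadata,
              featureFamilies = featureFamilies, outputDir = outputDir,
              tableFormat = tableFormat, orientation = orientation,
              depth = depth, rank = rank, jointRank = jointRank,
              maxIter = maxIter, tol = tol,
              seed = seed, trainFraction = trainFraction,
              nSplits = nSplits, featureQuantile = featureQuantile,
              vipThreshold = vipThreshold, permutations = permutations,
              numeratorFamily = numeratorFamily,
              denominatorFamily = denominatorFamily,
              plsdaComparison = plsdaComparison,
              excludeFirstTimepoint = excludeFirstTimepoint,
              lastTimepoints = lastTimepoints)
  class(cfg) <- "crossOmicsConfig"
  validatePipelineConfig(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipelineConfig()].
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Validate a pipeline configuration before any computation
#' @param cfg config list.
#' @return the config, or an error naming the invalid field.
#' @export
validatePipelineConfig <- function(cfg) {
  need <- c("microbeTable", "metaboliteTable", "metadata",
            "featureFamilies", "outputDir")
  for (f in need) {
    if (is.null(cfg[[f]])) stop("config missing required field: ", f)
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1L && f != "outputDir" &&
        !file.exists(v))
      stop("config field ", f, ": no such file: ", v)
  }
  if (cfg$depth <= 0) stop("config: depth must be positive")
  if (cfg$trainFraction <= 0.5 || cfg$trainFraction >= 0.95)
    stop("config: trainFraction must be in (0.5, 0.95)")
  if (length(cfg$plsdaComparison) != 2L)
    stop("config: plsdaComparison must name exactly 2 groups")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.writeTSV <- function(df, path, digits = 12) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    trimws(formatC(x, digits = digits, format = "g")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeMatrixTSV <- function(m, path, idcol = "id", digits = 12) {
  df <- data.frame(rownames(m),
                   trimws(formatC(m, digits = digits, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(idcol, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full microbiome-metabolome analysis pipeline
#'
#' Chains the stages: rarefaction, rclr + RPCA ordination of the
#' microbiome, PERMANOVA on the RPCA distances, the microbial family log
#' ratio with pairwise group tests and the mixed-effects age trend, PLS-DA
#' on the rclr metabolome with a VIP-based metabolite log ratio,
#' loading-based feature filtering, joint factorization with CV,
#' cross-omic feature correlations, and the microbiome-vs-metabolome
#' log-ratio regression. All artifacts plus a machine-readable provenance
#' JSON are written under `config$outputDir`; rerunning with an identical
#' config reproduces the outputs bit for bit.
#'
#' @param config a config from [pipelineConfig()] or a YAML path.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with the main in-memory results.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- validatePipelineConfig(config)
  say <- function(...) if (!quiet) message("[crossOmics] ", ...)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outputDir, f)

  loadTable <- function(x, kind) {
    if (is(x, "FeatureTable")) return(x)
    readFeatureTable(x, format = cfg$tableFormat, kind = kind,
                     orientation = cfg$orientation)
  }
  mic <- .stage("read_microbes", loadTable(cfg$microbeTable, "counts"))
  met <- .stage("read_metabolites",
                loadTable(cfg$metaboliteTable, "intensities"))
  meta <- .stage("read_metadata",
                 if (is.character(cfg$metadata)) readSampleMetadata(cfg$metadata)
                 else validateSampleMetadata(cfg$metadata))
  fams <- .stage("read_families",
                 if (is.character(cfg$featureFamilies))
                   utils::read.table(cfg$featureFamilies, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
                 else cfg$featureFamilies)

  say("rarefying microbiome to depth ", cfg$depth)
  micR <- .stage("rarefy", suppressMessages(
    rarefy(mic, depth = cfg$depth, seed = .streamSeed(cfg$seed, "rarefy"))))
  if (!all(sampleIDs(micR) %in% meta$sample_id))
    stop("pipeline stage 'align' failed: metadata missing for microbiome samples")
  metaMic <- meta[match(sampleIDs(micR), meta$sample_id), , drop = FALSE]
  if (!all(sampleIDs(met) %in% meta$sample_id))
    stop("pipeline stage 'align' failed: metadata missing for metabolome samples")
  metaMet <- meta[match(sampleIDs(met), meta$sample_id), , drop = FALSE]

  say("RPCA ordination of the microbiome")
  ord <- .stage("rpca", rpca(micR, rank = cfg$rank, maxIter = cfg$maxIter,
                             tol = cfg$tol))
  writeOrdination(ord$scores, ord$loadings, ord$eigenvalues,
                  ord$proportionExplained, out("microbiome_ordination.txt"))
  .writeMatrixTSV(ord$distances, out("microbiome_distances.tsv"),
                  idcol = "sample_id")

  say("PERMANOVA on RPCA distances")
  pv <- .stage("permanova",
               permanova(ord$distances, metaMic$group,
                         permutations = cfg$permutations,
                         seed = .streamSeed(cfg$seed, "permanova")))
  jsonlite::write_json(list(pseudo_F = unname(pv$statistic),
                            p_value = pv$p.value,
                            permutations = pv$permutations,
                            group_sizes = as.list(pv$groupSizes)),
                       out("permanova.json"), auto_unbox = TRUE, digits = NA)

  say("family log ratio (", cfg$numeratorFamily, " / ",
      cfg$denominatorFamily, ")")
  famRatio <- .stage("family_log_ratio", {
    num <- fams$feature_id[fams$family == cfg$numeratorFamily]
    den <- fams$feature_id[fams$family == cfg$denominatorFamily]
    featureSetLogRatio(micR, intersect(num, featureIDs(micR)),
                       intersect(den, featureIDs(micR)))
  })
  writeLogRatio(famRatio, out("family_log_ratio.tsv"), metaMic)

  lastAges <- utils::tail(sort(unique(metaMic$host_age)), cfg$lastTimepoints)
  mw <- .stage("pairwise_tests", {
    keep <- names(ratioValues(famRatio)) %in%
      metaMic$sample_id[metaMic$host_age %in% lastAges]
    v <- ratioValues(famRatio)[keep]
    g <- metaMic$group[match(names(v), metaMic$sample_id)]
    pairwiseMannWhitney(v, g)
  })
  .writeTSV(mw, out("family_ratio_pairwise_tests.tsv"))

  lme <- .stage("lme_trend", tryCatch(lmeTrend(famRatio, metaMic),
                                      error = function(e) NULL))
  if (!is.null(lme)) {
    co <- cbind(term = rownames(lme$coefficients), lme$coefficients)
    .writeTSV(co, out("family_ratio_lme_trend.tsv"))
  }

  say("PLS-DA: ", cfg$plsdaComparison[1], " vs ", cfg$plsdaComparison[2])
  plsRes <- .stage("plsda", {
    keep <- metaMet$group %in% cfg$plsdaComparison
    if (cfg$excludeFirstTimepoint)
      keep <- keep & metaMet$host_age > min(metaMet$host_age)
    sub <- met[metaMet$sample_id[keep], ]
    labels <- factor(metaMet$group[keep], levels = cfg$plsdaComparison)
    model <- fitPlsda(rclr(sub), labels, nComponents = 2, folds = 5,
                      seed = .streamSeed(cfg$seed, "plsda"),
                      vipThreshold = cfg$vipThreshold)
    sets <- significantFeatureLogRatio(model, sub, labels)
    list(model = model, labels = labels, sub = sub, sets = sets)
  })
  model <- plsRes$model
  .writeTSV(data.frame(feature_id = names(vipScores(model)),
                       vip = vipScores(model),
                       selected = names(vipScores(model)) %in%
                         selectedFeatures(model),
                       class_association = ifelse(
                         names(vipScores(model)) %in%
                           numeratorIDs(plsRes$sets), cfg$plsdaComparison[1],
                         ifelse(names(vipScores(model)) %in%
                                  denominatorIDs(plsRes$sets),
                                cfg$plsdaComparison[2], ""))),
            out("plsda_vip.tsv"))
  jsonlite::write_json(list(classes = model@classes,
                            n_components = model@nComponents,
                            cv_cer = cvCER(model),
                            n_selected = length(selectedFeatures(model)),
                            vip_threshold = model@vipThreshold),
                       out("plsda_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  metRatio <- .stage("metabolite_log_ratio",
                     featureSetLogRatio(met, numeratorIDs(plsRes$sets),
                                        denominatorIDs(plsRes$sets)))
  writeLogRatio(metRatio, out("metabolite_log_ratio.tsv"), metaMet)

  say("joint factorization of filtered tables")
  joint <- .stage("joint_factorization", {
    selMic <- selectFeaturesByLoading(
      stats::setNames(ord$loadings[, 1], rownames(ord$loadings)),
      q = cfg$featureQuantile)$selected
    al <- alignTables(micR[, selMic], met[, selectedFeatures(model)], meta)
    jointFactorize(list(microbes = al$t1, metabolites = al$t2),
                   rank = cfg$jointRank, maxIter = cfg$maxIter,
                   tol = cfg$tol,
                   seed = .streamSeed(cfg$seed, "jointcv"),
                   trainFraction = cfg$trainFraction,
                   nSplits = cfg$nSplits)
  })
  writeOrdination(sampleScores(joint),
                  do.call(rbind, tableLoadings(joint)),
                  singularValues(joint), proportionExplained(joint),
                  out("joint_ordination.txt"))
  .writeTSV(cvErrors(joint), out("joint_cv_errors.tsv"))
  cc <- .stage("cross_correlations", crossCorrelations(joint))
  .writeMatrixTSV(corMatrix(cc), out("cross_correlations.tsv"),
                  idcol = "feature_id")

  say("microbiome vs metabolome log-ratio regression")
  reg <- .stage("logratio_regression",
                logratioRegression(famRatio, metRatio))
  jsonlite::write_json(reg, out("logratio_regression.json"),
                       auto_unbox = TRUE, digits = NA)

  prov <- list(
    package = "crossOmics",
    package_version = as.character(utils::packageVersion("crossOmics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = cfg[setdiff(names(cfg), c("microbeTable",
                                           "metaboliteTable", "metadata",
                                           "featureFamilies",
                                           "outputDir"))],
    inputs = lapply(cfg[c("microbeTable", "metaboliteTable", "metadata",
                          "featureFamilies")], function(x)
                            if (is.character(x)) x else "<in-memory>"),
    seeds = list(master = cfg$seed,
                 rarefy = .streamSeed(cfg$seed, "rarefy"),
                 permanova = .streamSeed(cfg$seed, "permanova"),
                 plsda = .streamSeed(cfg$seed, "plsda"),
                 jointcv = .streamSeed(cfg$seed, "jointcv")),
    dropped_samples = list(rarefaction = droppedSamples(micR),
                           family_ratio = droppedSamples(famRatio),
                           metabolite_ratio = droppedSamples(metRatio)))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "list")

  say("done: ", cfg$outputDir)
  invisible(list(ordination = ord, permanova = pv, familyRatio = famRatio,
                 pairwiseTests = mw, lmeTrend = lme, plsda = model,
                 metaboliteRatio = metRatio, joint = joint,
                 correlations = cc, regression = reg,
                 outputDir = cfg$outputDir))
}
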