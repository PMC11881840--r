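#' @import methods
NULL

#' Sample-by-feature abundance table
#'
#' Container for a nonnegative sample x feature matrix of either sequencing
#' counts (e.g. 16S ASV counts) or LC-MS/MS peak intensities. Rows are
#' samples, columns are features; both must carry unique identifiers.
#'
#' @slot values nonnegative numeric matrix, samples in rows.
#' @slot kind `"counts"` or `"intensities"`.
#' @slot droppedSamples ids of samples removed by upstream filtering
#'   (e.g. rarefaction depth failures); empty on construction.
#'
#' @seealso [FeatureTable()], [rarefy()], [rclr()]
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", kind = "character",
                 droppedSamples = "character"),
  prototype(droppedSamples = character(0)))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "sample and feature ids (dimnames) are required")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicated sample ids")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicated feature ids")
  if (is.numeric(v) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "negative value in feature table")
  if (is.numeric(v) && anyNA(v))
    msg <- c(msg, "NA values are not allowed")
  if (!(length(object@kind) == 1L && object@kind %in% c("counts", "intensities")))
    msg <- c(msg, "kind must be 'counts' or 'intensities'")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values nonnegative numeric matrix (samples x features).
#' @param kind `"counts"` or `"intensities"`.
#' @param sampleIDs,featureIDs optional ids; default to the matrix dimnames.
#' @return a [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(5, 0, 2, 7, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' FeatureTable(m, "counts")
#' @export
FeatureTable <- function(values, kind = c("counts", "intensities"),
                         sampleIDs = rownames(values),
                         featureIDs = colnames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sampleIDs, featureIDs)
  new("FeatureTable", values = values, kind = kind)
}

#' Robust centered log-ratio matrix
#'
#' Result of the rclr transformation: per-sample log abundances centered on
#' the geometric mean of that sample's observed (positive) entries. Zeros in
#' the source table are *unobserved*, never imputed: `values` holds `NA`
#' where `mask` is `FALSE`.
#'
#' @slot values numeric matrix with `NA` at unobserved entries.
#' @slot mask logical matrix, `TRUE` where the source entry was positive.
#' @exportClass RclrMatrix
setClass("RclrMatrix",
  representation(values = "matrix", mask = "matrix"))

setValidity("RclrMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask dimensions differ")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(is.na(object@values[object@mask])))
    return("NA at an observed entry")
  if (any(!is.na(object@values[!object@mask])))
    return("non-NA at an unobserved entry")
  rm <- rowSums(object@mask)
  ok <- rowSums(object@values * object@mask, na.rm = TRUE)
  if (any(rm > 0 & abs(ok) > 1e-8 * pmax(rm, 1)))
    return("observed entries of a sample are not centered")
  TRUE
})

#' Natural log ratio of two feature sets
#'
#' Per-sample `ln(sum(numerator features) / sum(denominator features))`.
#' Samples where either sum is zero are excluded and recorded in
#' `droppedSamples`.
#'
#' @slot values named numeric vector of log ratios for retained samples.
#' @slot numeratorIDs,denominatorIDs disjoint feature-id sets.
#' @slot droppedSamples ids of excluded samples.
#' @exportClass LogRatioSeries
setClass("LogRatioSeries",
  representation(values = "numeric", numeratorIDs = "character",
                 denominatorIDs = "character", droppedSamples = "character"))

setValidity("LogRatioSeries", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@values))) msg <- c(msg, "non-finite log ratio")
  if (length(intersect(object@numeratorIDs, object@denominatorIDs)))
    msg <- c(msg, "numerator and denominator sets overlap")
  if (is.null(names(object@values)) && length(object@values))
    msg <- c(msg, "values must be named by sample id")
  if (length(msg)) msg else TRUE
})

#' Low-rank matrix completion result
#'
#' Factorization `X ~ U S V'` of a partially observed matrix, fitted on the
#' observed entries only. `U` and `V` have orthonormal columns and `S` is
#' diagonal with nonincreasing nonnegative entries.
#'
#' @slot U sample factors (n x r), orthonormal columns.
#' @slot S r x r diagonal core of singular values.
#' @slot V feature factors (p x r), orthonormal columns.
#' @slot iterations gradient iterations performed.
#' @slot observedRMSE root mean squared residual over observed entries.
#' @slot converged whether the relative loss change fell below `tol`.
#' @slot lossTrace mean squared observed-entry loss per iteration.
#' @exportClass CompletionResult
setClass("CompletionResult",
  representation(U = "matrix", S = "matrix", V = "matrix",
                 iterations = "integer", observedRMSE = "numeric",
                 converged = "logical", lossTrace = "numeric"))

setValidity("CompletionResult", function(object) {
  r <- ncol(object@U)
  msg <- character(0)
  if (max(abs(crossprod(object@U) - diag(r))) > 1e-6)
    msg <- c(msg, "U columns not orthonormal")
  if (max(abs(crossprod(object@V) - diag(r))) > 1e-6)
    msg <- c(msg, "V columns not orthonormal")
  d <- diag(object@S)
  if (any(d < -1e-10) || is.unsorted(rev(d)))
    msg <- c(msg, "singular values must be nonnegative and nonincreasing")
  if (length(msg)) msg else TRUE
})

#' Joint multi-table factorization
#'
#' Shared sample scores across several omics tables measured on the same
#' samples, with per-table feature loadings and cores, and cross-validated
#' reconstruction errors (observed-entry RMSE per random train/test split).
#'
#' @slot sampleScores n x r matrix of shared sample scores (U scaled by the
#'   shared singular values).
#' @slot sampleFactors n x r orthonormal shared basis U.
#' @slot tableCores list of r x r core matrices, one per table.
#' @slot tableLoadings list of feature-loading matrices (p_m x r).
#' @slot sharedEigenvalues shared singular values across tables.
#' @slot proportionExplained per-axis share of the rank-r model variance.
#' @slot cvTrainError,cvTestError observed-entry RMSE per CV split.
#' @slot lossTrace joint training objective per iteration (final full fit).
#' @exportClass JointFactorization
setClass("JointFactorization",
  representation(sampleScores = "matrix", sampleFactors = "matrix",
                 tableCores = "list", tableLoadings = "list",
                 sharedEigenvalues = "numeric",
                 proportionExplained = "numeric",
                 cvTrainError = "numeric", cvTestError = "numeric",
                 lossTrace = "numeric"))

setValidity("JointFactorization", function(object) {
  msg <- character(0)
  if (length(object@tableCores) != length(object@tableLoadings))
    msg <- c(msg, "cores/loadings length mismatch")
  if (any(object@cvTrainError < 0) || any(object@cvTestError < 0))
    msg <- c(msg, "negative CV error")
  if (sum(object@proportionExplained) > 1 + 1e-8)
    msg <- c(msg, "proportion explained exceeds 1")
  if (length(msg)) msg else TRUE
})

#' Cross-omic feature correlation matrix
#'
#' Correlations between reconstructed feature profiles of two tables from a
#' joint factorization; entries lie in `[-1, 1]`.
#'
#' @slot matrix features(table 1) x features(table 2) correlation matrix.
#' @slot method `"pearson"` or `"spearman"`.
#' @exportClass CrossOmicCorrelations
setClass("CrossOmicCorrelations",
  representation(matrix = "matrix", method = "character"))

setValidity("CrossOmicCorrelations", function(object) {
  if (any(abs(object@matrix) > 1 + 1e-12)) return("correlation outside [-1,1]")
  TRUE
})

#' Two-group PLS-DA model with VIP scores
#'
#' NIPALS partial least squares discriminant model on an rclr-transformed
#' table, with variable importance in projection (VIP) per feature and a
#' cross-validated classification error rate (CER).
#'
#' @slot nComponents number of latent components.
#' @slot weights,loadings,scores NIPALS X-weights (p x A), X-loadings
#'   (p x A) and X-scores (n x A).
#' @slot yLoadings per-component y loadings.
#' @slot rotation `W (P'W)^{-1}`, maps centered data to scores.
#' @slot vip per-feature VIP scores; `mean(vip^2) == 1`.
#' @slot cvCER pooled misclassification rate over held-out folds.
#' @slot selectedFeatures features with VIP above `vipThreshold`.
#' @slot vipThreshold selection cutoff (default 1).
#' @slot classes the two class labels, in factor-level order.
#' @slot center,scaleFactors column centering/scaling used for the fit.
#' @exportClass PlsdaModel
setClass("PlsdaModel",
  representation(nComponents = "integer", weights = "matrix",
                 loadings = "matrix", scores = "matrix",
                 yLoadings = "numeric", rotation = "matrix",
                 vip = "numeric", cvCER = "numeric",
                 selectedFeatures = "character", vipThreshold = "numeric",
                 classes = "character", center = "numeric",
                 scaleFactors = "numeric"))

setValidity("PlsdaModel", function(object) {
  msg <- character(0)
  if (abs(mean(object@vip^2) - 1) > 1e-8)
    msg <- c(msg, "VIP identity mean(vip^2) = 1 violated")
  if (object@cvCER < 0 || object@cvCER > 1)
    msg <- c(msg, "cvCER outside [0,1]")
  if (length(object@classes) != 2L) msg <- c(msg, "exactly two classes required")
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic paired cohort
#'
#' Describes the three-arm repeated-measures design emulated by
#' [simulateCohort()]: diet/exposure groups, mice per group, sampling
#' timepoints (host age in weeks), sequencing depth, zero-inflation, planted
#' effect size and latent rank.
#'
#' @slot groups group labels (diet-exposure).
#' @slot micePerGroup mice per group.
#' @slot timepoints host ages (weeks), strictly increasing.
#' @slot nMicrobes,nMetabolites feature counts per table.
#' @slot depthMean expected sequencing library size.
#' @slot depthSdlog lognormal sd of library sizes (log scale).
#' @slot dropout zero-inflation probability for counts.
#' @slot effectSize planted group effect at the final timepoint
#'   (natural-log units).
#' @slot rank number of shared latent factors.
#' @slot latentSD,subjectSD,noiseSD scales of latent scores, per-subject
#'   intercepts, and metabolite measurement noise (log scale).
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(groups = "character", micePerGroup = "integer",
                 timepoints = "numeric", nMicrobes = "integer",
                 nMetabolites = "integer", depthMean = "numeric",
                 depthSdlog = "numeric", dropout = "numeric",
                 effectSize = "numeric", rank = "integer",
                 latentSD = "numeric", subjectSD = "numeric",
                 noiseSD = "numeric"))

setValidity("CohortDesign", function(object) {
  msg <- character(0)
  if (object@micePerGroup < 2L) msg <- c(msg, "need >= 2 mice per group")
  if (length(object@timepoints) < 2L || is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be >= 2 and strictly increasing")
  pos <- c(object@nMicrobes, object@nMetabolites, object@depthMean, object@rank)
  if (any(pos <= 0)) msg <- c(msg, "counts parameters must be positive")
  if (object@dropout < 0 || object@dropout >= 1) msg <- c(msg, "dropout must be in [0,1)")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Planted quantities recorded by [simulateCohort()] for recovery tests:
#' latent sample factors shared by both omics tables, per-table loadings,
#' group effect ramps, the family labels of microbial features (including
#' the opposing Muribaculaceae-like and Akkermansiaceae-like families),
#' metabolite class memberships, and the planted microbe-metabolite pairs.
#'
#' @slot latentFactors n_samples x r matrix of latent scores.
#' @slot microbeLoadings,metaboliteLoadings feature x r loading matrices.
#' @slot groupEffects per-group multiplier on the planted effect ramp.
#' @slot familyMap named character: microbe feature -> family label.
#' @slot metaboliteClass named character: metabolite -> class label.
#' @slot plantedPairs data.frame with columns `microbe`, `metabolite`.
#' @slot differentialMicrobes list with `numerator` (Muribaculaceae-like)
#'   and `denominator` (Akkermansiaceae-like) feature ids.
#' @slot metaboliteSets list with `rc` and `hfhcIhc` associated metabolites.
#' @slot seed master seed the cohort was generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(latentFactors = "matrix", microbeLoadings = "matrix",
                 metaboliteLoadings = "matrix", groupEffects = "numeric",
                 familyMap = "character", metaboliteClass = "character",
                 plantedPairs = "data.frame", differentialMicrobes = "list",
                 metaboliteSets = "list", seed = "numeric"))

setValidity("SyntheticTruth", function(object) {
  dm <- object@differentialMicrobes
  if (length(intersect(dm$numerator, dm$denominator)))
    return("opposing differential feature families must be disjoint")
  TRUE
})
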