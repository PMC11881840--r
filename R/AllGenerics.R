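#' @name accessors
#' @title Accessors for crossOmics classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an object of the documented class.
#' @param x an object (for `dim`/`dimnames`/subsetting methods).
NULL

#' @rdname accessors
#' @export
setGeneric("tableValues", function(object) standardGeneric("tableValues"))
#' @rdname accessors
#' @export
setGeneric("tableKind", function(object) standardGeneric("tableKind"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("droppedSamples", function(object) standardGeneric("droppedSamples"))
#' @rdname accessors
#' @export
setGeneric("rclrValues", function(object) standardGeneric("rclrValues"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(object) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("ratioValues", function(object) standardGeneric("ratioValues"))
#' @rdname accessors
#' @export
setGeneric("numeratorIDs", function(object) standardGeneric("numeratorIDs"))
#' @rdname accessors
#' @export
setGeneric("denominatorIDs", function(object) standardGeneric("denominatorIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleFactors", function(object) standardGeneric("sampleFactors"))
#' @rdname accessors
#' @export
setGeneric("featureFactors", function(object) standardGeneric("featureFactors"))
#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("observedRMSE", function(object) standardGeneric("observedRMSE"))
#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))
#' @rdname accessors
#' @export
setGeneric("tableLoadings", function(object) standardGeneric("tableLoadings"))
#' @rdname accessors
#' @export
setGeneric("tableCores", function(object) standardGeneric("tableCores"))
#' @rdname accessors
#' @export
setGeneric("proportionExplained", function(object) standardGeneric("proportionExplained"))
#' @rdname accessors
#' @export
setGeneric("cvErrors", function(object) standardGeneric("cvErrors"))
#' @rdname accessors
#' @export
setGeneric("corMatrix", function(object) standardGeneric("corMatrix"))
#' @rdname accessors
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("cvCER", function(object) standardGeneric("cvCER"))

## ---- FeatureTable ----

#' @rdname accessors
#' @export
setMethod("tableValues", "FeatureTable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("tableKind", "FeatureTable", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(object) rownames(object@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "FeatureTable", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("droppedSamples", "FeatureTable", function(object) object@droppedSamples)

#' @rdname accessors
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dimnames", "FeatureTable", function(x) dimnames(x@values))

#' Subset a FeatureTable by samples (i) and features (j)
#' @param x a FeatureTable
#' @param i,j sample / feature indices or ids
#' @param ... ignored
#' @param drop ignored; tables never drop to vectors
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  initialize(x, values = v)
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s): %d samples x %d features\n",
              object@kind, nrow(object@values), ncol(object@values)))
  cat(sprintf("  sparsity: %.1f%% zero entries\n",
              100 * mean(object@values == 0)))
  if (length(object@droppedSamples))
    cat(sprintf("  dropped samples: %d\n", length(object@droppedSamples)))
})

## ---- RclrMatrix ----

#' @rdname accessors
#' @export
setMethod("rclrValues", "RclrMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("observedMask", "RclrMatrix", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "RclrMatrix", function(object) rownames(object@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "RclrMatrix", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("dim", "RclrMatrix", function(x) dim(x@values))

setMethod("show", "RclrMatrix", function(object) {
  cat(sprintf("RclrMatrix: %d samples x %d features, %.1f%% observed\n",
              nrow(object@values), ncol(object@values),
              100 * mean(object@mask)))
})

## ---- LogRatioSeries ----

#' @rdname accessors
#' @export
setMethod("ratioValues", "LogRatioSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("numeratorIDs", "LogRatioSeries", function(object) object@numeratorIDs)
#' @rdname accessors
#' @export
setMethod("denominatorIDs", "LogRatioSeries", function(object) object@denominatorIDs)
#' @rdname accessors
#' @export
setMethod("droppedSamples", "LogRatioSeries", function(object) object@droppedSamples)

setMethod("show", "LogRatioSeries", function(object) {
  cat(sprintf("LogRatioSeries: %d samples (%d dropped), ln(%d features / %d features)\n",
              length(object@values), length(object@droppedSamples),
              length(object@numeratorIDs), length(object@denominatorIDs)))
})

#' Coerce a LogRatioSeries to a data.frame
#' @param x a LogRatioSeries
#' @param ... ignored
#' @export
as.data.frame.LogRatioSeries <- function(x, ...) {
  data.frame(sample_id = names(x@values), log_ratio = unname(x@values),
             stringsAsFactors = FALSE)
}

## ---- CompletionResult ----

#' @rdname accessors
#' @export
setMethod("sampleFactors", "CompletionResult", function(object) object@U)
#' @rdname accessors
#' @export
setMethod("featureFactors", "CompletionResult", function(object) object@V)
#' @rdname accessors
#' @export
setMethod("singularValues", "CompletionResult", function(object) diag(object@S))
#' @rdname accessors
#' @export
setMethod("observedRMSE", "CompletionResult", function(object) object@observedRMSE)
#' @rdname accessors
#' @export
setMethod("lossTrace", "CompletionResult", function(object) object@lossTrace)

setMethod("show", "CompletionResult", function(object) {
  cat(sprintf("CompletionResult: rank %d, %d iterations (%s), observed RMSE %.4g\n",
              ncol(object@U), object@iterations,
              if (object@converged) "converged" else "max iterations",
              object@observedRMSE))
})

#' Reconstruct the fitted low-rank matrix U S V'
#' @param object a CompletionResult
#' @return dense numeric matrix of fitted values
#' @export
setGeneric("fittedMatrix", function(object) standardGeneric("fittedMatrix"))

#' @rdname fittedMatrix
#' @export
setMethod("fittedMatrix", "CompletionResult", function(object)
  object@U %*% object@S %*% t(object@V))

## ---- JointFactorization ----

#' @rdname accessors
#' @export
setMethod("sampleScores", "JointFactorization", function(object) object@sampleScores)
#' @rdname accessors
#' @export
setMethod("sampleFactors", "JointFactorization", function(object) object@sampleFactors)
#' @rdname accessors
#' @export
setMethod("tableLoadings", "JointFactorization", function(object) object@tableLoadings)
#' @rdname accessors
#' @export
setMethod("tableCores", "JointFactorization", function(object) object@tableCores)
#' @rdname accessors
#' @export
setMethod("singularValues", "JointFactorization", function(object) object@sharedEigenvalues)
#' @rdname accessors
#' @export
setMethod("proportionExplained", "JointFactorization", function(object) object@proportionExplained)
#' @rdname accessors
#' @export
setMethod("lossTrace", "JointFactorization", function(object) object@lossTrace)

#' @rdname accessors
#' @export
setMethod("cvErrors", "JointFactorization", function(object)
  data.frame(split = seq_along(object@cvTrainError),
             train_rmse = object@cvTrainError,
             test_rmse = object@cvTestError))

setMethod("show", "JointFactorization", function(object) {
  cat(sprintf("JointFactorization: %d tables, %d samples, rank %d\n",
              length(object@tableCores), nrow(object@sampleScores),
              ncol(object@sampleScores)))
  if (length(object@cvTestError))
    cat(sprintf("  CV observed-entry RMSE: train %.4g, test %.4g (%d splits)\n",
                mean(object@cvTrainError), mean(object@cvTestError),
                length(object@cvTestError)))
})

## ---- CrossOmicCorrelations ----

#' @rdname accessors
#' @export
setMethod("corMatrix", "CrossOmicCorrelations", function(object) object@matrix)

setMethod("show", "CrossOmicCorrelations", function(object) {
  cat(sprintf("CrossOmicCorrelations (%s): %d x %d features\n",
              object@method, nrow(object@matrix), ncol(object@matrix)))
})

## ---- PlsdaModel ----

#' @rdname accessors
#' @export
setMethod("vipScores", "PlsdaModel", function(object) object@vip)
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "PlsdaModel", function(object) object@selectedFeatures)
#' @rdname accessors
#' @export
setMethod("cvCER", "PlsdaModel", function(object) object@cvCER)
#' @rdname accessors
#' @export
setMethod("sampleScores", "PlsdaModel", function(object) object@scores)

setMethod("show", "PlsdaModel", function(object) {
  cat(sprintf("PlsdaModel: %s vs %s, %d components\n",
              object@classes[1], object@classes[2], object@nComponents))
  cat(sprintf("  CV CER: %.3f; %d features with VIP > %g\n",
              object@cvCER, length(object@selectedFeatures),
              object@vipThreshold))
})

## ---- SyntheticTruth / CohortDesign ----

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %s; %d mice/group, %d timepoints\n",
              paste(object@groups, collapse = ", "),
              object@micePerGroup, length(object@timepoints)))
  cat(sprintf("  %d microbes, %d metabolites, depth ~%g, dropout %.2f, effect %.2f, rank %d\n",
              object@nMicrobes, object@nMetabolites, object@depthMean,
              object@dropout, object@effectSize, object@rank))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d samples, rank %d; %d/%d opposing differential microbes; %d planted pairs\n",
              nrow(object@latentFactors), ncol(object@latentFactors),
              length(object@differentialMicrobes$numerator),
              length(object@differentialMicrobes$denominator),
              nrow(object@plantedPairs)))
})
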