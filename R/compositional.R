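#' Robust centered log-ratio (rclr) transformation
#'
#' Per sample, takes the natural log of each positive entry and centers on
#' the mean log of that sample's positive entries (the log of their
#' geometric mean). Zeros are marked unobserved — never imputed — which is
#' what makes the transform robust to the extreme sparsity of amplicon and
#' untargeted MS tables. The result is scale invariant: multiplying a
#' sample's row by any positive constant leaves its rclr values unchanged.
#'
#' @param object a [FeatureTable-class]; every sample needs at least one
#'   positive entry.
#' @param pseudocount optional constant added to all entries before the
#'   transform. Default 0 (off): the rclr exists precisely to avoid
#'   pseudocounts; the flag is provided for sensitivity analyses only.
#' @return an [RclrMatrix-class] with `NA` at unobserved entries and a
#'   logical observed mask.
#' @examples
#' t <- FeatureTable(matrix(c(1, 10, 100), 1,
#'                   dimnames = list("s1", c("a", "b", "c"))), "counts")
#' rclrValues(rclr(t))   # -2.302585  0  2.302585
#' @export
rclr <- function(object, pseudocount = 0) {
  stopifnot(is(object, "FeatureTable"))
  x <- tableValues(object)
  if (pseudocount > 0) x <- x + pseudocount
  zero <- rowSums(x > 0) == 0L
  if (any(zero))
    stop("sample(s) with no positive entries: ",
         paste(rownames(x)[zero], collapse = ", "))
  mask <- x > 0
  vals <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  vals[mask] <- log(x[mask])
  vals <- vals - rowMeans(vals, na.rm = TRUE)
  new("RclrMatrix", values = vals, mask = mask)
}

#' Natural log ratio of two feature sets
#'
#' Per sample, `ln(sum of numerator features / sum of denominator
#' features)`, the total-independent biomarker statistic used for e.g. a
#' Muribaculaceae / Akkermansiaceae family ratio. Samples where either sum
#' is zero are excluded and listed in the result's `droppedSamples`.
#'
#' @param object a [FeatureTable-class].
#' @param numerator,denominator disjoint, nonempty sets of feature ids
#'   present in `object`.
#' @return a [LogRatioSeries-class].
#' @export
featureSetLogRatio <- function(object, numerator, denominator) {
  stopifnot(is(object, "FeatureTable"))
  numerator <- as.character(numerator)
  denominator <- as.character(denominator)
  if (!length(numerator) || !length(denominator))
    stop("numerator and denominator must be nonempty")
  if (length(intersect(numerator, denominator)))
    stop("numerator and denominator sets overlap")
  missing <- setdiff(c(numerator, denominator), featureIDs(object))
  if (length(missing))
    stop("feature ids not in table: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- tableValues(object)
  num <- rowSums(v[, numerator, drop = FALSE])
  den <- rowSums(v[, denominator, drop = FALSE])
  drop <- num == 0 | den == 0
  vals <- log(num[!drop] / den[!drop])
  new("LogRatioSeries", values = vals,
      numeratorIDs = numerator, denominatorIDs = denominator,
      droppedSamples = rownames(v)[drop])
}

#' Log ratio of top- vs bottom-ranked features by loading
#'
#' Builds a feature-set log ratio from an ordination's feature loadings
#' (differential ranks): numerator = the `k` features with the largest
#' loadings, denominator = the `k` with the smallest.
#'
#' @param loadings named numeric vector of per-feature scores (e.g. axis-1
#'   feature loadings from [rpca()]).
#' @param object the [FeatureTable-class] the ratio is evaluated on.
#' @param k set size; must satisfy `2 * k <=` number of ranked features.
#' @param tieBreak `"error"` (default) refuses ambiguous top/bottom cuts;
#'   `"id"` breaks ties deterministically by feature id.
#' @return a [LogRatioSeries-class].
#' @export
loadingRankLogRatio <- function(loadings, object, k,
                                tieBreak = c("error", "id")) {
  tieBreak <- match.arg(tieBreak)
  k <- .assertScalarCount(k, "k")
  if (is.null(names(loadings))) stop("loadings must be named by feature id")
  loadings <- loadings[names(loadings) %in% featureIDs(object)]
  p <- length(loadings)
  if (2L * k > p)
    stop("k too large: need 2*k <= ", p, " ranked features")
  sv <- sort(unname(loadings), decreasing = TRUE)
  ambiguous <- (sv[k] == sv[k + 1L]) || (sv[p - k] == sv[p - k + 1L])
  if (ambiguous && tieBreak == "error")
    stop("ties make top/bottom undefined; use tieBreak = 'id'")
  ordTop <- order(-loadings, names(loadings))
  ordBot <- order(loadings, names(loadings))
  num <- names(loadings)[ordTop[seq_len(k)]]
  bot <- setdiff(names(loadings)[ordBot], num)
  featureSetLogRatio(object, numerator = num,
                     denominator = bot[seq_len(k)])
}

#' Write a LogRatioSeries with metadata to TSV
#'
#' Writes `sample_id`, `log_ratio`, plus `group` and `host_age` when a
#' metadata table is supplied; dropped samples go to a `<path>.dropped.tsv`
#' sidecar.
#'
#' @param object a [LogRatioSeries-class].
#' @param path output TSV path.
#' @param meta optional sample metadata data.frame.
#' @return `path`, invisibly.
#' @export
writeLogRatio <- function(object, path, meta = NULL) {
  df <- as.data.frame(object)
  if (!is.null(meta)) {
    i <- match(df$sample_id, meta$sample_id)
    df$group <- meta$group[i]
    df$host_age <- meta$host_age[i]
  }
  utils::write.table(format(df, digits = 12, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(droppedSamples(object)))
    utils::write.table(
      data.frame(dropped_sample = droppedSamples(object)),
      paste0(path, ".dropped.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(path)
}
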