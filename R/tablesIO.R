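#' Read a feature table from TSV or BIOM
#'
#' Reads a sample x feature abundance table. TSV orientation must be
#' declared: `"features"` (features as rows, samples as columns — the QIIME
#' convention) or `"samples"` (samples as rows). BIOM files (JSON or HDF5)
#' are read through the biomformat package and are always features x samples
#' on disk.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param kind `"counts"` or `"intensities"`.
#' @param orientation TSV row meaning; ignored for BIOM.
#' @return a [FeatureTable-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(5, 0, 2, 7, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' writeFeatureTable(FeatureTable(m, "counts"), tf, orientation = "samples")
#' readFeatureTable(tf, orientation = "samples")
#' @export
readFeatureTable <- function(path, format = c("tsv", "biom"),
                             kind = c("counts", "intensities"),
                             orientation = c("features", "samples")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    m <- t(m)
  } else {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                        comment.char = "", quote = "", row.names = NULL,
                        stringsAsFactors = FALSE),
      error = function(e) stop("ragged or malformed TSV (", path, "): ",
                               conditionMessage(e), call. = FALSE))
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicated ids in first column: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in feature table ", path)
    rownames(m) <- ids
    if (orientation == "features") m <- t(m)
  }
  if (any(m < 0)) stop("negative value in feature table ", path)
  FeatureTable(m, kind = kind)
}

#' Write a feature table to TSV or BIOM
#'
#' @param object a [FeatureTable-class].
#' @param path output path.
#' @param format `"tsv"` or `"biom"` (BIOM 1.0 JSON).
#' @param orientation TSV row meaning, as in [readFeatureTable()].
#' @param digits significant digits for intensity tables (counts are written
#'   as integers).
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(object, path, format = c("tsv", "biom"),
                              orientation = c("features", "samples"),
                              digits = 10) {
  stopifnot(is(object, "FeatureTable"))
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  v <- tableValues(object)
  if (format == "biom") {
    b <- biomformat::make_biom(t(v))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  if (orientation == "features") {
    m <- t(v); idcol <- "feature_id"
  } else {
    m <- v; idcol <- "sample_id"
  }
  vals <- if (tableKind(object) == "counts") {
    format(m, scientific = FALSE, trim = TRUE)
  } else {
    trimws(formatC(m, digits = digits, format = "g"))
  }
  out <- cbind(rownames(m), vals)
  colnames(out) <- c(idcol, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a QIIME2-style metadata TSV whose first column holds the sample id.
#' Required columns: `host_subject_id`, `host_age`, `diet`, `exposure`. The
#' `group` column (diet-exposure label) is derived when absent and checked
#' for consistency when present.
#'
#' @param path metadata TSV path.
#' @return a validated data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "",
                          stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  validateSampleMetadata(df)
}

#' Validate (and complete) a sample metadata table
#'
#' @param meta data.frame with columns `sample_id`, `host_subject_id`,
#'   `host_age`, `diet` (`RC`/`HFHC`), `exposure` (`Air`/`IHC`) and
#'   optionally `group`.
#' @return the validated data.frame, with `group` derived as
#'   `"<diet>-<exposure>"` if missing.
#' @export
validateSampleMetadata <- function(meta) {
  need <- c("sample_id", "host_subject_id", "host_age", "diet", "exposure")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata")
  if (!all(meta$diet %in% c("RC", "HFHC")))
    stop("diet must be RC or HFHC")
  if (!all(meta$exposure %in% c("Air", "IHC")))
    stop("exposure must be Air or IHC")
  if (any(meta$host_age < 0)) stop("host_age must be nonnegative")
  derived <- paste(meta$diet, meta$exposure, sep = "-")
  if (is.null(meta$group)) {
    meta$group <- derived
  } else if (!all(meta$group == derived)) {
    stop("group labels inconsistent with diet/exposure")
  }
  meta
}

#' Align two omics tables and metadata on shared samples
#'
#' Restricts both feature tables and the metadata to the intersection of
#' their sample ids, in a single common order (the order of appearance in
#' the first table). At least 3 shared samples are required.
#'
#' @param t1,t2 [FeatureTable-class] objects.
#' @param meta sample metadata data.frame (see [validateSampleMetadata()]).
#' @return list with elements `t1`, `t2`, `meta`.
#' @export
alignTables <- function(t1, t2, meta) {
  stopifnot(is(t1, "FeatureTable"), is(t2, "FeatureTable"))
  meta <- validateSampleMetadata(meta)
  shared <- intersect(intersect(sampleIDs(t1), sampleIDs(t2)),
                      meta$sample_id)
  if (length(shared) < 3L)
    stop("need >= 3 shared samples across tables and metadata, got ",
         length(shared))
  shared <- sampleIDs(t1)[sampleIDs(t1) %in% shared]
  list(t1 = t1[shared, ],
       t2 = t2[shared, ],
       meta = meta[match(shared, meta$sample_id), , drop = FALSE])
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement (hypergeometric) to a
#' common depth via [vegan::rrarefy()]. Samples whose total is below the
#' depth are dropped, not padded; their ids are recorded in the
#' `droppedSamples` slot of the result and reported via a message.
#'
#' @param object a counts [FeatureTable-class].
#' @param depth target depth (default 10200 reads).
#' @param seed RNG seed for reproducible subsampling.
#' @return rarefied [FeatureTable-class]; every retained sample sums to
#'   `depth` exactly.
#' @export
rarefy <- function(object, depth = 10200, seed = NULL) {
  stopifnot(is(object, "FeatureTable"))
  if (tableKind(object) != "counts") stop("rarefy requires a counts table")
  depth <- .assertScalarCount(depth, "depth")
  v <- tableValues(object)
  if (any(v != round(v))) stop("rarefy requires integer counts")
  totals <- rowSums(v)
  drop <- totals < depth
  dropped <- rownames(v)[drop]
  if (all(drop)) stop("no sample reaches depth ", depth)
  keep <- v[!drop, , drop = FALSE]
  # rrarefy warns when the smallest nonzero count exceeds 1 (a heuristic
  # for non-count data); our kind/integer checks already cover that.
  rar <- .withSeed(seed, function() suppressWarnings(vegan::rrarefy(keep, depth)))
  rar <- matrix(as.numeric(rar), nrow(keep), ncol(keep),
                dimnames = dimnames(keep))
  if (length(dropped))
    message("rarefy: dropped ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  new("FeatureTable", values = rar, kind = "counts",
      droppedSamples = dropped)
}
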