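#' @rdname ParameterSeries-class
#' @param object,x A \linkS4class{ParameterSeries}.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname ParameterSeries-class
#' @export
setMethod("seriesValues", "ParameterSeries", function(x) x@values)

#' @rdname ParameterSeries-class
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname ParameterSeries-class
#' @export
setMethod("seriesTimes", "ParameterSeries", function(x) x@times)

#' @rdname ParameterSeries-class
#' @export
setGeneric("seriesLevels", function(x) standardGeneric("seriesLevels"))

#' @rdname ParameterSeries-class
#' @export
setMethod("seriesLevels", "ParameterSeries", function(x) x@levels)

#' @rdname ParameterSeries-class
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))

#' @rdname ParameterSeries-class
#' @export
setMethod("definedMask", "ParameterSeries", function(x) x@defined)

setMethod("show", "ParameterSeries", function(object) {
    cat(sprintf("ParameterSeries '%s': %d frames x %d levels (%.3g-%.3g ns)\n",
                object@parameter, nrow(object@values), ncol(object@values),
                min(object@times), max(object@times)))
})

#' @rdname TrajectoryRecord-class
#' @param x A \linkS4class{TrajectoryRecord}.
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname TrajectoryRecord-class
#' @export
setMethod("sampleMeta", "TrajectoryRecord", function(x) x@meta)

#' @rdname TrajectoryRecord-class
#' @param parameter Optional registry parameter name; if given, returns that
#'   single series.
#' @export
setGeneric("trajectorySeries",
           function(x, parameter) standardGeneric("trajectorySeries"))

#' @rdname TrajectoryRecord-class
#' @export
setMethod("trajectorySeries", "TrajectoryRecord", function(x, parameter) {
    if (missing(parameter)) return(x@series)
    .checkParameterName(parameter)
    x@series[[parameter]]
})

setMethod("show", "TrajectoryRecord", function(object) {
    m <- object@meta
    cat(sprintf(
        "TrajectoryRecord %s/%s rep%d [%s, %s] (%s): %d frames, %d levels\n",
        m@gene, m@site, m@replicate,
        if (m@hotspot) "hotspot" else "nonhotspot",
        if (m@adducted) "adduct" else "control", m@dataset_tag,
        length(object@series[[1L]]@times),
        ncol(object@series[[1L]]@values)))
})

#' @rdname TrajectoryBundle-class
#' @param x A \linkS4class{TrajectoryBundle}.
#' @export
setGeneric("bundleRecords", function(x) standardGeneric("bundleRecords"))

#' @rdname TrajectoryBundle-class
#' @export
setMethod("bundleRecords", "TrajectoryBundle", function(x) x@records)

#' @rdname TrajectoryBundle-class
#' @export
setMethod("length", "TrajectoryBundle", function(x) length(x@records))

setMethod("show", "TrajectoryBundle", function(object) {
    metas <- lapply(object@records, function(r) r@meta)
    cat(sprintf("TrajectoryBundle: %d records (%d genes, %d sites)\n",
                length(object@records),
                length(unique(vapply(metas, function(m) m@gene, ""))),
                length(unique(vapply(metas, function(m)
                    paste(m@gene, m@site), "")))))
})

#' Extract the samples-x-features matrix from a HelicalFeatureSet
#'
#' Machine-learning code in this package works on samples-as-rows matrices;
#' the underlying assay stores features as rows (one column per simulation),
#' so this accessor transposes.
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @return Numeric matrix, samples x features, with feature column names.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "HelicalFeatureSet", function(x) {
    t(SummarizedExperiment::assay(x, "features"))
})

#' Class labels of a HelicalFeatureSet
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @return \code{classLabels}: factor over \code{hotspot_adduct},
#'   \code{hotspot_control}, \code{nonhotspot_adduct},
#'   \code{nonhotspot_control}; \code{isHotspot}/\code{isAdducted}: logical
#'   vectors.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "HelicalFeatureSet", function(x) {
    factor(SummarizedExperiment::colData(x)$class4, levels = .class4Levels())
})

#' @rdname classLabels
#' @export
setGeneric("isHotspot", function(x) standardGeneric("isHotspot"))

#' @rdname classLabels
#' @export
setMethod("isHotspot", "HelicalFeatureSet", function(x) {
    SummarizedExperiment::colData(x)$hotspot
})

#' @rdname classLabels
#' @export
setGeneric("isAdducted", function(x) standardGeneric("isAdducted"))

#' @rdname classLabels
#' @export
setMethod("isAdducted", "HelicalFeatureSet", function(x) {
    SummarizedExperiment::colData(x)$adducted
})

setMethod("show", "HelicalFeatureSet", function(object) {
    cat(sprintf("HelicalFeatureSet: %d features x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(SummarizedExperiment::colData(object)$class4)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

.class4Levels <- function() {
    c("hotspot_adduct", "hotspot_control", "nonhotspot_adduct",
      "nonhotspot_control")
}

.class4Of <- function(hotspot, adducted) {
    paste0(ifelse(hotspot, "hotspot", "nonhotspot"),
           ifelse(adducted, "_adduct", "_control"))
}
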