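#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment colData rowData
#'   assay assayNames
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd median rnorm runif setNames quantile qbinom var
#'   predict coef aggregate
#' @importFrom utils read.delim write.table combn head tail
NULL

#' ParameterSeries: one helical parameter over time and base-pair levels
#'
#' A per-simulation time series of a single helical parameter, as emitted by
#' the Curves+/Canal toolchain: rows are trajectory snapshots, columns are
#' 1-based base-pair levels. Cells where the parameter is undefined (e.g.
#' the first level of an inter-base-pair step parameter) carry
#' \code{defined = FALSE}.
#'
#' @slot parameter Registry parameter name.
#' @slot times Numeric vector of snapshot times (ns), strictly increasing.
#' @slot values Numeric matrix, \code{n_frames x n_levels}, parameter units.
#' @slot levels Integer vector of 1-based base-pair indices (one per column).
#' @slot defined Logical matrix, same shape as \code{values}; \code{FALSE}
#'   marks undefined cells.
#' @exportClass ParameterSeries
setClass("ParameterSeries",
    representation(parameter = "character", times = "numeric",
                   values = "matrix", levels = "integer",
                   defined = "matrix"))

setValidity("ParameterSeries", function(object) {
    msg <- character(0)
    if (length(object@parameter) != 1L ||
        !object@parameter %in% .registryNames())
        msg <- c(msg, "'parameter' must be a single registry name")
    nf <- nrow(object@values); nl <- ncol(object@values)
    if (nf < 1L || nl < 1L)
        msg <- c(msg, "values must have at least one frame and one level")
    if (length(object@times) != nf)
        msg <- c(msg, "length(times) must equal nrow(values)")
    if (nf > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (length(object@levels) != nl)
        msg <- c(msg, "length(levels) must equal ncol(values)")
    if (!identical(dim(object@defined), dim(object@values)))
        msg <- c(msg, "defined mask must match values in shape")
    if (any(is.na(object@values[object@defined])))
        msg <- c(msg, "defined cells must be non-missing")
    if (length(msg)) msg else TRUE
})

#' Construct a ParameterSeries
#'
#' @param parameter Registry parameter name.
#' @param times Snapshot times in ns, strictly increasing.
#' @param values Numeric matrix (frames x levels).
#' @param levels 1-based base-pair indices; defaults to \code{1:ncol(values)}.
#' @param defined Logical validity mask; defaults to \code{!is.na(values)}.
#' @return A \linkS4class{ParameterSeries}.
#' @export
ParameterSeries <- function(parameter, times, values,
                            levels = seq_len(ncol(values)),
                            defined = !is.na(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("ParameterSeries", parameter = parameter,
        times = as.numeric(times), values = values,
        levels = as.integer(levels), defined = defined)
}

#' SampleMeta: metadata for one simulated duplex
#'
#' Identifies a simulation: the gene context, the site (codon) label, the
#' 25-mer sequence of the adducted strand (5'->3'), methylated cytosine
#' positions, adduct status, hotspot label, replicate number and a dataset
#' tag. Bundled fixtures carry a guanine (the lesion/mutation site) at
#' position 7 and a methylated cytosine at position 6; those site-layout
#' rules are enforced at manifest validation rather than here, so that
#' duplexes of other lengths remain representable.
#'
#' @slot gene Gene context token (e.g. "TP53", "cII", "lacZ").
#' @slot site Site/codon label.
#' @slot sequence IUPAC string, adducted strand.
#' @slot methylated Integer vector of 1-based methylated positions.
#' @slot adducted Logical: carries the bulky adduct.
#' @slot hotspot Logical: mutational hotspot site.
#' @slot replicate Integer replicate id (>= 1).
#' @slot dataset_tag Dataset token (e.g. "train", "Val", "Meth").
#' @exportClass SampleMeta
setClass("SampleMeta",
    representation(gene = "character", site = "character",
                   sequence = "character", methylated = "integer",
                   adducted = "logical", hotspot = "logical",
                   replicate = "integer", dataset_tag = "character"))

setValidity("SampleMeta", function(object) {
    msg <- character(0)
    for (s in c("gene", "site", "sequence", "dataset_tag"))
        if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a single non-NA string", s))
    if (length(object@sequence) == 1L && !is.na(object@sequence) &&
        nchar(object@sequence) < 1L)
        msg <- c(msg, "sequence must be non-empty")
    if (length(object@replicate) != 1L || is.na(object@replicate) ||
        object@replicate < 1L)
        msg <- c(msg, "replicate must be an integer >= 1")
    for (s in c("adducted", "hotspot"))
        if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
    if (length(msg)) msg else TRUE
})

#' Construct a SampleMeta
#'
#' @param gene,site,sequence,dataset_tag Single strings.
#' @param methylated Integer vector of methylated positions (1-based).
#' @param adducted,hotspot Logical flags.
#' @param replicate Integer replicate id.
#' @return A \linkS4class{SampleMeta}.
#' @export
SampleMeta <- function(gene, site, sequence, methylated = integer(0),
                       adducted, hotspot, replicate,
                       dataset_tag = "train") {
    new("SampleMeta", gene = as.character(gene), site = as.character(site),
        sequence = toupper(as.character(sequence)),
        methylated = as.integer(methylated),
        adducted = as.logical(adducted), hotspot = as.logical(hotspot),
        replicate = as.integer(replicate),
        dataset_tag = as.character(dataset_tag))
}

#' TrajectoryRecord: all 17 parameter series of one simulation
#'
#' @slot meta A \linkS4class{SampleMeta}.
#' @slot series Named list of \linkS4class{ParameterSeries}, one per
#'   registry parameter; all share the same time axis.
#' @exportClass TrajectoryRecord
setClass("TrajectoryRecord",
    representation(meta = "SampleMeta", series = "list"))

setValidity("TrajectoryRecord", function(object) {
    msg <- character(0)
    want <- .registryNames()
    if (!setequal(names(object@series), want))
        msg <- c(msg, "series must contain exactly the 17 registry parameters")
    else {
        t0 <- object@series[[want[1L]]]@times
        for (p in want) {
            s <- object@series[[p]]
            if (!is(s, "ParameterSeries"))
                msg <- c(msg, sprintf("series '%s' is not a ParameterSeries", p))
            else if (!isTRUE(all.equal(s@times, t0)))
                msg <- c(msg, sprintf("series '%s' has a different time axis", p))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TrajectoryRecord
#'
#' @param meta A \linkS4class{SampleMeta}.
#' @param series Named list of \linkS4class{ParameterSeries} covering the
#'   full 17-parameter registry.
#' @return A \linkS4class{TrajectoryRecord}.
#' @export
TrajectoryRecord <- function(meta, series) {
    new("TrajectoryRecord", meta = meta,
        series = series[.registryNames()])
}

#' TrajectoryBundle: an ordered collection of trajectory records
#'
#' Record identity (gene, site, adducted, replicate, dataset_tag) is unique
#' within a bundle.
#'
#' @slot records List of \linkS4class{TrajectoryRecord}.
#' @exportClass TrajectoryBundle
setClass("TrajectoryBundle", representation(records = "list"))

.recordKey <- function(meta) {
    paste(meta@gene, meta@site, meta@adducted, meta@replicate,
          meta@dataset_tag, sep = "\r")
}

setValidity("TrajectoryBundle", function(object) {
    keys <- vapply(object@records, function(r) .recordKey(r@meta), "")
    if (anyDuplicated(keys))
        return(paste("duplicate record identity (gene, site, adducted,",
                     "replicate, dataset_tag) in bundle"))
    TRUE
})

#' Construct a TrajectoryBundle
#'
#' @param records List of \linkS4class{TrajectoryRecord}.
#' @return A \linkS4class{TrajectoryBundle}.
#' @export
TrajectoryBundle <- function(records = list()) {
    new("TrajectoryBundle", records = records)
}

#' HelicalFeatureSet: the aggregated feature matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose rows are
#' (base, parameter) features named \code{<base>—<parameter>} and whose
#' columns are simulations. \code{rowData} carries \code{base},
#' \code{parameter} and \code{nature}; \code{colData} carries the sample
#' metadata plus the derived labels \code{class4} (cross of hotspot and
#' adduct status), \code{hotspot} and \code{adducted}.
#'
#' @exportClass HelicalFeatureSet
setClass("HelicalFeatureSet", contains = "SummarizedExperiment")

setValidity("HelicalFeatureSet", function(object) {
    msg <- character(0)
    cd <- SummarizedExperiment::colData(object)
    need <- c("gene", "site", "adducted", "hotspot", "replicate",
              "dataset_tag", "class4")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("base", "parameter", "nature") %in% colnames(rd)))
        msg <- c(msg, "rowData must carry base, parameter and nature")
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    else if (any(is.na(SummarizedExperiment::assay(object, "features"))))
        msg <- c(msg, "feature matrix must have no missing values")
    if (length(msg)) msg else TRUE
})
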