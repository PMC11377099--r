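## Trajectory -> feature matrix: equilibration-window exclusion, terminus
## trimming, temporal aggregation, feature naming and label assembly.

## Feature names use the em-dash separator (e.g. "14—propeller"); an ASCII
## hyphen is accepted on input.
.FEATURE_SEP <- "—"

#' Analysis window specification
#'
#' @param start_time Window start in ns (frames with time >= start are
#'   retained).
#' @param end_time Window end in ns; \code{Inf} for an open window. When
#'   closed, frames with time < end are retained.
#' @return A list of class \code{WindowSpec}.
#' @export
windowSpec <- function(start_time = 0, end_time = Inf) {
    stopifnot(start_time >= 0)
    if (is.finite(end_time) && end_time <= start_time)
        stop("end_time must exceed start_time")
    structure(list(start_time = start_time, end_time = end_time),
              class = "WindowSpec")
}

#' Drop the equilibration window from a trajectory record
#'
#' Molecular-dynamics runs need an equilibration period before the sampled
#' ensemble is representative; the convention here is to discard the first
#' 10 ns of a 100 ns run before any aggregation.
#'
#' @param traj A \linkS4class{TrajectoryRecord}.
#' @param window A \code{\link{windowSpec}}.
#' @return The record with all 17 series restricted to frames with
#'   \code{start_time <= t} (and \code{t < end_time} when closed).
#' @export
trimEquilibration <- function(traj, window = windowSpec(10)) {
    stopifnot(is(traj, "TrajectoryRecord"), inherits(window, "WindowSpec"))
    times <- traj@series[[1L]]@times
    keep <- times >= window$start_time
    if (is.finite(window$end_time)) keep <- keep & times < window$end_time
    if (!any(keep)) stop("window excludes all frames")
    series <- lapply(traj@series, function(s)
        ParameterSeries(s@parameter, s@times[keep],
                        s@values[keep, , drop = FALSE], levels = s@levels,
                        defined = s@defined[keep, , drop = FALSE]))
    TrajectoryRecord(traj@meta, series)
}

#' Drop terminal base pairs from a trajectory record
#'
#' Terminal base pairs lack one stacking neighbour and fray during
#' simulation; two levels at each end are excluded by default, so a 25-mer
#' contributes levels 3-23. Original 1-based level labels are preserved.
#'
#' @param traj A \linkS4class{TrajectoryRecord}.
#' @param n_trim Number of levels removed from each end (default 2).
#' @return The trimmed record.
#' @export
trimTermini <- function(traj, n_trim = 2L) {
    stopifnot(is(traj, "TrajectoryRecord"), n_trim >= 0L)
    n_trim <- as.integer(n_trim)
    L <- ncol(traj@series[[1L]]@values)
    if (L <= 2L * n_trim)
        stop(sprintf("cannot trim %d levels from each end of %d levels",
                     n_trim, L))
    if (n_trim == 0L) return(traj)
    keep <- seq.int(n_trim + 1L, L - n_trim)
    series <- lapply(traj@series, function(s)
        ParameterSeries(s@parameter, s@times,
                        s@values[, keep, drop = FALSE],
                        levels = s@levels[keep],
                        defined = s@defined[, keep, drop = FALSE]))
    TrajectoryRecord(traj@meta, series)
}

#' Aggregate a trajectory record into one feature vector
#'
#' Each retained (base-pair level, parameter) cell is summarised over the
#' retained frames (masked frames excluded) into a single value, giving the
#' per-simulation feature vector. Features are ordered by ascending base
#' index, registry parameter order within a base, and named
#' \code{<base>—<parameter>}.
#'
#' @param traj A (trimmed) \linkS4class{TrajectoryRecord}.
#' @param aggregator \code{"mean"} (default), \code{"sd"} or \code{"median"}.
#' @return Named numeric vector of length \code{17 * n_levels}.
#' @export
aggregateRecord <- function(traj, aggregator = c("mean", "sd", "median")) {
    stopifnot(is(traj, "TrajectoryRecord"))
    aggregator <- match.arg(aggregator)
    fun <- switch(aggregator, mean = mean, sd = stats::sd,
                  median = stats::median)
    levels <- traj@series[[1L]]@levels
    params <- .registryNames()
    out <- numeric(length(levels) * length(params))
    nm <- character(length(out))
    k <- 0L
    for (li in seq_along(levels)) {
        for (p in params) {
            k <- k + 1L
            s <- traj@series[[p]]
            ok <- s@defined[, li]
            if (!any(ok))
                stop(sprintf(
                    "no defined frames for parameter %s at base %d", p,
                    levels[li]))
            out[k] <- fun(s@values[ok, li])
            nm[k] <- paste0(levels[li], .FEATURE_SEP, p)
        }
    }
    names(out) <- nm
    out
}

#' Parse feature names into base index and parameter
#'
#' @param names Character vector like \code{"14—propeller"}; an ASCII
#'   hyphen separator is also accepted.
#' @return data.frame with columns \code{base}, \code{parameter},
#'   \code{nature}.
#' @export
parseFeatureName <- function(names) {
    m <- regmatches(names,
                    regexec(paste0("^([0-9]+)(?:", .FEATURE_SEP,
                                   "|-)([a-z]+)$"), names))
    bad <- lengths(m) != 3L
    if (any(bad))
        stop("unparseable feature name(s): ",
             paste(names[bad], collapse = ", "))
    base <- as.integer(vapply(m, `[`, "", 2L))
    parameter <- vapply(m, `[`, "", 3L)
    data.frame(base = base, parameter = parameter,
               nature = parameterNature(parameter),
               stringsAsFactors = FALSE)
}

#' Build the feature matrix for a trajectory bundle
#'
#' Applies the equilibration window and terminus trimming to every record,
#' aggregates each into one feature vector, and assembles a
#' \linkS4class{HelicalFeatureSet}. Replicates remain separate samples;
#' rows (features) follow ascending base index with registry parameter
#' order within a base; samples follow bundle order. For an L-mer duplex
#' the feature count is \code{17 * (L - 2 * n_trim)} (357 for a 25-mer with
#' the default trim of 2).
#'
#' @param bundle A \linkS4class{TrajectoryBundle}.
#' @param window A \code{\link{windowSpec}}, or \code{NULL} to derive the
#'   window from \code{window_fraction} of each record's time span.
#' @param window_fraction Fraction of the span discarded from the start
#'   when \code{window} is \code{NULL} (default 0.10).
#' @param aggregator Temporal summary statistic (\code{"mean"},
#'   \code{"sd"}, \code{"median"}).
#' @param n_trim Levels removed from each terminus (default 2).
#' @return A \linkS4class{HelicalFeatureSet}.
#' @export
buildFeatureMatrix <- function(bundle, window = NULL,
                               window_fraction = 0.10,
                               aggregator = "mean", n_trim = 2L) {
    stopifnot(is(bundle, "TrajectoryBundle"), length(bundle@records) > 0L)
    Ls <- vapply(bundle@records,
                 function(r) ncol(r@series[[1L]]@values), 1L)
    if (length(unique(Ls)) != 1L)
        stop("records have mixed level counts: ",
             paste(unique(Ls), collapse = ", "))
    vecs <- lapply(bundle@records, function(r) {
        w <- window
        if (is.null(w)) {
            tt <- r@series[[1L]]@times
            w <- windowSpec(min(tt) + window_fraction * (max(tt) - min(tt)))
        }
        r <- trimEquilibration(r, w)
        r <- trimTermini(r, n_trim)
        aggregateRecord(r, aggregator)
    })
    feat <- do.call(cbind, vecs)   # features x samples
    metas <- lapply(bundle@records, function(r) r@meta)
    cd <- S4Vectors::DataFrame(
        gene = vapply(metas, function(m) m@gene, ""),
        site = vapply(metas, function(m) m@site, ""),
        sequence = vapply(metas, function(m) m@sequence, ""),
        adducted = vapply(metas, function(m) m@adducted, TRUE),
        hotspot = vapply(metas, function(m) m@hotspot, TRUE),
        replicate = vapply(metas, function(m) m@replicate, 1L),
        dataset_tag = vapply(metas, function(m) m@dataset_tag, ""))
    cd$class4 <- .class4Of(cd$hotspot, cd$adducted)
    colnames(feat) <- sprintf("%s_%s_%s_rep%d", cd$gene, cd$site,
                              ifelse(cd$adducted, "adduct", "control"),
                              cd$replicate)
    rd <- parseFeatureName(rownames(feat))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = feat),
        rowData = S4Vectors::DataFrame(rd), colData = cd)
    new("HelicalFeatureSet", se)
}

#' Write a HelicalFeatureSet as a TSV (metadata columns, then features)
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTSV <- function(x, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    out <- cbind(cd, as.data.frame(featureMatrix(x),
                                   check.names = FALSE))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a feature TSV back into a HelicalFeatureSet
#'
#' @param path Path written by \code{\link{writeFeatureTSV}}.
#' @return A \linkS4class{HelicalFeatureSet}.
#' @export
readFeatureTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     fileEncoding = "UTF-8")
    metaCols <- c("gene", "site", "sequence", "adducted", "hotspot",
                  "replicate", "dataset_tag", "class4")
    miss <- setdiff(metaCols, colnames(df))
    if (length(miss))
        stop("feature TSV missing column(s): ",
             paste(miss, collapse = ", "))
    featCols <- setdiff(colnames(df), metaCols)
    feat <- t(as.matrix(df[, featCols, drop = FALSE]))
    cd <- S4Vectors::DataFrame(df[, metaCols, drop = FALSE])
    cd$adducted <- as.logical(cd$adducted)
    cd$hotspot <- as.logical(cd$hotspot)
    colnames(feat) <- sprintf("%s_%s_%s_rep%d", cd$gene, cd$site,
                              ifelse(cd$adducted, "adduct", "control"),
                              cd$replicate)
    rd <- parseFeatureName(rownames(feat))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = feat),
        rowData = S4Vectors::DataFrame(rd), colData = cd)
    new("HelicalFeatureSet", se)
}
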