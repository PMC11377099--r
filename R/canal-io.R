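## Canal-style series I/O and manifest-driven bundle assembly.
##
## Dialect: one whitespace-delimited text file per helical parameter, one
## row per snapshot; column 1 is the time in ns, remaining columns are
## base-pair levels; '#' lines are comments; undefined cells are the
## literal sentinel 'NA'. Files are named <prefix>_<parameter>.ser.

.SENTINEL <- "NA"

#' Read a Canal-style helical-parameter series file
#'
#' @param path Path to a series file (whitespace-delimited; first column =
#'   snapshot time in ns; remaining columns = base-pair levels; lines
#'   starting with \code{#} ignored; undefined cells written as \code{NA}).
#' @param parameter Registry parameter name to attach to the series.
#' @param levels Optional 1-based base-pair indices for the columns;
#'   defaults to \code{1:n_levels}.
#' @return A \linkS4class{ParameterSeries} whose \code{defined} mask is
#'   \code{FALSE} exactly at sentinel cells.
#' @export
readCanalSeries <- function(path, parameter, levels = NULL) {
    .checkParameterName(parameter)
    if (!file.exists(path)) stop("no such series file: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty series file: ", path)
    toks <- strsplit(trimws(lines), "\\s+")
    ncols <- lengths(toks)
    if (length(unique(ncols)) != 1L) {
        bad <- lineno[which(ncols != ncols[1L])[1L]]
        stop(sprintf("ragged row in %s at line %d (expected %d fields)",
                     path, bad, ncols[1L]))
    }
    if (ncols[1L] < 2L)
        stop("series rows need a time column plus at least one level: ", path)
    flat <- unlist(toks, use.names = FALSE)
    m <- matrix(flat, nrow = length(toks), byrow = TRUE)
    num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
    badcell <- is.na(num) & m != .SENTINEL
    if (any(badcell)) {
        i <- which(badcell, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell '%s' in %s at line %d, field %d",
                     m[i[1L], i[2L]], path, lineno[i[1L]], i[2L]))
    }
    times <- num[, 1L]
    if (anyNA(times)) stop("missing time value in ", path)
    vals <- num[, -1L, drop = FALSE]
    if (is.null(levels)) levels <- seq_len(ncol(vals))
    ParameterSeries(parameter, times, vals, levels = levels,
                    defined = m[, -1L, drop = FALSE] != .SENTINEL)
}

#' Write a Canal-style series file
#'
#' Inverse of \code{\link{readCanalSeries}}: round-trips values to 1e-6 and
#' the defined mask exactly.
#'
#' @param series A \linkS4class{ParameterSeries}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCanalSeries <- function(series, path) {
    stopifnot(is(series, "ParameterSeries"))
    validObject(series)
    vals <- series@values
    cells <- matrix(sprintf("%.6f", vals), nrow = nrow(vals))
    cells[!series@defined] <- .SENTINEL
    rows <- paste(sprintf("%.6f", series@times),
                  apply(cells, 1L, paste, collapse = " "))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(sprintf("# parameter: %s", series@parameter),
                 sprintf("# levels: %s",
                         paste(series@levels, collapse = " ")),
                 rows), con)
    invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a TSV with header columns \code{gene}, \code{site},
#' \code{sequence}, \code{methylated_positions} (comma-separated, 1-based),
#' \code{adducted} and \code{hotspot} (0/1), \code{replicate},
#' \code{dataset_tag}, \code{series_prefix}.
#'
#' @param path Manifest path.
#' @return data.frame with typed columns, in file order.
#' @export
readManifest <- function(path) {
    if (!file.exists(path)) stop("no such manifest: ", path)
    man <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("gene", "site", "sequence", "methylated_positions",
              "adducted", "hotspot", "replicate", "dataset_tag",
              "series_prefix")
    miss <- setdiff(need, colnames(man))
    if (length(miss))
        stop("manifest missing column(s): ", paste(miss, collapse = ", "))
    man$adducted <- man$adducted == "1"
    man$hotspot <- man$hotspot == "1"
    man$replicate <- as.integer(man$replicate)
    man
}

.parseMethPositions <- function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Validate a sample manifest
#'
#' Checks the site-layout invariants of the bundled fixtures: 25-mer
#' sequences over A/C/G/T, guanine at position 7, a methylated cytosine at
#' position 6, replicate >= 1, and uniqueness of the record identity
#' (gene, site, adducted, replicate, dataset_tag).
#'
#' @param manifest data.frame from \code{\link{readManifest}} or a path.
#' @return Character vector of violations (empty when valid).
#' @export
validateManifest <- function(manifest) {
    if (is.character(manifest)) manifest <- readManifest(manifest)
    bad <- character(0)
    rowlab <- function(i) sprintf("row %d (%s/%s rep%s %s)", i,
                                  manifest$gene[i], manifest$site[i],
                                  manifest$replicate[i],
                                  manifest$dataset_tag[i])
    for (i in seq_len(nrow(manifest))) {
        sq <- toupper(manifest$sequence[i])
        if (nchar(sq) != 25L)
            bad <- c(bad, paste(rowlab(i), "- sequence is not 25 bases"))
        if (grepl("[^ACGT]", sq))
            bad <- c(bad, paste(rowlab(i), "- sequence has non-ACGT bases"))
        if (nchar(sq) >= 7L && substr(sq, 7L, 7L) != "G")
            bad <- c(bad, paste(rowlab(i), "- position 7 is not G"))
        meth <- .parseMethPositions(manifest$methylated_positions[i])
        if (!6L %in% meth)
            bad <- c(bad, paste(rowlab(i), "- position 6 not methylated"))
        if (length(meth) && any(substring(sq, meth, meth) != "C"))
            bad <- c(bad, paste(rowlab(i),
                                "- methylated position is not a C"))
        if (is.na(manifest$replicate[i]) || manifest$replicate[i] < 1L)
            bad <- c(bad, paste(rowlab(i), "- replicate must be >= 1"))
    }
    key <- paste(manifest$gene, manifest$site, manifest$adducted,
                 manifest$replicate, manifest$dataset_tag, sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
        bad <- c(bad, vapply(which(dup), function(i)
            paste(rowlab(i), "- duplicate record identity"), ""))
    bad
}

#' Load a trajectory bundle from a manifest and a data directory
#'
#' Reads, for every manifest row, the 17 per-parameter series files
#' \code{<series_prefix>_<parameter>.ser} under \code{data_dir} and
#' assembles a \linkS4class{TrajectoryBundle} in manifest order.
#'
#' @param manifest Manifest path or data.frame.
#' @param data_dir Directory holding the series files.
#' @return A \linkS4class{TrajectoryBundle}.
#' @export
loadBundle <- function(manifest, data_dir) {
    if (is.character(manifest)) manifest <- readManifest(manifest)
    bad <- validateManifest(manifest)
    if (length(bad))
        stop("manifest validation failed:\n  ",
             paste(bad, collapse = "\n  "))
    records <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
        meta <- SampleMeta(
            gene = manifest$gene[i], site = manifest$site[i],
            sequence = manifest$sequence[i],
            methylated = .parseMethPositions(
                manifest$methylated_positions[i]),
            adducted = manifest$adducted[i],
            hotspot = manifest$hotspot[i],
            replicate = manifest$replicate[i],
            dataset_tag = manifest$dataset_tag[i])
        series <- list()
        for (p in .registryNames()) {
            f <- file.path(data_dir,
                           sprintf("%s_%s.ser", manifest$series_prefix[i], p))
            if (!file.exists(f))
                stop(sprintf("missing series file for sample %s/%s rep%d, parameter %s: %s",
                             meta@gene, meta@site, meta@replicate, p, f))
            series[[p]] <- readCanalSeries(f, p)
        }
        records[[i]] <- TrajectoryRecord(meta, series)
        validObject(records[[i]])
    }
    bundle <- TrajectoryBundle(records)
    validObject(bundle)
    bundle
}

#' Write a trajectory bundle as manifest + series files
#'
#' @param bundle A \linkS4class{TrajectoryBundle}.
#' @param dir Output directory (created if absent).
#' @param manifest_name File name for the manifest TSV.
#' @return Path of the written manifest, invisibly.
#' @export
writeBundle <- function(bundle, dir, manifest_name = "manifest.tsv") {
    stopifnot(is(bundle, "TrajectoryBundle"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- lapply(seq_along(bundle@records), function(i) {
        m <- bundle@records[[i]]@meta
        prefix <- sprintf("%s_%s_%s_rep%d_%s", m@gene, m@site,
                          if (m@adducted) "adduct" else "control",
                          m@replicate, m@dataset_tag)
        for (p in .registryNames())
            writeCanalSeries(bundle@records[[i]]@series[[p]],
                             file.path(dir, sprintf("%s_%s.ser", prefix, p)))
        data.frame(gene = m@gene, site = m@site, sequence = m@sequence,
                   methylated_positions = paste(m@methylated,
                                                collapse = ","),
                   adducted = as.integer(m@adducted),
                   hotspot = as.integer(m@hotspot),
                   replicate = m@replicate, dataset_tag = m@dataset_tag,
                   series_prefix = prefix, stringsAsFactors = FALSE)
    })
    man <- do.call(rbind, rows)
    path <- file.path(dir, manifest_name)
    write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
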