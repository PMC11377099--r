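## Fixture builders shared across test files. Everything is generated in
## code; no binary fixtures.

## A valid 25-mer: methylated C at position 6, G (lesion site) at 7.
seq25 <- function() paste0("ATCGA", "CG", strrep("AT", 9L))

## A minimal TrajectoryRecord with L levels and n frames: every parameter
## series is baseline + iid noise (or a supplied matrix for one parameter).
makeRecord <- function(L = 25L, n = 50L, noise_sd = 0.1, seed = 1L,
                       meta = NULL, override = list(), times = NULL,
                       mask_level1_steps = FALSE) {
    set.seed(seed)
    if (is.null(times)) times <- seq(0, by = 0.1, length.out = n)
    reg <- helicalParameters()
    series <- list()
    for (p in reg$name) {
        vals <- if (!is.null(override[[p]])) override[[p]] else
            matrix(rnorm(n * L, 0, noise_sd), n, L)
        defined <- matrix(TRUE, n, L)
        if (mask_level1_steps &&
            reg$category[match(p, reg$name)] %in% c("inter", "bend")) {
            defined[, 1L] <- FALSE
            vals[, 1L] <- NA_real_
        }
        series[[p]] <- ParameterSeries(p, times, vals, defined = defined)
    }
    if (is.null(meta))
        meta <- SampleMeta(gene = "TP53", site = "s1",
                           sequence = substr(strrep(seq25(), 2L), 1L,
                                             max(L, 7L)),
                           methylated = 6L, adducted = TRUE,
                           hotspot = TRUE, replicate = 1L)
    TrajectoryRecord(meta, series)
}

## Build a HelicalFeatureSet directly from a samples-x-features matrix and
## hotspot/adduct flags (bypasses trajectory machinery for ML-stage tests).
makeFeatureSet <- function(X, hotspot, adducted, gene = "TP53",
                           dataset_tag = "train") {
    n <- nrow(X)
    if (is.null(colnames(X))) {
        reg <- helicalParameters()$name
        base <- rep(3:40, each = 17L)[seq_len(ncol(X))]
        par <- rep(reg, times = 40L)[seq_len(ncol(X))]
        colnames(X) <- paste0(base, "—", par)
    }
    site <- paste0("site", seq_len(n))
    cd <- S4Vectors::DataFrame(
        gene = gene, site = site, sequence = seq25(),
        adducted = adducted, hotspot = hotspot,
        replicate = 1L, dataset_tag = dataset_tag)
    cd$class4 <- paste0(ifelse(hotspot, "hotspot", "nonhotspot"),
                        ifelse(adducted, "_adduct", "_control"))
    feat <- t(X)
    colnames(feat) <- sprintf("%s_%s_%s_rep%d", cd$gene, cd$site,
                              ifelse(cd$adducted, "adduct", "control"),
                              cd$replicate)
    rd <- parseFeatureName(rownames(feat))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = feat),
        rowData = S4Vectors::DataFrame(rd), colData = cd)
    methods::new("HelicalFeatureSet", se)
}

## Four-class feature set: two informative columns (hotspot and adduct
## main effects), the rest pure noise.
makeSeparableSet <- function(n_per_class = 12L, p = 20L, effect = 6,
                             noise_sd = 1, seed = 1L) {
    set.seed(seed)
    hotspot <- rep(c(TRUE, TRUE, FALSE, FALSE), each = n_per_class)
    adducted <- rep(c(TRUE, FALSE, TRUE, FALSE), each = n_per_class)
    n <- length(hotspot)
    X <- matrix(rnorm(n * p, 0, noise_sd), n, p)
    X[, 1L] <- X[, 1L] + effect * hotspot
    X[, 2L] <- X[, 2L] + effect * adducted
    makeFeatureSet(X, hotspot, adducted)
}

## Binary-label (all-adducted) feature set with planted signal columns.
makeBinarySet <- function(n_per_class = 18L, p = 30L,
                          signal_cols = 1L, effect = 4, seed = 1L) {
    set.seed(seed)
    hotspot <- rep(c(TRUE, FALSE), each = n_per_class)
    n <- length(hotspot)
    X <- matrix(rnorm(n * p), n, p)
    for (j in signal_cols) X[, j] <- X[, j] + effect * hotspot
    makeFeatureSet(X, hotspot, adducted = rep(TRUE, n))
}

## A small valid manifest data.frame (no series files).
makeManifest <- function(n = 2L) {
    data.frame(
        gene = "TP53", site = paste0("s", seq_len(n)),
        sequence = seq25(), methylated_positions = "6",
        adducted = rep(c(TRUE, FALSE), length.out = n),
        hotspot = TRUE, replicate = 1L, dataset_tag = "train",
        series_prefix = paste0("pfx", seq_len(n)),
        stringsAsFactors = FALSE)
}
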