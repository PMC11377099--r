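## Synthetic trajectory generator: Canal-format bundles with the
## statistical structure the analysis assumes -- per-(parameter, level)
## AR(1) Gaussian noise around B-DNA-like baselines, per-series replicate
## offsets, planted mean-shift effects on chosen (parameter, base) cells,
## and hotspot/nonhotspot sequence sets with controlled regional GC
## content. No claim of molecular-mechanics realism.

#' A planted mean-shift effect
#'
#' @param parameter Registry parameter name.
#' @param base 1-based base-pair level carrying the shift (keep within the
#'   trimmed range, 3..23 for a 25-mer, for the effect to be learnable).
#' @param mean_shift Shift in parameter units, applied where the condition
#'   holds.
#' @param hotspot,adducted Condition predicate: \code{TRUE}/\code{FALSE}
#'   restrict to that stratum, \code{NA} means "any".
#' @param sd_scale Multiplier on the frame noise sd where the condition
#'   holds (default 1, mean shift only).
#' @return List of class \code{PlantedEffect}.
#' @export
plantedEffect <- function(parameter, base, mean_shift, hotspot = NA,
                          adducted = NA, sd_scale = 1) {
    .checkParameterName(parameter)
    stopifnot(base >= 1L, sd_scale >= 0)
    structure(list(parameter = parameter, base = as.integer(base),
                   mean_shift = mean_shift, hotspot = hotspot,
                   adducted = adducted, sd_scale = sd_scale),
              class = "PlantedEffect")
}

.effectApplies <- function(eff, hotspot, adducted) {
    (is.na(eff$hotspot) || eff$hotspot == hotspot) &&
        (is.na(eff$adducted) || eff$adducted == adducted)
}

#' Synthetic-bundle configuration
#'
#' Defaults emulate the training-set design: 6 hotspot and 6 nonhotspot
#' sites, triplicate simulations with and without the adduct (72 records),
#' 1000 frames over 100 ns, canonical B-DNA baselines (twist 34 degrees,
#' rise 3.4 Angstrom, other parameters centred at 0), frame noise sd of 4
#' degrees (rotational) / 0.4 Angstrom (translational), lag-1
#' autocorrelation 0.3, and a per-series replicate offset (sd a quarter of
#' the frame sd) representing run-to-run drift.
#'
#' @param n_hotspot_sites,n_nonhotspot_sites Sites per class.
#' @param replicates Replicate simulations per site and adduct state.
#' @param adduct_states Logical vector of adduct states simulated.
#' @param n_frames Snapshots per simulation.
#' @param span_ns Simulated time span; snapshot i sits at
#'   \code{(i-1) * span_ns / n_frames} ns.
#' @param ar1_phi Lag-1 autocorrelation of the frame noise, in [0, 1).
#' @param rot_sd,trans_sd Stationary frame noise sd for rotational
#'   (degrees) and translational (Angstrom) parameters.
#' @param offset_sd_frac Replicate-offset sd as a fraction of the frame sd.
#' @param baseline_twist,baseline_rise Baseline means; other parameters are
#'   0-centred.
#' @param planted_effects List of \code{\link{plantedEffect}}s.
#' @param gc_hotspot,gc_nonhotspot Regional GC targets for the two
#'   sequence classes.
#' @param gene,dataset_tag Metadata tokens.
#' @param site_labels Optional character vector of site labels (hotspot
#'   sites first), length \code{n_hotspot_sites + n_nonhotspot_sites}.
#' @param seq_length Duplex length (default 25).
#' @return List of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_hotspot_sites = 6L, n_nonhotspot_sites = 6L,
                            replicates = 3L,
                            adduct_states = c(TRUE, FALSE),
                            n_frames = 1000L, span_ns = 100,
                            ar1_phi = 0.3, rot_sd = 4, trans_sd = 0.4,
                            offset_sd_frac = 0.25,
                            baseline_twist = 34, baseline_rise = 3.4,
                            planted_effects = list(),
                            gc_hotspot = 0.7, gc_nonhotspot = 0.4,
                            gene = "TP53", dataset_tag = "train",
                            site_labels = NULL, seq_length = 25L) {
    stopifnot(n_hotspot_sites >= 1L, n_nonhotspot_sites >= 1L,
              replicates >= 1L, n_frames >= 1L, span_ns > 0,
              ar1_phi >= 0, ar1_phi < 1, rot_sd >= 0, trans_sd >= 0,
              seq_length >= 7L)
    n_sites <- n_hotspot_sites + n_nonhotspot_sites
    if (is.null(site_labels))
        site_labels <- c(paste0("hs", seq_len(n_hotspot_sites)),
                         paste0("nh", seq_len(n_nonhotspot_sites)))
    stopifnot(length(site_labels) == n_sites)
    for (eff in planted_effects)
        if (eff$base > seq_length)
            stop("planted base ", eff$base, " outside the ", seq_length,
                 "-mer")
    structure(as.list(environment()), class = "SyntheticConfig")
}

#' The training-scale preset with the default planted effects
#'
#' 6 hotspot + 6 nonhotspot TP53 codon labels, triplicate, both adduct
#' states (72 records). Planted effects encode (a) lesion-induced
#' distortion at the adduct base (buckle and rise at base 7, any hotspot
#' status), (b) sequence-intrinsic dynamics of hotspot sites (tip at base
#' 23, X displacement at base 10), and (c) hotspot-specific adduct response
#' (tip at base 10, propeller at base 14, shift at base 11) -- each a
#' 3-frame-sd mean shift.
#'
#' @param ... Overrides passed to \code{\link{syntheticConfig}}.
#' @return A \code{SyntheticConfig}.
#' @export
tp53Config <- function(...) {
    effects <- list(
        plantedEffect("buckle", 7L, 12, adducted = TRUE),
        plantedEffect("rise", 7L, 1.2, adducted = TRUE),
        plantedEffect("tip", 23L, 12, hotspot = TRUE),
        plantedEffect("xdisp", 10L, 1.2, hotspot = TRUE),
        plantedEffect("tip", 10L, 12, hotspot = TRUE, adducted = TRUE),
        plantedEffect("propeller", 14L, -12, hotspot = TRUE,
                      adducted = TRUE),
        plantedEffect("shift", 11L, 1.2, hotspot = TRUE, adducted = TRUE))
    args <- list(...)
    if (is.null(args$planted_effects)) args$planted_effects <- effects
    if (is.null(args$site_labels) &&
        is.null(args$n_hotspot_sites) && is.null(args$n_nonhotspot_sites))
        args$site_labels <- c("157", "158", "245", "248", "273", "282",
                              "170", "186", "202", "213", "267", "290")
    do.call(syntheticConfig, args)
}

#' The three interaction features planted by \code{\link{tp53Config}}
#'
#' @return Character vector of feature names shifted only in the
#'   hotspot-and-adducted stratum.
#' @export
tp53PlantedInteraction <- function() {
    c("10—tip", "14—propeller", "11—shift")
}

#' Generate random 25-mer sequences with a regional GC target
#'
#' Position 7 is fixed to G (the lesion/mutation site) and position 6 to C
#' (the methylated cytosine). Within the region 2-12 the number of G/C
#' bases is set to match \code{round(gc_target * 11)} as closely as the
#' two fixed positions allow; outside the region bases are G/C with
#' probability \code{gc_target}.
#'
#' @param n Number of sequences.
#' @param gc_target Regional GC fraction target in [0, 1].
#' @param seed Integer seed.
#' @param length Sequence length (default 25).
#' @return Character vector of sequences.
#' @export
generateSequences <- function(n, gc_target, seed = 0L, length = 25L) {
    stopifnot(n >= 1L, gc_target >= 0, gc_target <= 1, length >= 12L)
    set.seed(seed)
    region <- 2:12
    fixed_gc <- 2L           # C6 and G7
    free_region <- setdiff(region, c(6L, 7L))
    out <- character(n)
    for (i in seq_len(n)) {
        s <- rep(NA_character_, length)
        s[6L] <- "C"; s[7L] <- "G"
        k <- round(gc_target * length(region)) - fixed_gc
        k <- max(0L, min(length(free_region), k))
        gc_pos <- if (k > 0L) sample(free_region, k) else integer(0)
        for (p in free_region)
            s[p] <- if (p %in% gc_pos) sample(c("G", "C"), 1L) else
                sample(c("A", "T"), 1L)
        outside <- setdiff(seq_len(length), c(region, 6L, 7L))
        for (p in outside)
            s[p] <- if (runif(1) < gc_target) sample(c("G", "C"), 1L) else
                sample(c("A", "T"), 1L)
        out[i] <- paste(s, collapse = "")
    }
    out
}

## one AR(1) series: stationary sd 'sdev', lag-1 autocorrelation 'phi'
.ar1Series <- function(n, phi, sdev) {
    if (sdev == 0) return(numeric(n))
    eps <- rnorm(n, 0, sdev * sqrt(1 - phi^2))
    as.numeric(stats::filter(eps, phi, method = "recursive",
                             init = rnorm(1L, 0, sdev)))
}

#' Generate a synthetic trajectory bundle
#'
#' Produces one \linkS4class{TrajectoryRecord} per (site, adduct state,
#' replicate). Every (parameter, level) series is
#' \code{baseline + planted shifts + replicate offset + AR(1) noise};
#' the replicate offset is drawn once per series. Step-type parameters
#' (inter-base-pair and axis bend) are undefined at level 1, mirroring the
#' convention of indexing a step by its 3'-side base pair. Deterministic
#' given the seed.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @param seed Integer seed.
#' @return A \linkS4class{TrajectoryBundle}.
#' @export
generateBundle <- function(config = tp53Config(), seed = 0L) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(seed)
    reg <- helicalParameters()
    L <- config$seq_length
    n <- config$n_frames
    times <- (seq_len(n) - 1L) * config$span_ns / n
    hot <- c(rep(TRUE, config$n_hotspot_sites),
             rep(FALSE, config$n_nonhotspot_sites))
    seqs <- character(length(hot))
    seqs[hot] <- generateSequences(sum(hot), config$gc_hotspot,
                                   seed = seed * 2L + 1L, length = L)
    seqs[!hot] <- generateSequences(sum(!hot), config$gc_nonhotspot,
                                    seed = seed * 2L + 2L, length = L)
    set.seed(seed)   # sequence generation reseeds; restore the main stream
    baseline <- setNames(numeric(nrow(reg)), reg$name)
    baseline["twist"] <- config$baseline_twist
    baseline["rise"] <- config$baseline_rise
    stepwise <- reg$category %in% c("inter", "bend")
    names(stepwise) <- reg$name
    records <- list()
    for (si in seq_along(config$site_labels)) {
        for (adduct in config$adduct_states) {
            for (rep_i in seq_len(config$replicates)) {
                series <- list()
                for (p in reg$name) {
                    base_sd <- if (reg$nature[match(p, reg$name)] ==
                                   "rotational") config$rot_sd else
                                   config$trans_sd
                    vals <- matrix(0, n, L)
                    for (lv in seq_len(L)) {
                        shift <- 0; scale <- 1
                        for (eff in config$planted_effects) {
                            if (eff$parameter == p && eff$base == lv &&
                                .effectApplies(eff, hot[si], adduct)) {
                                shift <- shift + eff$mean_shift
                                scale <- scale * eff$sd_scale
                            }
                        }
                        offset <- rnorm(1L, 0,
                                        config$offset_sd_frac * base_sd)
                        vals[, lv] <- baseline[p] + shift + offset +
                            .ar1Series(n, config$ar1_phi,
                                       base_sd * scale)
                    }
                    defined <- matrix(TRUE, n, L)
                    if (stepwise[p]) defined[, 1L] <- FALSE
                    vals[!defined] <- NA_real_
                    series[[p]] <- ParameterSeries(p, times, vals,
                                                   defined = defined)
                }
                meta <- SampleMeta(
                    gene = config$gene, site = config$site_labels[si],
                    sequence = seqs[si], methylated = 6L,
                    adducted = adduct, hotspot = hot[si],
                    replicate = rep_i,
                    dataset_tag = config$dataset_tag)
                records[[length(records) + 1L]] <-
                    TrajectoryRecord(meta, series)
            }
        }
    }
    bundle <- TrajectoryBundle(records)
    validObject(bundle)
    bundle
}

#' Lag-1 sample autocorrelation of a series
#'
#' Generator self-check: estimates the AR(1) coefficient as the sample
#' correlation between consecutive frames.
#'
#' @param x Numeric vector (at least 50 frames), or a
#'   \linkS4class{ParameterSeries} column via \code{level}.
#' @param level Level index when \code{x} is a ParameterSeries.
#' @return Lag-1 autocorrelation estimate.
#' @export
ar1Autocorrelation <- function(x, level = 1L) {
    if (is(x, "ParameterSeries")) x <- x@values[, level]
    x <- as.numeric(x)
    if (length(x) < 50L)
        stop("need at least 50 frames to estimate autocorrelation")
    if (stats::sd(x) == 0)
        stop("autocorrelation undefined for a constant series")
    stats::cor(x[-length(x)], x[-1L])
}

#' Paths of the bundled synthetic site manifests
#'
#' Site tables for the cII and lacZ deployment contexts (7 sites each: 5
#' hotspot, 2 nonhotspot) and the 12-codon TP53 training context, with
#' synthetic 25-mer sequences generated by
#' \code{\link{generateSequences}} under the package's GC presets.
#'
#' @param gene \code{"cII"}, \code{"lacZ"} or \code{"TP53"}.
#' @return Path to the manifest TSV.
#' @export
bundledManifest <- function(gene = c("cII", "lacZ", "TP53")) {
    gene <- match.arg(gene)
    f <- system.file("extdata",
                     sprintf("%s_sites_synthetic.tsv", gene),
                     package = "helixclass", mustWork = TRUE)
    f
}
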