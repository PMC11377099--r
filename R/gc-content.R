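## Regional G/C-content analysis around the lesion site and the
## hotspot-vs-nonhotspot comparison. The default region spans base pairs
## 2-12 of the 25-mer (the printed range around the position-7 lesion; note
## 2-12 inclusive covers 11 positions).

#' Regional G/C fraction of a sequence
#'
#' @param sequence IUPAC string (A/C/G/T in the queried region; methylated
#'   cytosines count as C).
#' @param start,end 1-based inclusive region bounds (defaults 2 and 12).
#' @return Fraction of G or C among positions \code{start..end}.
#' @export
regionalGC <- function(sequence, start = 2L, end = 12L) {
    sequence <- toupper(sequence)
    if (start < 1L || end > nchar(sequence) || start > end)
        stop("region out of bounds for sequence of length ",
             nchar(sequence))
    region <- strsplit(substr(sequence, start, end), "")[[1L]]
    bad <- setdiff(unique(region), c("A", "C", "G", "T"))
    if (length(bad))
        stop("ambiguous base(s) in region: ", paste(bad, collapse = ", "))
    mean(region %in% c("G", "C"))
}

#' Compare regional G/C content between hotspot and nonhotspot sequences
#'
#' The default test is a two-sided permutation test on the difference of
#' group-mean G/C fractions: exhaustive over all group assignments when
#' their number is at most \code{max_exhaustive}, otherwise Monte-Carlo
#' with \code{n_perm} draws. Welch's t-test is available as an
#' alternative.
#'
#' @param hotspot_seqs,nonhotspot_seqs Character vectors of sequences
#'   (at least 2 per group).
#' @param start,end Region bounds (defaults 2 and 12).
#' @param test \code{"permutation"} (default) or \code{"welch"}.
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration is
#'   infeasible (default 10000).
#' @param max_exhaustive Enumeration cutoff on \code{choose(n1+n2, n1)}
#'   (default 20000).
#' @param seed Integer seed for the Monte-Carlo path.
#' @return List of class \code{GCReport}: \code{region}, per-group
#'   fractions (\code{gc_hotspot}, \code{gc_nonhotspot}), group means,
#'   \code{difference}, \code{test}, \code{exact} (exhaustive or not),
#'   \code{statistic}, \code{p_value}.
#' @export
compareGC <- function(hotspot_seqs, nonhotspot_seqs, start = 2L,
                      end = 12L, test = c("permutation", "welch"),
                      n_perm = 10000L, max_exhaustive = 20000,
                      seed = 0L) {
    test <- match.arg(test)
    if (length(hotspot_seqs) < 2L || length(nonhotspot_seqs) < 2L)
        stop("need at least 2 sequences per group")
    g1 <- vapply(hotspot_seqs, regionalGC, 0, start = start, end = end,
                 USE.NAMES = FALSE)
    g2 <- vapply(nonhotspot_seqs, regionalGC, 0, start = start, end = end,
                 USE.NAMES = FALSE)
    obs <- mean(g1) - mean(g2)
    n1 <- length(g1); n2 <- length(g2)
    exact <- NA
    if (test == "welch") {
        tt <- stats::t.test(g1, g2, var.equal = FALSE)
        stat <- unname(tt$statistic); p <- tt$p.value
    } else {
        pool <- c(g1, g2)
        eps <- 1e-12
        if (choose(n1 + n2, n1) <= max_exhaustive) {
            exact <- TRUE
            idx <- combn(n1 + n2, n1)
            diffs <- apply(idx, 2L, function(i)
                mean(pool[i]) - mean(pool[-i]))
            p <- mean(abs(diffs) >= abs(obs) - eps)
        } else {
            exact <- FALSE
            set.seed(seed)
            diffs <- replicate(n_perm, {
                i <- sample.int(n1 + n2, n1)
                mean(pool[i]) - mean(pool[-i])
            })
            ## add the observed assignment so p > 0
            p <- (sum(abs(diffs) >= abs(obs) - eps) + 1) / (n_perm + 1)
        }
        stat <- obs
    }
    structure(list(region = c(start = start, end = end),
                   gc_hotspot = g1, gc_nonhotspot = g2,
                   mean_hotspot = mean(g1), mean_nonhotspot = mean(g2),
                   difference = obs, test = test, exact = exact,
                   statistic = stat, p_value = p),
              class = "GCReport")
}

#' @export
print.GCReport <- function(x, ...) {
    cat(sprintf(
        "GCReport region %d-%d: hotspot %.3f vs nonhotspot %.3f (diff %+.3f)\n",
        x$region["start"], x$region["end"], x$mean_hotspot,
        x$mean_nonhotspot, x$difference))
    cat(sprintf("  %s test%s: p = %.5g\n", x$test,
                if (isTRUE(x$exact)) " (exhaustive)" else
                if (isFALSE(x$exact)) " (Monte-Carlo)" else "",
                x$p_value))
    invisible(x)
}
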