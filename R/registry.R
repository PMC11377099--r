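#' The 17-parameter helical schema
#'
#' Standardized geometric descriptors of duplex DNA measured per base-pair
#' level along the helix: six intra-base-pair parameters (shear, stretch,
#' stagger, buckle, propeller, opening), six inter-base-pair step parameters
#' (shift, slide, rise, tilt, roll, twist), four base-pair-axis parameters
#' (X/Y displacement, inclination, tip) and the overall axis bend.
#' Rotational parameters are reported in degrees, translational ones in
#' Angstrom; the axis bend is an angle and is treated as rotational.
#'
#' @return A data.frame with one row per parameter and columns
#'   \code{name}, \code{category} (\code{intra}, \code{inter}, \code{axis}
#'   or \code{bend}), \code{nature} (\code{rotational} or
#'   \code{translational}) and \code{units} (\code{degrees} or
#'   \code{angstrom}). Row order is the canonical registry order used for
#'   feature-column layout.
#' @examples
#' reg <- helicalParameters()
#' nrow(reg)                       # 17
#' subset(reg, nature == "rotational")$name
#' @export
helicalParameters <- function() {
    reg <- data.frame(
        name = c("shear", "stretch", "stagger", "buckle", "propeller",
                 "opening",
                 "shift", "slide", "rise", "tilt", "roll", "twist",
                 "xdisp", "ydisp", "inclination", "tip",
                 "axisbend"),
        category = c(rep("intra", 6L), rep("inter", 6L), rep("axis", 4L),
                     "bend"),
        stringsAsFactors = FALSE
    )
    rotational <- c("buckle", "propeller", "opening", "tilt", "roll",
                    "twist", "inclination", "tip", "axisbend")
    reg$nature <- ifelse(reg$name %in% rotational, "rotational",
                         "translational")
    reg$units <- ifelse(reg$nature == "rotational", "degrees", "angstrom")
    reg
}

#' Look up the nature (rotational/translational) of helical parameters
#'
#' @param parameter Character vector of registry parameter names.
#' @return Character vector of \code{"rotational"} / \code{"translational"}.
#' @export
parameterNature <- function(parameter) {
    reg <- helicalParameters()
    idx <- match(parameter, reg$name)
    if (anyNA(idx)) {
        stop("unknown helical parameter(s): ",
             paste(parameter[is.na(idx)], collapse = ", "))
    }
    reg$nature[idx]
}

## internal: registry names in canonical order
.registryNames <- function() helicalParameters()$name

.checkParameterName <- function(parameter) {
    if (length(parameter) != 1L || !parameter %in% .registryNames())
        stop("'parameter' must be one of the 17 registry names, got: ",
             paste(parameter, collapse = ", "))
    invisible(parameter)
}
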