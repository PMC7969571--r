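#' The nine-class anatomical label vocabulary
#'
#' The segmentation target vocabulary used throughout the package: eight
#' anatomical structures visible on transaxial bright-blood anatomy slices
#' plus a background ("other") class. Integer ids are stable across
#' serialization; background is always id 0.
#'
#' @return A data.frame with columns \code{id} (integer 0--8) and
#'   \code{name} (character).
#' @examples
#' labelClasses()
#' @export
labelClasses <- function() {
    data.frame(
        id = 0:8,
        name = c("background", "aorta", "left_atrium", "lv_wall",
                 "lv_cavity", "pulmonary_artery", "pleural_effusion",
                 "right_atrium", "rv_cavity"),
        stringsAsFactors = FALSE
    )
}

#' @rdname labelClasses
#' @export
nLabelClasses <- function() 9L

#' Map between label ids and names
#'
#' @param x integer ids (for \code{labelName}) or character names (for
#'   \code{labelId}).
#' @return character names / integer ids.
#' @examples
#' labelName(4)      # "lv_cavity"
#' labelId("aorta")  # 1
#' @export
labelName <- function(x) {
    lc <- labelClasses()
    i <- match(as.integer(x), lc$id)
    if (anyNA(i)) stop("invalid label id(s): ",
                       paste(x[is.na(i)], collapse = ", "))
    lc$name[i]
}

#' @rdname labelName
#' @export
labelId <- function(x) {
    lc <- labelClasses()
    i <- match(as.character(x), lc$name)
    if (anyNA(i)) stop("invalid label name(s): ",
                       paste(x[is.na(i)], collapse = ", "))
    lc$id[i]
}

# internal: TRUE iff every value of m is a valid label id
.validLabelValues <- function(m) {
    v <- as.vector(m)
    !anyNA(v) && all(v == as.integer(v)) && all(v >= 0L) && all(v <= 8L)
}
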