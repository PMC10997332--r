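#' Default ROI geometry for the 12 dorsal-cortex regions
#'
#' Centers (in mm, bregma origin, anterior positive, right positive) for the
#' six areas imaged per hemisphere: primary visual cortex (V1), antero-medial
#' secondary visual cortex (V2am), retrosplenial cortex (RSC), primary motor
#' cortex (M1), anterior cingulate cortex (A24b), and secondary motor cortex
#' (M2). The default layout places every anterior-posterior pair at or beyond
#' 0.9 bregma-lambda units (the short/long-range cutoff) and every
#' within-group pair below it, giving 30 short-range and 36 long-range pairs
#' out of the 66 total.
#'
#' @param bregma_lambda_mm Distance between bregma and lambda used to
#'   normalize pair distances. Default 4.2 mm.
#' @return A `data.frame` of class `cf_geometry` with columns `roi`, `area`,
#'   `hemisphere`, `x_mm`, `y_mm`, `group` and attribute `bregma_lambda_mm`.
#' @export
#' @examples
#' g <- default_roi_geometry()
#' range(pair_distances(g)$d_norm)
default_roi_geometry <- function(bregma_lambda_mm = 4.2) {
  stopifnot(is.numeric(bregma_lambda_mm), length(bregma_lambda_mm) == 1L,
            bregma_lambda_mm > 0)
  areas <- c("V1", "V2am", "RSC", "M1", "A24b", "M2")
  x <- c(V1 = 1.8, V2am = 1.5, RSC = 0.6, M1 = 1.6, A24b = 0.4, M2 = 0.8)
  y <- c(V1 = -3.6, V2am = -2.9, RSC = -2.6, M1 = 1.2, A24b = 1.7, M2 = 2.2)
  grp <- c(V1 = "posterior", V2am = "posterior", RSC = "posterior",
           M1 = "anterior", A24b = "anterior", M2 = "anterior")
  geom <- data.frame(
    roi = paste0(rep(areas, each = 2), c("_L", "_R")),
    area = rep(areas, each = 2),
    hemisphere = rep(c("L", "R"), times = 6),
    x_mm = as.numeric(rep(x[areas], each = 2)) * rep(c(-1, 1), times = 6),
    y_mm = as.numeric(rep(y[areas], each = 2)),
    group = rep(unname(grp[areas]), each = 2),
    stringsAsFactors = FALSE
  )
  attr(geom, "bregma_lambda_mm") <- bregma_lambda_mm
  class(geom) <- c("cf_geometry", "data.frame")
  geom
}

#' All ROI pair distances
#'
#' Euclidean distance in the top-view plane for all unordered ROI pairs,
#' together with the distance normalized by the bregma-lambda length. The
#' planar distance is an approximation of the actual axonal path length.
#'
#' @param geometry A `cf_geometry` object, see [default_roi_geometry()].
#' @return `data.frame` with columns `roi_a`, `roi_b`, `d_mm`, `d_norm`,
#'   in canonical order (`roi_a` precedes `roi_b` in geometry order).
#' @export
pair_distances <- function(geometry) {
  stopifnot(inherits(geometry, "cf_geometry"))
  bl <- attr(geometry, "bregma_lambda_mm")
  idx <- utils::combn(nrow(geometry), 2L)
  d <- sqrt((geometry$x_mm[idx[1, ]] - geometry$x_mm[idx[2, ]])^2 +
            (geometry$y_mm[idx[1, ]] - geometry$y_mm[idx[2, ]])^2)
  data.frame(
    roi_a = geometry$roi[idx[1, ]],
    roi_b = geometry$roi[idx[2, ]],
    d_mm = d,
    d_norm = d / bl,
    stringsAsFactors = FALSE
  )
}
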