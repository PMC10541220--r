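#' Split a myocardial mask into coronary territory sub-masks
#'
#' Partitions an annular short-axis myocardium mask into the three
#' coronary territories (LAD, LCX, RCA) by pixel angle, following the AHA
#' segment model collapsed to territories. The angle of each pixel is
#' measured counterclockwise from the right-ventricular insertion ray.
#' Basal and mid slices use six 60-degree sectors: sectors 1-2 (anterior,
#' anteroseptal) go to LAD, 3-4 (inferoseptal, inferior) to RCA and 5-6
#' (inferolateral, anterolateral) to LCX. The apical slice uses four
#' 90-degree sectors: anterior + septal to LAD, inferior to RCA, lateral
#' to LCX. A pixel lying exactly on a sector edge goes to the
#' lower-indexed sector. The three masks are pairwise disjoint and their
#' union is the input mask, whatever its shape.
#'
#' @param myo_mask logical 2D matrix (nonempty).
#' @param centroid `(y, x)` ring centre; defaults to the mask centroid.
#' @param rv_insertion_angle degrees counterclockwise from the image
#'   x-axis locating the RV insertion ray.
#' @param level slice level: `"basal"`, `"mid"` or `"apical"`.
#' @return named list of logical masks `LAD`, `LCX`, `RCA`.
#' @export
split_myocardium <- function(myo_mask, centroid = NULL,
                             rv_insertion_angle = 0,
                             level = c("basal", "mid", "apical")) {
  level <- match.arg(level)
  if (!any(myo_mask)) stop("split_myocardium: empty myocardium mask")
  idx <- which(myo_mask, arr.ind = TRUE)
  if (is.null(centroid)) centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  # math convention: x right, y up (image rows increase downward)
  dx <- idx[, 2] - centroid[2]
  dy <- centroid[1] - idx[, 1]
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  rel <- (theta - rv_insertion_angle) %% 360
  if (level == "apical") {
    sector <- pmax(ceiling(rel / 90), 1L)      # edge ties -> lower sector
    terr_of <- c("LAD", "LAD", "RCA", "LCX")
  } else {
    sector <- pmax(ceiling(rel / 60), 1L)
    terr_of <- c("LAD", "LAD", "RCA", "RCA", "LCX", "LCX")
  }
  assign_terr <- terr_of[sector]
  out <- lapply(TERRITORIES, function(tr) {
    m <- matrix(FALSE, nrow(myo_mask), ncol(myo_mask))
    m[idx[assign_terr == tr, , drop = FALSE]] <- TRUE
    m
  })
  setNames(out, TERRITORIES)
}
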