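# Contact-to-region assignment and lead/patient hit logic. Imaging-based
# localization is replaced by coordinates plus an axis-aligned box atlas of
# the thalamic subregions: the ANT subdivided (sagittal plane only) into
# ventral (ANT-V), dorsal (ANT-D) and posterior (ANT-P) parts, plus the
# mediodorsal nucleus (MD). A lead is a "hit" when at least one contact
# lies inside the ANT; otherwise it remained intraventricular ("miss").

ANT_REGIONS <- c("ANT-V", "ANT-D", "ANT-P")
ALL_REGIONS <- c(ANT_REGIONS, "MD")

#' Axis-aligned box atlas of thalamic subregions
#'
#' @param boxes Data frame with columns `region`, `side`, `xmin`, `xmax`,
#'   `ymin`, `ymax`, `zmin`, `zmax` (mm, patient space). Boxes are closed
#'   (boundary points belong to the box) and must not overlap.
#' @return A `region_atlas`.
#' @export
region_atlas <- function(boxes) {
  need <- c("region", "side", "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  if (!all(need %in% names(boxes)))
    stopf("atlas needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(boxes$region, ALL_REGIONS)
  if (length(bad)) stopf("unknown region(s): %s", paste(bad, collapse = ", "))
  if (any(boxes$xmin > boxes$xmax | boxes$ymin > boxes$ymax |
          boxes$zmin > boxes$zmax))
    stopf("degenerate atlas box (min > max)")
  for (i in seq_len(nrow(boxes))) for (j in seq_len(nrow(boxes))) {
    if (j <= i) next
    if (boxes$xmin[i] <= boxes$xmax[j] && boxes$xmax[i] >= boxes$xmin[j] &&
        boxes$ymin[i] <= boxes$ymax[j] && boxes$ymax[i] >= boxes$ymin[j] &&
        boxes$zmin[i] <= boxes$zmax[j] && boxes$zmax[i] >= boxes$zmin[j])
      stopf("atlas boxes %d and %d overlap", i, j)
  }
  structure(list(boxes = boxes), class = "region_atlas")
}

#' Synthetic default atlas
#'
#' A stand-in box parcellation (mm): lateral slabs at x in [-9,-3] (left)
#' and [3,9] (right); within a side ANT-V sits ventral, ANT-D dorsal,
#' ANT-P posterior, MD postero-medial. Purely synthetic geometry for
#' simulation and fixtures, not a brain atlas.
#'
#' @return A `region_atlas`.
#' @export
default_atlas <- function() {
  one_side <- function(side, x0, x1) data.frame(
    region = c("ANT-V", "ANT-D", "ANT-P", "MD"),
    side = side,
    xmin = x0, xmax = x1,
    ymin = c(1, 1, -2.5, -6), ymax = c(4, 4, 0.5, -3),
    zmin = c(0, 3.5, 0, 0), zmax = c(3, 6.5, 6.5, 6.5))
  region_atlas(rbind(one_side("left", -9, -3), one_side("right", 3, 9)))
}

#' Assign a contact coordinate to a region
#'
#' Closed bounds: boundary points belong to the box. Points in no box are
#' `"outside"`.
#'
#' @param coords Numeric length-3 vector `c(x, y, z)` or an n x 3 matrix /
#'   data frame with columns `x`, `y`, `z` (mm).
#' @param atlas A [region_atlas()].
#' @return Character vector of region labels.
#' @export
assign_region <- function(coords, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(as.data.frame(coords))
  b <- atlas$boxes
  vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[i, ]
    hit <- which(p[1L] >= b$xmin & p[1L] <= b$xmax &
                 p[2L] >= b$ymin & p[2L] <= b$ymax &
                 p[3L] >= b$zmin & p[3L] <= b$zmax)
    if (length(hit)) b$region[hit[1L]] else "outside"
  }, "")
}

#' Lead hit or miss
#'
#' @param regions Character vector of the lead's contact regions.
#' @return `"hit"` if any contact lies in an ANT subregion, else `"miss"`.
#' @export
lead_hit <- function(regions) {
  if (any(regions %in% ANT_REGIONS)) "hit" else "miss"
}

#' Patient-level hit summary
#'
#' `bilateral_hit`: both leads hit. `focus_side_hit`: for one-sided focus
#' laterality, that side's lead hit; for bilateral laterality, a bilateral
#' hit is required.
#'
#' @param left_hit,right_hit Logical, per-lead hit.
#' @param laterality `"left"`, `"right"`, or `"bilateral"` focus dominance.
#' @return List: `bilateral_hit`, `unilateral_hit`, `focus_side_hit`.
#' @export
patient_hit_summary <- function(left_hit, right_hit,
                                laterality = c("left", "right", "bilateral")) {
  laterality <- match.arg(laterality)
  bilateral <- left_hit && right_hit
  focus <- switch(laterality,
                  left = left_hit, right = right_hit, bilateral = bilateral)
  list(bilateral_hit = bilateral,
       unilateral_hit = xor(left_hit, right_hit),
       focus_side_hit = focus)
}
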