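#' CT volume container
#'
#' A 3-D grid of Hounsfield units with voxel geometry. Array layout is
#' (slice, row, col). Volume accounting uses the spacing *between* slices,
#' not the reconstructed slice thickness: with overlapping helical
#' reconstructions (e.g. 1.25 mm thick slices every 0.625 mm) thickness
#' would double-count tissue; thickness is kept as metadata.
#'
#' @param hu 3-D array of Hounsfield units, within \[-1024, 3071\]
#' @param in_plane_spacing in-plane voxel size, mm (> 0)
#' @param slice_spacing spacing between slice centres, mm (> 0)
#' @param slice_thickness reconstructed slice thickness, mm (> 0)
#' @return an object of class `ct_volume`
#' @export
ct_volume <- function(hu, in_plane_spacing, slice_spacing,
                      slice_thickness = slice_spacing) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stopf("`hu` must be a 3-D array")
  if (any(c(in_plane_spacing, slice_spacing, slice_thickness) <= 0))
    stopf("spacings must be > 0")
  rng <- range(hu)
  if (rng[1] < -1024 || rng[2] > 3071)
    stopf("HU values must lie within [-1024, 3071]")
  structure(list(hu = hu, in_plane_spacing = in_plane_spacing,
                 slice_spacing = slice_spacing,
                 slice_thickness = slice_thickness),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("CT volume %d x %d x %d (slice, row, col); %.3g mm in-plane, %.3g mm slice spacing (%.3g mm thick)\n",
              d[1], d[2], d[3], x$in_plane_spacing, x$slice_spacing,
              x$slice_thickness))
  cat(sprintf("  HU range [%d, %d]\n", min(x$hu), max(x$hu)))
  invisible(x)
}

# Voxel volume in mm^3 (spacing-based; see ct_volume docs).
voxel_volume_mm3 <- function(volume) {
  volume$in_plane_spacing^2 * volume$slice_spacing
}

#' Hounsfield-unit range for adipose tissue
#'
#' Constructor for an adipose attenuation interval (hu_min < hu_max), plus a
#' data-driven estimator. `estimate_hu_range()` smooths the in-body HU
#' density, locates the density mode nearest `prior_center` (default -15 HU,
#' the expected adipose attenuation), bounds it by the neighbouring density
#' valleys, and returns the interval holding the central `mode_mass`
#' (default 95%) of that mode's probability mass. Degenerate inputs (fewer
#' than two density modes, or essentially constant HU) fall back to the
#' published population-mean range (-32.2, 10.1) and set `fallback = TRUE`.
#'
#' @param hu_min,hu_max interval bounds, HU
#' @param fallback whether the value is the fallback default rather than a
#'   data-driven estimate
#' @return an object of class `hu_range`
#' @export
hu_range <- function(hu_min, hu_max, fallback = FALSE) {
  if (!is.finite(hu_min) || !is.finite(hu_max) || hu_min >= hu_max)
    stopf("need hu_min < hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max, fallback = fallback),
            class = "hu_range")
}

#' @export
print.hu_range <- function(x, ...) {
  cat(sprintf("HU range [%.1f, %.1f]%s\n", x$hu_min, x$hu_max,
              if (x$fallback) " (fallback default)" else ""))
  invisible(x)
}

#' @rdname hu_range
#' @param volume a [ct_volume()]
#' @param body_mask logical array delimiting the body (nonempty)
#' @param prior_center expected adipose HU (default -15)
#' @param mode_mass central probability mass of the adipose mode to cover
#'   (default 0.95)
#' @param default_range fallback interval when the histogram is degenerate
#' @export
estimate_hu_range <- function(volume, body_mask, prior_center = -15,
                              mode_mass = 0.95,
                              default_range = c(-32.2, 10.1)) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!any(body_mask)) stopf("`body_mask` is empty")
  x <- as.numeric(volume$hu[body_mask])
  fallback <- function() hu_range(default_range[1], default_range[2], TRUE)
  if (sd(x) < 1e-8) return(fallback())
  d <- density(x, n = 2048)
  y <- d$y
  # interior local maxima with some prominence
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_peak & y > 0.02 * max(y))
  if (length(peaks) < 2) return(fallback())
  mode_i <- peaks[which.min(abs(d$x[peaks] - prior_center))]
  # valleys: minimum density between the chosen mode and its neighbours
  left_peaks <- peaks[peaks < mode_i]
  right_peaks <- peaks[peaks > mode_i]
  lo_i <- if (length(left_peaks)) {
    lp <- max(left_peaks); lp + which.min(y[lp:mode_i]) - 1L
  } else 1L
  hi_i <- if (length(right_peaks)) {
    rp <- min(right_peaks); mode_i + which.min(y[mode_i:rp]) - 1L
  } else length(y)
  seg <- lo_i:hi_i
  w <- y[seg]
  cw <- cumsum(w) / sum(w)
  q <- (1 - mode_mass) / 2
  hu_min <- d$x[seg[max(1L, findInterval(q, cw))]]
  hu_max <- d$x[seg[min(length(seg), findInterval(1 - q, cw) + 1L)]]
  if (hu_min >= hu_max) return(fallback())
  hu_range(hu_min, hu_max, FALSE)
}

#' Threshold segmentation of a CT volume
#'
#' Per-voxel segmentation: a voxel is a candidate adipose voxel iff
#' `hu_min <= HU <= hu_max` (inclusive on both bounds).
#'
#' @param volume a [ct_volume()]
#' @param range an [hu_range()]
#' @return logical array, same dimensions as the volume
#' @export
threshold_segment <- function(volume, range) {
  stopifnot(inherits(volume, "ct_volume"), inherits(range, "hu_range"))
  volume$hu >= range$hu_min & volume$hu <= range$hu_max
}

#' 26-connected components of a 3-D mask
#'
#' Labels connected components of a logical array using 26-neighbour
#' connectivity. Component 0 is background; positive labels are in scan
#' order of each component's first voxel.
#'
#' @param mask logical 3-D array
#' @return integer array of component labels
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  array(.label_components_cpp(as.logical(mask), dim(mask)), dim = dim(mask))
}

#' Binary dilation of a 3-D mask
#'
#' Dilates by a Chebyshev ball of radius `r` (r iterations of 26-neighbour
#' dilation).
#'
#' @param mask logical 3-D array
#' @param r dilation radius in voxels (>= 0)
#' @return logical array
#' @export
dilate_mask <- function(mask, r = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, r >= 0)
  if (r == 0) return(mask)
  array(.dilate_cpp(as.logical(mask), dim(mask), as.integer(r)),
        dim = dim(mask))
}

#' Dice similarity coefficient
#'
#' 2|A intersect B| / (|A| + |B|) for two logical masks; 1 when both are
#' empty.
#'
#' @param a,b logical arrays of equal dimensions
#' @return Dice coefficient in \[0, 1\]
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Largest component label of `labels`; ties broken by larger voxel count,
# then by the component whose first voxel has the lower slice index.
largest_component <- function(labels) {
  sizes <- tabulate(labels[labels > 0])
  if (!length(sizes)) return(0L)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # scan order of first voxel: first dimension (slice) varies fastest,
    # so the earlier first-voxel component has the lower slice index
    firsts <- vapply(best, function(l) which(labels == l)[1], 0)
    best <- best[which.min(firsts)]
  }
  best[1]
}

#' Remove false positives from a candidate adipose mask
#'
#' The second step of the two-step quantification: HU thresholding yields a
#' candidate mask with known classes of false positives (A skin folds/eyes,
#' B airway-lung transition, C pericardial region, D gastrointestinal
#' contents, plus the scanner table). Two removal modes stand in for the
#' trained segmentation network:
#'
#' * `"oracle"`: subtracts the ground-truth class masks of a phantom exactly.
#' * `"rules"`: (table) removes any candidate connected component disjoint
#'   from the largest body component (body = largest 26-connected component
#'   of voxels above `air_hu`); (B) removes candidate voxels within
#'   `air_margin` voxels of air-filled regions enclosed in the body;
#'   (D) removes candidate components overlapping `git_mask` when provided.
#'   Classes A and C are not attempted by rules (they need anatomy the
#'   phantom encodes only as truth); components matched by no rule are kept.
#'
#' @param candidate logical candidate mask (from [threshold_segment()])
#' @param volume the [ct_volume()] (required in rules mode)
#' @param mode `"oracle"` or `"rules"`
#' @param truth a `phantom_truth` (required in oracle mode)
#' @param git_mask optional logical array of the gastrointestinal region
#'   (rules mode, class D)
#' @param air_hu HU below which a voxel counts as air (default -300)
#' @param air_margin dilation distance in voxels for class B (default 2)
#' @return an object of class `mask_set`: `candidate`, `removed` (named list
#'   of per-class masks), `final_adipose`
#' @export
remove_false_positives <- function(candidate, volume = NULL,
                                   mode = c("oracle", "rules"),
                                   truth = NULL, git_mask = NULL,
                                   air_hu = -300, air_margin = 2L) {
  mode <- match.arg(mode)
  stopifnot(is.array(candidate), length(dim(candidate)) == 3L)
  removed <- list()
  if (mode == "oracle") {
    if (is.null(truth)) stopf("oracle mode requires `truth`")
    for (cls in names(truth$class_masks))
      removed[[cls]] <- candidate & truth$class_masks[[cls]]
  } else {
    if (is.null(volume)) stopf("rules mode requires `volume`")
    dims <- dim(candidate)
    nonair <- volume$hu >= air_hu
    body_labels <- label_components(nonair)
    body_lab <- largest_component(body_labels)
    body <- body_labels == body_lab
    cand_labels <- label_components(candidate)
    n_comp <- max(cand_labels)
    if (n_comp > 0) {
      overlap_body <- vapply(seq_len(n_comp), function(l)
        any(body[cand_labels == l]), TRUE)
      removed$table <- array(cand_labels > 0 &
                               !overlap_body[pmax(cand_labels, 1L)],
                             dim = dims)
      # class B: candidate voxels near air enclosed in the body (air
      # components not touching the grid boundary)
      air <- volume$hu < air_hu
      air_labels <- label_components(air)
      face_labs <- unique(c(air_labels[1, , ], air_labels[dims[1], , ],
                            air_labels[, 1, ], air_labels[, dims[2], ],
                            air_labels[, , 1], air_labels[, , dims[3]]))
      face_labs <- setdiff(face_labs, 0L)
      enclosed <- air & !(air_labels %in% c(0L, face_labs))
      dim(enclosed) <- dims
      if (any(enclosed)) {
        near_air <- dilate_mask(enclosed, air_margin)
        removed$B <- candidate & near_air & !removed$table
      }
      if (!is.null(git_mask)) {
        sofar <- Reduce(`|`, removed, array(FALSE, dims))
        hit <- vapply(seq_len(n_comp), function(l)
          any(git_mask[cand_labels == l]), TRUE)
        removed$D <- array(cand_labels > 0 & hit[pmax(cand_labels, 1L)],
                           dim = dims) & !sofar
      }
    }
  }
  final <- candidate
  for (m in removed) final <- final & !m
  structure(list(candidate = candidate, removed = removed,
                 final_adipose = final, mode = mode),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("Segmentation masks (%s mode): %d candidate voxels, %d final adipose\n",
              x$mode, sum(x$candidate), sum(x$final_adipose)))
  for (cls in names(x$removed))
    cat(sprintf("  removed %-5s %d voxels\n", cls, sum(x$removed[[cls]])))
  invisible(x)
}

#' Volume and mass accounting for a segmentation
#'
#' Converts the final adipose mask into volumes, the adipose fraction, and
#' the adipose / nonadipose mass split: voxel volume is
#' `in_plane_spacing^2 * slice_spacing`; `at_fraction` is adipose voxels over
#' body voxels; `at_mass = body_mass * at_fraction` and
#' `nonat_mass = body_mass - at_mass`, so the two masses sum to body mass
#' exactly.
#'
#' @param masks a `mask_set` from [remove_false_positives()] (or a logical
#'   adipose array)
#' @param body_mask logical body mask (nonempty)
#' @param volume the [ct_volume()] (for voxel geometry)
#' @param body_mass scale-measured body mass, kg (> 0)
#' @return an object of class `composition_estimate` with `at_volume_cm3`,
#'   `body_volume_cm3`, `at_fraction`, `at_mass`, `nonat_mass`
#' @export
quantify <- function(masks, body_mask, volume, body_mass) {
  stopifnot(inherits(volume, "ct_volume"))
  assert_scalar_num(body_mass, "body_mass", 0, strict_lower = TRUE)
  final <- if (inherits(masks, "mask_set")) masks$final_adipose else masks
  if (!any(body_mask)) stopf("`body_mask` is empty")
  if (any(final & !body_mask))
    stopf("consistency error: final adipose mask extends outside the body mask")
  vox_cm3 <- voxel_volume_mm3(volume) / 1000
  n_body <- sum(body_mask)
  n_at <- sum(final)
  at_fraction <- n_at / n_body
  at_mass <- body_mass * at_fraction
  structure(list(
    at_volume_cm3 = n_at * vox_cm3,
    body_volume_cm3 = n_body * vox_cm3,
    at_fraction = at_fraction,
    at_mass = at_mass,
    nonat_mass = body_mass - at_mass,
    body_mass = body_mass
  ), class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf("Body %.1f cm^3, adipose %.1f cm^3 (%.2f%%); mass %.3f kg adipose / %.3f kg nonadipose\n",
              x$body_volume_cm3, x$at_volume_cm3, 100 * x$at_fraction,
              x$at_mass, x$nonat_mass))
  invisible(x)
}
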