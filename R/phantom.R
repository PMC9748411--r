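#' Specification of a voxel CT phantom
#'
#' Describes a desk-scale turtle body phantom: an ellipsoidal body with a
#' bony carapace shell, two lung air spaces, four adipose depots (neck,
#' sub-carapace, mesenteric, hindlimb) sized to a target adipose fraction,
#' and optional false-positive structures matching the classes a threshold
#' segmentation picks up: (A) skin folds/eyes, (B) the airway-lung
#' transition, (C) the pericardial region, (D) gastrointestinal contents,
#' plus the scanner table outside the body.
#'
#' @param grid_shape integer (slices, rows, cols); the default 160 x 96 x 96
#'   stands in for clinical 512 x 512 x ~1600 grids
#' @param in_plane_spacing in-plane voxel size, mm
#' @param slice_spacing spacing between slice centres, mm (0.625 by default;
#'   used for volume accounting)
#' @param slice_thickness reconstructed slice thickness, mm (metadata only)
#' @param target_at_fraction adipose fraction of body volume, in \[0, 0.5)
#' @param depot_shares named shares of the four depots (must sum to 1)
#' @param fp_plan which false-positive classes to inject; subset of
#'   `c("A","B","C","D","table")`
#' @param hu_model per-tissue HU distributions; see Details of
#'   [build_phantom()]
#' @param seed integer seed
#' @return a list of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(160L, 96L, 96L),
                         in_plane_spacing = 1.0,
                         slice_spacing = 0.625,
                         slice_thickness = 1.25,
                         target_at_fraction = 0.065,
                         depot_shares = c(neck = 0.25, sub_carapace = 0.25,
                                          mesenteric = 0.25, hindlimb = 0.25),
                         fp_plan = c("A", "B", "C", "D", "table"),
                         hu_model = default_hu_model(),
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stopf("`grid_shape` must be 3 dimensions, each >= 32 voxels")
  if (any(c(in_plane_spacing, slice_spacing, slice_thickness) <= 0))
    stopf("spacings must be > 0")
  assert_scalar_num(target_at_fraction, "target_at_fraction", 0)
  if (target_at_fraction >= 0.5) stopf("`target_at_fraction` must be < 0.5")
  depots <- c("neck", "sub_carapace", "mesenteric", "hindlimb")
  if (!setequal(names(depot_shares), depots))
    stopf("`depot_shares` must name exactly: %s", paste(depots, collapse = ", "))
  if (abs(sum(depot_shares) - 1) > 1e-8) stopf("depot shares must sum to 1")
  if (length(fp_plan)) {
    fp_plan <- match.arg(fp_plan, c("A", "B", "C", "D", "table"),
                         several.ok = TRUE)
  } else {
    fp_plan <- character(0)
  }
  structure(list(grid_shape = grid_shape, in_plane_spacing = in_plane_spacing,
                 slice_spacing = slice_spacing, slice_thickness = slice_thickness,
                 target_at_fraction = target_at_fraction,
                 depot_shares = depot_shares[depots],
                 fp_plan = if (length(fp_plan)) fp_plan else character(0),
                 hu_model = hu_model, seed = seed),
            class = "phantom_spec")
}

#' Default per-tissue HU model
#'
#' Means/SDs and truncation bounds (HU) for the simulated tissues. Adipose
#' defaults to mean -15, SD 10, truncated to the published population-mean
#' attenuation range (-32.2, 10.1); nonadipose soft tissue is kept at or
#' above +20, air at or below -300 and bone at or above +300, so the adipose
#' range separates cleanly; gastrointestinal contents deliberately overlap
#' the adipose range.
#'
#' @return nested list of tissue HU settings
#' @export
default_hu_model <- function() {
  list(adipose = list(mean = -15, sd = 10, range = c(-32.2, 10.1)),
       soft = list(mean = 40, sd = 15, min = 20),
       air = list(mean = -800, sd = 80, max = -300),
       outside = list(mean = -1000, sd = 30, max = -900),
       bone = list(mean = 700, sd = 150, min = 300),
       git = list(mean = 0, sd = 25, range = c(-60, 60)),
       table = list(mean = -10, sd = 5))
}

# Squared normalized ellipsoid radius over the whole grid; centers and
# semi-axes in voxel units. Returns a numeric vector of length prod(dims).
ellipsoid_u2 <- function(dims, center, semi) {
  n <- prod(dims)
  i0 <- 0:(n - 1)
  s <- (i0 %% dims[1]) + 1
  r <- ((i0 %/% dims[1]) %% dims[2]) + 1
  c_ <- (i0 %/% (dims[1] * dims[2])) + 1
  ((s - center[1]) / semi[1])^2 + ((r - center[2]) / semi[2])^2 +
    ((c_ - center[3]) / semi[3])^2
}

rtnorm_hu <- function(n, m) {
  lo <- if (!is.null(m$range)) m$range[1] else if (!is.null(m$min)) m$min else -Inf
  hi <- if (!is.null(m$range)) m$range[2] else if (!is.null(m$max)) m$max else Inf
  rtnorm(n, m$mean, m$sd, lo, hi)
}

#' Build a voxel CT phantom with ground truth
#'
#' Realizes a [phantom_spec()] as a Hounsfield-unit volume plus truth masks.
#' Adipose depots are rasterized by selecting, for each depot, exactly the
#' target number of voxels closest (in normalized ellipsoid distance) to the
#' depot centre among voxels not claimed by other structures, so the
#' voxelized adipose fraction matches `target_at_fraction` up to rounding.
#' False-positive structures are only realized for classes in `fp_plan`, and
#' every tissue draws its HU from `hu_model`, so a threshold at the adipose
#' range selects exactly adipose + injected false positives.
#'
#' @param spec a [phantom_spec()]
#' @return a list of class `ct_phantom` with elements `volume` (a
#'   [ct_volume()]) and `truth` (class `phantom_truth`: `adipose_mask`,
#'   `class_masks`, `body_mask`, `true_at_fraction_voxelized`)
#' @examples
#' ph <- build_phantom(phantom_spec(grid_shape = c(48, 40, 40), seed = 1))
#' ph$truth$true_at_fraction_voxelized
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  dims <- spec$grid_shape
  n <- prod(dims)
  ctr <- (dims + 1) / 2
  body_semi <- c(0.45, 0.38, 0.40) * dims
  u_body <- ellipsoid_u2(dims, ctr, body_semi)
  body <- u_body <= 1
  n_body <- sum(body)
  if (n_body == 0) stopf("zero-volume body")

  bone <- body & u_body >= 0.92^2
  lung_semi <- c(0.10, 0.07, 0.08) * dims
  lung1 <- ellipsoid_u2(dims, c(0.45, 0.36, 0.36) * dims, lung_semi) <= 1
  lung2 <- ellipsoid_u2(dims, c(0.45, 0.36, 0.64) * dims, lung_semi) <= 1
  lungs <- (lung1 | lung2) & body & !bone

  plan <- spec$fp_plan
  class_masks <- list()
  git_region <- ellipsoid_u2(dims, c(0.62, 0.58, 0.50) * dims,
                             c(0.10, 0.09, 0.11) * dims) <= 1
  git_region <- git_region & body & !bone & !lungs

  if ("B" %in% plan) {
    dil <- array(.dilate_cpp(lungs, dims, 1L), dim = dims)
    class_masks$B <- as.vector(dil) & !lungs & body & !bone
  }
  if ("C" %in% plan) {
    class_masks$C <- ellipsoid_u2(dims, c(0.32, 0.60, 0.50) * dims,
                                  c(0.05, 0.05, 0.06) * dims) <= 1
    class_masks$C <- class_masks$C & body & !bone & !lungs
    if (!is.null(class_masks$B)) class_masks$C <- class_masks$C & !class_masks$B
  }
  if ("A" %in% plan) {
    a_semi <- pmax(0.02 * dims, 1.5)
    a1 <- ellipsoid_u2(dims, c(0.10, 0.42, 0.42) * dims, a_semi) <= 1
    a2 <- ellipsoid_u2(dims, c(0.10, 0.42, 0.58) * dims, a_semi) <= 1
    a3 <- ellipsoid_u2(dims, c(0.50, 0.84, 0.50) * dims, a_semi) <= 1
    amask <- (a1 | a2 | a3) & body & !bone & !lungs & !git_region
    for (cm in class_masks) amask <- amask & !cm
    class_masks$A <- amask
  }
  if ("table" %in% plan) {
    i0 <- 0:(n - 1)
    r <- ((i0 %/% dims[1]) %% dims[2]) + 1
    slab <- r >= dims[2] - 2 & r <= dims[2] - 1 & !body
    class_masks$table <- slab
  }

  occupied <- body & FALSE
  for (cm in class_masks) occupied <- occupied | cm
  occupied <- occupied | bone | lungs | git_region

  # depots: exact-count nearest-voxel rasterization
  depot_defs <- list(
    neck = list(center = c(0.18, 0.50, 0.50), ratio = c(1.4, 0.8, 0.8)),
    sub_carapace = list(center = c(0.50, 0.30, 0.50), ratio = c(2.5, 0.45, 1.8)),
    mesenteric = list(center = c(0.42, 0.60, 0.38), ratio = c(1, 1, 1)),
    hindlimb = list(center = c(0.80, 0.55, 0.50), ratio = c(1.2, 0.9, 0.9)))
  interior <- body & u_body <= 0.86^2 & !occupied
  adipose <- rep(FALSE, n)
  n_at_total <- round(spec$target_at_fraction * n_body)
  shares <- spec$depot_shares
  n_targets <- round(shares * n_at_total)
  n_targets[length(n_targets)] <- n_at_total - sum(n_targets[-length(n_targets)])
  for (d in names(depot_defs)) {
    n_t <- n_targets[[d]]
    if (n_t <= 0) next
    def <- depot_defs[[d]]
    rho <- prod(def$ratio)^(1 / 3)
    a <- (n_t * 3 / (4 * pi))^(1 / 3) / rho
    semi <- pmax(a * def$ratio, 1)
    u_d <- ellipsoid_u2(dims, def$center * dims, semi)
    avail <- which(interior & u_d <= 1.5^2)
    if (length(avail) < n_t)
      stopf("generation error: infeasible target adipose fraction %.3f (depot '%s' cannot fit)",
            spec$target_at_fraction, d)
    sel <- avail[order(u_d[avail])[seq_len(n_t)]]
    adipose[sel] <- TRUE
    interior[sel] <- FALSE
  }

  hu <- with_seed(spec$seed, {
    hm <- spec$hu_model
    hu <- numeric(n)
    outside <- !body & !(if (!is.null(class_masks$table)) class_masks$table else rep(FALSE, n))
    hu[outside] <- rtnorm_hu(sum(outside), hm$outside)
    soft <- body & !bone & !lungs & !git_region & !adipose
    for (cm in class_masks) soft <- soft & !cm
    hu[soft] <- rtnorm_hu(sum(soft), hm$soft)
    hu[bone] <- rtnorm_hu(sum(bone), hm$bone)
    hu[lungs] <- rtnorm_hu(sum(lungs), hm$air)
    if ("D" %in% plan) {
      hu[git_region] <- rtnorm_hu(sum(git_region), hm$git)
    } else if (any(git_region)) {
      hu[git_region] <- rtnorm_hu(sum(git_region), hm$soft)
    }
    for (cls in intersect(c("A", "B", "C"), names(class_masks)))
      hu[class_masks[[cls]]] <- rtnorm_hu(sum(class_masks[[cls]]), hm$adipose)
    if (!is.null(class_masks$table)) {
      tm <- hm$table
      tm$range <- hm$adipose$range
      hu[class_masks$table] <- rtnorm_hu(sum(class_masks$table), tm)
    }
    hu[adipose] <- rtnorm_hu(sum(adipose), hm$adipose)
    hu
  })
  hu <- pmin(pmax(round(hu), -1024), 3071)
  # class D is the realized in-range part of the gastrointestinal contents
  if ("D" %in% plan) {
    rng <- spec$hu_model$adipose$range
    class_masks$D <- git_region & hu >= rng[1] & hu <= rng[2]
  }

  to_arr <- function(v) array(v, dim = dims)
  vol <- ct_volume(to_arr(as.integer(hu)), spec$in_plane_spacing,
                   spec$slice_spacing, spec$slice_thickness)
  truth <- structure(list(
    adipose_mask = to_arr(adipose),
    class_masks = lapply(class_masks[intersect(c("A", "B", "C", "D", "table"),
                                               names(class_masks))], to_arr),
    body_mask = to_arr(body),
    git_region = to_arr(git_region),
    true_at_fraction_voxelized = sum(adipose) / n_body
  ), class = "phantom_truth")
  structure(list(volume = vol, truth = truth, spec = spec),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  d <- dim(x$volume$hu)
  cat(sprintf("CT phantom %d x %d x %d, adipose fraction %.4f (target %.4f)\n",
              d[1], d[2], d[3], x$truth$true_at_fraction_voxelized,
              x$spec$target_at_fraction))
  cat(sprintf("  false-positive classes: %s\n",
              if (length(x$spec$fp_plan)) paste(x$spec$fp_plan, collapse = ", ")
              else "none"))
  invisible(x)
}
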