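# Coordinate convention (used everywhere): 0-based voxel indices, voxel-center
# sampling, axes ordered (x, y, z) with z the coarse 3 mm axis; the grid is
# centered on the origin of patient space; beams are coplanar in the axial
# (x, y) plane.

#' Voxelized relative-stopping-power phantom grid
#'
#' @param rsp 3-D numeric array of relative stopping power (>= 0; ~0 in air,
#'   ~1 in water-like tissue).
#' @param spacing Voxel spacing in mm, length-3 (default `c(1, 1, 3)`).
#' @param origin Patient-space position of the center of voxel (0,0,0); by
#'   default the grid is centered on (0,0,0).
#' @return Object of class `phantom_grid`.
#' @export
phantom_grid <- function(rsp, spacing = c(1, 1, 3), origin = NULL) {
  stopifnot(is.array(rsp), length(dim(rsp)) == 3, length(spacing) == 3)
  if (any(rsp < 0)) stop("rsp values must be non-negative")
  shape <- dim(rsp)
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), rsp = rsp),
            class = "phantom_grid")
}

#' Voxel-center coordinate arrays of a phantom grid
#'
#' @param grid A [phantom_grid()].
#' @return List with arrays `x`, `y`, `z` (mm) of the grid's shape.
#' @export
grid_coords <- function(grid) {
  sh <- grid$shape
  ax <- lapply(1:3, function(k) grid$origin[k] + (0:(sh[k] - 1)) * grid$spacing[k])
  list(x = array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh),
       y = array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh),
       z = array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh))
}

#' Structure set: named binary ROI masks with tissue assignments
#'
#' @param rois Named list of logical arrays, all of the grid's shape.
#' @param tissue Named numeric vector of alpha_x/beta_x ratios (Gy), one per
#'   ROI; defaults 3.7 Gy for the PTV and 2.0 Gy for everything else.
#' @param ptv_name Name of the target ROI (must be non-empty).
#' @param overlaps Character vector of OAR names declared to overlap the PTV.
#' @return Object of class `structure_set`.
#' @export
structure_set <- function(rois, tissue = NULL, ptv_name = "ptv",
                          overlaps = character()) {
  stopifnot(is.list(rois), !is.null(names(rois)), ptv_name %in% names(rois))
  sh <- dim(rois[[1]])
  for (nm in names(rois)) {
    if (!identical(dim(rois[[nm]]), sh)) stop("ROI mask shape mismatch: ", nm)
  }
  if (!any(rois[[ptv_name]])) stop("PTV mask is empty")
  if (is.null(tissue)) {
    tissue <- stats::setNames(rep(2.0, length(rois)), names(rois))
    tissue[ptv_name] <- 3.7
  }
  if (any(tissue <= 0)) stop("alpha/beta ratios must be positive")
  ptv <- rois[[ptv_name]]
  for (nm in setdiff(names(rois), c(ptv_name, overlaps))) {
    if (any(rois[[nm]] & ptv)) {
      stop("ROI '", nm, "' overlaps the PTV but is not declared in `overlaps`")
    }
  }
  structure(list(rois = rois, tissue = tissue, ptv_name = ptv_name,
                 overlaps = overlaps), class = "structure_set")
}

#' Names of the organ-at-risk ROIs of a structure set
#' @param structures A [structure_set()].
#' @return Character vector (all ROIs except the PTV).
#' @export
oar_names <- function(structures) {
  setdiff(names(structures$rois), structures$ptv_name)
}

.capsule_mask <- function(co, p1, p2, radius) {
  # distance from voxel centers to segment p1-p2
  d <- p2 - p1
  len2 <- sum(d^2)
  px <- co$x - p1[1]; py <- co$y - p1[2]; pz <- co$z - p1[3]
  t <- if (len2 > 0) pmin(pmax((px * d[1] + py * d[2] + pz * d[3]) / len2, 0), 1) else 0
  dx <- px - t * d[1]; dy <- py - t * d[2]; dz <- pz - t * d[3]
  dx^2 + dy^2 + dz^2 <= radius^2
}

.sphere_mask <- function(co, c0, r) {
  (co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2 <= r^2
}

.ellipsoid_mask <- function(co, c0, semi) {
  ((co$x - c0[1]) / semi[1])^2 + ((co$y - c0[2]) / semi[2])^2 +
    ((co$z - c0[3]) / semi[3])^2 <= 1
}

.zcyl_mask <- function(co, c0, r, halfz) {
  ((co$x - c0[1])^2 + (co$y - c0[2])^2 <= r^2) & (abs(co$z - c0[3]) <= halfz)
}

#' Generate a synthetic meningioma-like case
#'
#' Builds one of four stylized case templates emulating typical skull-base /
#' ocular meningioma geometries: a water-like body with an ellipsoidal PTV
#' and adjacent serial OARs (brainstem-, chiasm-, optic-nerve-, eye-like
#' structures), coplanar field configurations, and a 1.8 Gy(RBE)/fraction
#' prescription. Templates:
#' \describe{
#'   \item{A}{two opposed fields (180 deg apart), 29 fractions; brainstem,
#'     temporal lobes, optical system.}
#'   \item{B}{two fields 75 deg apart, 30 fractions; brainstem, chiasm,
#'     optic nerves, intra-auricular nerve.}
#'   \item{C}{two fields 32 deg apart, 30 fractions; brainstem, chiasm,
#'     right optic nerve.}
#'   \item{D}{single field, 28 fractions; shallow ocular PTV with the left
#'     optic nerve partially inside the PTV and an adjacent eye.}
#' }
#' Every template places at least one OAR within 5 mm of the PTV surface.
#' Generation is a pure function of `(template, seed, shape, spacing)`.
#'
#' @param template One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param seed Integer seed for the (small) stopping-power heterogeneity.
#' @param shape Grid shape in voxels (default `c(64, 64, 40)`).
#' @param spacing Voxel spacing in mm (default `c(1, 1, 3)`).
#' @param rsp_noise Relative standard deviation of in-body stopping-power
#'   heterogeneity (default 0.02).
#' @param bone_shell Add a 2 mm bone-like (rsp 1.5) shell at the body surface.
#' @return List with elements `grid` ([phantom_grid()]), `structures`
#'   ([structure_set()]), `beams` (beam configuration), and `prescription`.
#' @export
make_case <- function(template, seed = 1, shape = c(64, 64, 40),
                      spacing = c(1, 1, 3), rsp_noise = 0.02,
                      bone_shell = FALSE) {
  if (!is.character(template) || length(template) != 1 ||
      !template %in% c("A", "B", "C", "D")) {
    stop("unknown template label '", paste(template, collapse = ","),
         "': must be one of \"A\", \"B\", \"C\", \"D\"")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ext <- shape * spacing
  rb <- 0.45 * min(ext[1], ext[2])
  s <- rb / 28.8                      # anatomy scale relative to default grid
  rsp <- array(0, dim = shape)
  g0 <- phantom_grid(rsp, spacing)
  co <- grid_coords(g0)
  body <- ((co$x / (0.45 * ext[1]))^2 + (co$y / (0.45 * ext[2]))^2 <= 1) &
    (abs(co$z) <= 0.45 * ext[3])
  rsp[body] <- pmax(1 + rsp_noise * stats::rnorm(sum(body)), 0.8)
  if (bone_shell) {
    inner <- ((co$x / (0.45 * ext[1] - 2))^2 +
                (co$y / (0.45 * ext[2] - 2))^2 <= 1)
    rsp[body & !inner] <- 1.5
  }

  overlaps <- character()
  if (template == "A") {
    ptv_c <- c(0, 0, 0); ptv_semi <- c(9, 7, 7) * s
    angles <- c(0, 180); n_fx <- 29L
    rois <- list(
      brain_stem = quote(.zcyl_mask(co, c(0, 11 * s + 2, 0), 4 * s, 20 * s)),
      temporal_lobe_left = quote(.sphere_mask(co, c(-16 * s, 3 * s, 0), 5 * s)),
      temporal_lobe_right = quote(.sphere_mask(co, c(16 * s, 3 * s, 0), 5 * s)),
      optical_system = quote(.sphere_mask(co, c(0, -(11 * s + 3), 0), 4 * s)))
  } else if (template == "B") {
    ptv_c <- c(0, 0, 0); ptv_semi <- c(8, 7, 6) * s
    # 75 deg apart, chosen so neither field exits through a serial OAR
    angles <- c(255, 330); n_fx <- 30L
    rois <- list(
      brain_stem = quote(.zcyl_mask(co, c(0, 11 * s + 2, 0), 4 * s, 20 * s)),
      chiasma = quote(.sphere_mask(co, c(-(11 * s + 2), 0, 0), 3 * s)),
      optic_nerve_left = quote(.capsule_mask(co, c(-(11 * s + 2), 0, 0),
                                             c(-24 * s, 6 * s, 0), 2 * s)),
      optic_nerve_right = quote(.capsule_mask(co, c(-(11 * s + 2), 0, 0),
                                              c(-24 * s, -6 * s, 0), 2 * s)),
      intra_auricular_nerve = quote(.sphere_mask(co, c(22 * s, 6 * s, 0), 2.5 * s)))
  } else if (template == "C") {
    ptv_c <- c(0, 0, 0); ptv_semi <- c(9, 7, 7) * s
    angles <- c(0, 32); n_fx <- 30L
    rois <- list(
      brain_stem = quote(.zcyl_mask(co, c(0, 11 * s + 2, 0), 4 * s, 20 * s)),
      chiasma = quote(.sphere_mask(co, c(-(12 * s + 3), 0, 0), 3 * s)),
      optic_nerve_right = quote(.capsule_mask(co, c(-(12 * s + 3), 0, 0),
                                              c(-24 * s, -6 * s, 0), 2 * s)))
  } else {
    ptv_c <- c(-12 * s, 0, 0); ptv_semi <- c(6, 5, 5) * s
    angles <- 0; n_fx <- 28L
    rois <- list(
      eye_left = quote(.sphere_mask(co, c(-25.5 * s, 5 * s, 0), 3 * s)),
      optic_nerve_left = quote(.capsule_mask(co, c(-25.5 * s, 5 * s, 0),
                                             c(-12 * s, 0, 0), 2 * s)))
    overlaps <- "optic_nerve_left"
  }

  ptv <- .ellipsoid_mask(co, ptv_c, ptv_semi) & body
  env <- environment()
  masks <- c(list(ptv = ptv),
             lapply(rois, function(q) eval(q, env) & body))
  # OARs never extend into the PTV unless declared
  for (nm in setdiff(names(masks), c("ptv", overlaps))) {
    if (nm != "ptv") masks[[nm]] <- masks[[nm]] & !ptv
  }
  structures <- structure_set(masks, ptv_name = "ptv", overlaps = overlaps)

  beams <- list(
    fields = lapply(angles, function(a) {
      list(angle = a, isocenter = ptv_c, spot_spacing = 4, sigma0 = 3)
    }),
    energy_layer_spacing_mm = 2
  )
  class(beams) <- "beam_config"
  prescription <- list(dose_per_fraction = 1.8, n_fractions = n_fx,
                       constraints = NULL)
  class(prescription) <- "prescription"

  list(grid = phantom_grid(rsp, spacing), structures = structures,
       beams = beams, prescription = prescription, template = template,
       seed = seed)
}

#' Unit beam direction of a field angle
#'
#' Fields are coplanar in the axial plane; an angle of 0 degrees travels
#' along +x, 90 degrees along +y.
#' @param angle_deg Gantry angle in degrees.
#' @return Length-3 unit vector.
#' @export
field_direction <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(cos(th), sin(th), 0)
}

#' Minimal surface distance between the PTV and an OAR
#'
#' Minimum voxel-center distance between two masks, mm (0 if they overlap).
#' @param grid A [phantom_grid()].
#' @param mask_a,mask_b Logical arrays of the grid's shape.
#' @return Distance in mm.
#' @export
mask_min_distance <- function(grid, mask_a, mask_b) {
  if (any(mask_a & mask_b)) return(0)
  co <- grid_coords(grid)
  pa <- cbind(co$x[mask_a], co$y[mask_a], co$z[mask_a])
  pb <- cbind(co$x[mask_b], co$y[mask_b], co$z[mask_b])
  if (!nrow(pa) || !nrow(pb)) return(Inf)
  mind <- Inf
  for (i in seq_len(nrow(pb))) {
    d2 <- (pa[, 1] - pb[i, 1])^2 + (pa[, 2] - pb[i, 2])^2 + (pa[, 3] - pb[i, 3])^2
    mind <- min(mind, min(d2))
  }
  sqrt(mind)
}

#' Water-equivalent depth along a ray
#'
#' Path integral of relative stopping power along a ray, sampled by trilinear
#' interpolation at 0.5 mm steps: `WED = integral of rsp dl` from the entry
#' point up to the requested geometric depth.
#'
#' @param grid A [phantom_grid()].
#' @param entry Ray entry point, mm (length 3).
#' @param direction Unit direction vector (length 3).
#' @param depth Geometric path length to integrate over, mm.
#' @return Water-equivalent depth in mm (0, with a warning, if the ray never
#'   intersects the grid).
#' @export
water_equivalent_depth <- function(grid, entry, direction, depth) {
  stopifnot(length(entry) == 3, length(direction) == 3, depth >= 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector")
  if (depth == 0) return(0)
  h <- 0.5
  n <- max(1L, ceiling(depth / h))
  tmid <- (seq_len(n) - 0.5) * (depth / n)
  pts <- cbind(entry[1] + tmid * direction[1],
               entry[2] + tmid * direction[2],
               entry[3] + tmid * direction[3])
  vals <- trilinear_sample(grid, pts)
  if (all(is.na(vals))) {
    warning("ray does not intersect the grid; WED = 0")
    return(0)
  }
  sum(vals, na.rm = TRUE) * (depth / n)
}

# Trilinear interpolation of grid$rsp at patient-space points (n x 3 matrix).
# Points outside the grid return NA.
trilinear_sample <- function(grid, pts) {
  sh <- grid$shape
  cx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  cy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  cz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  outside <- cx < -0.5 | cx > sh[1] - 0.5 | cy < -0.5 | cy > sh[2] - 0.5 |
    cz < -0.5 | cz > sh[3] - 0.5
  ix <- floor(cx); iy <- floor(cy); iz <- floor(cz)
  fx <- cx - ix; fy <- cy - iy; fz <- cz - iz
  val <- numeric(nrow(pts))
  getv <- function(i, j, k) {
    ok <- i >= 0 & i < sh[1] & j >= 0 & j < sh[2] & k >= 0 & k < sh[3]
    v <- numeric(length(i))
    idx <- 1 + i[ok] + sh[1] * (j[ok] + sh[2] * k[ok])
    v[ok] <- grid$rsp[idx]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    val <- val + w * getv(ix + di, iy + dj, iz + dk)
  }
  val[outside] <- NA_real_
  val
}
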