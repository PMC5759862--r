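#' Ion beam model specification
#'
#' Bundles the ion species, ripple-filter setting and analytic beam-model
#' coefficients used to build influence matrices.
#'
#' @param ion `"proton"` or `"helium"`.
#' @param ripple_filter Logical; defaults to `TRUE` for helium (to avoid
#'   target dose inhomogeneity from the narrow helium peaks) and `FALSE`
#'   for protons.
#' @param params Beam-model coefficients, see [beam_defaults()].
#' @return Object of class `ion_beam_model`.
#' @export
ion_beam_model <- function(ion = c("proton", "helium"), ripple_filter = NULL,
                           params = beam_defaults(ion)) {
  ion <- match.arg(ion)
  if (is.null(ripple_filter)) ripple_filter <- ion == "helium"
  structure(list(ion = ion, ripple_filter = ripple_filter, params = params),
            class = "ion_beam_model")
}

# Lateral (v) and longitudinal (t) unit axes of a coplanar field
.field_axes <- function(angle_deg) {
  u <- field_direction(angle_deg)
  list(u = u, v = c(-u[2], u[1], 0))
}

#' Compute the voxel-by-spot influence matrices for a case
#'
#' Deterministic ray-cast + Gaussian-kernel pencil-beam engine. For every
#' field, voxel water-equivalent depths (WED) are ray-marched through the
#' stopping-power grid (trilinear sampling at 0.5 mm steps); energy layers
#' are selected to cover the PTV's WED extent at the configured Bragg-peak
#' spacing; spots are placed on a lateral grid covering the PTV's
#' beam's-eye-view projection plus one lateral sigma margin. Each influence
#' entry is `depth-dose(WED) x 2-D lateral Gaussian(off-axis distance,
#' sigma(depth))`; entries beyond 3.5 lateral sigmas or below 1e-4 of their
#' column maximum are dropped. Alongside the physical-dose store `D`,
#' LET-weighted (`L = D x LET_d(depth)`) and alpha-weighted
#' (`A = D x alpha/alpha_x(LET_d, ion, tissue)`) stores share the same
#' sparsity pattern, so that dose-averaged LET and radiosensitivity grids
#' are linear accumulations.
#'
#' @param phantom A [phantom_grid()].
#' @param structures A [structure_set()] (supplies per-voxel tissue
#'   alpha/beta for the alpha-weighted store).
#' @param beams Beam configuration as returned by [make_case()].
#' @param model An [ion_beam_model()].
#' @param cut_sigma Lateral kernel cutoff in sigmas (default 3.5).
#' @param rel_cutoff Relative per-column dose cutoff (default 1e-4).
#' @return Object of class `influence_matrix` with sparse `D`, `L`, `A`
#'   (voxels x spots, [Matrix::sparseMatrix()]), a `spots` data frame
#'   (field, angle, range_w, v, z), and grid metadata.
#' @export
compute_influence <- function(phantom, structures, beams, model,
                              cut_sigma = 3.5, rel_cutoff = 1e-4) {
  stopifnot(inherits(phantom, "phantom_grid"),
            inherits(structures, "structure_set"),
            inherits(model, "ion_beam_model"))
  sh <- phantom$shape
  nvox <- prod(sh)
  co <- grid_coords(phantom)
  ptv <- structures$rois[[structures$ptv_name]]

  # per-voxel tissue alpha/beta (normal tissue 2.0 unless an ROI says else;
  # PTV assignment wins over declared overlaps)
  abx <- array(2.0, dim = sh)
  for (nm in oar_names(structures)) abx[structures$rois[[nm]]] <-
    structures$tissue[[nm]]
  abx[ptv] <- structures$tissue[[structures$ptv_name]]

  tri <- list(i = integer(), j = integer(), d = numeric(), l = numeric(),
              a = numeric())
  spot_tab <- list()
  nspots <- 0L
  for (fi in seq_along(beams$fields)) {
    fld <- beams$fields[[fi]]
    ax <- .field_axes(fld$angle)
    iso <- fld$isocenter
    wed <- wed_grid_cpp(phantom$rsp, as.integer(sh), phantom$spacing,
                        phantom$origin, ax$u, 0.5)
    vlat <- as.numeric((co$x - iso[1]) * ax$v[1] + (co$y - iso[2]) * ax$v[2])
    zlat <- as.numeric(co$z - iso[3])

    wed_ptv <- wed[as.vector(ptv)]
    if (max(wed_ptv) < 10) {
      stop("no spot reaches the PTV for field ", fi, " (angle ", fld$angle,
           " deg): PTV water-equivalent depth extent [",
           round(min(wed_ptv), 1), ", ", round(max(wed_ptv), 1),
           "] mm is below the 10 mm range floor")
    }
    layers <- select_energy_layers(max(min(wed_ptv), 10), max(wed_ptv),
                                   beams$energy_layer_spacing_mm)
    layers <- pmin(layers, 300)

    depth_max <- max(layers) + 60
    curves <- lapply(layers, function(r) {
      bragg_curve(model$ion, r, ripple_filter = model$ripple_filter,
                  params = model$params, depth_max = depth_max)
    })
    depth <- curves[[1]]$depth
    dose_m <- vapply(curves, `[[`, numeric(length(depth)), "dose")
    let_m <- vapply(curves, `[[`, numeric(length(depth)), "let_d")
    sigma_m <- vapply(layers, function(r) {
      sigma_lateral(model$ion, depth, r, sigma0 = fld$sigma0,
                    params = model$params)
    }, numeric(length(depth)))
    support <- vapply(seq_along(layers), function(l) {
      depth[max(which(dose_m[, l] > 1e-6 * max(dose_m[, l])))]
    }, numeric(1))

    # spot lateral grid covering the PTV projection + one sigma margin
    pv <- vlat[as.vector(ptv)]; pz <- zlat[as.vector(ptv)]
    margin <- fld$sigma0 + fld$spot_spacing / 2
    vpos <- seq(min(pv) - margin, max(pv) + margin, by = fld$spot_spacing)
    zpos <- seq(min(pz) - margin, max(pz) + margin, by = fld$spot_spacing)
    lat <- expand.grid(v = vpos, z = zpos)
    keep <- vapply(seq_len(nrow(lat)), function(r) {
      any(abs(pv - lat$v[r]) <= margin & abs(pz - lat$z[r]) <= margin)
    }, logical(1))
    lat <- lat[keep, , drop = FALSE]
    if (!nrow(lat)) stop("no spot reaches the PTV for field ", fi,
                         " (angle ", fld$angle, " deg)")
    spots <- expand.grid(layer = seq_along(layers), pos = seq_len(nrow(lat)))
    sv <- lat$v[spots$pos]; sz <- lat$z[spots$pos]
    slayer <- spots$layer

    res <- spot_influence_cpp(wed, vlat, zlat, as.numeric(abx),
                              sv, sz, as.integer(slayer - 1L),
                              dose_m, let_m, sigma_m, support, DEPTH_STEP,
                              model$params$lambda, cut_sigma, rel_cutoff)
    if (!length(res$i)) stop("no spot reaches the PTV for field ", fi,
                             " (angle ", fld$angle, " deg)")
    tri$i <- c(tri$i, res$i + 1L)
    tri$j <- c(tri$j, res$j + 1L + nspots)
    tri$d <- c(tri$d, res$d)
    tri$l <- c(tri$l, res$l)
    tri$a <- c(tri$a, res$a)
    spot_tab[[fi]] <- data.frame(field = fi, angle = fld$angle,
                                 range_w = layers[slayer], v = sv, z = sz)
    nspots <- nspots + length(sv)
  }
  spots_df <- do.call(rbind, spot_tab)
  dims <- c(nvox, nspots)
  D <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$d, dims = dims)
  L <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$l, dims = dims)
  A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$a, dims = dims)
  # a spot must actually reach the PTV
  ptv_idx <- which(as.vector(ptv))
  if (sum(D[ptv_idx, , drop = FALSE]) == 0) {
    stop("no spot deposits dose in the PTV; check beam/energy-layer setup")
  }
  structure(list(D = D, L = L, A = A, spots = spots_df, ion = model$ion,
                 ripple_filter = model$ripple_filter, model = model,
                 shape = sh, spacing = phantom$spacing,
                 origin = phantom$origin),
            class = "influence_matrix")
}

#' Accumulate weighted-field dose, LET and radiosensitivity grids
#'
#' Mixed-field composition contract: the physical dose is linear in the spot
#' weights, `dose = D w`; dose-averaged LET and alpha/alpha_x are the
#' dose-weighted means of the contributing spots,
#' `let_d = (L w) / (D w)` and `alpha_ratio = (A w) / (D w)` where the dose
#' is positive (0 elsewhere). The beta/beta_x grid is identically 1
#' (constant-beta closure).
#'
#' @param matrix An [compute_influence()] result.
#' @param weights Non-negative spot weights, one per spot.
#' @return Object of class `field_grids` with arrays `dose` (Gy per
#'   fraction per unit weight scale), `let_d` (keV/um), `alpha_ratio`,
#'   `beta_ratio`.
#' @export
accumulate <- function(matrix, weights) {
  stopifnot(inherits(matrix, "influence_matrix"))
  if (length(weights) != ncol(matrix$D)) {
    stop("weights length (", length(weights), ") != number of spots (",
         ncol(matrix$D), ")")
  }
  if (any(weights < 0)) stop("spot weights must be non-negative")
  dose <- as.numeric(matrix$D %*% weights)
  lnum <- as.numeric(matrix$L %*% weights)
  anum <- as.numeric(matrix$A %*% weights)
  pos <- dose > 0
  let_d <- alpha <- numeric(length(dose))
  let_d[pos] <- lnum[pos] / dose[pos]
  alpha[pos] <- anum[pos] / dose[pos]
  beta <- as.numeric(pos)
  sh <- matrix$shape
  structure(list(dose = array(dose, sh), let_d = array(let_d, sh),
                 alpha_ratio = array(alpha, sh), beta_ratio = array(beta, sh)),
            class = "field_grids")
}

#' Serialize an influence matrix to a plain-text triplet bundle
#'
#' Writes `<stem>.triplets.csv` (columns i, j, d, l, a; 1-based voxel and
#' spot indices), `<stem>.spots.csv` and `<stem>.meta.json`.
#'
#' @param matrix An [compute_influence()] result.
#' @param stem Output path stem.
#' @return Invisibly, the vector of files written.
#' @export
write_influence <- function(matrix, stem) {
  ts <- Matrix::summary(matrix$D)
  tl <- Matrix::summary(matrix$L)
  ta <- Matrix::summary(matrix$A)
  trip <- data.frame(i = ts$i, j = ts$j, d = ts$x, l = tl$x, a = ta$x)
  f1 <- paste0(stem, ".triplets.csv")
  f2 <- paste0(stem, ".spots.csv")
  f3 <- paste0(stem, ".meta.json")
  utils::write.csv(trip, f1, row.names = FALSE)
  utils::write.csv(matrix$spots, f2, row.names = FALSE)
  jsonlite::write_json(list(ion = matrix$ion,
                            ripple_filter = matrix$ripple_filter,
                            shape = matrix$shape, spacing = matrix$spacing,
                            origin = matrix$origin,
                            nspots = ncol(matrix$D)),
                       f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
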