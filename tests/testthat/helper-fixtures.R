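# Shared fixtures and memoized heavy computations.

# Small, fast case for unit tests (anatomy scales with the grid).
small_case <- function(template = "D", seed = 3) {
  make_case(template, seed, shape = c(52, 52, 21))
}

# Uniform water phantom with a centered PTV and a single 0-degree field.
water_case <- function(shape = c(48, 40, 11), sigma0 = 3) {
  rsp <- array(1, dim = shape)
  grid <- phantom_grid(rsp, spacing = c(1, 1, 3))
  co <- grid_coords(grid)
  ptv <- (co$x^2 / 36 + co$y^2 / 25 + co$z^2 / 25) <= 1
  structures <- structure_set(list(ptv = ptv))
  beams <- structure(list(
    fields = list(list(angle = 0, isocenter = c(0, 0, 0),
                       spot_spacing = 4, sigma0 = sigma0)),
    energy_layer_spacing_mm = 2), class = "beam_config")
  list(grid = grid, structures = structures, beams = beams,
       prescription = list(dose_per_fraction = 1.8, n_fractions = 30))
}

# Hand-built influence object (1 voxel grid row space of `shape`) from dense
# matrices, for mixture-composition and optimizer oracles.
make_toy_influence <- function(D, let_per_spot, shape, ion = "proton",
                               abx = 3.7, lambda = 0.08) {
  nvox <- prod(shape)
  stopifnot(nrow(D) == nvox)
  L <- sweep(D, 2, let_per_spot, `*`)
  A <- sweep(D, 2, 1 + lambda * let_per_spot / abx, `*`)
  spots <- data.frame(field = 1L, angle = 0, range_w = 30,
                      v = seq_len(ncol(D)), z = 0)
  structure(list(D = Matrix::Matrix(D, sparse = TRUE),
                 L = Matrix::Matrix(L, sparse = TRUE),
                 A = Matrix::Matrix(A, sparse = TRUE),
                 spots = spots, ion = ion, ripple_filter = FALSE,
                 model = ion_beam_model(ion),
                 shape = shape, spacing = c(1, 1, 3),
                 origin = -(shape - 1) * c(1, 1, 3) / 2),
            class = "influence_matrix")
}

# Single-voxel-PTV structure set on a toy grid.
toy_structures <- function(shape, ptv_idx, oar_idx = NULL) {
  ptv <- array(FALSE, shape); ptv[ptv_idx] <- TRUE
  rois <- list(ptv = ptv)
  if (!is.null(oar_idx)) {
    oar <- array(FALSE, shape); oar[oar_idx] <- TRUE
    rois$oar <- oar
  }
  structure_set(rois)
}

# Memoized full-size two-stage pipeline results for the acceptance suite.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_case <- function(template, seed = 1) {
  key <- paste0("tpl_", template, "_", seed)
  if (!exists(key, envir = .acceptance_cache)) {
    case <- make_case(template, seed)
    res <- suppressWarnings(two_stage_compare(case))
    assign(key, res, envir = .acceptance_cache)
  }
  get(key, envir = .acceptance_cache)
}
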