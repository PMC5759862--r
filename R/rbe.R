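#' LET-dependent radiosensitivity ratio alpha/alpha_x
#'
#' Phenomenological linear-quadratic RBE model of the affine-in-LET class:
#' `alpha/alpha_x = intercept + lambda_ion * LET_d / (alpha_x/beta_x)`.
#' The slope is ion specific (`lambda_He > lambda_p > 0`, defaults 0.15 and
#' 0.08 Gy um/keV), so at equal dose-averaged LET the ratio is larger for
#' helium, and larger for more slowly responding tissue (smaller
#' alpha_x/beta_x). The beta term is left unchanged (`beta = beta_x`).
#'
#' @param let_d Dose-averaged LET, keV/um (>= 0; vectorized).
#' @param ion `"proton"` or `"helium"`.
#' @param abx Tissue alpha_x/beta_x ratio in Gy (> 0).
#' @param params Model coefficients, see [beam_defaults()] (`lambda` entry).
#' @param intercept Zero-LET ratio (default 1).
#' @return alpha/alpha_x, same length as `let_d`.
#' @export
alpha_ratio <- function(let_d, ion = c("proton", "helium"), abx,
                        params = beam_defaults(ion), intercept = 1) {
  ion <- match.arg(ion)
  if (any(let_d < 0)) stop("LET must be non-negative")
  if (any(abx <= 0)) stop("alpha_x/beta_x must be positive")
  intercept + params$lambda * let_d / abx
}

#' LQ iso-effect inversion: RBE-weighted dose from physical dose
#'
#' Per voxel, the RBE-weighted dose `D_RBE` solves the photon-equivalent
#' linear-quadratic effect equation
#' `alpha_x D_RBE + beta_x D_RBE^2 = (alpha/alpha_x) alpha_x d +
#' (beta/beta_x) beta_x d^2`, i.e. with `r = alpha_x/beta_x`:
#' `D_RBE = (-r + sqrt(r^2 + 4 r a d + 4 b d^2)) / 2`,
#' where `a = alpha/alpha_x`, `b = beta/beta_x`. Only the tissue
#' alpha_x/beta_x ratio is needed. `D_RBE = 0` where `d = 0`; RBE is
#' reported only at dosed voxels.
#'
#' @param d Physical dose per fraction, Gy (array or vector, >= 0).
#' @param alpha_ratio_grid alpha/alpha_x per voxel (same shape as `d`).
#' @param beta_ratio_grid beta/beta_x per voxel (default 1, constant-beta).
#' @param abx alpha_x/beta_x in Gy, scalar or per-voxel (> 0).
#' @return Object of class `biological_dose_grid` with `dose_rbe` (Gy(RBE))
#'   and `rbe` (0 at undosed voxels).
#' @export
rbe_weighted_dose <- function(d, alpha_ratio_grid, beta_ratio_grid = 1, abx) {
  if (any(abx <= 0)) stop("alpha_x/beta_x must be positive")
  if (any(d < 0)) stop("physical dose must be non-negative")
  a <- alpha_ratio_grid
  b <- beta_ratio_grid
  r <- abx
  dose_rbe <- (-r + sqrt(r^2 + 4 * r * a * d + 4 * b * d^2)) / 2
  dose_rbe[d == 0] <- 0
  rbe <- array(0, dim = if (is.array(d)) dim(d) else length(d))
  pos <- d > 0
  rbe[pos] <- dose_rbe[pos] / d[pos]
  if (is.array(d)) dose_rbe <- array(dose_rbe, dim(d))
  structure(list(dose_rbe = dose_rbe, rbe = rbe),
            class = "biological_dose_grid")
}

#' Fixed-RBE (1.1) biological dose for protons
#'
#' Clinical-practice proton weighting: `dose_rbe = 1.1 x d` everywhere.
#' Rejected for helium, for which only the variable model applies.
#'
#' @param d Physical dose per fraction, Gy.
#' @param ion Must be `"proton"`.
#' @return A `biological_dose_grid` with constant RBE 1.1 at dosed voxels.
#' @export
fixed_rbe_dose <- function(d, ion = "proton") {
  if (!identical(ion, "proton")) {
    stop("fixed RBE 1.1 applies to protons only; use the variable model for ",
         ion)
  }
  if (any(d < 0)) stop("physical dose must be non-negative")
  rbe <- array(0, dim = if (is.array(d)) dim(d) else length(d))
  rbe[d > 0] <- 1.1
  structure(list(dose_rbe = 1.1 * d, rbe = rbe),
            class = "biological_dose_grid")
}

#' Tumour-to-normal-tissue RBE ratio of two regions
#'
#' Ratio of the median per-voxel RBE inside the target region to the median
#' RBE inside a normal-tissue region, each restricted to voxels receiving at
#' least `min_dose` physical dose.
#'
#' @param rbe Per-voxel RBE array.
#' @param dose Per-voxel physical dose array.
#' @param target_mask,normal_mask Logical arrays.
#' @param min_dose Dose threshold, Gy (default 0.05).
#' @return Dimensionless ratio.
#' @export
rbe_region_ratio <- function(rbe, dose, target_mask, normal_mask,
                             min_dose = 0.05) {
  tsel <- target_mask & dose > min_dose
  nsel <- normal_mask & dose > min_dose
  if (!any(nsel)) stop("normal-tissue shell is empty (no dosed voxels)")
  if (!any(tsel)) stop("target region is empty (no dosed voxels)")
  stats::median(rbe[tsel]) / stats::median(rbe[nsel])
}

#' Proximal normal-tissue shell of a case
#'
#' Normal-tissue region upstream of the PTV: for each field, the voxels
#' inside the PTV's beam's-eye-view footprint (dilated by `dilate` mm) lying
#' between `gap` and `gap + thickness` mm proximal to the PTV's upstream
#' surface along the beam axis, restricted to the body and excluding the
#' PTV and all OARs. This is the low-LET entrance-channel tissue referenced
#' by the differential-RBE evaluation.
#'
#' @param grid A [phantom_grid()].
#' @param structures A [structure_set()].
#' @param beams Beam configuration.
#' @param gap Gap to the PTV surface along the beam axis, mm; keeps the
#'   shell clear of the proximal SOBP shoulder.
#' @param thickness Shell thickness along the beam axis, mm.
#' @param dilate Lateral dilation of the PTV footprint, mm.
#' @return Logical array.
#' @export
proximal_shell_mask <- function(grid, structures, beams, gap = 5,
                                thickness = 15, dilate = 2) {
  co <- grid_coords(grid)
  ptv <- structures$rois[[structures$ptv_name]]
  body <- grid$rsp > 0.5
  excl <- ptv
  for (nm in oar_names(structures)) excl <- excl | structures$rois[[nm]]
  shell <- array(FALSE, dim = grid$shape)
  for (fld in beams$fields) {
    ax <- .field_axes(fld$angle)
    iso <- fld$isocenter
    tcoord <- (co$x - iso[1]) * ax$u[1] + (co$y - iso[2]) * ax$u[2]
    vlat <- (co$x - iso[1]) * ax$v[1] + (co$y - iso[2]) * ax$v[2]
    zlat <- co$z - iso[3]
    pt <- tcoord[ptv]; pv <- vlat[ptv]; pz <- zlat[ptv]
    sel <- tcoord >= min(pt) - gap - thickness & tcoord <= min(pt) - gap &
      vlat >= min(pv) - dilate & vlat <= max(pv) + dilate &
      zlat >= min(pz) - dilate & zlat <= max(pz) + dilate
    shell <- shell | sel
  }
  shell & body & !excl
}

#' Differential RBE ratio of an optimized variable-RBE plan
#'
#' The tumour-to-normal-tissue RBE ratio of a plan: median RBE over the PTV
#' (alpha_x/beta_x 3.7 Gy, in-field LET and per-fraction dose) divided by
#' the median RBE over the proximal normal-tissue shell (alpha_x/beta_x
#' 2.0 Gy, its own LET and dose). Reported per ion; helium plans show a
#' larger ratio than proton plans, the differential effect favouring
#' normal-tissue sparing.
#'
#' @param plan An optimized plan from [optimize_plan()] (variable RBE mode).
#' @param case The case bundle the plan was optimized on ([make_case()]).
#' @param shell Optional logical array overriding [proximal_shell_mask()].
#' @param min_dose Dose threshold for voxel inclusion, Gy.
#' @return Dimensionless ratio.
#' @export
differential_rbe_ratio <- function(plan, case, shell = NULL, min_dose = 0.05) {
  stopifnot(inherits(plan, "ion_plan"))
  if (plan$rbe_mode != "variable") {
    stop("differential RBE ratio is defined for variable-RBE plans")
  }
  if (is.null(shell)) {
    shell <- proximal_shell_mask(case$grid, case$structures, case$beams)
  }
  ptv <- case$structures$rois[[case$structures$ptv_name]]
  rbe_region_ratio(plan$rbe, plan$grids$dose, ptv, shell, min_dose)
}
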