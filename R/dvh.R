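DX_LEVELS <- c(5, 10, 20, 33, 50, 66, 75, 95)

#' Cumulative dose-volume histogram of an ROI
#'
#' Volume fraction of the masked region receiving at least each dose level,
#' on uniform dose bins. Voxel volumes are uniform, so voxel counting
#' suffices. The raw voxel doses are retained on the returned object so
#' that Dx parameters can be extracted at full (sorted-voxel) resolution.
#'
#' @param dose_grid Dose array, Gy(RBE).
#' @param mask Logical array of the same shape (non-empty).
#' @param bin_width Dose bin width, Gy(RBE) (default 0.05).
#' @param roi ROI name carried on the curve.
#' @return Object of class `dvh_curve` with `dose_axis`, `volume_fraction`,
#'   `doses` (raw voxel doses) and `roi`.
#' @export
compute_dvh <- function(dose_grid, mask, bin_width = 0.05, roi = "roi") {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!any(mask)) stop("empty ROI mask")
  doses <- dose_grid[mask]
  dmax <- max(doses)
  axis <- seq(0, dmax + bin_width, by = bin_width)
  vf <- vapply(axis, function(d) mean(doses >= d), numeric(1))
  structure(list(roi = roi, dose_axis = axis, volume_fraction = vf,
                 doses = doses), class = "dvh_curve")
}

#' Dx from raw voxel doses
#'
#' Minimum dose received by the hottest x\% of the volume, computed as a
#' sorted-voxel quantile with linear interpolation between voxel ranks: the
#' value at rank position `n (100 - x)/100 + 1` of the ascending-sorted
#' doses (clamped to `[1, n]`), interpolating linearly at fractional ranks.
#'
#' @param doses Numeric vector of voxel doses.
#' @param x Percentage in (0, 100).
#' @return Dose in the input's units (vectorized over `x`).
#' @export
dx_values <- function(doses, x) {
  if (any(x <= 0 | x >= 100)) stop("x must be strictly between 0 and 100")
  if (!length(doses)) stop("empty dose vector")
  n <- length(doses)
  s <- sort(doses)
  vapply(x, function(xx) {
    pos <- min(max(n * (100 - xx) / 100 + 1, 1), n)
    lo <- floor(pos); hi <- ceiling(pos)
    s[lo] + (pos - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

#' Dx parameter of a DVH curve
#'
#' @param dvh A [compute_dvh()] curve.
#' @param x Percentage in (0, 100) (e.g. 5 for D5, 95 for D95).
#' @return Dose in Gy(RBE).
#' @export
dx <- function(dvh, x) {
  stopifnot(inherits(dvh, "dvh_curve"))
  dx_values(dvh$doses, x)
}

#' Full-treatment Dx table of a plan
#'
#' Dx parameters (D5, D10, D20, D33, D50, D66, D75, D95) per ROI at the
#' full treatment dose, i.e. the per-fraction biological dose grid scaled
#' by the number of fractions.
#'
#' @param plan An [optimize_plan()] result (with biological dose grid).
#' @param structures A [structure_set()].
#' @param prescription A prescription (list with `n_fractions`).
#' @return Object of class `dx_table`: data frame with `roi` and one column
#'   per Dx level, Gy(RBE).
#' @export
full_treatment_table <- function(plan, structures, prescription) {
  if (is.null(plan$bio)) stop("plan has no biological dose grid")
  nf <- prescription$n_fractions
  rows <- lapply(names(structures$rois), function(nm) {
    v <- plan$bio[structures$rois[[nm]]] * nf
    as.list(stats::setNames(dx_values(v, DX_LEVELS),
                            paste0("D", DX_LEVELS)))
  })
  out <- cbind(data.frame(roi = names(structures$rois),
                          stringsAsFactors = FALSE),
               do.call(rbind, lapply(rows, as.data.frame)))
  class(out) <- c("dx_table", "data.frame")
  out
}

#' Difference of two Dx tables
#'
#' Elementwise `A - B` (first-named plan minus second), per ROI and Dx
#' level, Gy(RBE).
#'
#' @param table_a,table_b [full_treatment_table()] results over the same
#'   ROI set and Dx levels.
#' @return A `dx_table` of differences.
#' @export
dvh_difference_table <- function(table_a, table_b) {
  if (!identical(table_a$roi, table_b$roi) ||
      !identical(names(table_a), names(table_b))) {
    stop("Dx tables have mismatched ROI sets or Dx levels")
  }
  out <- table_a
  num <- setdiff(names(out), "roi")
  out[num] <- table_a[num] - table_b[num]
  out
}

#' Nested dose-level masks
#'
#' Boolean masks of the voxels above 10, 20, 50, 80, 95 and 107 percent of
#' the total prescribed dose; higher-level masks nest inside lower-level
#' ones.
#'
#' @param dose_grid Total-treatment dose array, Gy(RBE).
#' @param prescription_total Total prescribed dose, Gy(RBE) (> 0).
#' @param levels_pct Percent thresholds (default the six standard levels).
#' @return Named list of logical arrays (`">10%"`, ...).
#' @export
dose_level_masks <- function(dose_grid, prescription_total,
                             levels_pct = c(10, 20, 50, 80, 95, 107)) {
  if (prescription_total <= 0) stop("prescription_total must be positive")
  out <- lapply(levels_pct, function(p) dose_grid > p / 100 * prescription_total)
  names(out) <- paste0(">", levels_pct, "%")
  out
}

#' Dose-difference overdose maps between two plans
#'
#' Two labeled threshold maps of where each plan overdoses the other:
#' `a_minus_b` thresholds `max(0, A - B)` at 3, 6, 9, 12, 15 and 18 Gy(RBE)
#' (and `b_minus_a` likewise); their supports are disjoint.
#'
#' @param dose_a,dose_b Total-treatment dose arrays on the same grid.
#' @param levels Threshold levels in Gy(RBE).
#' @return List of two named lists of logical arrays.
#' @export
dose_difference_map <- function(dose_a, dose_b,
                                levels = c(3, 6, 9, 12, 15, 18)) {
  if (!identical(dim(dose_a), dim(dose_b))) stop("dose grids have different shapes")
  dif <- dose_a - dose_b
  thr <- function(d) {
    out <- lapply(levels, function(l) d > l)
    names(out) <- paste0(">", levels, "Gy(RBE)")
    out
  }
  list(a_minus_b = thr(pmax(dif, 0) * (dif > 0)),
       b_minus_a = thr(pmax(-dif, 0) * (dif < 0)))
}

#' Write a Dx table to CSV (round-trip exact)
#'
#' Numbers are serialized with 17 significant digits so that reading the
#' file back reproduces the doubles bit-exactly.
#'
#' @param table A `dx_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dx_table <- function(table, path) {
  out <- table
  num <- setdiff(names(out), "roi")
  for (nm in num) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a Dx table written by [write_dx_table()]
#' @param path CSV path.
#' @return A `dx_table`.
#' @export
read_dx_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(out), "roi")) out[[nm]] <- as.numeric(out[[nm]])
  class(out) <- c("dx_table", "data.frame")
  out
}

#' Render a difference table for visual inspection
#'
#' One-decimal formatting with a configurable decimal mark (comma matches
#' European-style table formatting).
#'
#' @param table A `dx_table` (typically of differences).
#' @param dec Decimal mark, `","` or `"."`.
#' @return Data frame of character columns.
#' @export
render_diff_table <- function(table, dec = ",") {
  out <- table
  for (nm in setdiff(names(out), "roi")) {
    out[[nm]] <- formatC(round(out[[nm]], 1), format = "f", digits = 1,
                         decimal.mark = dec)
  }
  out
}

#' Plot DVH curves per ROI for a set of plans
#'
#' One panel per ROI with the cumulative DVH of each plan at full treatment
#' dose (proton fixed RBE dotted, proton variable dashed, helium solid).
#'
#' @param plans Named list of plans.
#' @param structures A [structure_set()].
#' @param prescription Prescription (for the fraction number).
#' @param file Output PDF path.
#' @return Invisibly, `file`.
#' @export
plot_dvh_panel <- function(plans, structures, prescription, file) {
  nf <- prescription$n_fractions
  ltys <- c(3, 2, 1)[seq_along(plans)]
  rois <- names(structures$rois)
  grDevices::pdf(file, width = 8, height = 2.5 * ceiling(length(rois) / 2))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(length(rois) / 2), 2), mar = c(4, 4, 2, 1))
  for (nm in rois) {
    first <- TRUE
    for (k in seq_along(plans)) {
      cv <- compute_dvh(plans[[k]]$bio * nf, structures$rois[[nm]], roi = nm)
      if (first) {
        graphics::plot(cv$dose_axis, 100 * cv$volume_fraction, type = "l",
                       lty = ltys[k], xlab = "Dose [Gy(RBE)]",
                       ylab = "Volume [%]", main = nm, ylim = c(0, 100))
        first <- FALSE
      } else {
        graphics::lines(cv$dose_axis, 100 * cv$volume_fraction, lty = ltys[k])
      }
    }
    graphics::legend("topright", legend = names(plans), lty = ltys,
                     cex = 0.7, bty = "n")
  }
  invisible(file)
}
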