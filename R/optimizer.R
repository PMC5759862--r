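#' Planning constraints
#'
#' Constraint scheme used by the spot-weight optimizer: the PTV should
#' receive the prescribed biological dose per fraction, its D5 must not
#' exceed `ptv_max_pct` percent of the prescription, each OAR carries a
#' hard-ish cap on its D5 (hottest-5\%) dose, and an additional low-dose
#' term with a smaller weight shrinks the OAR volume receiving any dose.
#'
#' @param prescription_fx Prescribed biological dose per fraction, Gy(RBE)
#'   (default 1.8).
#' @param ptv_max_pct Hot-spot cap for D5 of the PTV, percent of the
#'   prescription (default 107, must be >= 100).
#' @param oar_d5_caps Named numeric vector: per-OAR D5 cap, Gy(RBE) per
#'   fraction.
#' @param term_weights Named list of positive penalty weights: `ptv_dev`,
#'   `ptv_over`, `oar_d5`, `oar_low`. The low-dose weight must be smaller
#'   than the D5-cap weight.
#' @return Object of class `plan_constraints`.
#' @export
plan_constraints <- function(prescription_fx = 1.8, ptv_max_pct = 107,
                             oar_d5_caps = numeric(),
                             term_weights = list(ptv_dev = 100,
                                                 ptv_over = 1000,
                                                 oar_d5 = 50,
                                                 oar_low = 1)) {
  if (prescription_fx <= 0) stop("prescription must be positive")
  if (ptv_max_pct < 100) stop("ptv_max_pct must be >= 100")
  w <- term_weights
  if (any(unlist(w) <= 0)) stop("all term weights must be positive")
  if (w$oar_low >= w$oar_d5) {
    stop("low-dose weight must be smaller than the D5-cap weight")
  }
  structure(list(prescription_fx = prescription_fx, ptv_max_pct = ptv_max_pct,
                 oar_d5_caps = oar_d5_caps, term_weights = w),
            class = "plan_constraints")
}

#' Default constraints for a case
#'
#' Initial stage-1 constraint set: prescription from the case, 107\% PTV
#' hot-spot cap, and a uniform initial OAR D5 cap of `oar_cap_frac` of the
#' per-fraction prescription for every OAR (the achieved values, not these
#' starting caps, are what stage 2 inherits).
#'
#' @param case A [make_case()] bundle.
#' @param oar_cap_frac Initial OAR D5 cap as a fraction of the prescription.
#' @return A [plan_constraints()] object.
#' @export
default_constraints <- function(case, oar_cap_frac = 0.56) {
  p <- case$prescription$dose_per_fraction
  oars <- oar_names(case$structures)
  plan_constraints(
    prescription_fx = p,
    oar_d5_caps = stats::setNames(rep(oar_cap_frac * p, length(oars)), oars))
}

# Optimization context: ROI-row submatrices and index bookkeeping.
.opt_context <- function(matrix, structures, constraints) {
  sh <- matrix$shape
  ptv <- as.vector(structures$rois[[structures$ptv_name]])
  oars <- oar_names(structures)
  # PTV-priority in declared overlap regions: OAR penalty terms act on the
  # OAR voxels outside the PTV (the prescription governs the shared voxels)
  masks <- lapply(oars, function(nm)
    as.vector(structures$rois[[nm]]) & !ptv)
  names(masks) <- oars
  rows <- sort(unique(c(which(ptv), unlist(lapply(masks, which)))))
  sub <- function(M) M[rows, , drop = FALSE]
  pos <- match(seq_len(prod(sh)), rows)
  abx <- rep(2.0, length(rows))
  for (nm in oars) abx[stats::na.omit(pos[which(masks[[nm]])])] <-
    structures$tissue[[nm]]
  abx[stats::na.omit(pos[which(ptv)])] <-
    structures$tissue[[structures$ptv_name]]
  list(rows = rows,
       Ds = sub(matrix$D), Ls = sub(matrix$L), As = sub(matrix$A),
       ptv_idx = stats::na.omit(pos[which(ptv)]),
       oar_idx = lapply(masks, function(m) stats::na.omit(pos[which(m)])),
       abx = abx, ion = matrix$ion)
}

# Per-voxel effective RBE (on context rows) for the current weights.
.effective_rbe <- function(ctx, w, rbe_mode) {
  phys <- as.numeric(ctx$Ds %*% w)
  if (rbe_mode == "fixed_1p1") {
    return(list(phys = phys, r = rep(1.1, length(phys))))
  }
  anum <- as.numeric(ctx$As %*% w)
  r <- rep(1, length(phys))
  pos <- phys > 0
  a <- rep(1, length(phys))
  a[pos] <- anum[pos] / phys[pos]
  bio <- rbe_weighted_dose(phys, a, 1, ctx$abx)
  r[pos] <- bio$dose_rbe[pos] / phys[pos]
  list(phys = phys, r = r, a = a)
}

# Hottest-5% voxel index sets (the smooth D5 surrogate support), per OAR.
.hot_sets <- function(bio, ctx) {
  lapply(ctx$oar_idx, function(idx) {
    n <- length(idx)
    if (!n) return(integer())
    k <- max(1L, ceiling(0.05 * n))
    idx[order(bio[idx], decreasing = TRUE)[seq_len(k)]]
  })
}

# Smooth objective/gradient for frozen per-voxel rbe `r` and hot sets.
.smooth_objective <- function(ctx, cons, r, hot) {
  p <- cons$prescription_fx
  pmax_ <- cons$ptv_max_pct / 100 * p
  wts <- cons$term_weights
  nptv <- length(ctx$ptv_idx)
  list(
    fn = function(w) {
      bio <- r * as.numeric(ctx$Ds %*% w)
      f <- wts$ptv_dev * mean((bio[ctx$ptv_idx] - p)^2) +
        wts$ptv_over * mean(pmax(bio[ctx$ptv_idx] - pmax_, 0)^2)
      for (nm in names(ctx$oar_idx)) {
        idx <- ctx$oar_idx[[nm]]
        if (!length(idx)) next
        cap <- cons$oar_d5_caps[[nm]]
        h <- hot[[nm]]
        if (length(h)) f <- f + wts$oar_d5 * mean(pmax(bio[h] - cap, 0)^2)
        f <- f + wts$oar_low * mean(bio[idx]^2)
      }
      f
    },
    gr = function(w) {
      bio <- r * as.numeric(ctx$Ds %*% w)
      g <- numeric(length(bio))
      g[ctx$ptv_idx] <- g[ctx$ptv_idx] +
        wts$ptv_dev * 2 * (bio[ctx$ptv_idx] - p) / nptv +
        wts$ptv_over * 2 * pmax(bio[ctx$ptv_idx] - pmax_, 0) / nptv
      for (nm in names(ctx$oar_idx)) {
        idx <- ctx$oar_idx[[nm]]
        if (!length(idx)) next
        cap <- cons$oar_d5_caps[[nm]]
        h <- hot[[nm]]
        if (length(h)) g[h] <- g[h] +
            wts$oar_d5 * 2 * pmax(bio[h] - cap, 0) / length(h)
        g[idx] <- g[idx] + wts$oar_low * 2 * bio[idx] / length(idx)
      }
      as.numeric(Matrix::crossprod(ctx$Ds, r * g))
    }
  )
}

#' Constraint objective of a weight vector
#'
#' The scalar planning objective: a sum of quadratic penalties on the
#' per-fraction biological dose — PTV deviation from the prescription, PTV
#' overdose above the hot-spot cap, per-OAR overdose of the hottest-5\%
#' voxels above the D5 cap, and a low-dose term over each whole OAR with its
#' smaller weight. All terms are means over their voxel sets; the hottest-5\%
#' sets are recomputed for the given weights. Zero iff every term is
#' satisfied exactly.
#'
#' @param weights Non-negative spot weights.
#' @param matrix An [compute_influence()] result.
#' @param structures A [structure_set()].
#' @param constraints A [plan_constraints()].
#' @param rbe_mode `"fixed_1p1"` (protons) or `"variable"`.
#' @return Scalar objective value (>= 0).
#' @export
objective <- function(weights, matrix, structures, constraints,
                      rbe_mode = c("fixed_1p1", "variable")) {
  rbe_mode <- match.arg(rbe_mode)
  if (length(weights) != ncol(matrix$D)) {
    stop("weights length (", length(weights), ") != number of spots (",
         ncol(matrix$D), ")")
  }
  if (rbe_mode == "fixed_1p1" && matrix$ion != "proton") {
    stop("fixed RBE 1.1 applies to protons only")
  }
  ctx <- .opt_context(matrix, structures, constraints)
  .objective_ctx(weights, ctx, constraints, rbe_mode)
}

.objective_ctx <- function(weights, ctx, constraints, rbe_mode) {
  er <- .effective_rbe(ctx, weights, rbe_mode)
  bio <- er$r * er$phys
  hot <- .hot_sets(bio, ctx)
  .smooth_objective(ctx, constraints, er$r, hot)$fn(weights)
}

#' Optimize spot weights for a plan
#'
#' Projected bound-constrained quasi-Newton optimization (L-BFGS-B, weights
#' bounded below by 0) of the planning [objective()]. Outer iterations
#' freeze the per-voxel effective RBE (for variable-RBE plans, recomputed
#' from the current weights) and the hottest-5\% OAR voxel sets, then solve
#' the resulting smooth quadratic subproblem; steps are accepted while the
#' true objective is non-increasing. The fixed-RBE subproblem is convex.
#' Initialization is deterministic: uniform weights scaled to match the
#' prescription at the PTV's central voxel (or a supplied warm start).
#'
#' @inheritParams objective
#' @param options List: `max_outer` (default 12), `maxit_inner` (300),
#'   `pgtol` (1e-6), `w_init` (optional warm-start weight vector).
#' @return Object of class `ion_plan`: weights, per-fraction `grids`
#'   ([accumulate()] result), biological dose `bio` and per-voxel `rbe`
#'   arrays, `objective_trace`, `achieved_d5` per OAR (per fraction,
#'   Gy(RBE)), and a `converged` flag.
#' @export
optimize_plan <- function(matrix, structures, constraints,
                          rbe_mode = c("fixed_1p1", "variable"),
                          options = list()) {
  rbe_mode <- match.arg(rbe_mode)
  if (rbe_mode == "fixed_1p1" && matrix$ion != "proton") {
    stop("fixed RBE 1.1 applies to protons only")
  }
  opts <- utils::modifyList(list(max_outer = 20, maxit_inner = 300,
                                 pgtol = 1e-6, w_init = NULL), options)
  ctx <- .opt_context(matrix, structures, constraints)
  cons <- constraints
  nspot <- ncol(matrix$D)

  if (is.null(opts$w_init)) {
    # uniform weights scaled so the PTV's central voxel gets the prescription
    co <- expand.grid(seq_len(matrix$shape[1]), seq_len(matrix$shape[2]),
                      seq_len(matrix$shape[3]))
    ptvv <- as.vector(structures$rois[[structures$ptv_name]])
    cen <- colMeans(co[ptvv, ])
    d2 <- rowSums(sweep(co[ptvv, ], 2, cen)^2)
    vcen <- which(ptvv)[which.min(d2)]
    icen <- match(vcen, ctx$rows)
    rowsum_cen <- sum(ctx$Ds[icen, ])
    r0 <- if (rbe_mode == "fixed_1p1") 1.1 else
      if (matrix$ion == "helium") 1.3 else 1.1
    w <- rep(cons$prescription_fx / (r0 * rowsum_cen), nspot)
  } else {
    stopifnot(length(opts$w_init) == nspot)
    w <- pmax(opts$w_init, 0)
  }

  trace <- .objective_ctx(w, ctx, cons, rbe_mode)
  converged <- FALSE
  r_prev <- NULL
  for (it in seq_len(opts$max_outer)) {
    er <- .effective_rbe(ctx, w, rbe_mode)
    # damp the RBE refresh to stabilise the variable-RBE fixed point
    r_it <- if (is.null(r_prev) || rbe_mode == "fixed_1p1") er$r else
      0.5 * er$r + 0.5 * r_prev
    r_prev <- r_it
    hot <- .hot_sets(r_it * er$phys, ctx)
    sm <- .smooth_objective(ctx, cons, r_it, hot)
    fit <- stats::optim(w, sm$fn, sm$gr, method = "L-BFGS-B",
                        lower = 0,
                        control = list(maxit = opts$maxit_inner,
                                       factr = 1e4, pgtol = opts$pgtol))
    w_new <- pmax(fit$par, 0)   # clamp L-BFGS-B rounding below the bound
    f_new <- .objective_ctx(w_new, ctx, cons, rbe_mode)
    if (f_new > utils::tail(trace, 1) + 1e-12) break  # reject, keep previous
    rel_change <- max(abs(w_new - w)) / max(max(abs(w)), 1e-12)
    w <- w_new
    trace <- c(trace, f_new)
    if (rel_change < 1e-5) { converged <- TRUE; break }
    if (it == opts$max_outer) converged <- TRUE
  }
  if (!converged) {
    warning("optimizer stopped before weight stabilization; plan flagged")
  }

  grids <- accumulate(matrix, w)
  abx_grid <- array(2.0, dim = matrix$shape)
  for (nm in oar_names(structures)) abx_grid[structures$rois[[nm]]] <-
    structures$tissue[[nm]]
  ptvm <- structures$rois[[structures$ptv_name]]
  abx_grid[ptvm] <- structures$tissue[[structures$ptv_name]]
  bio <- if (rbe_mode == "fixed_1p1") {
    fixed_rbe_dose(grids$dose, "proton")
  } else {
    rbe_weighted_dose(grids$dose, grids$alpha_ratio, grids$beta_ratio,
                      abx_grid)
  }
  # achieved D5 on the penalized (outside-PTV) part of each OAR, so frozen
  # stage-2 caps are consistent with the optimized quantity
  achieved <- vapply(oar_names(structures), function(nm) {
    m <- structures$rois[[nm]] & !ptvm
    if (!any(m)) m <- structures$rois[[nm]]
    if (!any(m)) return(NA_real_)   # ROI empty on this grid
    dx_values(bio$dose_rbe[m], 5)
  }, numeric(1))

  structure(list(ion = matrix$ion, rbe_mode = rbe_mode, weights = w,
                 grids = grids, bio = bio$dose_rbe, rbe = bio$rbe,
                 objective_trace = trace, converged = converged,
                 constraints = cons, achieved_d5 = achieved,
                 spots = matrix$spots, shape = matrix$shape),
            class = "ion_plan")
}

#' Two-stage proton/helium plan comparison workflow
#'
#' Stage 1 optimizes a fixed-RBE (1.1) proton plan under the initial
#' constraints and freezes the achieved per-OAR D5 values (plus an optional
#' margin) as the caps. Stage 2 re-optimizes under those identical caps with
#' the variable RBE model for both protons (warm-started from stage 1) and
#' helium ions (ripple filter on by default). If a stage-2 plan exceeds a
#' frozen cap by more than 5\%, that cap is relaxed in multiplicative 5\%
#' steps (at most 3) and the optimization repeated; any relaxation is
#' recorded in the returned cap provenance.
#'
#' @param case A [make_case()] bundle.
#' @param constraints Optional initial [plan_constraints()]; defaults to
#'   [default_constraints()].
#' @param margin Additive margin (Gy(RBE)/fraction) on the frozen caps.
#' @param cap_floor Lower bound on the frozen caps as a fraction of the
#'   per-fraction prescription (default 0.15): an OAR the stage-1 proton
#'   plan happens to leave nearly undosed still receives a clinically
#'   meaningful (tolerance-level) cap rather than an accidental ~0 one.
#' @param ripple_helium Use the ripple filter for the helium plan.
#' @param options Optimizer options, see [optimize_plan()].
#' @return List with `proton_fixed`, `proton_variable`, `helium_variable`
#'   plans, the frozen `caps`, `cap_provenance`, and the input `case`.
#' @export
two_stage_compare <- function(case, constraints = NULL, margin = 0,
                              cap_floor = 0.15, ripple_helium = TRUE,
                              options = list()) {
  if (is.null(constraints)) constraints <- default_constraints(case)
  model_p <- ion_beam_model("proton", ripple_filter = FALSE)
  infl_p <- compute_influence(case$grid, case$structures, case$beams, model_p)
  stage1 <- optimize_plan(infl_p, case$structures, constraints, "fixed_1p1",
                          options)

  caps <- pmax(stage1$achieved_d5 + margin,
               cap_floor * constraints$prescription_fx)
  caps[is.na(caps)] <- cap_floor * constraints$prescription_fx
  cons2 <- constraints
  cons2$oar_d5_caps <- caps
  provenance <- list(stage1_achieved_d5 = stage1$achieved_d5,
                     margin = margin, relaxations = list())

  run_stage2 <- function(infl, w_init, label) {
    cons <- cons2
    for (round in 0:3) {
      plan <- optimize_plan(infl, case$structures, cons, "variable",
                            utils::modifyList(options,
                                              list(w_init = w_init)))
      over <- plan$achieved_d5 > cons$oar_d5_caps * 1.05
      if (!any(over) || round == 3) {
        if (any(over)) warning(label, ": caps still exceeded after relaxation")
        return(list(plan = plan, caps = cons$oar_d5_caps))
      }
      cons$oar_d5_caps[over] <- cons$oar_d5_caps[over] * 1.05
      provenance$relaxations[[length(provenance$relaxations) + 1]] <<-
        list(plan = label, round = round + 1,
             relaxed = names(which(over)))
    }
  }

  s2p <- run_stage2(infl_p, stage1$weights, "proton_variable")
  rm(infl_p)
  model_he <- ion_beam_model("helium", ripple_filter = ripple_helium)
  infl_he <- compute_influence(case$grid, case$structures, case$beams,
                               model_he)
  s2he <- run_stage2(infl_he, NULL, "helium_variable")
  rm(infl_he)

  list(proton_fixed = stage1, proton_variable = s2p$plan,
       helium_variable = s2he$plan, caps = caps,
       cap_provenance = provenance, case = case)
}
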