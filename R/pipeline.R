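#' Write a volume array as NIfTI
#'
#' @param vol Numeric or logical 3-D array.
#' @param path Output path (`.nii.gz`).
#' @param spacing Voxel spacing in mm.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 3)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                         pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path NIfTI path.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a plan's spot list as CSV
#'
#' One record per spot: field, energy-layer range, lateral x (beam's-eye
#' v), lateral y (z), weight.
#'
#' @param plan An [optimize_plan()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spot_list <- function(plan, path) {
  out <- data.frame(field = plan$spots$field, range_w = plan$spots$range_w,
                    x = plan$spots$v, y = plan$spots$z,
                    weight = plan$weights)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.default_config <- function() {
  list(template = "A", seed = 1, shape = c(64, 64, 40),
       spacing = c(1, 1, 3), rsp_noise = 0.02, bone_shell = FALSE,
       ripple_helium = TRUE, margin = 0, oar_cap_frac = 0.56,
       out_dir = "ionplan_out", write_volumes = TRUE, plot = TRUE,
       optimizer = list())
}

#' Validate and complete a run configuration
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults; unknown keys are rejected with the offending key named.
#' @return Completed configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(def, config)
}

#' Run the full case pipeline
#'
#' End-to-end orchestration: generates the phantom case, builds influence
#' matrices, runs the two-stage optimization (fixed-RBE proton constraint
#' derivation, then variable-RBE proton and helium plans under identical
#' caps), and writes phantom volumes, three spot lists, per-plan Dx tables,
#' the three difference tables (He - p_fixed, He - p_var, p_var - p_fixed),
#' dose-level masks, dose-difference maps, a DVH plot and a machine-readable
#' JSON manifest (which also records the constraint-cap provenance and
#' constraint-satisfaction flags). A copy of the run configuration is
#' written next to the outputs.
#'
#' @param config See [run_config()].
#' @return Invisibly, the manifest list (`files`, `total_prescription_gyrbe`,
#'   `constraints_satisfied`, ...).
#' @export
run_case <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, paste0(...))
  files <- character()
  add <- function(f) files <<- c(files, basename(f))

  case <- make_case(cfg$template, cfg$seed, shape = cfg$shape,
                    spacing = cfg$spacing, rsp_noise = cfg$rsp_noise,
                    bone_shell = cfg$bone_shell)
  cons <- default_constraints(case, oar_cap_frac = cfg$oar_cap_frac)
  res <- two_stage_compare(case, constraints = cons, margin = cfg$margin,
                           ripple_helium = cfg$ripple_helium,
                           options = cfg$optimizer)
  plans <- list(proton_fixed = res$proton_fixed,
                proton_variable = res$proton_variable,
                helium_variable = res$helium_variable)
  presc <- case$prescription
  total_presc <- presc$dose_per_fraction * presc$n_fractions

  yaml::write_yaml(cfg, out("config.yaml")); add(out("config.yaml"))
  if (cfg$write_volumes) {
    add(write_volume(case$grid$rsp, out("rsp.nii.gz"), cfg$spacing))
    for (nm in names(case$structures$rois)) {
      add(write_volume(case$structures$rois[[nm]],
                       out("mask_", nm, ".nii.gz"), cfg$spacing))
    }
  }
  tabs <- list()
  for (nm in names(plans)) {
    add(write_spot_list(plans[[nm]], out("plan_", nm, ".csv")))
    tabs[[nm]] <- full_treatment_table(plans[[nm]], case$structures, presc)
    add(write_dx_table(tabs[[nm]], out("dx_", nm, ".csv")))
  }
  diffs <- list(
    he_minus_p_fixed = dvh_difference_table(tabs$helium_variable,
                                            tabs$proton_fixed),
    he_minus_p_var = dvh_difference_table(tabs$helium_variable,
                                          tabs$proton_variable),
    p_var_minus_p_fixed = dvh_difference_table(tabs$proton_variable,
                                               tabs$proton_fixed))
  for (nm in names(diffs)) add(write_dx_table(diffs[[nm]],
                                              out("diff_", nm, ".csv")))
  if (cfg$write_volumes) {
    for (nm in names(plans)) {
      masks <- dose_level_masks(plans[[nm]]$bio * presc$n_fractions,
                                total_presc)
      lab <- Reduce(`+`, masks)      # label volume: count of levels exceeded
      add(write_volume(lab, out("levels_", nm, ".nii.gz"), cfg$spacing))
    }
    dmap <- dose_difference_map(plans$helium_variable$bio * presc$n_fractions,
                                plans$proton_variable$bio * presc$n_fractions)
    add(write_volume(Reduce(`+`, dmap$a_minus_b),
                     out("overdose_he_minus_p.nii.gz"), cfg$spacing))
    add(write_volume(Reduce(`+`, dmap$b_minus_a),
                     out("overdose_p_minus_he.nii.gz"), cfg$spacing))
  }
  if (cfg$plot) {
    add(plot_dvh_panel(plans, case$structures, presc, out("dvh.pdf")))
  }

  d5_ptv_pct <- 100 * dx_values(
    plans$proton_fixed$bio[case$structures$rois$ptv] * presc$n_fractions, 5) /
    total_presc
  satisfied <- d5_ptv_pct <= cons$ptv_max_pct
  manifest <- list(
    package_version = as.character(utils::packageVersion("ionplan")),
    template = cfg$template, seed = cfg$seed,
    dose_per_fraction_gyrbe = presc$dose_per_fraction,
    n_fractions = presc$n_fractions,
    total_prescription_gyrbe = total_presc,
    frozen_caps_gyrbe_per_fx = as.list(res$caps),
    cap_provenance = res$cap_provenance,
    d5_ptv_pct_proton_fixed = d5_ptv_pct,
    constraints_satisfied = satisfied,
    files = c(files, "manifest.json"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic small fixtures for tests
#'
#' Constructs, in a few seconds, (i) a 100-voxel dose vector with
#' analytically known Dx values, (ii) a 2-spot/2-voxel toy influence system
#' with a closed-form optimal weight vector, and (iii) a small template-D
#' case on a reduced grid. Bit-identical for a given seed.
#'
#' @param seed Integer seed.
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  dvh_doses <- sample(1:100)          # permuted 1..100 Gy; D5 = 96, D50 = 51
  toy <- list(
    D = matrix(c(1, 0.2, 0.2, 1), 2, 2),   # voxel x spot dose per weight
    prescription = 1.8)
  # closed form: D w = p * 1/1.1  =>  w = solve(D) p/1.1
  toy$w_star <- solve(toy$D, rep(toy$prescription / 1.1, 2))
  small_case <- make_case("D", seed, shape = c(41, 41, 17))
  list(dvh_doses = dvh_doses, toy = toy, small_case = small_case)
}
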