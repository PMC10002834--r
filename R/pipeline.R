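#' Study configuration
#'
#' Bundles every knob of the desk-scale study: geometry, meshing, operating
#' points, solver, dye, endpoint and statistics settings.  Defaults mirror
#' the bench protocol (CO sweep 3-11 L/min, 60/40 caval split, calibrated
#' outlet resistances, CGS fluid properties) at a mesh resolution that runs
#' on one CPU in minutes.
#'
#' @param models character vector of model ids among `"blank"`, `"vip109"`,
#'   `"vip162"` (blade heights 1.09 / 1.62 mm).
#' @param CO_values cardiac outputs to sweep (L/min).
#' @param target_h mesh size (cm).
#' @param dim 3 (tetrahedral junction) or 2 (planar cross-channel analog).
#' @param ivc_fraction IVC share of CO.
#' @param R_rpa,R_lpa outlet resistances (dyn.s/cm^5).
#' @param dye_edge dye cube edge (cm).
#' @param dye_kappa dye diffusivity (cm^2/s).
#' @param dye_dt,dye_t_end scalar transport step and horizon (s).
#' @param wss_threshold low-WSS cutoff (dyn/cm^2).
#' @param cut_offset cut-plane distance from the junction center (cm).
#' @param stats_bias,stats_noise_sd,seed synthetic measurement parameters.
#' @param steady_max_steps pseudo-transient step cap.
#' @param output_dir optional artifact directory (NULL = keep in memory).
#' @return A `run_config` list.
#' @export
run_config <- function(models = c("blank", "vip162"),
                       CO_values = c(3, 5, 7, 9, 11),
                       target_h = 0.3, dim = 3L,
                       ivc_fraction = 0.6,
                       R_rpa = 204.51, R_lpa = 222.49,
                       dye_edge = 3.5, dye_kappa = 1e-4,
                       dye_dt = 0.02, dye_t_end = 5,
                       wss_threshold = 5, cut_offset = 4,
                       stats_bias = 0.23, stats_noise_sd = 0.25,
                       seed = 1L, steady_max_steps = 60L,
                       output_dir = NULL) {
  if (!length(CO_values)) stop("run_config: CO list must be non-empty")
  if (any(CO_values <= 0)) stop("run_config: all CO values must be positive")
  bad <- setdiff(models, c("blank", "vip109", "vip162"))
  if (length(bad))
    stop(sprintf("run_config: unknown model id(s): %s", paste(bad, collapse = ", ")))
  structure(list(models = models, CO_values = CO_values, target_h = target_h,
                 dim = as.integer(dim),
                 ivc_fraction = ivc_fraction, R_rpa = R_rpa, R_lpa = R_lpa,
                 dye_edge = dye_edge, dye_kappa = dye_kappa,
                 dye_dt = dye_dt, dye_t_end = dye_t_end,
                 wss_threshold = wss_threshold, cut_offset = cut_offset,
                 stats_bias = stats_bias, stats_noise_sd = stats_noise_sd,
                 seed = as.integer(seed),
                 steady_max_steps = as.integer(steady_max_steps),
                 output_dir = output_dir), class = "run_config")
}

#' Geometry for a model id
#' @param model `"blank"`, `"vip109"` or `"vip162"`.
#' @return A [junction_geometry].
#' @export
model_geometry <- function(model) {
  switch(model,
         blank = junction_geometry(insert_kind = "none"),
         vip109 = junction_geometry(insert_kind = "bicone",
                                    blade_height = 0.109),
         vip162 = junction_geometry(insert_kind = "bicone",
                                    blade_height = 0.162,
                                    fillet_edges = TRUE),
         stop(sprintf("unknown model id '%s'", model)))
}

#' Save/load a study configuration as YAML
#' @param config a [run_config].
#' @param file path.
#' @return `write_run_config`: invisibly the path; `read_run_config`: the
#'   config.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  lst <- yaml::read_yaml(file)
  do.call(run_config, lst[setdiff(names(lst), character(0))])
}

#' Run one case of the study
#'
#' Meshes the requested model, solves steady flow at the given operating
#' point, and extracts the endpoint report (pressure losses between the cut
#' planes, flow split, power loss, wall-shear summaries), optionally
#' followed by the dye-washout stage.  Artifacts (VTU fields, manifest)
#' are written when the config names an output directory.
#'
#' @param config a [run_config].
#' @param CO cardiac output (L/min).
#' @param model model id.
#' @param with_dye also run the washout stage.
#' @param mesh optional pre-built mesh (skips meshing).
#' @param target_h optional mesh-size override.
#' @return List with `report` (one-row data.frame), `field`, `mesh`,
#'   `traction`, and (optionally) `washout`, `mean_washout`.
#' @export
run_case <- function(config, CO, model, with_dye = FALSE, mesh = NULL,
                     target_h = NULL) {
  if (!is.finite(CO) || CO <= 0)
    stop("run_case: cardiac output must be positive (parameter error)")
  h <- target_h %||% config$target_h
  if (is.null(mesh)) {
    geom <- model_geometry(model)
    mesh <- make_junction_mesh(geom, h, dim = config$dim %||% 3L)
    audit_mesh(mesh)
  }
  bc <- make_bc_set(CO, config$ivc_fraction, config$R_rpa, config$R_lpa)
  st <- solver_settings(steady_mode = TRUE,
                        steady_max_steps = config$steady_max_steps)
  field <- solve_steady(mesh, bc, st)
  if (field$info$flag == "solver_failure")
    stop(sprintf("run_case: flow stage failed for %s at CO=%g", model, CO))
  losses <- junction_pressure_losses(field, config$cut_offset)
  split <- flow_split(field)
  pw <- power_loss(field, rho = bc$fluid$density)
  wall_groups <- unique(grep("^wall", mesh$face_labels, value = TRUE))
  tr <- wall_traction(field, wall_groups, mu = bc$fluid$viscosity)
  tw <- tawss(tr)
  os <- osi(tr)
  rep_row <- data.frame(
    CO_L_min = CO, model = model,
    dP_ivc_rpa = losses$dP_ivc_rpa, dP_ivc_lpa = losses$dP_ivc_lpa,
    dP_svc_rpa = losses$dP_svc_rpa, dP_svc_lpa = losses$dP_svc_lpa,
    dP_max_mmHg = losses$dP_max,
    flow_split_rpa_pct = split,
    power_loss_mW = pw,
    mean_osi = mean(os),
    solver_flag = field$info$flag,
    stringsAsFactors = FALSE)
  for (g in wall_groups) {
    rep_row[[paste0("tawss_", sub("^wall_", "", g))]] <-
      mean_tawss(tr, tw, mesh, g)
    rep_row[[paste0("low_wss_frac_", sub("^wall_", "", g))]] <-
      low_wss_area_fraction(tr, tw, mesh, g, config$wss_threshold)
  }
  out <- list(report = rep_row, field = field, mesh = mesh, traction = tr)
  if (with_dye) {
    region <- dye_region(edge = config$dye_edge)
    sf0 <- init_dye(mesh, region)
    sf <- advance_scalar(sf0, field, dt = config$dye_dt,
                         t_end = config$dye_t_end, kappa = config$dye_kappa)
    wf <- washout_time(sf)
    mw <- mean_washout(wf, region)
    rep_row$mean_washout_s <- mw$mean_T
    rep_row$washout_censored_frac <- mw$censored_fraction
    out$report <- rep_row
    out$washout <- wf
    out$mean_washout <- mw
  }
  if (!is.null(config$output_dir)) {
    cdir <- file.path(config$output_dir, sprintf("%s_CO%g", model, CO))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    export_flow_field(out$field, cdir)
    if (with_dye) export_washout_field(out$washout,
                                       file.path(cdir, "washout.vtu"))
    utils::write.csv(out$report, file.path(cdir, "report.csv"),
                     row.names = FALSE)
    qual <- mesh_quality(mesh)
    manifest <- list(model = model, CO = CO, target_h = h,
                     seed = config$seed,
                     solver = list(flag = field$info$flag,
                                   n_steps = field$info$n_steps,
                                   residuals = field$info$residuals),
                     mesh = list(n_nodes = nrow(mesh$nodes),
                                 n_cells = nrow(mesh$cells),
                                 mean_aspect_ratio = qual$mean_aspect_ratio,
                                 min_dihedral_deg = qual$min_dihedral_deg))
    jsonlite::write_json(manifest, file.path(cdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the full CO x model sweep
#'
#' Executes every (CO, model) case, joins the endpoint table with synthetic
#' mock-loop measurements (configured bias/noise, seeded), and computes the
#' Bland-Altman agreement statistics.  Individual case failures are recorded
#' and skipped, not fatal.
#'
#' @param config a [run_config].
#' @param with_dye run the washout stage per case.
#' @return List with `reports` (data.frame), `mcl` (synthetic dataset),
#'   `comparison` (joined table), `bland_altman`, `pearson_r`, `failures`.
#' @export
sweep_cases <- function(config, with_dye = FALSE) {
  if (!length(config$CO_values)) stop("sweep_cases: empty CO list")
  reports <- list(); failures <- list()
  meshes <- list()
  for (model in config$models) {
    geom <- model_geometry(model)
    meshes[[model]] <- make_junction_mesh(geom, config$target_h,
                                          dim = config$dim %||% 3L)
    audit_mesh(meshes[[model]])
    for (CO in config$CO_values) {
      res <- tryCatch(
        run_case(config, CO, model, with_dye = with_dye,
                 mesh = meshes[[model]]),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(model = model, CO = CO, message = conditionMessage(res))
      } else {
        reports[[length(reports) + 1L]] <- res$report
      }
    }
  }
  reports <- do.call(rbind, reports)
  mcl <- synth_mcl_measurements(reports$dP_max_mmHg,
                                bias = config$stats_bias,
                                noise_sd = config$stats_noise_sd,
                                seed = config$seed,
                                CO = reports$CO_L_min,
                                model = reports$model)
  comp <- comparison_table(reports, mcl)
  pc <- paired_comparison(comp$dP_cfd, comp$dP_mcl,
                          paste(comp$model, comp$CO_L_min))
  out <- list(reports = reports, mcl = mcl, comparison = comp,
              bland_altman = bland_altman(pc),
              pearson_r = if (nrow(comp) >= 3L) pearson_r(pc) else NA_real_,
              failures = failures)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(reports, file.path(config$output_dir, "reports.csv"),
                     row.names = FALSE)
    write_mcl_csv(mcl, file.path(config$output_dir, "mcl_synthetic.csv"))
    utils::write.csv(comp, file.path(config$output_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  out
}

#' Mesh-sensitivity study
#'
#' Solves the same case on nested meshes (each level halving the target
#' element size), reports the maximum inlet-outlet pressure loss per level
#' and the pairwise relative differences, the convergence audit of the
#' bench-replication protocol.
#'
#' @param config a [run_config].
#' @param model model id (default the insert model).
#' @param CO cardiac output (default the highest configured).
#' @param levels number of nested levels (>= 2).
#' @param h_coarse coarsest target size (default `2 * config$target_h`).
#' @param dim 3 (tetrahedral) or 2 (planar cross-channel analog; the cheap
#'   acceptance-profile mode).
#' @param fine_max_steps pseudo-step budget for the finest level.  At the
#'   highest cardiac output the finest level is quasi-steady (incipient
#'   vortex shedding); a fixed implicit pseudo-step budget from the
#'   prolonged coarse solution defines a reproducible reported state.
#' @return Data frame with `level`, `target_h`, `n_cells`, `dP_max_mmHg`,
#'   `rel_diff_pct` (vs previous level), `flag`; attribute
#'   `finest_pair_rel_diff_pct`.
#' @export
mesh_sensitivity <- function(config, model = "vip162",
                             CO = max(config$CO_values), levels = 3L,
                             h_coarse = 2 * config$target_h, dim = 3L,
                             fine_max_steps = 8L) {
  if (levels < 2L) stop("mesh_sensitivity: need at least 2 levels")
  hs <- h_coarse / 2^(seq_len(levels) - 1L)
  out <- data.frame(level = seq_len(levels), target_h = hs,
                    n_cells = NA_integer_, dP_max_mmHg = NA_real_,
                    rel_diff_pct = NA_real_, flag = NA_character_)
  geom <- model_geometry(model)
  bc <- make_bc_set(CO, config$ivc_fraction, config$R_rpa, config$R_lpa)
  st <- solver_settings(steady_mode = TRUE,
                        steady_max_steps = config$steady_max_steps)
  prev <- NULL
  for (k in seq_len(levels)) {
    ## nested refinement of one coarse discretization: the levels share a
    ## converging geometry, so the differences measure discretization error
    mesh <- if (is.null(prev)) make_junction_mesh(geom, hs[1L], dim = dim)
            else refine_junction_mesh(prev$mesh, geom)
    audit_mesh(mesh)
    dP_k <- NULL
    if (is.null(prev)) {
      field <- solve_steady(mesh, bc, st)
    } else if (k < levels) {
      tf <- prolong_nodal_state(mesh, prev$field$v[[1L]], prev$field$p[[1L]])
      field <- solve_steady(mesh, bc, st, v0 = tf$v, p0 = tf$p)
    } else {
      ## finest level: at high CO no stable steady state exists (incipient
      ## shedding), so evolve a fixed pseudo-step budget from the prolonged
      ## solution and average the pressure loss over two sub-states
      tf <- prolong_nodal_state(mesh, prev$field$v[[1L]], prev$field$p[[1L]])
      sub <- max(2L, fine_max_steps %/% 2L)
      vcur <- tf$v; pcur <- tf$p
      dps <- numeric(0)
      for (rep in 1:2) {
        field <- solve_steady(mesh, bc,
                              solver_settings(steady_mode = TRUE,
                                              steady_max_steps = sub),
                              v0 = vcur, p0 = pcur)
        if (field$info$flag == "solver_failure")
          stop(sprintf("mesh_sensitivity: flow stage failed at level %d", k))
        vcur <- field$v[[1L]]; pcur <- field$p[[1L]]
        dps <- c(dps, junction_pressure_losses(field, config$cut_offset)$dP_max)
        if (field$info$flag == "converged") break
      }
      dP_k <- mean(dps)
    }
    if (field$info$flag == "solver_failure")
      stop(sprintf("mesh_sensitivity: flow stage failed at level %d", k))
    out$n_cells[k] <- nrow(mesh$cells)
    out$dP_max_mmHg[k] <- dP_k %||%
      junction_pressure_losses(field, config$cut_offset)$dP_max
    out$flag[k] <- field$info$flag
    if (k > 1L)
      out$rel_diff_pct[k] <- 100 * abs(out$dP_max_mmHg[k] -
                                       out$dP_max_mmHg[k - 1L]) /
                             abs(out$dP_max_mmHg[k])
    prev <- list(mesh = mesh, field = field)
  }
  attr(out, "finest_pair_rel_diff_pct") <- out$rel_diff_pct[levels]
  out
}

#' Nearest-node transfer of a flow state between meshes
#'
#' Chunked nearest-neighbor lookup used to warm-start refined solves from a
#' coarser solution.
#'
#' @param mesh_from,mesh_to source and destination meshes.
#' @param v,p nodal state on `mesh_from`.
#' @return List with `v`, `p` on `mesh_to`.
#' @export
transfer_nodal_state <- function(mesh_from, mesh_to, v, p) {
  A <- mesh_from$nodes
  B <- mesh_to$nodes
  nB <- nrow(B)
  idx <- integer(nB)
  chunk <- 2000L
  a2 <- rowSums(A^2)
  for (s in seq(1L, nB, by = chunk)) {
    e <- min(nB, s + chunk - 1L)
    D <- outer(rowSums(B[s:e, , drop = FALSE]^2), a2, "+") -
      2 * B[s:e, , drop = FALSE] %*% t(A)
    idx[s:e] <- max.col(-D, ties.method = "first")
  }
  list(v = v[idx, , drop = FALSE], p = p[idx])
}
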