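#' Scenario configuration
#'
#' Bundles everything one coupled simulation needs: initial mesh spec,
#' mechanical and signaling parameters, cue schedule, growth policy, frame
#' count and output options. One simulation time frame consists of one
#' growth event, its scheduled edge-swap run, and a mechanical relaxation;
#' the chemical field is re-converged to quasi-steady state on the current
#' geometry at the start of every frame.
#'
#' @param mesh list: `subdivisions`, `radius`, `cap_angle` (initial bud
#'   patch angular radius, radians).
#' @param mech a [mech_params()].
#' @param signaling a [signaling_params()].
#' @param cue list: `umin` (> 0), `umax`, `n_schedule` (see
#'   [cue_exponent_at()]).
#' @param growth a [growth_policy()].
#' @param frames number of growth events to simulate.
#' @param relax_max_steps,relax_force_tol mechanical relaxation budget per
#'   frame (applied after the swap run).
#' @param relax_per_swap mechanical Euler steps interleaved after each swap
#'   attempt, so the scheduled swap count doubles as the relaxation clock
#'   between growth events.
#' @param chem_cold_start if `TRUE`, the activator field is reset
#'   to the uniform set point before each frame's quasi-steady solve, so
#'   the chemical state is a function of the current geometry and cue only
#'   (history-free quasi-steady coupling, no hysteresis of the bistable
#'   self-enhancement); the scalar inhibitor is carried over for speed.
#' @param fixed_tip `NULL`, or a list enabling the ablation mode in which
#'   the growth region is pinned at the bud tip, bypassing the signaling
#'   submodel: `list(n_faces = )` for a constant-size footprint of the
#'   faces nearest the tip, or `list(height_fraction = )` for the top
#'   fraction of the bud height.
#' @param seed RNG seed for the whole run.
#' @param snapshot_every write a VTK snapshot every this many frames
#'   (0 = never) into `out_dir`.
#' @param out_dir output directory for snapshots/CSV (created on demand).
#' @param scale list `list(length_um = , frame_min = )` mapping simulation
#'   units to microns/minutes, used only for the `sim_time` column.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(mesh = list(subdivisions = 3, radius = 1, cap_angle = 0.35),
                            mech = mech_params(),
                            signaling = signaling_params(),
                            cue = list(umin = 0.05, umax = 1, n_schedule = 2),
                            growth = growth_policy(),
                            frames = 160,
                            relax_max_steps = 200, relax_force_tol = 5e-2,
                            relax_per_swap = 0, chem_cold_start = FALSE,
                            fixed_tip = NULL,
                            seed = 1, snapshot_every = 0, out_dir = NULL,
                            scale = list(length_um = 2.5, frame_min = 0.5)) {
  stopifnot(frames >= 1, cue$umin > 0, cue$umax > cue$umin)
  structure(list(mesh = mesh, mech = mech, signaling = signaling, cue = cue,
                 growth = growth, frames = as.integer(frames),
                 relax_max_steps = relax_max_steps,
                 relax_force_tol = relax_force_tol,
                 relax_per_swap = relax_per_swap,
                 chem_cold_start = chem_cold_start,
                 fixed_tip = fixed_tip, seed = seed,
                 snapshot_every = snapshot_every, out_dir = out_dir,
                 scale = scale),
            class = "scenario_config")
}

#' Scenario presets
#'
#' Named configurations for the package's in-silico experiments:
#' \describe{
#'   \item{fig3_n2}{shallow cue (n = 2): insertion spread over the bud,
#'     spherical budding.}
#'   \item{fig3_n8}{sharp cue (n = 8): insertion restricted to the tip,
#'     tubular budding.}
#'   \item{fig4_es25 / fig4_es75 / fig4_es125}{fixed-tip growth with 25,
#'     75 or 125 edge-swap attempts per frame (signaling bypassed).}
#'   \item{fig4_schedule150 / fig4_schedule100}{fixed-tip growth switching
#'     from 25 to 50 swaps after frame 150 / 100.}
#'   \item{fig5_case1 / fig5_case2}{time-varying cue exponent: n ramps
#'     5 -> 12, then decays to 7; case 2 decays twice as slowly.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [scenario_config()] (e.g. `seed`,
#'   `frames`).
#' @return a `scenario_config`.
#' @export
preset_scenario <- function(name, ...) {
  over <- list(...)
  base <- switch(name,
    fig3_n2 = list(cue = list(umin = 0.05, umax = 1, n_schedule = 2),
                   relax_max_steps = 100, relax_per_swap = 4,
                   growth = annealing_growth(50)),
    fig3_n8 = list(cue = list(umin = 0.05, umax = 1, n_schedule = 8),
                   relax_max_steps = 100, relax_per_swap = 4,
                   growth = annealing_growth(50)),
    fig4_es25 = list(fixed_tip = list(n_faces = 30),
                     relax_max_steps = 100, relax_per_swap = 4,
                     growth = annealing_growth(25)),
    fig4_es75 = list(fixed_tip = list(n_faces = 30),
                     relax_max_steps = 100, relax_per_swap = 4,
                     growth = annealing_growth(75)),
    fig4_es125 = list(fixed_tip = list(n_faces = 30),
                      relax_max_steps = 100, relax_per_swap = 4,
                      growth = annealing_growth(125)),
    fig4_schedule150 = list(fixed_tip = list(n_faces = 30),
                            relax_max_steps = 100, relax_per_swap = 4,
                            growth = annealing_growth(
                              list(frames = c(1, 151), steps = c(25, 50)))),
    fig4_schedule100 = list(fixed_tip = list(n_faces = 30),
                            relax_max_steps = 100, relax_per_swap = 4,
                            growth = annealing_growth(
                              list(frames = c(1, 101), steps = c(25, 50)))),
    fig5_case1 = list(cue = list(umin = 0.05, umax = 1,
                                 n_schedule = list(frames = c(1, 50, 100),
                                                   n = c(5, 12, 7))),
                      relax_max_steps = 100, relax_per_swap = 4,
                      growth = annealing_growth(25)),
    fig5_case2 = list(cue = list(umin = 0.05, umax = 1,
                                 n_schedule = list(frames = c(1, 50, 150),
                                                   n = c(5, 12, 7))),
                      relax_max_steps = 100, relax_per_swap = 4,
                      growth = annealing_growth(25)),
    stop("unknown preset: ", name)
  )
  do.call(scenario_config, utils::modifyList(base, over))
}

# Growth policy of the relaxation-time and stabilization experiments:
# swaps act on
# the bud at an annealing temperature, and deposited material is born flat
# so that bending provides a genuine drive toward the equilibrium
# (spherical) shape; the scheduled swap count is then the operative
# relaxation dial.
annealing_growth <- function(es) {
  growth_policy(es_schedule = es, kT = 0.2, swap_domain = "bud",
                rest_dihedral = "flat")
}

#' Names of the available presets
#' @return character vector.
#' @export
list_presets <- function() {
  c("fig3_n2", "fig3_n8", "fig4_es25", "fig4_es75", "fig4_es125",
    "fig4_schedule150", "fig4_schedule100", "fig5_case1", "fig5_case2")
}

# Growth region for the fixed-tip ablation mode: a constant-size insertion
# footprint of the n_faces bud faces whose centroids lie closest to the
# current tip vertex. A fixed footprint (rather than a height fraction)
# keeps the insertion region from adapting to the bud shape, which is the
# point of the ablation. A height_fraction field is also honoured for
# configs that ask for the top fraction of the bud height instead.
fixed_tip_region <- function(mesh, spec) {
  bud <- which(mesh$region == REGION_BUD)
  vid <- unique(as.vector(mesh$F[bud, ]))
  tip <- vid[which.max(mesh$V[vid, 3])]
  C <- (mesh$V[mesh$F[bud, 1], , drop = FALSE] +
        mesh$V[mesh$F[bud, 2], , drop = FALSE] +
        mesh$V[mesh$F[bud, 3], , drop = FALSE]) / 3
  if (!is.null(spec$n_faces)) {
    d2 <- rowSums(sweep(C, 2, mesh$V[tip, ])^2)
    bud[order(d2)[seq_len(min(spec$n_faces, length(bud)))]]
  } else {
    z_tip <- max(mesh$V[vid, 3])
    ring_v <- unique(as.vector(mesh$edges[mesh$septin, ]))
    neck_z <- mean(mesh$V[ring_v, 3])
    sel <- bud[C[, 3] >= z_tip - spec$height_fraction * (z_tip - neck_z)]
    if (length(sel) == 0) sel <- bud[which.max(C[, 3])]
    sel
  }
}

#' Run a coupled budding scenario
#'
#' Per frame: (1) evaluate the cue at the current frame; (2) re-converge
#' the reaction-diffusion system to quasi-steady state on the current
#' geometry (skipped in fixed-tip mode); (3) determine the eligible growth
#' region; (4) perform the growth event; (5) transfer the chemical state to
#' the grown mesh; (6) run the scheduled edge swaps; (7) relax the surface
#' mechanically; (8) record shape metrics. Fully reproducible under a
#' fixed seed.
#'
#' @param config a `scenario_config`.
#' @param progress print a per-frame log line.
#' @return an object of class `scenario_result`: list with `records` (one
#'   row per frame), `mesh`, `state`, `config`, `flags` (per-frame
#'   homeostasis/validity flags).
#' @export
run_scenario <- function(config, progress = FALSE) {
  set.seed(config$seed)
  mesh <- build_icosphere(config$mesh$subdivisions, config$mesh$radius)
  mesh <- init_bud_patch(mesh, c(0, 0, 1), config$mesh$cap_angle)
  sp <- config$signaling
  state <- chemical_state(rep(sp$kss, nrow(mesh$V)), 1)
  gp <- config$growth
  records <- vector("list", config$frames)
  flags <- logical(config$frames)
  use_signal <- is.null(config$fixed_tip)
  for (frame in seq_len(config$frames)) {
    stage <- "cue_field"
    res <- tryCatch({
      cf <- cue_field(mesh, config$cue, frame)
      if (use_signal) {
        stage <- "solve_quasi_steady"
        if (config$chem_cold_start)
          state <- chemical_state(rep(sp$kss, nrow(mesh$V)), state$b)
        state <- solve_quasi_steady(mesh, state, cf, sp)
        stage <- "eligible_faces"
        region <- eligible_faces(mesh, state$a, gp$threshold_fraction)
        if (length(region) == 0)  # degenerate field fallback
          region <- fixed_tip_region(mesh, list(height_fraction = 0.2))
      } else {
        region <- fixed_tip_region(mesh, config$fixed_tip)
      }
      stage <- "growth_event"
      old_mesh <- mesh
      mesh <- growth_event(mesh, region, gp)
      stage <- "transfer_state"
      state <- transfer_state_after_remodel(old_mesh, state, mesh)
      stage <- "run_swaps"
      n_es <- es_steps_at(gp$es_schedule, frame)
      mesh <- run_swaps(mesh, n_es, config$mech, gp$kT, gp$swap_domain,
                        relax_per_swap = config$relax_per_swap,
                        relax_force_tol = config$relax_force_tol)
      stage <- "relax"
      mesh <- relax(mesh, config$mech, config$relax_max_steps,
                    config$relax_force_tol)
      stage <- "metrics"
      g <- compute_geometry(mesh)
      en <- attr(mesh, "energy")
      ph <- polarization_height(mesh, state$a, gp$threshold_fraction)
      abar <- surface_average(mesh, state$a, g$vertex_dual_area)
      ok <- abs(abar - sp$kss) < 0.05 * sp$kss || !use_signal
      rec <- data.frame(
        frame = frame,
        sim_time = frame * config$scale$frame_min,
        bud_area = bud_area(mesh, g),
        AR_pca = aspect_ratio(mesh, "pca"),
        AR_heightwidth = aspect_ratio(mesh, "heightwidth"),
        PH = ph$PH, relative_PH = ph$relative_PH,
        conc_max = ph$conc_max, abar = abar, b = state$b,
        E_total = en$stretch + en$bend + en$area + en$morse,
        E_stretch = en$stretch, E_bend = en$bend, E_area = en$area,
        E_morse = en$morse,
        n_exponent = cf$n, es_steps = n_es,
        accepted_swaps = attr(mesh, "accepted_swaps"),
        region_faces = length(region),
        vertices = nrow(mesh$V))
      list(rec = rec, ok = ok)
    }, error = function(e) {
      stop(sprintf("scenario aborted at frame %d, stage %s: %s",
                   frame, stage, conditionMessage(e)), call. = FALSE)
    })
    records[[frame]] <- res$rec
    flags[frame] <- res$ok
    if (progress)
      message(sprintf("frame %3d | area %.3f AR %.3f abar %.4f swaps %d",
                      frame, res$rec$bud_area, res$rec$AR_pca,
                      res$rec$abar, res$rec$accepted_swaps))
    if (config$snapshot_every > 0 && frame %% config$snapshot_every == 0 &&
        !is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_snapshot(mesh, state,
                     file.path(config$out_dir, sprintf("frame_%04d.vtk", frame)),
                     cue = cue_field(mesh, config$cue, frame),
                     threshold_fraction = gp$threshold_fraction)
    }
  }
  structure(list(records = do.call(rbind, records), mesh = mesh,
                 state = state, config = config, flags = flags),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  r <- x$records
  cat(sprintf("scenario_result: %d frames, final bud area %.3f, final AR %.3f\n",
              nrow(r), r$bud_area[nrow(r)], r$AR_pca[nrow(r)]))
  invisible(x)
}

#' Write a simulation snapshot
#'
#' VTK snapshots carry the active-Cdc42 field and a per-vertex region
#' label, plus the per-face cue and growth eligibility; PLY/OFF snapshots
#' carry geometry only.
#'
#' @param mesh a `surface_mesh`.
#' @param state a `chemical_state` (or `NULL`).
#' @param path output path; the extension selects the format
#'   (`.vtk`, `.ply`, `.off`).
#' @param cue optional `cue_field` for the per-face cue value.
#' @param threshold_fraction eligibility threshold used for the per-face
#'   eligibility flag.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(mesh, state = NULL, path,
                           cue = NULL, threshold_fraction = 0.8) {
  if (grepl("\\.(ply|off)$", path, ignore.case = TRUE))
    return(write_mesh(mesh, path))
  pd <- list()
  cd <- list(region = as.numeric(mesh$region))
  if (!is.null(state)) {
    pd$a <- state$a
    elig <- rep(0, nrow(mesh$F))
    ef <- tryCatch(eligible_faces(mesh, state$a, threshold_fraction),
                   error = function(e) integer(0))
    elig[ef] <- 1
    cd$eligible <- elig
  }
  vreg <- rep(0, nrow(mesh$V))
  vreg[unique(as.vector(mesh$F[mesh$region == REGION_BUD, ]))] <- 1
  pd$region <- vreg
  if (!is.null(cue)) cd$u <- cue$u
  write_vtk(mesh, path, point_data = pd, cell_data = cd)
}

#' Write the per-frame metrics table as CSV
#'
#' @param result a `scenario_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(result, path) {
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}

#' Load a scenario configuration from YAML
#'
#' The YAML mirrors the [scenario_config()] arguments; unknown fields are
#' rejected. A top-level `preset` key loads the named preset and applies
#' the remaining fields as overrides.
#'
#' @param path YAML file.
#' @return a `scenario_config`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("preset", "mesh", "mech", "signaling", "cue", "growth", "frames",
             "relax_max_steps", "relax_force_tol", "relax_per_swap", "chem_cold_start",
             "fixed_tip", "seed", "snapshot_every", "out_dir", "scale")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$mech)) y$mech <- do.call(mech_params, y$mech)
  if (!is.null(y$signaling)) y$signaling <- do.call(signaling_params, y$signaling)
  if (!is.null(y$growth)) y$growth <- do.call(growth_policy, y$growth)
  if (!is.null(y$preset)) {
    preset <- y$preset; y$preset <- NULL
    do.call(preset_scenario, c(list(name = preset), y))
  } else {
    do.call(scenario_config, y)
  }
}

#' Validate a scenario configuration
#'
#' @param config a `scenario_config`.
#' @return character vector of problems (length 0 when valid).
#' @export
validate_config <- function(config) {
  probs <- character(0)
  chk <- function(cond, msg) if (!cond) probs <<- c(probs, msg)
  chk(config$mesh$subdivisions >= 0, "mesh.subdivisions must be >= 0")
  chk(config$mesh$radius > 0, "mesh.radius must be > 0")
  chk(config$mesh$cap_angle > 0 && config$mesh$cap_angle < pi,
      "mesh.cap_angle must be in (0, pi)")
  chk(config$frames >= 1, "frames must be >= 1")
  chk(config$cue$umin > 0, "cue.umin must be > 0")
  chk(config$cue$umax > config$cue$umin, "cue.umax must exceed cue.umin")
  chk(config$growth$threshold_fraction > 0 && config$growth$threshold_fraction <= 1,
      "growth.threshold_fraction must be in (0, 1]")
  probs
}
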