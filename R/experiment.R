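#' Per-vertebra pose perturbation of a spine model
#'
#' Applies to every vertebra an independent seeded rigid perturbation:
#' sagittal (left-right axis) rotation drawn uniformly within
#' `rot_deg` degrees about the vertebral body centroid, and translation
#' drawn uniformly within `trans_mm` mm per axis. Used to derive a
#' supine-like configuration from a standing model (and vice versa) with
#' known ground-truth transforms.
#'
#' @param spine a `spine_model`.
#' @param rot_deg half-range of the sagittal rotation (deg).
#' @param trans_mm half-range of the translation per axis (mm).
#' @param seed integer seed.
#' @return list with `spine` (perturbed model) and `perturbations`
#'   (named list of the applied world-frame `rigid_transform`s).
#' @export
perturb_spine <- function(spine, rot_deg = 10, trans_mm = 10, seed = 1L) {
  labs <- vertebra_labels()
  draws <- with_seed(seed, {
    lapply(labs, function(l) list(ang = stats::runif(1, -rot_deg, rot_deg),
                                  tr = stats::runif(3, -trans_mm, trans_mm)))
  })
  names(draws) <- labs
  pert <- list()
  for (l in labs) {
    v <- spine$vertebrae[[l]]
    ctr <- as.numeric(apply_transform(v$pose, mesh_centroid(v$mesh)))
    Rp <- rot_x(draws[[l]]$ang)
    tp <- ctr - as.numeric(Rp %*% ctr) + draws[[l]]$tr
    pert[[l]] <- rigid_transform(Rp, tp)
    spine$vertebrae[[l]]$pose <- compose_transforms(pert[[l]], v$pose)
  }
  list(spine = spine, perturbations = pert)
}

#' Experiment configuration for the synthetic validation pipeline
#'
#' @param n_cases number of synthetic cases.
#' @param seed master seed; all per-case seeds are derived from it.
#' @param init_seed seed stream for the initial-pose jitter (vary it to
#'   obtain independent repeat registrations of identical cases).
#' @param pert_deg,pert_mm supine-vs-standing per-vertebra perturbation
#'   half-ranges (deg, mm).
#' @param contour_fraction fraction of each silhouette used as target
#'   contour (1 = full closed silhouette; e.g. 0.4 emulates corpus-only
#'   edge selection).
#' @param resolution silhouette rasterization step (mm).
#' @param init_jitter_deg,init_jitter_mm seeded jitter applied to each
#'   initial pose before refinement.
#' @param plan_jitter_deg per-segment half-range of the standing-plan
#'   jitter across cases (deg).
#' @param init initial-pose source: `"contours"` (coarse pose estimated
#'   from the target contours) or `"poses"` (the supine poses, emulating
#'   the manual vertebra alignment that precedes contour selection).
#'   Partial contours default to `"poses"` since a centroid/axis estimate
#'   from a fraction of the silhouette is structurally biased.
#' @param opts a [registration_options()].
#' @param env a `biplanar_environment` (defaults to [default_environment()]
#'   centered on the lumbar region).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_cases = 20, seed = 1L, init_seed = seed + 500L,
                              pert_deg = 10, pert_mm = 10,
                              contour_fraction = 1, resolution = 0.25,
                              init_jitter_deg = 2, init_jitter_mm = 2,
                              plan_jitter_deg = 3,
                              init = if (contour_fraction < 1) "poses"
                                     else "contours",
                              opts = registration_options(),
                              env = NULL) {
  stopifnot(n_cases >= 1, pert_deg >= 0, pert_mm >= 0,
            contour_fraction > 0, contour_fraction <= 1)
  init <- match.arg(init, c("contours", "poses"))
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 init_seed = as.integer(init_seed), pert_deg = pert_deg,
                 pert_mm = pert_mm, contour_fraction = contour_fraction,
                 resolution = resolution,
                 init_jitter_deg = init_jitter_deg,
                 init_jitter_mm = init_jitter_mm,
                 plan_jitter_deg = plan_jitter_deg, init = init,
                 opts = opts, env = env), class = "experiment_config")
}

standing_base_angles <- function() c(2, 5, 7, 10, 12.6)

simulate_case <- function(cfg, i) {
  case_seed <- cfg$seed + i * 1009L
  shapes <- default_spine_shapes(seed = case_seed)
  ang <- with_seed(case_seed + 1L,
                   standing_base_angles() +
                     stats::runif(5, -cfg$plan_jitter_deg, cfg$plan_jitter_deg))
  plan <- sagittal_plan(ang, disc_heights = 10)
  standing <- assemble_spine(shapes, plan)
  sup <- perturb_spine(standing, cfg$pert_deg, cfg$pert_mm,
                       seed = case_seed + 2L)
  list(id = i, seed = case_seed, shapes = shapes, plan = plan,
       standing = standing, supine = sup$spine,
       gt_angles = angle_set(plan$intersegmental_angles,
                             plan_ll(plan, shapes)))
}

case_targets <- function(case, env, resolution, fraction) {
  labs <- vertebra_labels()
  out <- lapply(labs, function(l) {
    v <- case$standing$vertebrae[[l]]
    tg <- lapply(list(env$frontal, env$sagittal), function(vw) {
      sil <- silhouette_contour(v$mesh, v$pose, vw, resolution)
      if (fraction < 1)
        partial_silhouette(sil, fraction, n_segments = 2,
                           seed = case$seed + 3L + match(vw$name,
                             c("frontal", "sagittal")))
      else sil
    })
    stats::setNames(tg, c("frontal", "sagittal"))
  })
  stats::setNames(out, labs)
}

#' Run the synthetic end-to-end validation experiment
#'
#' For each seeded case: build a standing spine model (jittered standing
#' plan), derive the supine configuration by per-vertebra perturbation,
#' project exact silhouette target contours of the standing pose in both
#' views (optionally partial), register the supine meshes
#' ([initialize_pose()] + [register_vertebra()] with seeded initial-pose
#' jitter), construct the postregistrational midsagittal section and
#' measure intersegmental and LL angles on it. Deterministic given the
#' config seeds.
#'
#' @param cfg an [experiment_config()].
#' @param outdir optional directory for the per-case summary CSV.
#' @param verbose print one line per case.
#' @return An object of class `validation_run`: per-case results
#'   (`cases`), the angle-difference table (`angles`), config.
#' @export
run_validation_experiment <- function(cfg = experiment_config(),
                                      outdir = NULL, verbose = FALSE) {
  env <- cfg$env %||% default_environment(center = c(0, 0, 80))
  rows <- list()
  cases <- vector("list", cfg$n_cases)
  for (i in seq_len(cfg$n_cases)) {
    res <- tryCatch({
      case <- simulate_case(cfg, i)
      targets <- case_targets(case, env, cfg$resolution,
                              cfg$contour_fraction)
      # the ambiguity warning from the coarse initializer is expected for
      # near-square frontal outlines; the in-plane search disambiguates
      regs <- withCallingHandlers(
        register_spine(case$supine, targets, env, cfg$opts,
                       init = cfg$init,
                       init_jitter_deg = cfg$init_jitter_deg,
                       init_jitter_mm = cfg$init_jitter_mm,
                       jitter_seed = cfg$init_seed + i * 613L),
        warning = function(w) {
          if (grepl("near-isotropic", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      regmod <- registered_spine(case$supine, regs)
      meas <- compute_angles(regmod, route = "section")
      dd <- angle_abs_diff(meas, case$gt_angles)
      case$registered_poses <- lapply(regs, function(r) r$final_pose)
      case$results <- regs
      case$measured_angles <- meas
      case$failed <- FALSE
      if (verbose)
        message(sprintf("case %02d: mean |dAngle| %.3f deg, |dLL| %.3f deg",
                        i, mean(dd$intersegmental), dd$LL))
      list(case = case,
           row = data.frame(case = i, t(dd$intersegmental), LL = dd$LL,
                            measured_LL = meas$LL, gt_LL = case$gt_angles$LL,
                            rms = mean(vapply(regs, function(r)
                              r$rms_residual, numeric(1))),
                            converged = all(vapply(regs, function(r)
                              r$converged, logical(1)))))
    }, error = function(e) {
      message("case ", i, " failed: ", conditionMessage(e))
      list(case = list(id = i, failed = TRUE,
                       error = conditionMessage(e)), row = NULL)
    })
    cases[[i]] <- res$case
    if (!is.null(res$row)) rows[[length(rows) + 1L]] <- res$row
  }
  angles <- do.call(rbind, rows)
  run <- structure(list(cases = cases, angles = angles, config = cfg),
                   class = "validation_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(format(angles, digits = 10),
                     file.path(outdir, "validation_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  run
}

#' @export
print.validation_run <- function(x, ...) {
  s <- accuracy_summary(x)
  cat(sprintf("<validation_run> %d cases (%d ok): mean |d interseg| %.3f deg, mean |dLL| %.3f deg\n",
              length(x$cases), nrow(x$angles), s$mean_intersegmental,
              s$mean_LL))
  invisible(x)
}

#' Registration accuracy summary of a validation run
#'
#' Mean absolute differences between angles measured on the
#' postregistrational midsagittal sections and the ground-truth standing
#' angles, pooled over segments and cases.
#'
#' @param run a `validation_run`.
#' @return list with `mean_intersegmental` (deg, pooled over the 5
#'   segments of all cases), `per_segment` (deg), `mean_LL` (deg),
#'   `n_cases`.
#' @export
accuracy_summary <- function(run) {
  a <- run$angles
  segs <- segment_labels()
  list(mean_intersegmental = mean(as.matrix(a[, segs])),
       per_segment = colMeans(a[, segs]),
       mean_LL = mean(a$LL),
       n_cases = nrow(a))
}

#' Dice overlap of registered versus ground-truth poses
#'
#' Voxelizes every registered vertebra and the same vertebra at its
#' ground-truth standing pose on a shared grid and reports the Dice
#' similarity index per vertebra.
#'
#' @param run a `validation_run`.
#' @param voxel_size voxel edge (mm); 0.6 mirrors the CT grid.
#' @return data.frame with case, label and dice columns.
#' @export
registration_dice <- function(run, voxel_size = 0.6) {
  rows <- list()
  for (case in run$cases) {
    if (isTRUE(case$failed)) next
    for (l in vertebra_labels()) {
      mesh <- case$standing$vertebrae[[l]]$mesh
      vp <- voxelize_pair(mesh, case$registered_poses[[l]],
                          mesh, case$standing$vertebrae[[l]]$pose,
                          voxel_size)
      rows[[length(rows) + 1L]] <-
        data.frame(case = case$id, label = l, dice = dice(vp[[1]], vp[[2]]))
    }
  }
  do.call(rbind, rows)
}

#' Compare two repeat registration runs of identical cases
#'
#' The reproducibility analysis: corresponding registered vertebral
#' meshes from two runs (same cases, different initial-pose seeds) are
#' compared by one-sided Metro mean surface distance, and the measured LL
#' values by the single-measurement absolute-agreement ICC.
#'
#' @param run_a,run_b `validation_run` objects over identical cases.
#' @param samples_per_mm2 surface sampling density for the distances.
#' @return list with `distances` (data.frame case/label/mean_distance),
#'   `fraction_below_1mm`, `icc_LL` (`icc_estimate`), and the paired LL
#'   matrix `ll`.
#' @export
compare_runs <- function(run_a, run_b, samples_per_mm2 = 0.5) {
  rows <- list()
  for (i in seq_along(run_a$cases)) {
    ca <- run_a$cases[[i]]; cb <- run_b$cases[[i]]
    if (isTRUE(ca$failed) || isTRUE(cb$failed)) next
    for (l in vertebra_labels()) {
      mesh <- ca$standing$vertebrae[[l]]$mesh
      ma <- apply_transform(ca$registered_poses[[l]], mesh)
      mb <- apply_transform(cb$registered_poses[[l]], mesh)
      d <- mean_surface_distance(ma, mb, samples_per_mm2,
                                 seed = ca$seed + 17L)
      rows[[length(rows) + 1L]] <-
        data.frame(case = ca$id, label = l, mean_distance = d)
    }
  }
  distances <- do.call(rbind, rows)
  ll <- cbind(a = run_a$angles$measured_LL, b = run_b$angles$measured_LL)
  list(distances = distances,
       fraction_below_1mm = mean(distances$mean_distance < 1),
       icc_LL = icc(ll, "single"),
       ll = ll)
}

#' Agreement report between two sets of registrations
#'
#' The twofold comparison of two registration sets: per-vertebra Metro
#' mean surface distances with their cumulative distribution (fraction of
#' vertebra pairs below each distance), per-angle ICCs (the five
#' intersegmental angles and LL), and optionally per-vertebra Dice
#' indices of the voxelized registered meshes.
#'
#' @param run_a,run_b `validation_run` objects over identical cases.
#' @param comparison label for the report (e.g. `"I1T1 vs I1T2"`).
#' @param with_dice also voxelize both registrations (0.6 mm) and report
#'   per-vertebra Dice.
#' @param samples_per_mm2 surface sampling density.
#' @param icc_variant `"single"` (intra-rater, ICC(A,1)) or `"mean_k"`
#'   (inter-rater, ICC(A,k), k = 2).
#' @return An object of class `agreement_report`.
#' @export
build_agreement_report <- function(run_a, run_b, comparison = "run A vs run B",
                                   with_dice = FALSE, samples_per_mm2 = 0.5,
                                   icc_variant = c("single", "mean_k")) {
  icc_variant <- match.arg(icc_variant)
  cmp <- compare_runs(run_a, run_b, samples_per_mm2)
  meas_a <- measured_angle_matrix(run_a)
  meas_b <- measured_angle_matrix(run_b)
  icc_tab <- do.call(rbind, lapply(colnames(meas_a), function(s) {
    ic <- icc(cbind(meas_a[, s], meas_b[, s]), icc_variant)
    data.frame(angle = s, icc = ic$estimate, lower = ic$lower,
               upper = ic$upper)
  }))
  thr <- seq(0, ceiling(max(cmp$distances$mean_distance) * 10) / 10 + 0.1,
             by = 0.1)
  cum <- data.frame(distance_mm = thr,
                    fraction = vapply(thr, function(t0)
                      mean(cmp$distances$mean_distance <= t0), numeric(1)))
  dsi <- NULL
  if (with_dice) {
    rows <- list()
    for (i in seq_along(run_a$cases)) {
      ca <- run_a$cases[[i]]; cb <- run_b$cases[[i]]
      if (isTRUE(ca$failed) || isTRUE(cb$failed)) next
      for (l in vertebra_labels()) {
        mesh <- ca$standing$vertebrae[[l]]$mesh
        vp <- voxelize_pair(mesh, ca$registered_poses[[l]],
                            mesh, cb$registered_poses[[l]], 0.6)
        rows[[length(rows) + 1L]] <- data.frame(case = ca$id, label = l,
                                                dice = dice(vp[[1]], vp[[2]]))
      }
    }
    dsi <- do.call(rbind, rows)
  }
  structure(list(comparison = comparison, distances = cmp$distances,
                 fraction_below_1mm = cmp$fraction_below_1mm,
                 cumulative = cum, icc = icc_tab, dice = dsi),
            class = "agreement_report")
}

# n_cases x 6 matrix of measured angles (5 segments + LL) of a run.
measured_angle_matrix <- function(run) {
  ok <- !vapply(run$cases, function(c) isTRUE(c$failed), logical(1))
  m <- t(vapply(run$cases[ok], function(c)
    c(c$measured_angles$intersegmental, LL = c$measured_angles$LL),
    numeric(6)))
  colnames(m) <- c(segment_labels(), "LL")
  m
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$comparison, "\n")
  cat(sprintf("  %d vertebra pairs; mean distance %.3f mm; %.1f%% below 1 mm\n",
              nrow(x$distances), mean(x$distances$mean_distance),
              100 * x$fraction_below_1mm))
  cat("  angle ICCs:\n")
  print(x$icc, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an agreement report as CSV files
#'
#' `distances.csv` (one row per vertebra pair), `icc.csv` (one row per
#' angle) and `cumulative.csv` (the cumulative-distance curve).
#'
#' @param report an `agreement_report`.
#' @param dir output directory (created if needed).
#' @export
write_agreement_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$distances, file.path(dir, "distances.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$icc, file.path(dir, "icc.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$cumulative, file.path(dir, "cumulative.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$dice))
    utils::write.csv(report$dice, file.path(dir, "dice.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
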