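# Registration tests share one spine/environment fixture; exact targets are
# silhouettes of the ground-truth standing pose.

test_that("options validate their invariants", {
  expect_error(registration_options(convergence_tol = 0), "convergence_tol")
  expect_error(registration_options(view_weights = c(frontal = 0,
                                                     sagittal = 0)),
               "weights")
})

test_that("initial pose from contours lands near the ground truth", {
  sp <- fix_spine()
  env <- fix_env()
  for (l in c("L1", "L4", "S")) {
    v <- sp$vertebrae[[l]]
    tg <- vertebra_targets(sp, l, env)
    # near-square frontal outlines legitimately warn about axis ambiguity
    ip <- suppressWarnings(initialize_pose(v$mesh, tg, env))
    pe <- pose_error(ip, v$pose, v$mesh)
    expect_lt(pe["rot_deg"], 5)
    expect_lt(pe["trans_mm"], 2)
  }
})

test_that("translation-only offsets are recovered by centroid matching", {
  sp <- fix_spine()
  env <- fix_env()
  v <- sp$vertebrae[["L3"]]
  tg <- vertebra_targets(sp, "L3", env)
  # the mesh knows nothing of the 30 mm offset; the targets pull it back
  ip <- suppressWarnings(initialize_pose(v$mesh, tg, env))
  ctr_gt <- apply_transform(v$pose, mesh_centroid(v$mesh))
  ctr_ip <- apply_transform(ip, mesh_centroid(v$mesh))
  expect_lt(sqrt(sum((ctr_gt - ctr_ip)^2)), 2)
})

test_that("degenerate collinear targets are rejected", {
  env <- fix_env()
  line <- contour2d(cbind(seq(-20, 20, 2), seq(-20, 20, 2) * 0.5))
  v <- fix_spine()$vertebrae[["L3"]]
  expect_error(initialize_pose(v$mesh, list(frontal = line, sagittal = line),
                               env),
               "degenerate")
})

test_that("registration from the truth stays at the truth", {
  sp <- fix_spine()
  env <- fix_env()
  v <- sp$vertebrae[["L3"]]
  tg <- vertebra_targets(sp, "L3", env)
  r <- register_vertebra(v$mesh, v$pose, tg, env)
  expect_true(r$converged)
  expect_lt(r$rms_residual, 0.25)  # rasterization floor at 0.25 mm targets
  pe <- pose_error(r$final_pose, v$pose, v$mesh)
  expect_lt(pe["rot_deg"], 0.1)
  expect_lt(pe["trans_mm"], 0.1)
})

test_that("perturbed poses are recovered and cost is monotone", {
  set.seed(202)
  sp <- fix_spine()
  env <- fix_env()
  errs <- matrix(NA_real_, 0, 2)
  for (i in 1:20) {
    l <- sample(vertebra_labels(), 1)
    v <- sp$vertebrae[[l]]
    tg <- vertebra_targets(sp, l, env)
    init <- perturb_about_centroid(v$pose, v$mesh, runif(1, -10, 10),
                                   runif(3, -10, 10))
    r <- register_vertebra(v$mesh, init, tg, env)
    expect_true(all(r$step_cost_after <= r$step_cost_before + 1e-9))
    errs <- rbind(errs, pose_error(r$final_pose, v$pose, v$mesh))
  }
  expect_lt(median(errs[, 1]), 0.5)  # deg
  expect_lt(median(errs[, 2]), 0.5)  # mm
})

test_that("a 45-degree start never reports a silent success", {
  sp <- fix_spine()
  env <- fix_env()
  v <- sp$vertebrae[["L3"]]
  tg <- vertebra_targets(sp, "L3", env)
  init <- perturb_about_centroid(v$pose, v$mesh, 45, c(0, 0, 0))
  opts <- registration_options(restarts = 0)  # probe the raw capture range
  r <- register_vertebra(v$mesh, init, tg, env, opts)
  pe <- pose_error(r$final_pose, v$pose, v$mesh)
  expect_true(!r$converged || r$rms_residual > 0.5 || pe["rot_deg"] < 1)
})

test_that("partial corpus-like contours still drive recovery", {
  set.seed(31)
  sp <- fix_spine()
  env <- fix_env()
  for (l in c("L2", "L5")) {
    v <- sp$vertebrae[[l]]
    tg <- lapply(list(env$frontal, env$sagittal), function(vw) {
      sil <- silhouette_contour(v$mesh, v$pose, vw, 0.25)
      partial_silhouette(sil, 0.4, n_segments = 3,
                         seed = 7 + match(vw$name, c("frontal", "sagittal")))
    })
    names(tg) <- c("frontal", "sagittal")
    init <- perturb_about_centroid(v$pose, v$mesh, 8, c(3, -6, 4))
    r <- register_vertebra(v$mesh, init, tg, env)
    pe <- pose_error(r$final_pose, v$pose, v$mesh)
    expect_lt(pe["rot_deg"], 1)
    expect_lt(pe["trans_mm"], 1)
  }
})

test_that("residuals are equivariant under a global rigid motion", {
  sp <- fix_spine()
  env <- fix_env()
  v <- sp$vertebrae[["L4"]]
  tg <- vertebra_targets(sp, "L4", env)
  opts <- registration_options(max_iterations = 3)
  r0 <- register_vertebra(v$mesh, v$pose, tg, env, opts)
  # move scene + environment together; targets move implicitly because the
  # detector frame moves with the environment
  g <- rigid_transform(rot_z(9) %*% rot_x(4), c(25, -40, 60))
  env_g <- apply_transform(g, env)
  pose_g <- compose_transforms(g, v$pose)
  # detector (u, v) coordinates are frame-free, so the same target contours
  # apply in the moved scene
  r1 <- register_vertebra(v$mesh, pose_g, tg, env_g, opts)
  expect_lt(abs(r0$rms_residual - r1$rms_residual), 1e-6)
})

test_that("spine registration propagates labelled errors", {
  sp <- fix_spine()
  env <- fix_env()
  targets <- lapply(vertebra_labels(), function(l)
    vertebra_targets(sp, l, env, resolution = 0.5))
  names(targets) <- vertebra_labels()
  broken <- targets
  broken[["L3"]] <- NULL
  expect_error(register_spine(sp, broken, env), "L3")
  no_sag <- targets
  no_sag[["L2"]]$sagittal <- NULL
  expect_error(register_spine(sp, no_sag, env, init = "poses"), "L2")
})

test_that("whole-spine registration from supine-like poses converges", {
  sp <- fix_spine()
  env <- fix_env()
  pert <- perturb_spine(sp, rot_deg = 8, trans_mm = 8, seed = 5)
  targets <- lapply(vertebra_labels(), function(l)
    vertebra_targets(sp, l, env))
  names(targets) <- vertebra_labels()
  res <- register_spine(pert$spine, targets, env, init = "poses")
  expect_named(res, vertebra_labels())
  for (l in vertebra_labels()) {
    expect_true(res[[l]]$converged)
    pe <- pose_error(res[[l]]$final_pose, sp$vertebrae[[l]]$pose,
                     sp$vertebrae[[l]]$mesh)
    expect_lt(pe["rot_deg"], 1)
    expect_lt(pe["trans_mm"], 1)
  }
})
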