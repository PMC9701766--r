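# Shared fixtures, built lazily once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_shapes <- function() fixture("shapes", function() default_spine_shapes(seed = 3))

fix_spine <- function() fixture("spine", function()
  assemble_spine(fix_shapes(), default_sagittal_plan("standing")))

fix_env <- function() fixture("env", function()
  default_environment(center = c(0, 0, 80)))

fix_vertebra <- function() fixture("vertebra", function()
  make_vertebra(default_shape_params("L3", seed = 7), label = "L3"))

# pose error: total rotation angle (deg) and centroid displacement (mm)
pose_error <- function(p, gt, mesh) {
  dR <- p$R %*% t(gt$R)
  ang <- (180 / pi) * acos(pmin(1, pmax(-1, (sum(diag(dR)) - 1) / 2)))
  c1 <- apply_transform(p, mesh_centroid(mesh))
  c2 <- apply_transform(gt, mesh_centroid(mesh))
  c(rot_deg = ang, trans_mm = sqrt(sum((c1 - c2)^2)))
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rot_axis(ax, stats::runif(1, -180, 180)),
                  stats::rnorm(3, sd = 50))
}

shoelace_area <- function(p) {
  abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2]) / 2)
}

# targets (both views) for one vertebra of a spine at its current pose
vertebra_targets <- function(spine, label, env, resolution = 0.25) {
  v <- spine$vertebrae[[label]]
  list(frontal = silhouette_contour(v$mesh, v$pose, env$frontal, resolution),
       sagittal = silhouette_contour(v$mesh, v$pose, env$sagittal, resolution))
}

perturb_about_centroid <- function(pose, mesh, rot_deg_x, tr) {
  ctr <- as.numeric(apply_transform(pose, mesh_centroid(mesh)))
  Rp <- rot_x(rot_deg_x)
  compose_transforms(rigid_transform(Rp, ctr - as.numeric(Rp %*% ctr) + tr),
                     pose)
}
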