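#' Options for contour-based registration
#'
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the pooled RMS residual changes by
#'   less than this between iterations (mm).
#' @param correspondence_cap target samples farther than this (mm) from
#'   the projected silhouette are discarded as outliers.
#' @param view_weights named weights `c(frontal=, sagittal=)` for pooling
#'   the two views (not both zero).
#' @param densify_step target-contour resampling step (mm).
#' @param edge_sample_step sampling step along projected silhouette rim
#'   edges (mm).
#' @param restarts if the final RMS residual exceeds `restart_threshold`
#'   (a local minimum), retry up to this many times from deterministically
#'   jittered initial poses and keep the best result.
#' @param restart_threshold RMS residual (mm) above which a result is
#'   treated as a failed basin and restarted.
#' @param seed seed of the restart jitter draws.
#' @return An object of class `registration_options`.
#' @export
registration_options <- function(max_iterations = 150,
                                 convergence_tol = 5e-4,
                                 correspondence_cap = 10,
                                 view_weights = c(frontal = 1, sagittal = 1),
                                 densify_step = 0.5, edge_sample_step = 0.5,
                                 restarts = 3, restart_threshold = 0.5,
                                 seed = 1L) {
  stopifnot(max_iterations >= 1, convergence_tol > 0, correspondence_cap > 0,
            densify_step > 0, edge_sample_step > 0, restarts >= 0,
            restart_threshold > 0)
  if (any(view_weights < 0) || sum(view_weights) <= 0)
    stop("view weights must be non-negative and not both zero")
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 correspondence_cap = correspondence_cap,
                 view_weights = view_weights,
                 densify_step = densify_step,
                 edge_sample_step = edge_sample_step,
                 restarts = as.integer(restarts),
                 restart_threshold = restart_threshold,
                 seed = seed), class = "registration_options")
}

# Occluding-rim samples of a posed mesh w.r.t. one view: 3D points (local
# frame) on mesh edges whose two adjacent faces face opposite ways from the
# source. Returns local-frame sample points (n x 3).
silhouette_rim_points <- function(mesh, adj, pose, view, step) {
  world <- apply_transform(pose, mesh)
  n <- face_normals(world)
  if (view$orthographic) {
    d <- view$origin - view$source
    s <- as.numeric(n %*% d)
  } else {
    ctr <- (world$vertices[world$faces[, 1], , drop = FALSE] +
            world$vertices[world$faces[, 2], , drop = FALSE] +
            world$vertices[world$faces[, 3], , drop = FALSE]) / 3
    s <- rowSums(n * sweep(ctr, 2, view$source, "-"))
  }
  sgn <- s > 0
  rim <- which(!is.na(adj$f2) & sgn[adj$f1] != sgn[adj$f2])
  if (length(rim) == 0) stop("no silhouette edges found in view ", view$name)
  a <- mesh$vertices[adj$edges[rim, 1], , drop = FALSE]
  b <- mesh$vertices[adj$edges[rim, 2], , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  ns <- pmax(2L, ceiling(len / step) + 1L)
  reps <- rep(seq_along(rim), ns)
  tt <- unlist(lapply(ns, function(k) seq(0, 1, length.out = k)))
  a[reps, , drop = FALSE] * (1 - tt) + b[reps, , drop = FALSE] * tt
}

#' Coarse initial pose from target contours
#'
#' Surrogate for the manual per-vertebra alignment step: the translation
#' places the mesh so its projection centroid matches the target-contour
#' centroid in both views (linear least-squares triangulation), and the
#' rotation aligns the 2D principal axes of the projected mesh with those
#' of the targets in each view. A warning flags the near-symmetric case
#' where the principal-axis direction is ambiguous.
#'
#' @param mesh a `triangle_mesh` (local frame).
#' @param targets list with elements `frontal` and `sagittal`, each a
#'   `contour2d` or list of them.
#' @param env a `biplanar_environment`.
#' @return A `rigid_transform` initial pose.
#' @export
initialize_pose <- function(mesh, targets, env) {
  views <- list(frontal = env$frontal, sagittal = env$sagittal)
  tpts <- lapply(views, function(v) {
    cl <- as_contour_list(targets[[v$name]])
    do.call(rbind, lapply(cl, function(cc)
      densify_contour(cc, 1)$points))
  })
  for (nm in names(tpts)) {
    sv <- svd(stats::cov(tpts[[nm]]))
    if (sv$d[1] < 1e-9 || sv$d[2] < 1e-10 * sv$d[1])
      stop("degenerate (collinear) target contour in ", nm, " view")
  }
  ctr_t <- lapply(tpts, colMeans)
  X <- triangulate_detector_points(views, ctr_t)
  R <- diag(3)
  cm <- mesh_centroid(mesh)
  tr <- rigid_transform(R, X - as.numeric(R %*% cm))
  # the mesh side of every comparison is built exactly like the targets
  # (rasterized silhouette, arc-length resampled) so centroids and axes
  # are directly comparable
  rim_uv <- function(tr, v)
    densify_contour(silhouette_contour(mesh, tr, v, 0.5), 1)$points
  for (pass in 1:5) {
    for (nm in c("sagittal", "frontal")) {
      v <- views[[nm]]
      pm <- principal_axis(rim_uv(tr, v))
      pt <- principal_axis(tpts[[nm]])
      if (pt$ratio > 0.8 || pm$ratio > 0.8) {
        # near-isotropic outline: the axis direction is not identifiable;
        # leave the rotation untouched in this view
        if (pass == 1)
          warning("near-isotropic target in ", nm,
                  " view: principal-axis alignment is ambiguous")
        next
      }
      d <- wrap_half(pt$angle - pm$angle)
      ax <- X - v$source
      ax <- ax / sqrt(sum(ax^2))
      # in-plane CCW rotation on the detector corresponds to rotation about
      # the (source -> object) axis; sign fixed by the (u, v, axis) handedness
      sgn <- sign(sum(cross3(v$u, v$v) * ax))
      R <- project_so3(rot_axis(ax, sgn * d) %*% R)
      tr <- rigid_transform(R, X - as.numeric(R %*% cm))
    }
    # translation refinement: match projected rim centroids to the target
    # centroids by triangulating both and shifting by the difference
    ctr_m <- lapply(views, function(v) colMeans(rim_uv(tr, v)))
    X_m <- triangulate_detector_points(views, ctr_m)
    tr <- rigid_transform(R, tr$t + (X - X_m))
  }
  # principal axes can agree while the in-plane tilt is still a few degrees
  # off (the silhouette shape itself changes with rotation, and perspective
  # rotation axes are slightly oblique); a coarse 1-D search over each
  # view's in-plane rotation, scored by mean contour distance, removes the
  # bias
  for (nm in c("sagittal", "frontal")) {
    v <- views[[nm]]
    ax <- X - v$source
    ax <- ax / sqrt(sum(ax^2))
    score <- function(cand_tr)
      mean(cpp_nn2d(tpts[[nm]], rim_uv(cand_tr, v))$distance)
    best <- tr; best_s <- score(tr)
    for (d in setdiff(seq(-9, 9, by = 1.5), 0)) {
      Rd <- rot_axis(ax, d)
      cand <- rigid_transform(project_so3(Rd %*% tr$R),
                              as.numeric(Rd %*% (tr$t - X)) + X)
      s <- score(cand)
      if (s < best_s) { best <- cand; best_s <- s }
    }
    tr <- best
  }
  ctr_m <- lapply(views, function(v) colMeans(rim_uv(tr, v)))
  tr <- rigid_transform(tr$R,
                        tr$t + (X - triangulate_detector_points(views, ctr_m)))
  tr
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

wrap_half <- function(deg) {
  d <- (deg + 90) %% 180 - 90
  d
}

# Orientation (degrees, in [0, 180)) of the principal axis of 2D points,
# with the minor/major eigenvalue ratio as an identifiability measure.
principal_axis <- function(p) {
  cv <- stats::cov(p)
  e <- eigen(cv, symmetric = TRUE)
  list(angle = .rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1])) %% 180,
       ratio = e$values[2] / max(e$values[1], 1e-300))
}

# Least-squares 3D point whose projections match given detector points.
triangulate_detector_points <- function(views, det_pts) {
  A <- NULL; b <- NULL
  for (nm in names(views)) {
    v <- views[[nm]]; uv <- det_pts[[nm]]
    sid <- as.numeric(sum((v$origin - v$source) * v$normal) /
                        sum(v$normal * v$normal))
    # perspective: u * ((X - s).n) = ((o - s).n) * ((X - s).u)
    for (k in 1:2) {
      ax <- if (k == 1) v$u else v$v
      row <- uv[k] * v$normal - sid * ax
      A <- rbind(A, row)
      b <- c(b, sum(row * v$source))
    }
  }
  as.numeric(qr.solve(A, b))
}

#' Register one vertebra to biplanar target contours
#'
#' Iterative contour-based 6-DOF refinement: each iteration projects the
#' mesh's occluding rim into both views, matches every densified target
#' sample to its nearest projected rim point (pairs beyond
#' `correspondence_cap` are dropped), and updates the pose by a damped
#' Gauss-Newton step on an axis-angle + translation increment minimizing
#' the weighted sum of squared 2D correspondence distances over both
#' views. Iterations stop when the pooled RMS residual changes by less
#' than `convergence_tol` or `max_iterations` is reached. The damped step
#' acceptance makes the matched cost non-increasing across accepted steps.
#'
#' @param mesh a `triangle_mesh` (local/CT frame).
#' @param init initial `rigid_transform`.
#' @param targets list `frontal`/`sagittal` of target contours
#'   (`contour2d` or lists of them).
#' @param env a `biplanar_environment`.
#' @param opts a [registration_options()].
#' @return An object of class `registration_result`: `final_pose`,
#'   `rms_residual` (mm, pooled over views), `per_view_residuals`,
#'   `iterations`, `converged`, `trace` (per-iteration pooled RMS).
#' @export
register_vertebra <- function(mesh, init, targets, env,
                              opts = registration_options()) {
  stopifnot(inherits(init, "rigid_transform"))
  best <- register_vertebra_once(mesh, init, targets, env, opts)
  if (best$rms_residual <= opts$restart_threshold || opts$restarts == 0)
    return(best)
  # likely wrong basin: retry from jittered starts, keep the best residual
  jit <- with_seed(opts$seed, lapply(seq_len(opts$restarts), function(k)
    list(omega = stats::runif(3, -1, 1) * .deg2rad(5),
         tr = stats::runif(3, -5, 5))))
  ctr0 <- as.numeric(apply_transform(init, mesh_centroid(mesh)))
  for (k in seq_len(opts$restarts)) {
    Rp <- axis_angle_matrix(jit[[k]]$omega)
    tp <- ctr0 - as.numeric(Rp %*% ctr0) + jit[[k]]$tr
    alt_init <- compose_transforms(rigid_transform(project_so3(Rp), tp), init)
    alt <- tryCatch(register_vertebra_once(mesh, alt_init, targets, env, opts),
                    error = function(e) NULL)
    if (!is.null(alt) && alt$rms_residual < best$rms_residual) best <- alt
    if (best$rms_residual <= opts$restart_threshold) break
  }
  best
}

register_vertebra_once <- function(mesh, init, targets, env, opts) {
  views <- list(frontal = env$frontal, sagittal = env$sagittal)
  for (nm in names(views))
    if (is.null(targets[[nm]]))
      stop("no target contours for the ", nm, " view",
           if (!is.null(mesh$label)) paste0(" (", mesh$label, ")") else "")
  tsamp <- lapply(views, function(v) {
    cl <- as_contour_list(targets[[v$name]])
    do.call(rbind, lapply(cl, function(cc)
      densify_contour(cc, opts$densify_step)$points))
  })
  adj <- mesh_edges(mesh)
  pose <- init
  lambda <- 1e-4
  trace <- numeric(0)
  cost_before <- numeric(0)
  cost_after <- numeric(0)
  per_view <- c(frontal = NA_real_, sagittal = NA_real_)
  rms_prev <- Inf
  converged <- FALSE
  it <- 0L
  w <- opts$view_weights
  while (it < opts$max_iterations) {
    it <- it + 1L
    # --- correspondences ---------------------------------------------------
    corr_X <- list(); corr_U <- list(); corr_w <- list()
    sq_by_view <- c(frontal = 0, sagittal = 0)
    n_by_view <- c(frontal = 0L, sagittal = 0L)
    for (nm in names(views)) {
      v <- views[[nm]]
      rim_local <- silhouette_rim_points(mesh, adj, pose, v,
                                         opts$edge_sample_step)
      rim_uv <- project_points(v, apply_transform(pose, rim_local))
      nn <- cpp_nn2d(tsamp[[nm]], rim_uv)
      keep <- nn$distance <= opts$correspondence_cap
      if (!any(keep))
        stop("no correspondences within the cap in the ", nm, " view")
      corr_X[[nm]] <- rim_local[nn$index[keep], , drop = FALSE]
      corr_U[[nm]] <- tsamp[[nm]][keep, , drop = FALSE]
      corr_w[[nm]] <- rep(w[nm], sum(keep))
      sq_by_view[nm] <- sum(nn$distance[keep]^2)
      n_by_view[nm] <- sum(keep)
    }
    per_view <- sqrt(sq_by_view / pmax(n_by_view, 1L))
    wsum <- sum(w[names(n_by_view)] * n_by_view)
    cost <- sum(w["frontal"] * sq_by_view["frontal"] +
                w["sagittal"] * sq_by_view["sagittal"])
    rms <- sqrt(cost / wsum)
    trace <- c(trace, rms)
    if (!is.finite(cost)) stop("non-finite registration cost")
    if (abs(rms_prev - rms) < opts$convergence_tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    # --- damped Gauss-Newton step on fixed correspondences -----------------
    step <- gn_step(pose, corr_X, corr_U, corr_w, views, lambda, cost)
    pose <- step$pose
    lambda <- step$lambda
    if (!is.null(step$cost_before)) {
      cost_before <- c(cost_before, step$cost_before)
      cost_after <- c(cost_after, step$cost_after)
    }
  }
  structure(list(final_pose = pose, rms_residual = trace[length(trace)],
                 per_view_residuals = per_view, iterations = it,
                 converged = converged, trace = trace,
                 step_cost_before = cost_before,
                 step_cost_after = cost_after,
                 label = mesh$label),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result%s> rms %.3f mm (frontal %.3f, sagittal %.3f), %d iterations, %sconverged\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$rms_residual, x$per_view_residuals["frontal"],
              x$per_view_residuals["sagittal"], x$iterations,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

# One damped Gauss-Newton update with retry on cost increase; residuals are
# numerically differentiated in the 6 increment parameters (axis-angle about
# the current correspondence centroid + translation).
gn_step <- function(pose, corr_X, corr_U, corr_w, views, lambda, cost0) {
  Xw <- lapply(names(views), function(nm)
    apply_transform(pose, corr_X[[nm]]))
  names(Xw) <- names(views)
  ctr <- colMeans(do.call(rbind, Xw))
  resid_fun <- function(delta) {
    Rd <- axis_angle_matrix(delta[1:3])
    r <- list()
    for (nm in names(views)) {
      Y <- sweep(sweep(Xw[[nm]], 2, ctr, "-") %*% t(Rd), 2,
                 ctr + delta[4:6], "+")
      p <- project_points(views[[nm]], Y)
      r[[nm]] <- sqrt(corr_w[[nm]]) * (p - corr_U[[nm]])
    }
    as.numeric(do.call(rbind, r))
  }
  r0 <- resid_fun(numeric(6))
  J <- matrix(0, length(r0), 6)
  h <- c(rep(1e-5, 3), rep(1e-3, 3))
  for (k in 1:6) {
    d <- numeric(6); d[k] <- h[k]
    J[, k] <- (resid_fun(d) - resid_fun(-d)) / (2 * h[k])
  }
  JtJ <- crossprod(J)
  g <- crossprod(J, r0)
  for (try in 1:8) {
    delta <- tryCatch(
      -solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), g),
      error = function(e) NULL)
    if (!is.null(delta)) {
      rn <- resid_fun(as.numeric(delta))
      if (sum(rn^2) <= sum(r0^2)) {
        Rd <- axis_angle_matrix(delta[1:3])
        Rn <- project_so3(Rd %*% pose$R)
        tn <- as.numeric(Rd %*% (pose$t - ctr)) + ctr + delta[4:6]
        return(list(pose = rigid_transform(Rn, tn),
                    lambda = max(lambda / 3, 1e-8),
                    cost_before = sum(r0^2), cost_after = sum(rn^2)))
      }
    }
    lambda <- lambda * 10
  }
  # no acceptable step found; keep the pose (counts as cost unchanged)
  list(pose = pose, lambda = lambda,
       cost_before = sum(r0^2), cost_after = sum(r0^2))
}

#' Register a whole spine model
#'
#' Runs [initialize_pose()] (or uses supplied initial poses) followed by
#' [register_vertebra()] independently for each of L1..L5 and S (the
#' method is rigid per vertebra); results are returned in anatomical
#' order.
#'
#' @param spine a `spine_model` holding the (supine) meshes; its poses are
#'   used as initial poses when `init = "poses"`.
#' @param targets named list per vertebral label, each a list with
#'   `frontal` and `sagittal` target contours.
#' @param env a `biplanar_environment`.
#' @param opts a [registration_options()].
#' @param init `"contours"` (coarse pose from the targets) or `"poses"`
#'   (start from the spine's stored poses).
#' @param init_jitter_deg,init_jitter_mm optional seeded jitter applied to
#'   every initial pose (sagittal rotation about the posed centroid and
#'   translation, uniform within the half-ranges); used to obtain
#'   independent repeat registrations in reproducibility experiments.
#' @param jitter_seed integer seed for the jitter draws.
#' @return named list of `registration_result`, L1..S.
#' @export
register_spine <- function(spine, targets, env, opts = registration_options(),
                           init = c("contours", "poses"),
                           init_jitter_deg = 0, init_jitter_mm = 0,
                           jitter_seed = NULL) {
  init <- match.arg(init)
  labs <- vertebra_labels()
  missing <- labs[!labs %in% names(targets)]
  if (length(missing) > 0)
    stop("missing target contours for: ", paste(missing, collapse = ", "))
  jit <- if (init_jitter_deg > 0 || init_jitter_mm > 0) {
    with_seed(jitter_seed, {
      stats::setNames(lapply(labs, function(l)
        list(ang = stats::runif(1, -init_jitter_deg, init_jitter_deg),
             tr = stats::runif(3, -init_jitter_mm, init_jitter_mm))), labs)
    })
  } else NULL
  out <- lapply(labs, function(l) {
    mesh <- spine$vertebrae[[l]]$mesh
    p0 <- if (init == "contours")
      tryCatch(initialize_pose(mesh, targets[[l]], env),
               error = function(e) stop(l, ": ", conditionMessage(e),
                                        call. = FALSE))
    else spine$vertebrae[[l]]$pose
    if (!is.null(jit)) {
      ctr <- as.numeric(apply_transform(p0, mesh_centroid(mesh)))
      Rp <- rot_x(jit[[l]]$ang)
      tp <- ctr - as.numeric(Rp %*% ctr) + jit[[l]]$tr
      p0 <- compose_transforms(rigid_transform(Rp, tp), p0)
    }
    tryCatch(register_vertebra(mesh, p0, targets[[l]], env, opts),
             error = function(e) stop(l, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  stats::setNames(out, labs)
}
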