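#' Environment calibration JSON
#'
#' A biplanar environment is stored as one JSON object with a `frontal`
#' and a `sagittal` view, each holding source position, detector origin,
#' detector axes `u`/`v`, pixel spacing, image size and the orthographic
#' flag (all geometry in mm).
#'
#' @param env a `biplanar_environment`.
#' @param path file path.
#' @export
write_environment_json <- function(env, path) {
  enc <- function(v) list(name = v$name, source = v$source,
                          detector_origin = v$origin, u = v$u, v = v$v,
                          pixel_spacing = v$pixel_spacing, size = v$size,
                          orthographic = v$orthographic)
  jsonlite::write_json(list(frontal = enc(env$frontal),
                            sagittal = enc(env$sagittal)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_environment_json
#' @export
read_environment_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(o) projection_view(o$name, o$source, o$detector_origin,
                                     o$u, o$v, o$pixel_spacing, o$size,
                                     isTRUE(o$orthographic))
  biplanar_environment(dec(obj$frontal), dec(obj$sagittal))
}

#' Radiograph image PNG I/O (16-bit grayscale)
#'
#' @param image a `radiograph_image` (pixels in [0, 1]).
#' @param path file path.
#' @param pixel_spacing,view metadata to attach on read.
#' @export
write_radiograph_png <- function(image, path) {
  px <- image$pixels
  px[px < 0] <- 0
  px[px > 1] <- 1
  png::writePNG(px, path, dpi = 25.4 / image$pixel_spacing)
  invisible(path)
}

#' @rdname write_radiograph_png
#' @export
read_radiograph_png <- function(path, pixel_spacing, view = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  radiograph_image(px, pixel_spacing, view)
}

#' Registered pose set JSON
#'
#' Named per-vertebra transforms, each as 9 row-major rotation entries
#' plus a 3-entry translation (mm).
#'
#' @param poses named list of `rigid_transform` (labels L1..S).
#' @param path file path.
#' @export
write_poses_json <- function(poses, path) {
  jsonlite::write_json(lapply(poses, function(p)
    list(rotation = as.numeric(t(p$R)), translation = as.numeric(p$t))),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_poses_json
#' @export
read_poses_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(o)
    rigid_transform(matrix(o$rotation, 3, 3, byrow = TRUE), o$translation))
}

#' Angle sets as a CSV table
#'
#' One row per case with columns `L1L2..L5S1` and `LL` (degrees, period
#' decimal separator, stable column order).
#'
#' @param angle_sets list of `angle_set` (optionally named by case).
#' @param path file path.
#' @export
write_angles_csv <- function(angle_sets, path) {
  df <- do.call(rbind, lapply(angle_sets, as.data.frame))
  df <- cbind(case = if (is.null(names(angle_sets)))
    seq_along(angle_sets) else names(angle_sets), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic case bundle to disk
#'
#' The on-disk layout of one case: per-vertebra STL meshes
#' (`<case>_<label>.stl`, supine/CT frame), `env.json`, per-view target
#' contour JSON, rendered standing radiograph PNGs, and the ground-truth
#' file (standing poses, supine poses, plan, seeds).
#'
#' @param case a case as produced by the validation experiment generator.
#' @param env a `biplanar_environment`.
#' @param dir output directory.
#' @param case_id identifier used in filenames.
#' @param render also render and store the standing radiographs.
#' @return `dir`, invisibly.
#' @export
write_case_bundle <- function(case, env, dir, case_id = "case", render = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in vertebra_labels()) {
    v <- case$supine$vertebrae[[l]]
    write_stl(apply_transform(v$pose, v$mesh),
              file.path(dir, sprintf("%s_%s.stl", case_id, l)))
  }
  write_environment_json(env, file.path(dir, "env.json"))
  tg <- case_targets(case, env, 0.5, 1)
  for (l in vertebra_labels())
    write_contours_json(c(as_contour_list(tg[[l]]$frontal),
                          as_contour_list(tg[[l]]$sagittal)),
                        file.path(dir, sprintf("%s_%s_contours.json",
                                               case_id, l)))
  write_poses_json(lapply(case$standing$vertebrae, `[[`, "pose"),
                   file.path(dir, sprintf("%s_standing_poses.json", case_id)))
  write_poses_json(lapply(case$supine$vertebrae, `[[`, "pose"),
                   file.path(dir, sprintf("%s_supine_poses.json", case_id)))
  jsonlite::write_json(list(seed = case$seed,
                            plan = case$plan$intersegmental_angles,
                            disc_heights = case$plan$disc_heights,
                            gt_LL = case$gt_angles$LL),
                       file.path(dir, sprintf("%s_ground_truth.json", case_id)),
                       digits = NA, auto_unbox = TRUE)
  if (render) {
    for (vn in c("frontal", "sagittal")) {
      img <- render_silhouette_radiograph(case$standing, env[[vn]])
      write_radiograph_png(img, file.path(dir, sprintf("%s_%s.png",
                                                       case_id, vn)))
    }
  }
  invisible(dir)
}
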