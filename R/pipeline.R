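# End-to-end pipeline: standardize -> landmarks -> initial alignment ->
# final alignment, plus the file-level entry points used by the command
# line script (inst/cli/osteoplate.R).

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: 40 mm distal crop, 2 mm
#' watershed margin, +/-30 degree rotation bounds and objective weights
#' (105, 100, 4, 5, 60).
#'
#' @param ... overrides, e.g. `place_config(z_cut = 35)`.
#' @return Named list of parameters.
#' @export
place_config <- function(...) {
  cfg <- list(z_cut = 40, area_factor = 4, z_band = 3, poly_degree = 3,
              slice_mm = 1, margin = 2, contact_tol = 0.05,
              weights = objective_weights(), rot_limit = 30, ftol = 1e-6,
              max_iter = 500)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) &&
      !inherits(over[[1]], "objective_weights") && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Place a plate on a bone
#'
#' Runs the four algorithm stages on already-loaded meshes.  Right-side
#' anatomy is mirrored onto the canonical left side on entry and all
#' outputs are mirrored back, so both sides share one code path.
#'
#' @param bone bone [tri_mesh()] with its two osteotomy cut faces meshed
#'   as conspicuously large triangles.
#' @param plate plate [tri_mesh()].
#' @param side `"left"` or `"right"`.
#' @param config a [place_config()] list.
#' @param verbose print stage progress.
#' @return Object of class `plate_placement` with the standardized bone,
#'   landmarks, initial placement, optimization result and the placed
#'   plate mesh (in the standardized bone frame, mirrored back for
#'   right-side input).
#' @export
place_plate <- function(bone, plate, side = c("left", "right"),
                        config = place_config(), verbose = FALSE) {
  side <- match.arg(side)
  config <- place_config(config)
  say <- function(...) if (verbose) message(...)
  mirrored <- side == "right"
  if (mirrored) {
    bone <- mirror_mesh(bone)
    plate <- mirror_mesh(plate)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  say("stage a: defining coordinate system")
  planes_raw <- stage("landmarks", detect_osteotomy_planes(
    bone, area_factor = config$area_factor))
  fr_bone <- stage("frame", standardize_bone(bone, planes_raw, side = "left"))
  bone_std <- fr_bone$mesh
  planes_std <- lapply(planes_raw, function(p) apply_frame(fr_bone, p))
  fr_plate <- stage("frame", standardize_plate(plate))
  plate_std <- fr_plate$mesh
  say("stage b: finding landmarks")
  bone_lm <- stage("landmarks", bone_landmarks(
    bone_std, planes_std, z_cut = config$z_cut, z_band = config$z_band,
    poly_degree = config$poly_degree, slice_mm = config$slice_mm))
  plate_lm <- stage("landmarks", plate_landmarks(plate_std))
  say("stage c: initial alignment")
  init <- stage("initial_alignment", initial_place(
    bone_lm, plate_lm, bone_std, plate_std, margin = config$margin,
    contact_tol = config$contact_tol))
  say("stage d: final alignment")
  final <- stage("final_alignment", optimize_pose(
    init, plate_std, plate_lm, bone_std, bone_lm,
    weights = config$weights, rot_limit = config$rot_limit,
    ftol = config$ftol, max_iter = config$max_iter))
  placed_std <- apply_pose(plate_std, final$pose)
  bone_out <- if (mirrored) mirror_mesh(bone_std) else bone_std
  placed_out <- if (mirrored) mirror_mesh(placed_std) else placed_std
  structure(list(side = side,
                 config = config,
                 bone_frame = fr_bone,
                 plate_frame = fr_plate,
                 bone_std = bone_std,
                 plate_std = plate_std,
                 bone_landmarks = bone_lm,
                 plate_landmarks = plate_lm,
                 initial = init,
                 final = final,
                 placed_plate_std = placed_std,
                 bone_out = bone_out,
                 placed_plate = placed_out),
            class = "plate_placement")
}

#' @export
print.plate_placement <- function(x, ...) {
  cat(sprintf("plate_placement (%s side)\n", x$side))
  cat(sprintf("  watershed margin: %.3f mm; initial contact: %.4f mm\n",
              x$initial$watershed_margin, x$initial$contact_distance))
  print(x$final)
  invisible(x)
}

.placement_report <- function(pl) {
  t <- pl$final$terms
  list(side = pl$side,
       initial_objective = pl$final$initial_objective,
       final_objective = pl$final$objective_value,
       converged = pl$final$converged,
       iterations = pl$final$iterations,
       terms = list(d_plate = t$d_plate, d_top = t$d_top,
                    d_bottom = t$d_bottom, M_penalty = t$M_penalty,
                    theta_penalty = t$theta_penalty, y_dev = t$y_dev),
       watershed_margin_mm = pl$initial$watershed_margin,
       initial_contact_mm = pl$initial$contact_distance,
       pose = list(rotation_deg = pl$final$pose$rotation,
                   translation_mm = pl$final$pose$translation,
                   center = pl$final$pose$center))
}

#' Run the placement pipeline on STL files
#'
#' Loads the bone and plate STLs, runs [place_plate()] and writes the
#' standardized bone, the placed plate and a report (`report.txt` plus a
#' machine-readable `report.json` holding the objective terms, penetration
#' count, watershed margin, convergence flag and final pose).
#'
#' @param bone_path,plate_path input STL paths.
#' @param side `"left"` or `"right"`.
#' @param out_dir output directory (created if missing).
#' @param config a [place_config()] list.
#' @param format STL output dialect.
#' @param verbose print stage progress.
#' @return The `plate_placement`, invisibly.
#' @export
run_place <- function(bone_path, plate_path, side = "left", out_dir = ".",
                      config = place_config(), format = "binary",
                      verbose = FALSE) {
  bone <- load_stl(bone_path)
  plate <- load_stl(plate_path)
  pl <- place_plate(bone, plate, side = side, config = config,
                    verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_stl(pl$bone_out, file.path(out_dir, "standardized_bone.stl"),
           format = format)
  save_stl(pl$placed_plate, file.path(out_dir, "placed_plate.stl"),
           format = format)
  rep <- .placement_report(pl)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(sprintf("osteoplate placement report (%s side)", pl$side),
           sprintf("initial objective : %.4f", rep$initial_objective),
           sprintf("final objective   : %.4f", rep$final_objective),
           sprintf("converged         : %s (%d iterations)",
                   rep$converged, rep$iterations),
           sprintf("penetration count : %d", rep$terms$M_penalty),
           sprintf("watershed margin  : %.3f mm", rep$watershed_margin_mm))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(pl)
}

#' Compare two placed plates from STL files
#'
#' Always reports the unpaired maximum Hausdorff distance; rotation and
#' translation differences are added when pose records (JSON files as
#' written by [run_place()]) are supplied.
#'
#' @param path_a,path_b placed plate STL paths.
#' @param pose_a,pose_b optional pose JSON paths.
#' @return A `comparison_metrics` object.
#' @export
run_compare <- function(path_a, path_b, pose_a = NULL, pose_b = NULL) {
  a <- load_stl(path_a)
  b <- load_stl(path_b)
  read_pose <- function(p) {
    if (is.null(p)) return(NULL)
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    if (!is.null(j$pose)) j <- j$pose
    rigid_pose(j$rotation_deg, j$translation_mm, j$center)
  }
  pa <- read_pose(pose_a)
  pb <- read_pose(pose_b)
  point <- if (!is.null(pa)) pa$center else c(0, 0, 0)
  m <- compare_placements(a, b, pa, pb, point = point)
  print(m)
  invisible(m)
}

#' Write a synthetic test case to disk
#'
#' @param out_dir output directory.
#' @param seed integer seed for [synth_case()].
#' @param resolution `"standard"` or `"coarse"`.
#' @param format STL dialect.
#' @return Invisibly, the generated case.
#' @export
run_synth <- function(out_dir = ".", seed = 1, resolution = "standard",
                      format = "binary") {
  case <- synth_case(seed, resolution = resolution)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_stl(case$bone$mesh, file.path(out_dir, "bone.stl"), format = format)
  save_stl(case$plate$mesh, file.path(out_dir, "plate.stl"), format = format)
  truth <- list(
    bone = list(
      distal_plane = list(point = case$bone$truth$planes$distal$point,
                          normal = case$bone$truth$planes$distal$normal),
      proximal_plane = list(point = case$bone$truth$planes$proximal$point,
                            normal = case$bone$truth$planes$proximal$normal),
      crest = as.data.frame(case$bone$truth$crest),
      styloid = case$bone$truth$styloid),
    plate = list(top_left = case$plate$truth$top_left,
                 top_right = case$plate$truth$top_right,
                 bottom = case$plate$truth$bottom))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(case)
}
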