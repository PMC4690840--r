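#' Pipeline configuration
#'
#' Describes a full run of the model-generation workflow: input segmentation
#' (file path or phantom spec), tag-role map, smoothing configuration, target
#' resolution, meshing and fiber options, output directory and seed. After
#' the tagged segmentation is provided (or generated), the workflow is fully
#' automatic.
#'
#' @param input path to a tagged label image, or a \code{\link{phantom_spec}}.
#' @param roles named list mapping roles (\code{lv_myo}, \code{rv_myo},
#'   \code{lv_pool}, \code{rv_pool}, \code{base}) to integer labels; defaults
#'   to the phantom convention 1..5.
#' @param smoothing a \code{\link{smoothing_config}}.
#' @param target_spacing output voxel spacing (mm); a value above the source
#'   spacing triggers a warning (downsampling), not an error.
#' @param mesh_tags labels to mesh (default: all nonzero).
#' @param fiber a \code{\link{fiber_config}}.
#' @param output_dir artifact directory.
#' @param seed integer seed for all randomness (phantom boundary noise).
#' @param log_level \code{"info"}, \code{"debug"} or \code{"quiet"}.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = phantom_spec(),
                            roles = list(lv_myo = 1L, rv_myo = 2L,
                                         lv_pool = 3L, rv_pool = 4L,
                                         base = 5L),
                            smoothing = smoothing_config(),
                            target_spacing = 0.5,
                            mesh_tags = NULL,
                            fiber = fiber_config(),
                            output_dir = tempfile("cardiomesh_"),
                            seed = 1L,
                            log_level = "info") {
  stopifnot(inherits(smoothing, "smoothing_config"),
            inherits(fiber, "fiber_config"),
            target_spacing > 0)
  required <- c("lv_myo", "lv_pool", "rv_myo", "rv_pool")
  missing <- setdiff(required, names(roles))
  if (length(missing) && !(identical(sort(missing), sort(c("rv_myo", "rv_pool")))))
    stop(sprintf(
      "tag-role map must cover derive_bc_surfaces roles; missing: %s",
      paste(missing, collapse = ", ")))
  structure(list(input = input, roles = roles, smoothing = smoothing,
                 target_spacing = target_spacing, mesh_tags = mesh_tags,
                 fiber = fiber, output_dir = output_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the \code{\link{pipeline_config}} arguments; the
#' \code{input} key is either a file path or a mapping of
#' \code{\link{phantom_spec}} fields, and \code{smoothing}/\code{fiber} are
#' mappings of the respective config fields.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (is.list(input)) input <- do.call(phantom_spec, input)
  args <- list(input = input)
  if (!is.null(y$roles)) args$roles <- lapply(y$roles, as.integer)
  if (!is.null(y$smoothing)) args$smoothing <- do.call(smoothing_config,
                                                       y$smoothing)
  if (!is.null(y$fiber)) args$fiber <- do.call(fiber_config, y$fiber)
  for (k in c("target_spacing", "mesh_tags", "output_dir", "seed",
              "log_level"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Run the full model-generation pipeline
#'
#' Executes extract -> smooth -> rasterize -> mesh -> tag surfaces -> fibers,
#' writing every stage's artifact to the output directory together with a
#' manifest (configuration, content hash, package version). Identical
#' configuration and seed give byte-identical CARP outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list (the model bundle): \code{image} (source),
#'   \code{surface} (smoothed \code{tagged_surface}),
#'   \code{smoothing_report}, \code{image_hi} (re-rasterized
#'   \code{label_image}), \code{mesh} (\code{tet_mesh}), \code{surfaces}
#'   (BC \code{face_set}s), \code{fibers} (\code{fiber_field}),
#'   \code{paths} (artifact files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_info <- function(...) if (config$log_level != "quiet")
    message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_info("[%s] done in %.1f s", name, proc.time()[3] - t0)
    out
  }
  paths <- list()

  image <- stage("input", {
    if (inherits(config$input, "phantom_spec")) {
      spec <- config$input
      spec$seed <- config$seed
      make_biventricular_phantom(spec)
    } else read_label_image(config$input)
  })
  paths$image <- file.path(config$output_dir, "segmentation.nii.gz")
  write_label_image(image, paths$image)
  if (config$target_spacing > min(image$spacing))
    warning("target_spacing is coarser than the source spacing (downsampling)")

  surf0 <- stage("extract-surfaces", extract_surfaces(image))
  paths$surface_raw <- file.path(config$output_dir, "surface_raw.vtk")
  write_vtk_surface(surf0, paths$surface_raw)

  sm <- stage("smooth", smooth_surface(surf0, image$spacing,
                                       config$smoothing))
  paths$surface <- file.path(config$output_dir, "surface_smoothed.vtk")
  write_vtk_surface(sm$surface, paths$surface)
  log_info("  max displacement: %.4f voxels",
           sm$report$max_displacement_voxels)

  image_hi <- stage("rasterize",
                    rasterize_surfaces(sm$surface, config$target_spacing))
  paths$image_hi <- file.path(config$output_dir, "segmentation_hi.nii.gz")
  write_label_image(image_hi, paths$image_hi)

  mesh <- stage("mesh", mesh_from_label_image(image_hi,
                                              tags = config$mesh_tags))
  log_info("  %d nodes, %d tetrahedra", nrow(mesh$nodes), nrow(mesh$tets))

  surfaces <- stage("tag-surfaces", derive_bc_surfaces(mesh, config$roles))
  for (nm in c("lv_endo", "rv_endo", "epi", "base")) {
    p <- file.path(config$output_dir, paste0(nm, ".surf"))
    write_carp_surf(surfaces[[nm]], p)
    paths[[nm]] <- p
  }

  fibers <- stage("fibers", assign_fibers(mesh, surfaces, config$fiber,
                                          myo_tags = c(config$roles$lv_myo,
                                                       config$roles$rv_myo)))
  base_mesh <- file.path(config$output_dir, "model")
  paths$carp <- write_carp_mesh(mesh, base_mesh, fibers = fibers)
  paths$vtu <- file.path(config$output_dir, "model.vtu")
  write_vtu_mesh(mesh, paths$vtu, fibers = fibers)

  cfgp <- file.path(config$output_dir, "config.json")
  cfg_json <- config
  cfg_json$input <- if (inherits(config$input, "phantom_spec"))
    unclass(config$input) else config$input
  cfg_json$smoothing <- unclass(cfg_json$smoothing)
  cfg_json$fiber <- unclass(cfg_json$fiber)
  jsonlite::write_json(unclass(cfg_json), cfgp, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "cardiomesh",
    version = as.character(utils::packageVersion("cardiomesh")),
    config_md5 = unname(tools::md5sum(cfgp)),
    seed = config$seed,
    artifacts = lapply(paths, basename),
    mesh = list(nodes = nrow(mesh$nodes), elements = nrow(mesh$tets)))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_info("pipeline finished in %.1f s", proc.time()[3] - t_all)

  invisible(list(image = image, surface = sm$surface,
                 smoothing_report = sm$report, image_hi = image_hi,
                 mesh = mesh, surfaces = surfaces, fibers = fibers,
                 paths = paths))
}

#' Run the invariant suite on a model bundle
#'
#' Re-checks the stage contracts on an existing bundle: closed per-tag
#' surfaces, box-constraint feasibility, mesh conformity and positivity,
#' disjointness and coverage of the BC surfaces, and fiber orthonormality.
#'
#' @param bundle result of \code{\link{run_pipeline}}.
#' @return \code{TRUE} invisibly; stops at the first violated invariant.
#' @export
check_bundle <- function(bundle) {
  check_surface_closed(bundle$surface, allow_degenerate = TRUE)
  check_mesh(bundle$mesh)
  s <- bundle$surfaces
  for (a in c("lv_endo", "rv_endo", "epi", "base"))
    for (b in setdiff(c("lv_endo", "rv_endo", "epi", "base"), a))
      if (nrow(face_set_op(s[[a]], s[[b]], "intersection")$faces))
        stop(sprintf("BC surfaces %s and %s overlap", a, b))
  fib <- bundle$fibers
  myo <- fib$myocardial
  for (v in list(fib$f[myo, ], fib$s[myo, ], fib$n[myo, ]))
    if (max(abs(row_norms(v) - 1)) > 1e-9) stop("non-unit fiber axes")
  if (max(abs(rowSums(fib$f[myo, ] * fib$s[myo, ]))) > 1e-9)
    stop("fiber/sheet axes not orthogonal")
  invisible(TRUE)
}
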