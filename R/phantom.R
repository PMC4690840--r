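#' Specification of a synthetic biventricular phantom
#'
#' Describes a tagged biventricular segmentation built from truncated
#' ellipsoidal shells with analytically known surfaces. The LV is a thick
#' ellipsoidal shell centered at the world origin; the RV is a second,
#' thinner shell whose overlap with the LV region is relabelled LV, producing
#' a fused crescent with a shared septal wall. Both are truncated by a flat
#' base plane normal to z (apex at the -z pole), and a one-voxel cap above
#' the cut carries the base tag.
#'
#' Default dimensions are a compact idealized biventricular geometry with a
#' clinically realistic wall-thickness-to-voxel ratio at 1 mm spacing.
#'
#' @param lv_outer_radii LV outer semi-axes (mm).
#' @param lv_wall_thickness LV wall thickness (mm).
#' @param rv_outer_radii RV outer semi-axes (mm), or \code{NULL} for an
#'   LV-only phantom.
#' @param rv_wall_thickness RV wall thickness (mm).
#' @param rv_center_offset RV center offset from the LV center (mm).
#' @param base_cut_height fraction of the long (z) axis retained, in (0, 1].
#' @param spacing isotropic voxel spacing (mm) or length-3 vector.
#' @param noise_probability per-boundary-voxel relabelling probability.
#' @param seed integer seed driving the boundary noise.
#' @param base_cap add a one-voxel layer with the base tag above the cut
#'   plane (default \code{TRUE}).
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(lv_outer_radii = c(16, 16, 26),
                         lv_wall_thickness = 5,
                         rv_outer_radii = c(14, 17, 22),
                         rv_wall_thickness = 3.5,
                         rv_center_offset = c(-12, 0, 3),
                         base_cut_height = 0.8,
                         spacing = 1,
                         noise_probability = 0,
                         seed = 1L,
                         base_cap = TRUE) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0),
            base_cut_height > 0, base_cut_height <= 1,
            noise_probability >= 0, noise_probability <= 1,
            lv_wall_thickness > 0, lv_wall_thickness < min(lv_outer_radii))
  if (!is.null(rv_outer_radii))
    stopifnot(rv_wall_thickness > 0,
              rv_wall_thickness < min(rv_outer_radii))
  structure(list(lv_outer_radii = lv_outer_radii,
                 lv_wall_thickness = lv_wall_thickness,
                 rv_outer_radii = rv_outer_radii,
                 rv_wall_thickness = rv_wall_thickness,
                 rv_center_offset = rv_center_offset,
                 base_cut_height = base_cut_height,
                 spacing = spacing,
                 noise_probability = noise_probability,
                 seed = as.integer(seed),
                 base_cap = isTRUE(base_cap)),
            class = "phantom_spec")
}

# Standard phantom tag table.
phantom_tags <- c("1" = "LV_myo", "2" = "RV_myo", "3" = "LV_pool",
                  "4" = "RV_pool", "5" = "base")

#' Generate a synthetic tagged biventricular segmentation
#'
#' Voxelizes the phantom described by \code{spec} onto an axis-aligned grid
#' (voxel centers classified against the analytic ellipsoids), applies the
#' base cut, optionally tags a one-voxel base cap, and finally applies
#' boundary noise if \code{spec$noise_probability > 0}. The result carries an
#' \code{"analytic"} attribute with exact signed-distance evaluators for every
#' analytic surface (for test use).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a \code{label_image} with labels 1 = LV_myo, 2 = RV_myo,
#'   3 = LV_pool, 4 = RV_pool, 5 = base cap.
#' @export
make_biventricular_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  if (spec$lv_wall_thickness < min(sp) / 2 ||
      (!is.null(spec$rv_outer_radii) && spec$rv_wall_thickness < min(sp) / 2))
    stop("shell not resolvable at the requested spacing")

  lv_out <- spec$lv_outer_radii
  lv_in <- lv_out - spec$lv_wall_thickness
  has_rv <- !is.null(spec$rv_outer_radii)
  lo <- -lv_out
  hi <- lv_out
  if (has_rv) {
    rv_out <- spec$rv_outer_radii
    rv_in <- rv_out - spec$rv_wall_thickness
    rv_c <- spec$rv_center_offset
    lo <- pmin(lo, rv_c - rv_out)
    hi <- pmax(hi, rv_c + rv_out)
  }
  z_cut <- -lv_out[3] + spec$base_cut_height * 2 * lv_out[3]
  hi[3] <- min(hi[3], z_cut + 2 * sp[3])
  lo <- lo - 2 * sp
  hi <- hi + 2 * sp
  dims <- pmax(ceiling((hi - lo) / sp), 1)
  origin <- lo

  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)

  in_ell <- function(cx, r) ((X - cx[1]) / r[1])^2 + ((Y - cx[2]) / r[2])^2 +
    ((Z - cx[3]) / r[3])^2 < 1
  lv_o <- in_ell(c(0, 0, 0), lv_out)
  lv_i <- in_ell(c(0, 0, 0), lv_in)

  lab <- array(0L, dim = dims)
  if (has_rv) {
    rv_o <- in_ell(rv_c, rv_out)
    rv_i <- in_ell(rv_c, rv_in)
    lab[rv_o & !rv_i] <- 2L
    lab[rv_i] <- 4L
  }
  lab[lv_o & !lv_i] <- 1L   # LV takes precedence: RV overlap relabelled
  lab[lv_i] <- 3L

  pre_cut <- lab != 0L
  lab[Z > z_cut] <- 0L
  if (spec$base_cap)
    lab[pre_cut & Z > z_cut & Z <= z_cut + sp[3]] <- 5L

  present <- as.character(sort(unique(lab[lab != 0L])))
  img <- label_image(lab, spacing = sp, origin = origin,
                     tags = phantom_tags[present])
  analytic <- list(
    lv_outer = list(type = "ellipsoid", center = c(0, 0, 0), radii = lv_out),
    lv_inner = list(type = "ellipsoid", center = c(0, 0, 0), radii = lv_in),
    base_plane_z = z_cut,
    spec = spec)
  if (has_rv) {
    analytic$rv_outer <- list(type = "ellipsoid", center = rv_c, radii = rv_out)
    analytic$rv_inner <- list(type = "ellipsoid", center = rv_c, radii = rv_in)
  }
  attr(img, "analytic") <- analytic
  if (spec$noise_probability > 0)
    img <- add_boundary_noise(img, spec$noise_probability, spec$seed)
  img
}

#' Signed distance to one of the phantom's analytic surfaces
#'
#' @param image a phantom \code{label_image} (carrying the \code{"analytic"}
#'   attribute) or the attribute itself.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param surface one of \code{"lv_outer"}, \code{"lv_inner"},
#'   \code{"rv_outer"}, \code{"rv_inner"}.
#' @return signed distances (mm), negative inside the ellipsoid.
#' @export
phantom_surface_distance <- function(image, points, surface = "lv_outer") {
  an <- if (inherits(image, "label_image")) attr(image, "analytic") else image
  if (is.null(an)) stop("no analytic surface metadata on this image")
  s <- an[[surface]]
  if (is.null(s)) stop(sprintf("no analytic surface '%s'", surface))
  ellipsoid_distance(points, s$radii, s$center)
}

# Analytic volume of the truncated LV myocardial shell (closed form).
phantom_lv_shell_volume <- function(spec) {
  lv_out <- spec$lv_outer_radii
  lv_in <- lv_out - spec$lv_wall_thickness
  z_cut <- -lv_out[3] + spec$base_cut_height * 2 * lv_out[3]
  ellipsoid_volume_below(lv_out, 0, z_cut) -
    ellipsoid_volume_below(lv_in, 0, z_cut)
}

#' Randomly perturb region boundaries of a label image
#'
#' Emulates segmentation staircase/jitter artifacts: every voxel that is
#' 6-adjacent to a differently-labelled voxel is, with probability \code{p},
#' reassigned the label of a uniformly chosen differing neighbor. All
#' reassignments are computed simultaneously from the input labels; interior
#' voxels are untouched. Deterministic given \code{seed}.
#'
#' @param image a \code{label_image}.
#' @param p per-boundary-voxel probability in [0, 1].
#' @param seed integer seed.
#' @return a \code{label_image} (analytic metadata, if any, is preserved).
#' @export
add_boundary_noise <- function(image, p, seed = 1L) {
  stopifnot(inherits(image, "label_image"), p >= 0, p <= 1)
  if (p == 0) return(image)
  v <- image$voxels
  d <- dim(v)
  n <- prod(d)
  # neighbor label arrays in the 6 axis directions; NA outside the grid
  shift <- function(arr, ax, by) {
    out <- array(NA_integer_, dim = d)
    if (d[ax] < 2L) return(out)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1L) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax]-1) }
    else { idx_dst[[ax]] <- 1:(d[ax]-1); idx_src[[ax]] <- 2:d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb <- matrix(NA_integer_, nrow = n, ncol = 6)
  k <- 0L
  for (ax in 1:3) for (by in c(1L, -1L)) {
    k <- k + 1L
    nb[, k] <- as.vector(shift(v, ax, by))
  }
  vv <- as.vector(v)
  differ <- nb != vv & !is.na(nb)
  ndiff <- rowSums(differ)
  boundary <- which(ndiff > 0L)
  if (!length(boundary)) return(image)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sel <- boundary[stats::runif(length(boundary)) < p]
  if (length(sel)) {
    pick <- ceiling(stats::runif(length(sel)) * ndiff[sel])
    cs <- differ[sel, , drop = FALSE] * 1L
    cs <- t(apply(cs, 1, cumsum))
    col <- max.col(cs == pick & differ[sel, , drop = FALSE], "first")
    vv[sel] <- nb[cbind(sel, col)]
  }
  out <- label_image(array(vv, dim = d), image$spacing, image$origin,
                     image$tags)
  attr(out, "analytic") <- attr(image, "analytic")
  out
}
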