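#' Configuration for constrained variational surface smoothing
#'
#' The smoothed surface minimizes the quadratic norm of the discrete surface
#' Laplacian of the vertex positions, subject to per-vertex box constraints:
#' no coordinate may move more than \code{box_halfwidth_voxels} times the
#' source voxel size from its initial position, keeping the result within the
#' margin of error of the segmentation.
#'
#' @param box_halfwidth_voxels box half-width in voxel units (default 0.5).
#' @param laplacian_kind \code{"uniform-graph"} (umbrella weights, default)
#'   or \code{"cotangent"}.
#' @param max_iterations iteration cap.
#' @param tolerance relative objective-decrease stopping tolerance.
#' @param solver \code{"projected-gradient"} (monotone accelerated projected
#'   gradient) or \code{"admm"}.
#' @param constraint \code{"box"} (axis-aligned, exact projection; default)
#'   or \code{"ball"} (Euclidean ball of the same radius, sensitivity
#'   variant).
#' @return an object of class \code{smoothing_config}.
#' @export
smoothing_config <- function(box_halfwidth_voxels = 0.5,
                             laplacian_kind = c("uniform-graph", "cotangent"),
                             max_iterations = 2000L,
                             tolerance = 1e-8,
                             solver = c("projected-gradient", "admm"),
                             constraint = c("box", "ball")) {
  box_halfwidth_voxels <- as.numeric(box_halfwidth_voxels)
  tolerance <- as.numeric(tolerance)
  stopifnot(box_halfwidth_voxels >= 0, tolerance > 0, max_iterations >= 1)
  structure(list(box_halfwidth_voxels = box_halfwidth_voxels,
                 laplacian_kind = match.arg(laplacian_kind),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 solver = match.arg(solver),
                 constraint = match.arg(constraint)),
            class = "smoothing_config")
}

#' Discrete Laplacian of a triangulated surface
#'
#' Uniform-graph ("umbrella") kind: row i encodes
#' \eqn{x_i - \mathrm{mean}(neighbors of i)}; rows sum to zero. Cotangent
#' kind: standard cotangent weights, normalized per row so the diagonal is 1.
#'
#' @param surface a \code{tagged_surface}.
#' @param kind \code{"uniform-graph"} or \code{"cotangent"}.
#' @return a sparse \code{dgCMatrix}.
#' @export
build_surface_laplacian <- function(surface,
                                    kind = c("uniform-graph", "cotangent")) {
  kind <- match.arg(kind)
  n <- nrow(surface$vertices)
  f <- surface$faces
  ii <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  jj <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  if (kind == "uniform-graph") {
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    A@x <- rep(1, length(A@x))  # collapse duplicate edge entries to weight 1
    deg <- Matrix::rowSums(A)
    if (any(deg == 0)) stop("isolated vertex (no neighbors)")
    Matrix::Diagonal(n) - Matrix::Diagonal(n, 1 / deg) %*% A
  } else {
    V <- surface$vertices
    cot_at <- function(p, q, r) {
      # cotangent of the angle at p in triangle (p,q,r)
      u <- V[q, , drop = FALSE] - V[p, , drop = FALSE]
      v <- V[r, , drop = FALSE] - V[p, , drop = FALSE]
      rowSums(u * v) / pmax(row_norms(cross_rows(u, v)), 1e-300)
    }
    # edge (a,b) opposite vertex c in each face
    wi <- c(f[, 1], f[, 2], f[, 3])
    wj <- c(f[, 2], f[, 3], f[, 1])
    w <- c(cot_at(f[, 3], f[, 1], f[, 2]),
           cot_at(f[, 1], f[, 2], f[, 3]),
           cot_at(f[, 2], f[, 3], f[, 1])) / 2
    W <- Matrix::sparseMatrix(i = c(wi, wj), j = c(wj, wi), x = c(w, w),
                              dims = c(n, n))
    rs <- Matrix::rowSums(W)
    if (any(rs <= 0)) stop("degenerate cotangent weights (isolated vertex?)")
    Matrix::Diagonal(n) - Matrix::Diagonal(n, 1 / rs) %*% W
  }
}

#' Smooth a tagged surface under half-voxel displacement constraints
#'
#' Minimizes \eqn{\|L X\|^2} over vertex positions \eqn{X}, subject to
#' \eqn{|X_{ia} - X^0_{ia}| \le h_a} per vertex and axis, where \eqn{h_a}
#' is \code{box_halfwidth_voxels} times the source voxel size along axis a.
#' Connectivity and face labels are unchanged; the constraint is enforced
#' exactly (projection is the last step of every iteration).
#'
#' @param surface a \code{tagged_surface}.
#' @param voxel_size source voxel size in mm (scalar or per-axis length 3);
#'   defaults to the spacing recorded in the surface metadata.
#' @param config a \code{\link{smoothing_config}}.
#' @return list with elements \code{surface} (smoothed) and \code{report}
#'   (class \code{smoothing_report}: objectives, iterations, max displacement
#'   in voxel units, convergence flag).
#' @export
smooth_surface <- function(surface, voxel_size = NULL,
                           config = smoothing_config()) {
  stopifnot(inherits(surface, "tagged_surface"))
  if (is.null(voxel_size)) {
    if (is.null(surface$meta$spacing))
      stop("voxel_size not given and no spacing in surface metadata")
    voxel_size <- surface$meta$spacing
  }
  h <- rep_len(voxel_size, 3L) * config$box_halfwidth_voxels
  X0 <- surface$vertices
  L <- build_surface_laplacian(surface, config$laplacian_kind)
  obj <- function(X) sum((L %*% X)@x^2)
  f0 <- obj(X0)

  if (all(h == 0) || f0 == 0) {
    rep_ <- smoothing_report(f0, f0, 0L, 0, TRUE)
    return(list(surface = surface, report = rep_))
  }

  if (config$solver == "projected-gradient") {
    res <- solve_pg(L, X0, h, config, f0, ball = config$constraint == "ball")
  } else {
    res <- solve_admm(L, X0, h, config, f0, ball = config$constraint == "ball")
  }
  X <- res$X
  disp <- abs(X - X0)
  maxd <- max(sweep(disp, 2, rep_len(voxel_size, 3L), "/"))
  out <- surface
  out$vertices <- X
  list(surface = out,
       report = smoothing_report(f0, obj(X), res$iter, maxd, res$converged))
}

smoothing_report <- function(f0, f1, iter, maxd, converged) {
  structure(list(initial_objective = f0, final_objective = f1,
                 iterations_used = iter, max_displacement_voxels = maxd,
                 converged = converged),
            class = "smoothing_report")
}

#' @export
print.smoothing_report <- function(x, ...) {
  cat(sprintf(paste0("smoothing_report: objective %.6g -> %.6g in %d",
                     " iterations\n  max displacement %.4g voxels%s\n"),
              x$initial_objective, x$final_objective, x$iterations_used,
              x$max_displacement_voxels,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

project_feasible <- function(X, X0, h, ball) {
  if (!ball) {
    pmin(pmax(X, sweep(X0, 2, h, "-")), sweep(X0, 2, h, "+"))
  } else {
    r <- min(h)
    D <- X - X0
    nn <- row_norms(D)
    f <- pmin(1, r / pmax(nn, 1e-300))
    X0 + D * f
  }
}

# Monotone accelerated projected gradient (FISTA step with fallback to the
# plain projected-gradient iterate whenever the accelerated candidate would
# increase the objective), step size from a power-iteration estimate of
# ||L||_2^2.
solve_pg <- function(L, X0, h, config, f0, ball = FALSE) {
  Lt <- Matrix::t(L)
  obj <- function(X) {
    Y <- L %*% X
    sum(Y@x^2)
  }
  grad <- function(X) 2 * as.matrix(Lt %*% (L %*% X))
  # power iteration on L'L
  v <- rep(1, nrow(X0)) + seq_len(nrow(X0)) / nrow(X0)
  v <- v / sqrt(sum(v^2))
  for (i in 1:60) {
    v <- as.vector(Lt %*% (L %*% v))
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  lip <- 2 * max(nv, 1e-12) * 1.02
  step <- 1 / lip

  X <- X0
  Yk <- X0
  tk <- 1
  fprev <- f0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    cand <- project_feasible(Yk - step * grad(Yk), X0, h, ball)
    fc <- obj(cand)
    if (fc > fprev) {  # monotone safeguard: plain PG step from X
      cand <- project_feasible(X - step * grad(X), X0, h, ball)
      fc <- obj(cand)
      tk <- 1
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Yk <- cand + ((tk - 1) / tk1) * (cand - X)
    tk <- tk1
    reldec <- (fprev - fc) / max(fprev, 1e-300)
    X <- cand
    if (fc <= fprev && reldec < config$tolerance) {
      fprev <- fc
      converged <- TRUE
      break
    }
    fprev <- fc
  }
  if (!converged)
    warning("smoothing did not converge within max_iterations; returning best iterate")
  list(X = X, iter = iter, converged = converged)
}

# ADMM on  min ||L x||^2 + I_box(z)  s.t. x = z  (per coordinate axis; the
# quadratic is axis-separable, and the linear system matrix is shared).
solve_admm <- function(L, X0, h, config, f0, ball = FALSE) {
  n <- nrow(X0)
  rho <- 1
  M <- 2 * Matrix::crossprod(L) + rho * Matrix::Diagonal(n)
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(M), "CsparseMatrix"))
  Z <- X0
  U <- matrix(0, n, 3)
  obj <- function(X) sum((L %*% X)@x^2)
  fprev <- f0
  converged <- FALSE
  iter <- 0L
  Xbest <- X0
  fbest <- f0
  for (iter in seq_len(config$max_iterations)) {
    X <- as.matrix(Matrix::solve(ch, rho * (Z - U)))
    Z <- project_feasible(X + U, X0, h, ball)
    U <- U + X - Z
    fc <- obj(Z)  # feasible iterate
    if (fc <= fbest) { fbest <- fc; Xbest <- Z }
    reldec <- abs(fprev - fc) / max(fprev, 1e-300)
    prim <- sqrt(sum((X - Z)^2)) / sqrt(n)
    if (iter > 5 && reldec < config$tolerance && prim < 1e-8) {
      converged <- TRUE
      break
    }
    fprev <- fc
  }
  if (!converged)
    warning("smoothing (ADMM) did not converge within max_iterations")
  list(X = Xbest, iter = iter, converged = converged)
}
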