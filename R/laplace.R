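# Linear (P1) tetrahedral finite elements for the Laplace-Dirichlet problems
# underlying transmural/apicobasal coordinates and the fiber rule.

# Per-element shape-function gradients and volumes.
# Returns list(grad = list of 4 m x 3 matrices, vol = m-vector).
p1_gradients <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  p1 <- n[t[, 1], , drop = FALSE]; p2 <- n[t[, 2], , drop = FALSE]
  p3 <- n[t[, 3], , drop = FALSE]; p4 <- n[t[, 4], , drop = FALSE]
  # grad lambda_i = N_i / (6V) with N_i the inward-scaled normal of the
  # opposite face; signs chosen so that sum_i grad lambda_i = 0.
  d <- rowSums((p2 - p1) * cross_rows(p3 - p1, p4 - p1))  # 6V
  g2 <- cross_rows(p3 - p1, p4 - p1) / d
  g3 <- cross_rows(p4 - p1, p2 - p1) / d
  g4 <- cross_rows(p2 - p1, p3 - p1) / d
  g1 <- -(g2 + g3 + g4)
  list(grad = list(g1, g2, g3, g4), vol = d / 6)
}

# Assemble the P1 stiffness matrix K_ij = int grad phi_i . grad phi_j.
assemble_stiffness <- function(mesh, geo = NULL) {
  if (is.null(geo)) geo <- p1_gradients(mesh)
  t <- mesh$tets
  m <- nrow(t)
  nn <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 16)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- t[, a]
    jj[[k]] <- t[, b]
    xx[[k]] <- rowSums(geo$grad[[a]] * geo$grad[[b]]) * geo$vol
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nn, nn))
}

# Jacobi-preconditioned conjugate gradient for SPD sparse systems.
cg_solve <- function(A, b, tol = 1e-10, maxit = 20000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b * b))
  if (bn == 0) return(list(x = x, iter = 0L, relres = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r * r))
    if (rn / bn <= tol) return(list(x = x, iter = it, relres = rn / bn))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning(sprintf("CG did not reach tol %g (relres %g)", tol, rn / bn))
  list(x = x, iter = maxit, relres = rn / bn)
}

# Normalize a Dirichlet specification into (node index, value) vectors.
# dirichlet: list of list(nodes=|faces=face_set, value=scalar or per-node).
dirichlet_nodes <- function(mesh, dirichlet) {
  nodes <- integer(0)
  vals <- numeric(0)
  for (dc in dirichlet) {
    nd <- if (inherits(dc[[1]], "face_set")) face_set_nodes(dc[[1]])
          else as.integer(dc[[1]])
    v <- rep_len(as.numeric(dc$value), length(nd))
    nodes <- c(nodes, nd)
    vals <- c(vals, v)
  }
  if (anyDuplicated(nodes)) {
    agg <- tapply(vals, nodes, function(v) {
      if (max(v) - min(v) > 1e-12)
        stop("non-disjoint Dirichlet sets with conflicting values")
      v[1]
    })
    nodes <- as.integer(names(agg))
    vals <- as.numeric(agg)
  }
  o <- order(nodes)
  list(nodes = nodes[o], values = vals[o])
}

#' Solve a Laplace-Dirichlet problem on a tetrahedral mesh
#'
#' Linear tetrahedral finite-element solution of \eqn{\nabla^2 u = 0} with
#' prescribed nodal boundary values, solved by Jacobi-preconditioned
#' conjugate gradients to relative residual \code{tol}. The discrete
#' maximum principle is checked: nodal values outside the Dirichlet range by
#' more than \code{1e-8} raise a warning.
#'
#' @param mesh a \code{tet_mesh} (typically a myocardial \code{\link{submesh}}).
#' @param dirichlet list of boundary conditions, each a list whose first
#'   element is a \code{face_set} or an integer node vector and whose
#'   \code{value} is a scalar or per-node vector.
#' @param tol relative residual tolerance.
#' @param stiffness optional precomputed stiffness matrix (reused across
#'   fields on the same mesh).
#' @return an object of class \code{laplace_field}: list with \code{values}
#'   (nodal), \code{dirichlet} (nodes, values), \code{relres}, \code{iter}.
#' @export
solve_laplace <- function(mesh, dirichlet, tol = 1e-10, stiffness = NULL) {
  bc <- dirichlet_nodes(mesh, dirichlet)
  if (!length(bc$nodes)) stop("singular system: no Dirichlet nodes")
  nn <- nrow(mesh$nodes)
  K <- if (is.null(stiffness)) assemble_stiffness(mesh) else stiffness
  u <- numeric(nn)
  u[bc$nodes] <- bc$values
  free <- setdiff(seq_len(nn), bc$nodes)
  if (length(unique(bc$values)) == 1L) {
    u[free] <- bc$values[1]  # constant solution, exactly
    res <- list(iter = 0L, relres = 0)
  } else {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -as.vector(K[free, bc$nodes, drop = FALSE] %*% bc$values)
    res <- cg_solve(Kff, rhs, tol = tol)
    u[free] <- res$x
  }
  lo <- min(bc$values); hi <- max(bc$values)
  if (min(u) < lo - 1e-8 || max(u) > hi + 1e-8)
    warning("discrete maximum principle violated on this mesh")
  structure(list(values = u, dirichlet = bc,
                 relres = res$relres, iter = res$iter),
            class = "laplace_field")
}

#' @export
print.laplace_field <- function(x, ...) {
  cat(sprintf(paste0("laplace_field: %d nodes (%d Dirichlet), range ",
                     "[%.4g, %.4g]\n  CG iterations %d, relative residual %.2e\n"),
              length(x$values), length(x$dirichlet$nodes), min(x$values),
              max(x$values), x$iter, x$relres))
  invisible(x)
}

# Per-element constant gradient of a nodal field.
element_gradients <- function(mesh, values, geo = NULL) {
  if (is.null(geo)) geo <- p1_gradients(mesh)
  t <- mesh$tets
  g <- geo$grad[[1]] * values[t[, 1]] + geo$grad[[2]] * values[t[, 2]] +
    geo$grad[[3]] * values[t[, 3]] + geo$grad[[4]] * values[t[, 4]]
  g
}

# Per-element mean of a nodal field.
element_means <- function(mesh, values) {
  t <- mesh$tets
  (values[t[, 1]] + values[t[, 2]] + values[t[, 3]] + values[t[, 4]]) / 4
}
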