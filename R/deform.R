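# SR-ARAP (smoothed-rotation as-rigid-as-possible) non-rigid deformation:
# cotangent edge weights, the deformation energy, and the alternating
# local/global minimizer with hard positional constraints.

#' Cotangent edge weights of a triangle mesh
#'
#' For an interior edge the weight is `cot(theta_A) + cot(theta_B)` where
#' `theta_A`, `theta_B` are the angles opposite the edge in its two incident
#' triangles; a boundary edge uses its single opposite angle. Non-positive
#' totals are clamped to `1e-6` so the Laplacian stays positive definite;
#' zero-area triangles contribute nothing (with a warning).
#'
#' @param mesh a [surface_mesh()].
#' @return A list with `edges` (m x 2, 1-based, first column smaller) and
#'   `weights` (length m).
#' @export
cotangent_weights <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  Tr <- mesh$triangles
  V <- mesh$vertices
  lo <- integer(0); hi <- integer(0); ct <- numeric(0)
  warned <- FALSE
  for (s in 1:3) {
    # edge (a, b) opposite vertex c
    a <- Tr[, s]; b <- Tr[, s %% 3 + 1]; c <- Tr[, (s + 1) %% 3 + 1]
    u <- V[a, , drop = FALSE] - V[c, , drop = FALSE]
    w <- V[b, , drop = FALSE] - V[c, , drop = FALSE]
    dotp <- rowSums(u * w)
    crossn <- sqrt(pmax(0,
      (u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
      (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
      (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
    zero_area <- crossn < 1e-14
    if (any(zero_area) && !warned) {
      warning("zero-area triangles excluded from cotangent weights")
      warned <- TRUE
    }
    cotv <- ifelse(zero_area, 0, dotp / pmax(crossn, 1e-300))
    lo <- c(lo, pmin(a, b)); hi <- c(hi, pmax(a, b)); ct <- c(ct, cotv)
  }
  key <- paste(lo, hi)
  first <- !duplicated(key)
  wsum <- as.numeric(rowsum(ct, factor(key, levels = key[first]),
                            reorder = FALSE))
  list(edges = cbind(lo[first], hi[first]), weights = pmax(wsum, 1e-6))
}

#' Define an SR-ARAP deformation problem
#'
#' @param mesh source [surface_mesh()] `S`.
#' @param constraint_idx indices of control vertices (>= 1 of them).
#' @param constraint_pos k x 3 matrix of target positions (metres).
#' @param alpha scalar weight of the rotation-smoothness term; multiplied by
#'   the total surface area `A` (recomputed per call) so the term is
#'   invariant to global scaling.
#' @param max_iterations cap on local/global iterations.
#' @param tolerance absolute energy value below which iteration stops;
#'   `NULL` means `1e-6` times the initial energy.
#' @return An object of class `deformation_problem`.
#' @export
deformation_problem <- function(mesh, constraint_idx, constraint_pos,
                                alpha = 0.01, max_iterations = 20,
                                tolerance = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), length(constraint_idx) >= 1)
  constraint_pos <- matrix(as.numeric(constraint_pos), ncol = 3)
  stopifnot(nrow(constraint_pos) == length(constraint_idx),
            all(constraint_idx >= 1),
            all(constraint_idx <= nrow(mesh$vertices)))
  A <- mesh_area(mesh)
  if (A <= 0) stop("source surface must have positive area")
  structure(
    list(S = mesh, constraint_idx = as.integer(constraint_idx),
         constraint_pos = constraint_pos, alpha = alpha, area = A,
         max_iterations = as.integer(max_iterations), tolerance = tolerance),
    class = "deformation_problem"
  )
}

#' SR-ARAP deformation energy
#'
#' `E(S') = sum_i sum_{j in N(i)} [ w_ij ||(v'_i - v'_j) - R_i (v_i - v_j)||^2
#'  + alpha A ||R_i - R_j||_F^2 ]`, with the rotation-smoothness term inside
#' the double sum (per directed edge) and the Frobenius norm on rotation
#' differences.
#'
#' @param problem a [deformation_problem()].
#' @param S_prime n x 3 matrix of deformed vertex positions.
#' @param rotations 3 x 3 x n array of per-vertex rotations.
#' @return The (non-negative) energy value.
#' @export
srarap_energy <- function(problem, S_prime, rotations) {
  stopifnot(inherits(problem, "deformation_problem"))
  V <- problem$S$vertices
  S_prime <- matrix(as.numeric(S_prime), ncol = 3)
  if (nrow(S_prime) != nrow(V)) stop("S_prime must match the source vertex count")
  cw <- cotangent_weights(problem$S)
  aA <- problem$alpha * problem$area
  E <- 0
  for (dir in 1:2) {
    i <- cw$edges[, dir]; j <- cw$edges[, 3 - dir]
    e <- V[i, , drop = FALSE] - V[j, , drop = FALSE]
    ep <- S_prime[i, , drop = FALSE] - S_prime[j, , drop = FALSE]
    for (r in seq_along(i)) {
      Ri <- rotations[, , i[r]]
      resid <- ep[r, ] - as.numeric(Ri %*% e[r, ])
      E <- E + cw$weights[r] * sum(resid^2) +
        aA * sum((Ri - rotations[, , j[r]])^2)
    }
  }
  E
}

# closest rotation (polar factor) to M, det +1
.polar_rotation <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  R
}

#' Solve an SR-ARAP deformation
#'
#' Alternates a LOCAL step — per-vertex optimal rotations via the
#' orthogonal-Procrustes solution on the weighted 1-ring, with the
#' rotation-smoothness coupling handled by a Gauss-Seidel sweep that adds
#' the neighbors' current rotations to the cross-covariance before
#' re-projection onto SO(3) — and a GLOBAL step solving the sparse
#' cotangent-Laplacian system for the free vertex positions with control
#' vertices eliminated (hard constraints). Both half-steps are exact
#' coordinate minimizers, so the energy trace is non-increasing. Iteration
#' stops at `max_iterations` or when the energy falls below the tolerance.
#'
#' @param problem a [deformation_problem()].
#' @return An object of class `deformation_result`: `S_prime` (deformed
#'   [surface_mesh()]), `rotations` (3 x 3 x n), `energy_trace`.
#' @export
deform <- function(problem) {
  stopifnot(inherits(problem, "deformation_problem"))
  V <- problem$S$vertices
  n <- nrow(V)
  cidx <- problem$constraint_idx
  cpos <- problem$constraint_pos
  cw <- cotangent_weights(problem$S)
  aA <- problem$alpha * problem$area

  # adjacency with weights
  ii <- c(cw$edges[, 1], cw$edges[, 2])
  jj <- c(cw$edges[, 2], cw$edges[, 1])
  ww <- c(cw$weights, cw$weights)
  nbr_raw <- split(seq_along(ii), ii)       # directed-edge slots per vertex
  nbr <- vector("list", n)
  nbr[as.integer(names(nbr_raw))] <- nbr_raw
  deg_rs <- rowsum(ww, group = ii)
  deg <- numeric(n)
  deg[as.integer(rownames(deg_rs))] <- deg_rs

  # disconnected free components: solve only components holding a constraint
  comp <- mesh_components(problem$S)
  con_comp <- unique(comp[cidx])
  orphan <- which(!(comp %in% con_comp))
  if (length(orphan) > 0)
    warning("mesh has components without constraints; they are translated ",
            "rigidly with their nearest constrained component")

  solved <- setdiff(seq_len(n), orphan)
  free <- setdiff(solved, cidx)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = -ww, dims = c(n, n)) +
    Matrix::Diagonal(n, x = deg)
  Lff <- L[free, free, drop = FALSE]
  Lfc <- L[free, cidx, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lff), LDL = FALSE, perm = TRUE)

  Vp <- V
  Vp[cidx, ] <- cpos
  R <- array(rep(diag(3), n), dim = c(3, 3, n))
  Rflat <- matrix(rep(as.numeric(diag(3)), each = n), n, 9)

  # directed edge vectors and the reverse-slot map (slot s = (i, j); its
  # reverse holds -e and lets R_j e_ij be reused from vertex j's products)
  m2 <- length(cw$weights)
  eDir <- V[ii, , drop = FALSE] - V[jj, , drop = FALSE]
  rev_slot <- c(seq_len(m2) + m2, seq_len(m2))
  slots_of <- nbr

  # REdir[s, ] = R_{ii[s]} %*% eDir[s, ]
  re_dir <- function() {
    out <- matrix(0, 2 * m2, 3)
    for (v in solved) {
      sl <- slots_of[[v]]
      if (is.null(sl)) next
      out[sl, ] <- eDir[sl, , drop = FALSE] %*% t(matrix(Rflat[v, ], 3, 3))
    }
    out
  }

  energy <- function(REdir) {
    epDir <- Vp[ii, , drop = FALSE] - Vp[jj, , drop = FALSE]
    rot_diff <- rowSums((Rflat[ii, , drop = FALSE] -
                           Rflat[jj, , drop = FALSE])^2)
    sum(ww * rowSums((epDir - REdir)^2)) + aA * sum(rot_diff)
  }

  REdir <- re_dir()
  E0 <- energy(REdir)
  tol <- if (is.null(problem$tolerance)) 1e-6 * E0 else problem$tolerance
  trace <- numeric(0)
  for (iter in seq_len(problem$max_iterations)) {
    # LOCAL: Gauss-Seidel over vertices (each update is the exact coordinate
    # minimizer, so the sweep cannot increase the energy)
    for (v in solved) {
      sl <- slots_of[[v]]
      if (is.null(sl)) next
      js <- jj[sl]
      e <- eDir[sl, , drop = FALSE]
      ep <- t(Vp[v, ] - t(Vp[js, , drop = FALSE]))
      M <- crossprod(ep * ww[sl], e)                # sum w e' e^T
      M <- M + 2 * aA * matrix(colSums(Rflat[js, , drop = FALSE]), 3, 3)
      Rv <- .polar_rotation(M)
      R[, , v] <- Rv
      Rflat[v, ] <- as.numeric(Rv)
    }
    REdir <- re_dir()
    # GLOBAL: rhs_i = sum_j w_ij (R_i + R_j)/2 (v_i - v_j)
    contrib <- ww / 2 * (REdir - REdir[rev_slot, , drop = FALSE])
    rs <- rowsum(contrib, group = ii)
    rhs <- matrix(0, n, 3)
    rhs[as.integer(rownames(rs)), ] <- rs
    if (length(free) > 0) {
      b <- rhs[free, , drop = FALSE] - as.matrix(Lfc %*% cpos)
      Vp[free, ] <- as.matrix(Matrix::solve(ch, b))
    }
    Vp[cidx, ] <- cpos
    trace <- c(trace, energy(REdir))
    if (trace[iter] < tol) break
  }

  # orphan components ride along with their nearest constrained component
  if (length(orphan) > 0 && length(solved) > 0) {
    kn <- knn_search(V[solved, , drop = FALSE], V[orphan, , drop = FALSE], k = 1)
    near <- solved[kn$idx[, 1]]
    Vp[orphan, ] <- V[orphan, , drop = FALSE] +
      (Vp[near, , drop = FALSE] - V[near, , drop = FALSE])
  }

  structure(
    list(S_prime = surface_mesh(Vp, problem$S$triangles),
         rotations = R, energy_trace = trace),
    class = "deformation_result"
  )
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf("<deformation_result: %d vertices, %d iterations, final E=%.3g>\n",
              nrow(x$S_prime$vertices), length(x$energy_trace),
              if (length(x$energy_trace)) x$energy_trace[length(x$energy_trace)]
              else NA_real_))
  invisible(x)
}

#' Propagate matched keypoint targets onto the model surface
#'
#' Each matched model-graph keypoint `k` drives the source-surface vertex it
#' is mapped to (`source_map[k]`); the control target is that vertex
#' displaced by the keypoint's matched displacement (input keypoint position
#' minus model keypoint position). Only surface vertices that are mapped
#' images of matched keypoints become control vertices; duplicates keep the
#' first (best-ordered) match.
#'
#' @param surface the model [surface_mesh()] to be deformed.
#' @param model_graph,input_graph deformation graphs of the model and input
#'   surfaces.
#' @param matches result of [match_bidirectional()].
#' @return A list with `idx` (control vertex indices) and `pos` (targets).
#' @export
propagate_constraints <- function(surface, model_graph, input_graph, matches) {
  if (nrow(matches) == 0)
    return(list(idx = integer(0), pos = matrix(0, 0, 3)))
  k <- matches$model_keypoint
  sv <- model_graph$source_map[k]
  disp <- input_graph$graph_mesh$vertices[matches$input_keypoint, , drop = FALSE] -
    model_graph$graph_mesh$vertices[k, , drop = FALSE]
  keep <- !duplicated(sv)
  idx <- sv[keep]
  list(idx = idx,
       pos = surface$vertices[idx, , drop = FALSE] + disp[keep, , drop = FALSE])
}
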