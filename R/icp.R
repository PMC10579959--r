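#' ICP iteration controls
#'
#' All the iteration/convergence/correspondence knobs of the iterative closest
#' point registration. Stage one of the two-stage pipeline uses the defaults;
#' stage two caps `max_iterations` at 3 so it can only refine the previous
#' alignment.
#'
#' @param max_iterations maximum ICP iterations (>= 1).
#' @param rmse_rel_tolerance relative change in point-to-plane RMSE below
#'   which the iteration is declared converged.
#' @param rejection_distance_factor correspondences farther than this multiple
#'   of the median correspondence distance are discarded (> 1); robustifies
#'   against partial EAM coverage.
#' @param min_correspondences minimum surviving pairs; fewer signals
#'   non-overlapping clouds.
#' @param init_strategy `"identity"`, `"centroid"` (translation aligning the
#'   centroids, the default) or `"centroid_pca"` (principal axes, sign
#'   combination chosen by lowest initial RMSE, for arbitrary frames).
#' @return An object of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 50L, rmse_rel_tolerance = 1e-4,
                       rejection_distance_factor = 3,
                       min_correspondences = 6L,
                       init_strategy = c("centroid", "identity", "centroid_pca")) {
  init_strategy <- match.arg(init_strategy)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1")
  if (rmse_rel_tolerance <= 0) stop("`rmse_rel_tolerance` must be > 0")
  if (rejection_distance_factor <= 1)
    stop("`rejection_distance_factor` must be > 1")
  structure(list(max_iterations = max_iterations,
                 rmse_rel_tolerance = rmse_rel_tolerance,
                 rejection_distance_factor = rejection_distance_factor,
                 min_correspondences = as.integer(min_correspondences),
                 init_strategy = init_strategy),
            class = "icp_config")
}

#' Closest-point correspondences with median-distance outlier rejection
#'
#' For every moving point, finds its nearest fixed point through an exact
#' grid-accelerated search, then discards pairs farther than
#' `rejection_distance_factor` times the median pair distance.
#'
#' @param moving_points,fixed_points n x 3 / m x 3 coordinate matrices (mm).
#' @param rejection_distance_factor multiple of the median distance beyond
#'   which pairs are rejected.
#' @param min_correspondences error if fewer pairs survive.
#' @return A list with `moving_index`, `fixed_index`, `distance` (all filtered).
#' @export
find_correspondences <- function(moving_points, fixed_points,
                                 rejection_distance_factor = 3,
                                 min_correspondences = 6L) {
  moving_points <- as.matrix(moving_points)
  fixed_points <- as.matrix(fixed_points)
  if (nrow(moving_points) == 0L || nrow(fixed_points) == 0L)
    stop("point clouds must be non-empty")
  nn <- nearest_neighbor(moving_points, fixed_points)
  med <- median(nn$distance)
  keep <- nn$distance <= rejection_distance_factor * med
  if (sum(keep) < min_correspondences)
    stop("only ", sum(keep), " correspondences survive rejection (need ",
         min_correspondences, "); the clouds do not overlap")
  list(moving_index = which(keep),
       fixed_index = nn$index[keep],
       distance = nn$distance[keep])
}

#' Rigid transform minimizing the point-to-plane cost
#'
#' Finds the rigid transform minimizing
#' `sum_i [ (R p_i + t - q_i) . n_i ]^2` for matched point pairs, where `n_i`
#' is the unit surface normal at the fixed point `q_i` — the planes the
#' registration aligns. Each step linearizes the rotation (small-angle) into a
#' 6 x 6 normal system and projects the update back onto the rotation group
#' (polar decomposition); the step is repeated (Gauss-Newton) on the fixed
#' correspondences until the cost stops improving, so in the small-angle
#' regime the returned transform attains the cost minimum.
#'
#' When the normal system is rank deficient (for example all normals parallel,
#' which leaves in-plane motion unconstrained), the minimum-norm solution is
#' returned by default; with `strict_rank = TRUE` it is an error instead.
#'
#' @param moving,fixed matched n x 3 coordinate matrices (row i of `moving`
#'   corresponds to row i of `fixed`).
#' @param fixed_normals n x 3 unit normals at the fixed points.
#' @param max_steps maximum Gauss-Newton steps on the fixed correspondences.
#' @param tol stop when the cost improves by less than `tol * max(cost, 1)`.
#' @param strict_rank error on a rank-deficient system instead of returning
#'   the minimum-norm solution.
#' @return A [rigid_transform()]; attribute `"cost"` holds the achieved
#'   point-to-plane cost (mm^2).
#' @export
solve_point_to_plane <- function(moving, fixed, fixed_normals,
                                 max_steps = 25L, tol = 1e-14,
                                 strict_rank = FALSE) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  fixed_normals <- as.matrix(fixed_normals)
  n <- nrow(moving)
  if (n < 6L) stop("need at least 6 correspondences, got ", n)
  if (nrow(fixed) != n || nrow(fixed_normals) != n)
    stop("`moving`, `fixed` and `fixed_normals` must have matching rows")
  nl <- sqrt(rowSums(fixed_normals^2))
  if (any(abs(nl - 1) > 1e-6))
    stop("`fixed_normals` must be unit length (max |len - 1| = ",
         format(max(abs(nl - 1))), ")")

  p2p_cost <- function(R, t) {
    r <- rowSums((transform_points(moving, list(rotation = R, translation = t)) - fixed) * fixed_normals)
    sum(r^2)
  }

  R <- diag(3)
  t <- c(0, 0, 0)
  cost0 <- p2p_cost(R, t)
  cost <- cost0
  for (step in seq_len(max_steps)) {
    p <- sweep(moving %*% t(R), 2, t, `+`)
    r <- rowSums((p - fixed) * fixed_normals)
    cr <- cbind(p[, 2] * fixed_normals[, 3] - p[, 3] * fixed_normals[, 2],
                p[, 3] * fixed_normals[, 1] - p[, 1] * fixed_normals[, 3],
                p[, 1] * fixed_normals[, 2] - p[, 2] * fixed_normals[, 1])
    J <- cbind(cr, fixed_normals)
    A <- crossprod(J)
    b <- -crossprod(J, r)
    sv <- svd(A)
    rank_tol <- 1e-10 * max(sv$d)
    deficient <- any(sv$d < rank_tol)
    if (deficient && strict_rank)
      stop("rank-deficient point-to-plane system (", sum(sv$d >= rank_tol),
           "/6 constrained degrees of freedom); the normals do not constrain ",
           "the transform")
    dinv <- ifelse(sv$d < rank_tol, 0, 1 / sv$d)
    x <- sv$v %*% (dinv * crossprod(sv$u, b))
    w <- x[1:3]
    dt <- x[4:6]
    # skew matrix of w (column-major): rows (0,-w3,w2; w3,0,-w1; -w2,w1,0)
    W <- matrix(c(0, w[3], -w[2],
                  -w[3], 0, w[1],
                  w[2], -w[1], 0), 3, 3)
    Rn <- project_to_rotation((diag(3) + W) %*% R)
    tn <- as.numeric((diag(3) + W) %*% t) + dt
    cn <- p2p_cost(Rn, tn)
    if (cn > cost - tol * max(cost, 1)) {
      if (cn < cost) { R <- Rn; t <- tn; cost <- cn }
      break
    }
    R <- Rn
    t <- tn
    cost <- cn
  }
  # the linearized step can in principle overshoot; never return something
  # worse than no motion at all
  if (cost > cost0) {
    R <- diag(3)
    t <- c(0, 0, 0)
    cost <- cost0
  }
  out <- rigid_transform(R, t)
  attr(out, "cost") <- cost
  attr(out, "rank_deficient") <- deficient
  out
}

#' Iterative closest point registration with a point-to-plane residual
#'
#' Repeats correspondence search and point-to-plane transform estimation until
#' the relative change in RMSE drops below `config$rmse_rel_tolerance` or
#' `config$max_iterations` is reached. The accepted RMSE sequence is
#' non-increasing: an iteration that raises the RMSE is discarded and
#' terminates the loop. `converged` is `TRUE` when the iteration stopped
#' because the RMSE stagnated (relative change below tolerance, an RMSE of
#' essentially zero, or a discarded raise at the cost floor) and `FALSE` only
#' when the iteration cap was reached while the RMSE was still improving.
#' Returns the composed transform mapping `moving` into the frame of `fixed`.
#'
#' @param moving,fixed [labeled_surface()] objects; by convention the imaging
#'   anatomy moves and the EAM anatomy is fixed.
#' @param fixed_normals a `normal_field` for `fixed` (see [estimate_normals()]);
#'   estimated automatically when `NULL`.
#' @param config an [icp_config()].
#' @param initial optional initial [rigid_transform()]; overrides
#'   `config$init_strategy`.
#' @return A list with `transform` (a [rigid_transform()]) and `diagnostics`
#'   (class `icp_diagnostics`: per-iteration `rmse` (mm, evaluated over all
#'   moving points so iterations are comparable; the transform update itself
#'   uses only the correspondences surviving rejection),
#'   `correspondences_used`, `iterations_run`, `converged`).
#' @export
icp_point_to_plane <- function(moving, fixed, fixed_normals = NULL,
                               config = icp_config(), initial = NULL) {
  stopifnot(inherits(moving, "labeled_surface"), inherits(fixed, "labeled_surface"),
            inherits(config, "icp_config"))
  if (is.null(fixed_normals)) fixed_normals <- estimate_normals(fixed)
  stopifnot(inherits(fixed_normals, "normal_field"))
  if (nrow(fixed_normals$normals) != n_vertices(fixed))
    stop("`fixed_normals` does not match `fixed` (",
         nrow(fixed_normals$normals), " vs ", n_vertices(fixed), " vertices)")
  current <- initial %||% initialize_transform(moving, fixed, config$init_strategy)
  stopifnot(inherits(current, "rigid_transform"))

  mv0 <- moving$vertices
  fx <- fixed$vertices
  nrm <- fixed_normals$normals
  rmse_trace <- numeric(0)
  ncorr_trace <- integer(0)
  converged <- FALSE
  k <- 0L
  while (k < config$max_iterations) {
    mv <- transform_points(mv0, current)
    nn <- nearest_neighbor(mv, fx)
    med <- median(nn$distance)
    keep <- nn$distance <= config$rejection_distance_factor * med
    if (sum(keep) < config$min_correspondences)
      stop("iteration ", k + 1L, ": only ", sum(keep), " correspondences ",
           "survive rejection (need ", config$min_correspondences,
           "); the clouds do not overlap", call. = FALSE)
    corr <- list(moving_index = which(keep), fixed_index = nn$index[keep])
    # the tracked RMSE is evaluated over *all* moving points so successive
    # iterations are comparable; the solve below uses only the robust subset
    res_all <- rowSums((mv - fx[nn$index, , drop = FALSE]) *
                         nrm[nn$index, , drop = FALSE])
    rmse <- sqrt(mean(res_all^2))
    if (k > 0L && rmse > rmse_trace[k] + 1e-9) {
      # discard the iteration that raised the RMSE and stop: the iteration
      # has stagnated at its cost floor, which is convergence (an alignment
      # stuck in a wrong basin is caught by the median-residual flag, not
      # here)
      converged <- TRUE
      break
    }
    k <- k + 1L
    rmse_trace[k] <- rmse
    ncorr_trace[k] <- length(corr$moving_index)
    if (rmse < 1e-9 ||
        (k > 1L && abs(rmse_trace[k - 1L] - rmse) <
           config$rmse_rel_tolerance * max(rmse_trace[k - 1L], 1e-12))) {
      converged <- TRUE
      break
    }
    # one linearized solve per ICP iteration: fully minimizing on the current
    # (partly wrong) correspondences overshoots and destabilizes the descent
    inc <- tryCatch(
      solve_point_to_plane(mv[corr$moving_index, , drop = FALSE],
                           fx[corr$fixed_index, , drop = FALSE],
                           nrm[corr$fixed_index, , drop = FALSE],
                           max_steps = 1L),
      error = function(e) stop("iteration ", k, ": ", conditionMessage(e),
                               call. = FALSE))
    current <- compose_transforms(rigid_transform(inc$rotation, inc$translation),
                                  current)
  }
  diagnostics <- structure(
    list(rmse = rmse_trace, correspondences_used = ncorr_trace,
         iterations_run = k, converged = converged),
    class = "icp_diagnostics")
  list(transform = current, diagnostics = diagnostics)
}

#' @export
print.icp_diagnostics <- function(x, ...) {
  cat("ICP diagnostics: ", x$iterations_run, " iteration(s), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  if (x$iterations_run > 0L)
    cat(sprintf("  point-to-plane RMSE %.4g -> %.4g mm, %d correspondences at end\n",
                x$rmse[1], x$rmse[x$iterations_run],
                x$correspondences_used[x$iterations_run]))
  invisible(x)
}

# initial transform per strategy; centroid_pca tries the 4 proper sign
# assignments of the principal axes and keeps the lowest initial RMSE
initialize_transform <- function(moving, fixed, strategy) {
  cm <- colMeans(moving$vertices)
  cf <- colMeans(fixed$vertices)
  switch(strategy,
    identity = rigid_transform(),
    centroid = rigid_transform(diag(3), cf - cm),
    centroid_pca = {
      Em <- eigen(stats::cov(moving$vertices), symmetric = TRUE)$vectors
      Ef <- eigen(stats::cov(fixed$vertices), symmetric = TRUE)$vectors
      if (det(Em) < 0) Em[, 3] <- -Em[, 3]
      if (det(Ef) < 0) Ef[, 3] <- -Ef[, 3]
      signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      best <- NULL
      best_rmse <- Inf
      for (s in signs) {
        R <- Ef %*% diag(s) %*% t(Em)
        tr <- rigid_transform(R, cf - as.numeric(R %*% cm))
        mv <- transform_points(moving$vertices, tr)
        rmse <- sqrt(mean(nearest_neighbor(mv, fixed$vertices)$distance^2))
        if (rmse < best_rmse) { best_rmse <- rmse; best <- tr }
      }
      best
    })
}
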