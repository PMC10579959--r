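#' Two-stage alignment pipeline controls
#'
#' Stage one registers the full anatomies — the pulmonary veins, appendage and
#' mitral annulus are the most distinctive landmarks and lock in the global
#' pose. Stage two re-runs the registration after excluding those structures
#' (their shape differs systematically between imaging and EAM), initialized
#' at the stage-one result and capped at `stage2_max_iterations = 3` so it can
#' only refine, not undo, the previous alignment.
#'
#' @param stage2_excluded_labels structures removed before the refinement
#'   stage and the quality metrics. Default: the four PVs, the appendage and
#'   the mitral annulus.
#' @param stage2_max_iterations iteration cap for the refinement (>= 1,
#'   default 3).
#' @param stage1,stage2 [icp_config()] for each stage (`stage2$max_iterations`
#'   is overridden by `stage2_max_iterations`).
#' @param fail_median_mm automatic failure threshold on the median residual
#'   distance (mm); default 5, the outer quality threshold of the metrics.
#' @param remesh a [remesh_config()] applied before registration.
#' @param remesh_mode `"auto"` resamples any input that fails the isotropy/
#'   density trigger (see [isotropic_remesh()]), `"imaging_only"` restricts
#'   this to the imaging side (segmentation exports are the non-isotropic
#'   ones), `"none"` disables remeshing.
#' @param metric_thresholds distances (mm) reported as surface percentages.
#' @param metric_mode `"vertex"` or `"surface"`, see [residual_distances()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stage2_excluded_labels = c("LSPV", "LIPV", "RSPV",
                                                       "RIPV", "LAA",
                                                       "MV_ANNULUS"),
                            stage2_max_iterations = 3L,
                            stage1 = icp_config(),
                            stage2 = icp_config(max_iterations = 3L),
                            fail_median_mm = 5.0,
                            remesh = remesh_config(),
                            remesh_mode = c("auto", "imaging_only", "none"),
                            metric_thresholds = c(2.5, 5.0),
                            metric_mode = c("vertex", "surface")) {
  remesh_mode <- match.arg(remesh_mode)
  metric_mode <- match.arg(metric_mode)
  stage2_max_iterations <- as.integer(stage2_max_iterations)
  if (stage2_max_iterations < 1L) stop("`stage2_max_iterations` must be >= 1")
  bad <- setdiff(stage2_excluded_labels, setdiff(LA_LABELS, "BODY"))
  if (length(bad))
    stop("`stage2_excluded_labels` must be a subset of {",
         paste(setdiff(LA_LABELS, "BODY"), collapse = ", "), "}; got ",
         paste(bad, collapse = ", "))
  stopifnot(inherits(stage1, "icp_config"), inherits(stage2, "icp_config"),
            inherits(remesh, "remesh_config"))
  stage2$max_iterations <- stage2_max_iterations
  structure(list(stage2_excluded_labels = stage2_excluded_labels,
                 stage2_max_iterations = stage2_max_iterations,
                 stage1 = stage1, stage2 = stage2,
                 fail_median_mm = fail_median_mm, remesh = remesh,
                 remesh_mode = remesh_mode,
                 metric_thresholds = metric_thresholds,
                 metric_mode = metric_mode),
            class = "pipeline_config")
}

#' Align an imaging anatomy with an EAM anatomy (two-stage ICP-PP)
#'
#' The package's central fit: fully automated rigid alignment of a labeled
#' imaging (CT/MRI) left-atrial surface with an electro-anatomical mapping
#' anatomy. Runs the optional isotropic-resampling trigger, stage-one
#' registration on the full anatomies, stage-two refinement with the
#' distinctive structures excluded (3 iterations at most), residual-distance
#' quality metrics on the refined alignment, and an automatic pass/fail
#' assessment.
#'
#' @param imaging the labeled moving [labeled_surface()] (CT/MRI side).
#' @param eam the fixed [labeled_surface()] acquired by the mapping system;
#'   may be entirely unlabeled.
#' @param config a [pipeline_config()].
#' @return An object of class `la_alignment` with components
#'   `stage1_transform`, `stage2_transform`, `composed_transform` (all
#'   [rigid_transform()]; `composed = stage2 o stage1`), `stage1_diagnostics`,
#'   `stage2_diagnostics`, `summary` (a `distance_summary`), `passed`,
#'   `fail_reason`, plus the (resampled) surfaces used. Methods: `print`,
#'   `summary`, `coef` (4 x 4 homogeneous matrix), `predict` (apply the
#'   composed transform), `residuals` (per-vertex residual distances),
#'   `plot`.
#' @examples
#' \donttest{
#' la <- generate_phantom(phantom_params(target_spacing = 3))
#' tr <- random_rigid_transform(10, 5, seed = 7)
#' eam <- simulate_acquisition(la, acquisition_params(tr, noise_sd = 0, seed = 7))
#' fit <- align_la(la, eam)
#' fit
#' }
#' @export
align_la <- function(imaging, eam, config = pipeline_config()) {
  stopifnot(inherits(imaging, "labeled_surface"), inherits(eam, "labeled_surface"),
            inherits(config, "pipeline_config"))
  cl <- match.call()
  img <- imaging
  fx <- eam
  if (config$remesh_mode != "none") {
    img <- isotropic_remesh(img, config$remesh, seed = 1L)
    if (config$remesh_mode == "auto")
      fx <- isotropic_remesh(fx, config$remesh, seed = 2L)
  }
  fx_normals <- estimate_normals(fx)

  stage1 <- tryCatch(
    icp_point_to_plane(img, fx, fx_normals, config$stage1),
    error = function(e) stop("stage 1: ", conditionMessage(e), call. = FALSE))

  img2 <- exclude_labels(img, config$stage2_excluded_labels)$surface
  eam_labeled <- any(fx$labels != "BODY")
  if (eam_labeled) {
    fx2 <- exclude_labels(fx, config$stage2_excluded_labels)$surface
    fx2_normals <- estimate_normals(fx2)
  } else {
    fx2 <- fx
    fx2_normals <- fx_normals
  }
  stage2 <- tryCatch(
    icp_point_to_plane(img2, fx2, fx2_normals, config$stage2,
                       initial = stage1$transform),
    error = function(e) stop("stage 2: ", conditionMessage(e), call. = FALSE))

  composed <- stage2$transform
  stage2_delta <- compose_transforms(composed, invert_transform(stage1$transform))
  aligned <- apply_transform(img, composed)
  summ <- residual_distances(aligned, fx,
                             excluded_labels = config$stage2_excluded_labels,
                             thresholds = config$metric_thresholds,
                             mode = config$metric_mode)
  flag <- flag_alignment(stage1$diagnostics, stage2$diagnostics, summ,
                         config$fail_median_mm)
  structure(list(stage1_transform = stage1$transform,
                 stage2_transform = stage2_delta,
                 composed_transform = composed,
                 stage1_diagnostics = stage1$diagnostics,
                 stage2_diagnostics = stage2$diagnostics,
                 summary = summ, passed = flag$passed,
                 fail_reason = flag$reason,
                 imaging = img, eam = fx, aligned_imaging = aligned,
                 config = config, call = cl),
            class = "la_alignment")
}

#' Automatic pass/fail assessment of an alignment
#'
#' Replaces a manual visual check with three mechanical criteria, evaluated in
#' order: the median residual distance (excluded structures removed) must not
#' exceed `fail_median_mm`; stage one must have converged; the stage-two
#' final RMSE must not exceed the stage-one final RMSE by more than 20%
#' (refinement must not degrade the fit).
#'
#' @param stage1_diagnostics,stage2_diagnostics `icp_diagnostics` of the two
#'   stages.
#' @param summary the `distance_summary` of the final alignment.
#' @param fail_median_mm threshold (mm) on the median residual.
#' @return A list with `passed` (logical) and `reason` (`NULL`, or the first
#'   failed check: `"median_exceeds_threshold"`, `"stage1_not_converged"`,
#'   `"stage2_rmse_regression"`).
#' @export
flag_alignment <- function(stage1_diagnostics, stage2_diagnostics, summary,
                           fail_median_mm = 5.0) {
  stopifnot(inherits(summary, "distance_summary"))
  if (summary$median_mm > fail_median_mm)
    return(list(passed = FALSE, reason = "median_exceeds_threshold"))
  if (!isTRUE(stage1_diagnostics$converged))
    return(list(passed = FALSE, reason = "stage1_not_converged"))
  r1 <- stage1_diagnostics$rmse[stage1_diagnostics$iterations_run]
  r2 <- stage2_diagnostics$rmse[stage2_diagnostics$iterations_run]
  if (length(r1) && length(r2) && r2 > 1.2 * r1 + 1e-12)
    return(list(passed = FALSE, reason = "stage2_rmse_regression"))
  list(passed = TRUE, reason = NULL)
}

## ---- methods ---------------------------------------------------------------

#' @export
print.la_alignment <- function(x, ...) {
  cat("Two-stage LA alignment (point-to-plane ICP)\n")
  cat("  moving:", x$imaging$name, "->", "fixed:", x$eam$name, "\n")
  aa <- rotation_to_axis_angle(x$composed_transform$rotation)
  cat(sprintf("  composed transform: %.2f deg rotation, %.2f mm translation\n",
              aa$angle * 180 / pi, vec_norm(x$composed_transform$translation)))
  cat(sprintf("  median residual: %.2f mm  |  %s\n", x$summary$median_mm,
              if (x$passed) "PASSED" else paste0("FAILED (", x$fail_reason, ")")))
  invisible(x)
}

#' @export
summary.la_alignment <- function(object, ...) {
  s1 <- object$stage1_diagnostics
  s2 <- object$stage2_diagnostics
  out <- list(
    name = paste(object$imaging$name, "->", object$eam$name),
    stage1_iterations = s1$iterations_run,
    stage1_converged = s1$converged,
    stage1_final_rmse = s1$rmse[s1$iterations_run],
    stage2_iterations = s2$iterations_run,
    stage2_final_rmse = s2$rmse[s2$iterations_run],
    median_mm = object$summary$median_mm,
    mean_mm = object$summary$mean_mm,
    pct_below = object$summary$pct_below,
    passed = object$passed,
    fail_reason = object$fail_reason)
  class(out) <- "summary.la_alignment"
  out
}

#' @export
print.summary.la_alignment <- function(x, ...) {
  cat("Two-stage LA alignment:", x$name, "\n")
  cat(sprintf("  stage 1: %d iteration(s), %s, final point-to-plane RMSE %.3f mm\n",
              x$stage1_iterations,
              if (x$stage1_converged) "converged" else "NOT converged",
              x$stage1_final_rmse))
  cat(sprintf("  stage 2: %d iteration(s) (cap 3), final RMSE %.3f mm\n",
              x$stage2_iterations, x$stage2_final_rmse))
  cat(sprintf("  residuals: median %.2f mm, mean %.2f mm\n", x$median_mm, x$mean_mm))
  for (i in seq_along(x$pct_below))
    cat(sprintf("  surface < %s mm: %.1f%%\n", names(x$pct_below)[i], x$pct_below[i]))
  cat(" ", if (x$passed) "PASSED" else paste0("FAILED: ", x$fail_reason), "\n")
  invisible(x)
}

#' @export
coef.la_alignment <- function(object, ...) as_homogeneous(object$composed_transform)

#' @export
#' @method predict la_alignment
predict.la_alignment <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$imaging
  if (inherits(newdata, "labeled_surface"))
    apply_transform(newdata, object$composed_transform)
  else
    transform_points(as.matrix(newdata), object$composed_transform)
}

#' @export
residuals.la_alignment <- function(object, ...) object$summary$per_vertex_distance

#' @export
plot.la_alignment <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2.5, 1))
  on.exit(par(op))
  r1 <- x$stage1_diagnostics$rmse
  r2 <- x$stage2_diagnostics$rmse
  plot(seq_along(r1), r1, type = "b", pch = 16, col = "steelblue",
       xlim = c(1, length(r1) + length(r2)),
       ylim = range(c(r1, r2)), xlab = "iteration",
       ylab = "point-to-plane RMSE (mm)", main = "Convergence")
  if (length(r2))
    lines(length(r1) + seq_along(r2), r2, type = "b", pch = 17, col = "firebrick")
  legend("topright", legend = c("stage 1", "stage 2"), pch = c(16, 17),
         col = c("steelblue", "firebrick"), bty = "n")
  d <- x$summary$per_vertex_distance
  hist(d, breaks = 30, col = "grey80", border = "white",
       xlab = "residual distance (mm)", main = "Residuals")
  abline(v = x$summary$thresholds, lty = 2)
  invisible(x)
}
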