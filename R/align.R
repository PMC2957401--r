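# The user-facing fit: align two surface patches and report the match.

#' Align two surface patches
#'
#' Finds the rigid-body transform superposing a query patch onto a
#' target patch by global minimization of an alignment objective:
#' either the injective *matching distance* (assignment-based, the
#' default) or the classical closest-point objective. The default
#' search is the controlled random search (CRS) global optimizer;
#' `method = "icp"` runs the iterative closest point baseline from a
#' given starting pose instead. In `same-property` mode only atoms
#' sharing a physico-chemical class may be matched.
#'
#' If the query has more atoms than the target, the roles are swapped
#' internally and the reported transform is inverted back, so the
#' report always describes the transform carrying `query` onto
#' `target`.
#'
#' @param query,target [surface_patch()] objects (bare n x 3 matrices
#'   are wrapped with `NONE` labels).
#' @param objective `"matching"` or `"closest"`.
#' @param mode `"same-property"`, `"all-pairs"`, or `"relax"`.
#' @param method `"crs"` (global) or `"icp"` (local baseline).
#' @param control a [crs_control()].
#' @param aligned_cutoff post-superposition distance (Angstrom) within
#'   which an assigned pair counts as aligned (default 2.0); RMSD and
#'   SAS are computed over exactly these pairs.
#' @param domain optional [search_domain()] for the translation
#'   (default: box centered on the centroid offset, half-width the sum
#'   of the patch half-diameters).
#' @param init initial pose for `method = "icp"`.
#' @param seed integer seed for the stochastic search.
#' @return An object of class `surface_alignment` with components
#'   `transform` (a [rigid_transform()]), `assignment`, `pairs`
#'   (aligned pairs with distances), `n_aligned`, `rmsd`, `sas`,
#'   `similarity`, `objective_value` (Angstrom^2), `converged`,
#'   `trace`, and the echoed configuration. Methods: `print`,
#'   `summary`, `coef` (the 7-vector), `predict` (apply the fitted
#'   transform to new coordinates), `fitted` (transformed query
#'   coordinates), `residuals` (per-pair distances), `plot`.
#' @examples
#' inst <- make_instance(12, seed = 1)
#' fit <- align_patches(inst$P, inst$Q, control = crs_control(max_evals = 3000),
#'                      seed = 1)
#' fit
#' coef(fit)
#' @export
align_patches <- function(query, target,
                          objective = c("matching", "closest"),
                          mode = c("same-property", "all-pairs", "relax"),
                          method = c("crs", "icp"),
                          control = crs_control(), aligned_cutoff = 2.0,
                          domain = NULL, init = identity_transform(),
                          seed = NULL) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!inherits(query, "surface_patch")) query <- surface_patch(query)
  if (!inherits(target, "surface_patch")) target <- surface_patch(target)
  n <- nrow(query$coords); m <- nrow(target$coords)
  swapped <- n > m
  A <- if (swapped) target else query
  B <- if (swapped) query else target
  labA <- if (mode == "all-pairs") NULL else A$labels
  labB <- if (mode == "all-pairs") NULL else B$labels
  if (is.null(domain)) domain <- default_search_domain(A$coords, B$coords)

  if (method == "crs") {
    g <- make_objective(A$coords, B$coords, kind = objective,
                        labels_P = labA, labels_Q = labB, mode = mode)
    fit <- run_crs(g, domain, control, seed = seed)
    tf <- fit$best
    gval <- fit$g_best
    converged <- fit$converged
    trace <- fit$trace
    evals <- fit$eval_count
  } else {
    if (!is.null(seed)) set.seed(seed)
    fit <- run_icp(A$coords, B$coords, init = if (swapped)
      transform_invert(init) else init,
      labels_P = labA, labels_Q = labB,
      mode = if (mode == "same-property") "same-property" else "all-pairs")
    tf <- fit$transform
    gval <- fit$f
    converged <- fit$converged
    trace <- data.frame(eval = seq_along(fit$trace), g_min = fit$trace,
                        g_max = fit$trace)
    evals <- fit$iterations
  }

  # final assignment at the fitted transform
  Aa <- apply_transform(tf, A$coords)
  if (objective == "matching") {
    md <- matching_distance(A$coords, B$coords, tf, labA, labB,
                            mode = if (mode == "all-pairs") "all-pairs"
                                   else mode)
    assignment <- md$assignment
  } else {
    assignment <- closest_point_mapping(Aa, B$coords, labA, labB,
                                        restrict = mode == "same-property")
  }
  pairs <- aligned_pairs(assignment, Aa, B$coords, cutoff = aligned_cutoff)
  n_aligned <- nrow(pairs)
  r <- if (n_aligned > 0) rmsd(pairs) else NA_real_
  s <- if (n_aligned > 0) sas(r, n_aligned) else NA_real_

  if (swapped) {
    tf_out <- transform_invert(tf)
    inv_assign <- rep(NA_integer_, n)
    ok <- !is.na(assignment)
    inv_assign[assignment[ok]] <- which(ok)
    assignment_out <- inv_assign
    pairs_out <- data.frame(p = pairs$q, q = pairs$p,
                            distance = pairs$distance)
    pairs_out <- pairs_out[order(pairs_out$p), , drop = FALSE]
    rownames(pairs_out) <- NULL
  } else {
    tf_out <- tf
    assignment_out <- assignment
    pairs_out <- pairs
  }

  structure(list(
    transform = tf_out, assignment = assignment_out, pairs = pairs_out,
    n_aligned = n_aligned, rmsd = r, sas = s,
    similarity = similarity_score(n_aligned, n, m),
    objective_value = gval, converged = converged, trace = trace,
    eval_count = evals, swapped = swapped,
    query = query, target = target,
    config = list(objective = objective, mode = mode, method = method,
                  aligned_cutoff = aligned_cutoff, seed = seed,
                  control = control,
                  version = as.character(utils::packageVersion("surfalign"))),
    call = match.call()
  ), class = "surface_alignment")
}

#' @export
print.surface_alignment <- function(x, digits = 3, ...) {
  cat("Surface patch alignment (", x$config$method, ", ",
      x$config$objective, " objective, ", x$config$mode, ")\n", sep = "")
  cat("  query ", nrow(x$query$coords), " atoms -> target ",
      nrow(x$target$coords), " atoms\n", sep = "")
  cat("  aligned atoms:", x$n_aligned,
      "| RMSD:", signif(x$rmsd, digits), "A",
      "| SAS:", format(x$sas),
      "| similarity:", signif(x$similarity, digits), "\n")
  cat("  objective:", format(signif(x$objective_value, digits)), "A^2 (",
      if (x$converged) "converged" else "not converged", ")\n")
  invisible(x)
}

#' @export
summary.surface_alignment <- function(object, ...) {
  x <- object
  cat("Call: ")
  print(x$call)
  print(x)
  print(x$transform)
  if (nrow(x$pairs)) {
    cat("Aligned pair distances (A):\n")
    print(summary(x$pairs$distance))
  }
  unmatched <- sum(is.na(x$assignment))
  if (unmatched)
    cat(unmatched, "query atom(s) unmatched (excluded or infeasible)\n")
  invisible(x)
}

#' @export
coef.surface_alignment <- function(object, ...) {
  v <- as_vector7(object$transform)
  names(v) <- c("a0", "a1", "a2", "a3", "tx", "ty", "tz")
  v
}

#' @export
fitted.surface_alignment <- function(object, ...) {
  apply_transform(object$transform, object$query$coords)
}

#' @export
residuals.surface_alignment <- function(object, ...) {
  object$pairs$distance
}

#' @export
#' @param object a `surface_alignment`.
#' @param newdata n x 3 coordinate matrix to carry through the fitted
#'   transform (default: the query coordinates).
#' @rdname align_patches
predict.surface_alignment <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object))
  apply_transform(object$transform, newdata)
}

#' @export
plot.surface_alignment <- function(x, which = c("trace", "residuals"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$trace
    graphics::plot(tr$eval, tr$g_max, type = "s", log = "y",
                   xlab = "objective evaluations",
                   ylab = "population objective (A^2)", ...)
    graphics::lines(tr$eval, pmax(tr$g_min, .Machine$double.xmin),
                    type = "s", lty = 2)
    graphics::legend("topright", legend = c("g_max", "g_min"),
                     lty = c(1, 2), bty = "n")
  } else {
    if (!nrow(x$pairs)) stop("no aligned pairs to plot")
    graphics::hist(x$pairs$distance, xlab = "pair distance (A)",
                   main = "aligned pair distances", ...)
  }
  invisible(x)
}

#' Full JSON report of an alignment
#'
#' Serializes transform, pairs, scores, and the configuration echo
#' (including seed and package version) sufficient to reproduce the
#' run.
#' @param fit a `surface_alignment`.
#' @param path output JSON file.
#' @export
write_alignment_report <- function(fit, path) {
  ctl <- fit$config$control
  jsonlite::write_json(list(
    transform = list(quaternion = fit$transform$q,
                     translation = fit$transform$t),
    n_aligned = fit$n_aligned, rmsd = fit$rmsd, sas = fit$sas,
    similarity = fit$similarity, objective_value = fit$objective_value,
    converged = fit$converged, eval_count = fit$eval_count,
    pairs = fit$pairs, assignment = fit$assignment,
    config = list(objective = fit$config$objective, mode = fit$config$mode,
                  method = fit$config$method,
                  aligned_cutoff = fit$config$aligned_cutoff,
                  seed = fit$config$seed,
                  M = ctl$M, epsilon = ctl$epsilon, alpha0 = ctl$alpha0,
                  max_evals = ctl$max_evals,
                  version = fit$config$version)
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
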