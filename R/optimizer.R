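# Controlled random search (CRS) over rigid transforms, and the ICP
# local baseline.

#' Control parameters for the CRS optimizer
#'
#' The decision variable has `N = 6` degrees of freedom (3 rotation + 3
#' translation), stored as a 7-vector (unit quaternion + translation).
#' The population holds `M` points; the conventional choice `M = 25 N =
#' 150` balances global reliability against convergence speed.
#'
#' @param M population size (default `25 * 6`); at least `10 * N`.
#' @param epsilon absolute stopping tolerance on `g_max - g_min`
#'   (Angstrom^2).
#' @param alpha0 initial reflection parameter, in (0, 1).
#' @param max_evals total objective-evaluation budget (includes the `M`
#'   initialization evaluations).
#' @param weighted_centroid weight the centroid toward better points
#'   (`TRUE`, default) or use the plain average (classic CRS).
#' @param relative_spread stop on `(g_max - g_min) / max(g_max, tiny)`
#'   instead of the absolute spread.
#' @param include_best always include the current best point among the
#'   `N + 1` drawn points (off by default).
#' @return list of class `crs_control`.
#' @export
crs_control <- function(M = 150, epsilon = 1e-4, alpha0 = 0.95,
                        max_evals = 20000, weighted_centroid = TRUE,
                        relative_spread = FALSE, include_best = FALSE) {
  N <- 6L
  M <- as.integer(M)
  if (M < 10L * N) stop("M must be at least 10 * N = 60")
  if (!(alpha0 > 0 && alpha0 < 1)) stop("alpha0 must lie in (0, 1)")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (max_evals <= M) stop("max_evals must exceed M")
  structure(list(N = N, M = M, epsilon = epsilon, alpha0 = alpha0,
                 max_evals = as.integer(max_evals),
                 weighted_centroid = isTRUE(weighted_centroid),
                 relative_spread = isTRUE(relative_spread),
                 include_best = isTRUE(include_best)),
            class = "crs_control")
}

#' Initialize the CRS population
#'
#' Draws `M` transforms uniformly from the search domain (quaternions
#' uniform on the unit 3-sphere, translations uniform in the box) and
#' evaluates the objective on each.
#'
#' @param objective `function(a7) -> Angstrom^2`.
#' @param domain a [search_domain()].
#' @param control a [crs_control()].
#' @return list of class `crs_population`: `points` (7 x M matrix),
#'   `values` (numeric(M)), `eval_count`.
#' @export
crs_init_population <- function(objective, domain, control = crs_control()) {
  M <- control$M
  pts <- matrix(NA_real_, 7, M)
  vals <- numeric(M)
  for (i in seq_len(M)) {
    v <- NA_real_
    for (try in 1:50) {
      a <- random_transform(domain)
      v <- objective(as_vector7(a))
      if (is.finite(v) || try == 50) break
    }
    if (!is.finite(v)) stop("objective not finite on sampled transforms")
    pts[, i] <- as_vector7(a)
    vals[i] <- v
  }
  structure(list(points = pts, values = vals, eval_count = M),
            class = "crs_population")
}

#' Reflection-parameter schedule
#'
#' `alpha` starts at (essentially) `alpha0` and decays with the
#' iteration count and with the population spread:
#' `alpha0 * spread / (spread + 10 * epsilon) / (1 + k / (50 * M))`.
#' It is non-increasing in both arguments and tends to 0 as the spread
#' approaches the stopping tolerance, so the search reflects almost at
#' full strength (near-Price reflections, which are what gives CRS its
#' global reach) for as long as the population is spread out, and only
#' contracts onto the centroid in the endgame. Schedules that decay
#' `alpha` proportionally to `spread / spread0` collapse the population
#' onto local minima long before the global basin is found.
#'
#' @param k iteration count (accepted + rejected steps so far).
#' @param spread current `g_max - g_min`.
#' @param spread0 initial spread (kept for context; not used by the
#'   default schedule).
#' @param control a [crs_control()].
#' @return alpha in \[0, alpha0).
#' @export
update_alpha <- function(k, spread, spread0, control = crs_control()) {
  spread <- max(0, spread)
  control$alpha0 * spread / (spread + 10 * control$epsilon) /
    (1 + k / (50 * control$M))
}

#' One CRS search/update step
#'
#' Draws `N + 1` distinct points from the population, forms their
#' weighted centroid `a_c`, reflects it over the worst drawn point
#' `a_dag` as `(1 + alpha) a_c - alpha a_dag`, renormalizes the
#' quaternion block ([normalize_candidate()]), and evaluates the
#' candidate. The candidate replaces the population-wide worst point iff
#' it improves on `g_max`; otherwise the population is unchanged.
#'
#' @param pop a `crs_population`.
#' @param objective objective closure.
#' @param alpha reflection parameter for this step.
#' @param control a [crs_control()].
#' @return updated `crs_population` with attribute `"accepted"`.
#' @export
crs_step <- function(pop, objective, alpha, control = crs_control()) {
  M <- ncol(pop$points)
  k <- control$N + 1L
  for (attempt in 1:20) {
    if (control$include_best) {
      idx <- c(which.min(pop$values),
               sample(setdiff(seq_len(M), which.min(pop$values)), k - 1L))
    } else {
      idx <- sample.int(M, k)
    }
    sub <- pop$points[, idx, drop = FALSE]
    gv <- pop$values[idx]
    worst <- which.max(gv)
    if (control$weighted_centroid) {
      # mild pull toward better points: eta at half the population
      # spread keeps the weights within about a factor of three, which
      # biases the centroid without collapsing the search
      gmin <- min(pop$values); gmax <- max(pop$values)
      eta <- 0.5 * (gmax - gmin + 1e-12)
      w <- 1 / (gv - gmin + eta)
      w <- w / sum(w)
    } else {
      w <- rep(1 / k, k)
    }
    a_c <- as.numeric(sub %*% w)
    a_raw <- (1 + alpha) * a_c - alpha * sub[, worst]
    cand <- tryCatch(normalize_candidate(a_raw), error = function(e) NULL)
    if (!is.null(cand)) break
  }
  if (is.null(cand)) stop("degenerate reflection candidate; search collapsed")
  g_new <- objective(as_vector7(cand))
  pop$eval_count <- pop$eval_count + 1L
  accepted <- is.finite(g_new) && g_new < max(pop$values)
  if (accepted) {
    j <- which.max(pop$values)
    pop$points[, j] <- as_vector7(cand)
    pop$values[j] <- g_new
  }
  attr(pop, "accepted") <- accepted
  pop
}

#' Run the controlled random search
#'
#' Population-based derivative-free global minimization of the
#' (non-smooth) alignment objective: initialize `M` random transforms,
#' then repeat reflect-and-replace steps until the population values
#' collapse (`g_max - g_min < epsilon`) or the evaluation budget is
#' spent. The population maximum and minimum are non-increasing over
#' accepted updates.
#'
#' @inheritParams crs_init_population
#' @param seed optional integer seed (applied via `set.seed`).
#' @return list of class `crs_fit`: `best` (`rigid_transform`),
#'   `g_best`, `converged`, `eval_count`, `population`, and `trace`
#'   (data frame `eval`, `g_min`, `g_max` recorded at initialization and
#'   at every accepted update).
#' @export
run_crs <- function(objective, domain, control = crs_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- crs_init_population(objective, domain, control)
  spread0 <- max(pop$values) - min(pop$values)
  tr_eval <- pop$eval_count
  tr_min <- min(pop$values)
  tr_max <- max(pop$values)
  k <- 0L
  spread_now <- function(p) {
    s <- max(p$values) - min(p$values)
    if (control$relative_spread) s / max(abs(max(p$values)), 1e-12) else s
  }
  while (spread_now(pop) >= control$epsilon &&
         pop$eval_count < control$max_evals) {
    alpha <- update_alpha(k, max(pop$values) - min(pop$values), spread0,
                          control)
    pop <- crs_step(pop, objective, alpha, control)
    k <- k + 1L
    if (attr(pop, "accepted")) {
      tr_eval <- c(tr_eval, pop$eval_count)
      tr_min <- c(tr_min, min(pop$values))
      tr_max <- c(tr_max, max(pop$values))
    }
  }
  best <- which.min(pop$values)
  structure(list(
    best = normalize_candidate(pop$points[, best]),
    g_best = pop$values[best],
    converged = spread_now(pop) < control$epsilon,
    eval_count = pop$eval_count,
    population = pop,
    trace = data.frame(eval = tr_eval, g_min = tr_min, g_max = tr_max)
  ), class = "crs_fit")
}

#' @export
print.crs_fit <- function(x, ...) {
  cat("CRS fit: g_best =", format(x$g_best), "A^2 after", x$eval_count,
      "evaluations (", if (x$converged) "converged" else "budget exhausted",
      ")\n")
  invisible(x)
}

#' Iterative closest point baseline
#'
#' Alternates the closest-point mapping with the closed-form optimal
#' rigid transform for that mapping until the objective stalls. The
#' objective is non-increasing across iterations; the algorithm
#' converges to a local minimum that depends on the initial relative
#' positioning of the two patches.
#'
#' @param P,Q coordinate matrices (n x 3, m x 3).
#' @param init initial `rigid_transform` (the initial relative
#'   positioning; default identity).
#' @param labels_P,labels_Q optional atom-class labels.
#' @param mode `"all-pairs"` or `"same-property"` (restricts the
#'   closest-point search to same-class atoms).
#' @param tol stop when the objective improves by less than `tol`.
#' @param max_iter iteration cap.
#' @return list of class `icp_fit`: `transform`, `mapping`, `f`
#'   (Angstrom^2), `iterations`, `converged`, `trace` (f per iteration).
#' @export
run_icp <- function(P, Q, init = identity_transform(), labels_P = NULL,
                    labels_Q = NULL, mode = "all-pairs", tol = 1e-8,
                    max_iter = 100) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  restrict <- match.arg(mode, c("all-pairs", "same-property")) ==
    "same-property"
  a <- init
  f_old <- Inf
  trace <- numeric(0)
  psi <- NULL
  for (it in seq_len(max_iter)) {
    Pa <- apply_transform(a, P)
    psi <- closest_point_mapping(Pa, Q, labels_P, labels_Q, restrict)
    if (anyNA(psi)) stop("closest-point mapping infeasible under label filter")
    sol <- optimal_transform(P, Q, psi)
    a <- sol$transform
    f <- sol$msd
    trace <- c(trace, f)
    if (f <= tol || f_old - f < tol) {
      return(structure(list(transform = a, mapping = psi, f = f,
                            iterations = it, converged = TRUE, trace = trace),
                       class = "icp_fit"))
    }
    f_old <- f
  }
  structure(list(transform = a, mapping = psi, f = f_old, iterations = max_iter,
                 converged = FALSE, trace = trace), class = "icp_fit")
}

#' @export
print.icp_fit <- function(x, ...) {
  cat("ICP fit: f =", format(x$f), "A^2 after", x$iterations, "iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n")
  invisible(x)
}
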