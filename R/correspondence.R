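# Objectives: closest-point mapping and the assignment-based matching
# distance on a (optionally physico-chemically filtered) bipartite graph.

#' Physico-chemical atom classes
#'
#' Closed vocabulary: hydrogen-bond acceptor (ACC), donor (DO),
#' acceptor/donor (AD), aliphatic (ALI), aromatic (PI), plus NONE for
#' atoms outside the five classes.
#' @export
ATOM_CLASSES <- c("ACC", "DO", "AD", "ALI", "PI", "NONE")

# integer codes for the C++ kernels: NONE -> 0
label_codes <- function(labels, n) {
  if (is.null(labels)) return(rep(1L, n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match point count")
  bad <- setdiff(unique(labels), ATOM_CLASSES)
  if (length(bad)) stop("unknown atom class: ", paste(bad, collapse = ", "))
  code <- match(labels, c("NONE", "ACC", "DO", "AD", "ALI", "PI")) - 1L
  code
}

mode_code <- function(mode) {
  switch(match.arg(mode, c("all-pairs", "same-property", "relax")),
         "all-pairs" = 0L, "same-property" = 1L, "relax" = 2L)
}

#' Mean squared residual of a mapping under a transform
#'
#' The mean square error between `P` and `Q` for a point-to-point
#' mapping `psi` and transform `a`:
#' `f(psi, a) = mean(|Q[psi[i], ] - R p_i - t|^2)` in Angstrom^2.
#'
#' @param P n x 3 source coordinates.
#' @param Q m x 3 target coordinates.
#' @param mapping integer(n), values in `1..m`; need not be injective.
#' @param transform a [rigid_transform()].
#' @return non-negative scalar, zero iff all pairs coincide exactly.
#' @export
mean_square_error <- function(P, Q, mapping, transform = identity_transform()) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  mapping <- as.integer(mapping)
  if (length(mapping) != nrow(P)) stop("mapping must cover every point of P")
  if (any(mapping < 1) || any(mapping > nrow(Q)))
    stop("mapping index out of range")
  mean_sq_residual(P, Q[mapping, , drop = FALSE], transform)
}

#' Closest-point mapping
#'
#' Assigns each point of the (already transformed) query to its nearest
#' target point by Euclidean distance. Ties are broken by lowest target
#' index. The result minimizes the mean squared residual over all
#' (not necessarily injective) mappings.
#'
#' @param Pa n x 3 transformed query coordinates.
#' @param Q m x 3 target coordinates.
#' @param labels_P,labels_Q optional atom-class labels; when both are
#'   given and `restrict = TRUE`, each query atom only considers
#'   same-class targets.
#' @param restrict restrict to compatible labels (default `FALSE`).
#' @return integer(n) mapping into `1..m` (`NA` when a restricted atom
#'   has no compatible target).
#' @export
closest_point_mapping <- function(Pa, Q, labels_P = NULL, labels_Q = NULL,
                                  restrict = FALSE) {
  Pa <- as.matrix(Pa); Q <- as.matrix(Q)
  if (nrow(Pa) == 0 || nrow(Q) == 0) stop("empty point set")
  .cpp_closest_map(Pa, Q, label_codes(labels_P, nrow(Pa)),
                   label_codes(labels_Q, nrow(Q)), isTRUE(restrict))
}

#' Build the bipartite cost graph between two patches
#'
#' Nodes are the atoms of the transformed query (`Pa`) and of the target
#' (`Q`); an edge `(p, q)` carries cost `|q - p_a|^2` (Angstrom^2). In
#' `same-property` mode an edge is present only when the two atoms share
#' an atom class; `NONE`-labelled query atoms have no edges and are
#' excluded (reported in `excluded_p`). In `relax` mode incompatible
#' pairs are kept at a large finite penalty (10 x squared target
#' diameter) so batch runs never abort on infeasible label sets.
#'
#' @param Pa n x 3 transformed query coordinates.
#' @param Q m x 3 target coordinates (`n <= m` required; swap first).
#' @param labels_P,labels_Q atom-class labels (ignored in `all-pairs`).
#' @param mode `"all-pairs"`, `"same-property"` or `"relax"`.
#' @return object of class `cost_graph`: `edges` data frame
#'   (`p`, `q`, `cost`), counts `n`, `m`, the mode, and `excluded_p`.
#' @export
build_cost_graph <- function(Pa, Q, labels_P = NULL, labels_Q = NULL,
                             mode = c("all-pairs", "same-property", "relax")) {
  mode <- match.arg(mode)
  Pa <- as.matrix(Pa); Q <- as.matrix(Q)
  n <- nrow(Pa); m <- nrow(Q)
  if (n == 0 || m == 0) stop("empty point set")
  if (n > m) stop("build_cost_graph requires |P| <= |Q|; swap the patches")
  cp <- label_codes(labels_P, n)
  cq <- label_codes(labels_Q, m)
  D2 <- outer(rowSums(Pa^2), rowSums(Q^2), "+") - 2 * (Pa %*% t(Q))
  D2[D2 < 0] <- 0
  keep_p <- seq_len(n)
  excluded <- integer(0)
  if (mode == "same-property") {
    excluded <- which(cp == 0L)
    keep_p <- setdiff(keep_p, excluded)
    if (!length(keep_p)) stop("no query atoms carry a matchable atom class")
  }
  compat <- matrix(TRUE, n, m)
  if (mode != "all-pairs") compat <- outer(cp, cq, "==") & cp != 0L
  # relax-mode penalty: 10 x squared diameter of the joint point cloud
  penalty <- 10 * max(stats::dist(rbind(Pa, Q)))^2
  edges <- NULL
  if (mode == "same-property") {
    ok <- compat[keep_p, , drop = FALSE]
    miss <- keep_p[rowSums(ok) == 0]
    if (length(miss))
      stop("infeasible graph: query atom(s) ", paste(miss, collapse = ", "),
           " have no same-class target atom")
    idx <- which(ok, arr.ind = TRUE)
    edges <- data.frame(p = keep_p[idx[, 1]], q = idx[, 2],
                        cost = D2[cbind(keep_p[idx[, 1]], idx[, 2])])
  } else {
    idx <- expand.grid(p = seq_len(n), q = seq_len(m))
    cost <- D2[cbind(idx$p, idx$q)]
    if (mode == "relax") cost[!compat[cbind(idx$p, idx$q)]] <- penalty
    edges <- data.frame(p = idx$p, q = idx$q, cost = cost)
  }
  edges <- edges[order(edges$p, edges$q), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, m = m, mode = mode,
                 excluded_p = excluded, included_p = keep_p),
            class = "cost_graph")
}

#' @export
print.cost_graph <- function(x, ...) {
  cat("Bipartite cost graph: n =", x$n, ", m =", x$m, ", mode =", x$mode,
      ",", nrow(x$edges), "edges\n")
  if (length(x$excluded_p))
    cat("  excluded (NONE) query atoms:", paste(x$excluded_p, collapse = ", "), "\n")
  invisible(x)
}

#' Solve the asymmetric assignment problem on a cost graph
#'
#' Minimum-cost injective assignment: every query node matched to
#' exactly one target node, every target node used at most once. Solved
#' exactly by a shortest-augmenting-path (Jonker-Volgenant style)
#' method; ties between alternate optima are resolved deterministically
#' by lowest target index.
#'
#' @param graph a [build_cost_graph()] result.
#' @return list: `assignment` (integer(n), `NA` for excluded query
#'   atoms), `total_cost` (sum of selected edge costs, Angstrom^2),
#'   `mean_cost` (`total_cost` / number of assigned atoms).
#' @export
solve_aap <- function(graph) {
  stopifnot(inherits(graph, "cost_graph"))
  keep <- graph$included_p
  nr <- length(keep)
  cost <- matrix(NA_real_, nr, graph$m)
  e <- graph$edges
  cost[cbind(match(e$p, keep), e$q)] <- e$cost
  sol <- .cpp_solve_aap(cost)
  if (!sol$feasible)
    stop("infeasible assignment: no injective matching covers the query")
  assignment <- rep(NA_integer_, graph$n)
  assignment[keep] <- sol$assignment
  list(assignment = assignment, total_cost = sol$total_cost,
       mean_cost = sol$total_cost / nr)
}

#' Matching distance between a transformed query and a target
#'
#' The dissimilarity at transform `a`: the mean squared residual of the
#' minimum-cost *injective* assignment of query atoms to target atoms
#' (solution of the asymmetric assignment problem on the cost graph).
#' Because injectivity is a restriction of the mapping class, the
#' matching distance is never smaller than the closest-point objective
#' at the same transform.
#'
#' @inheritParams build_cost_graph
#' @param P n x 3 query coordinates (untransformed).
#' @param transform a [rigid_transform()] applied to `P`.
#' @return list: `value` (Angstrom^2), `assignment` (integer(n)).
#' @export
matching_distance <- function(P, Q, transform = identity_transform(),
                              labels_P = NULL, labels_Q = NULL,
                              mode = "all-pairs") {
  g <- build_cost_graph(apply_transform(transform, P), Q,
                        labels_P, labels_Q, mode)
  sol <- solve_aap(g)
  list(value = sol$mean_cost, assignment = sol$assignment)
}

#' Alignment objective g(a)
#'
#' Evaluates the scalar objective minimized by the optimizer at a given
#' transform: `kind = "closest"` uses the closest-point mapping (the
#' inner problem of ICP); `kind = "matching"` uses the injective
#' matching distance. Both are Lipschitz-continuous, non-smooth
#' functions of the transform and are evaluated in compiled code.
#'
#' @inheritParams matching_distance
#' @param kind `"matching"` (default) or `"closest"`.
#' @return scalar objective value (Angstrom^2); `Inf` for an infeasible
#'   configuration in `same-property` mode.
#' @export
objective <- function(P, Q, transform, kind = c("matching", "closest"),
                      labels_P = NULL, labels_Q = NULL, mode = "all-pairs") {
  kind <- match.arg(kind)
  make_objective(P, Q, kind, labels_P, labels_Q, mode)(as_vector7(transform))
}

#' Compile an objective closure over the 7-vector parameterization
#'
#' Returns `function(a7) -> Angstrom^2` suitable for [run_crs()]; `a7`
#' is quaternion (renormalized defensively) followed by translation.
#' @inheritParams objective
#' @keywords internal
#' @export
make_objective <- function(P, Q, kind = c("matching", "closest"),
                           labels_P = NULL, labels_Q = NULL,
                           mode = "all-pairs") {
  kind <- match.arg(kind)
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) == 0 || nrow(Q) == 0) stop("empty point set")
  cp <- label_codes(labels_P, nrow(P))
  cq <- label_codes(labels_Q, nrow(Q))
  mcode <- mode_code(mode)
  kcode <- if (kind == "closest") 0L else 1L
  # relax penalty: 10 x squared diameter of the joint point cloud
  penalty <- 10 * max(stats::dist(rbind(P, Q)))^2
  if (mcode == 1L) {
    # structural feasibility is independent of the transform: check once
    keep <- cp != 0L
    if (!any(keep)) stop("no query atoms carry a matchable atom class")
    miss <- which(keep)[!cp[keep] %in% cq]
    if (length(miss))
      stop("infeasible graph: query atom(s) ", paste(miss, collapse = ", "),
           " have no same-class target atom")
    if (kcode == 1L && sum(keep) > nrow(Q))
      stop("more matchable query atoms than target atoms; swap the patches")
  }
  if (kcode == 1L && mcode != 1L && nrow(P) > nrow(Q))
    stop("matching objective requires |P| <= |Q|; swap the patches")
  function(a7) .cpp_objective(P, Q, as.numeric(a7), cp, cq, kcode, mcode,
                              penalty)
}

#' Write a cost graph or assignment to TSV (debugging aid)
#' @param graph a `cost_graph`.
#' @param path output file.
#' @export
write_cost_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
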