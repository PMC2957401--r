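# Rigid-body transforms parameterized by unit quaternion + translation.

#' Construct a rigid-body transform
#'
#' A rigid (isometric) transform in 3D is stored as a unit quaternion
#' `q = (a0, a1, a2, a3)` plus a translation vector in Angstrom. The
#' quaternion is canonicalized so that `a0 >= 0` (and, when `a0 == 0`,
#' the first nonzero of `a1, a2, a3` is positive), resolving the
#' two-to-one quaternion cover of the rotation group.
#'
#' @param quaternion numeric(4), must have unit norm within `tol`.
#' @param translation numeric(3) in Angstrom.
#' @param tol tolerance on `abs(norm - 1)`.
#' @return An object of class `rigid_transform` with elements `q` and `t`.
#' @examples
#' rigid_transform(c(1, 0, 0, 0), c(1, 2, 3))
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0),
                            translation = c(0, 0, 0), tol = 1e-9) {
  q <- as.numeric(quaternion)
  t <- as.numeric(translation)
  stopifnot(length(q) == 4, length(t) == 3)
  if (any(!is.finite(q)) || any(!is.finite(t)))
    stop("non-finite transform components")
  nq <- sqrt(sum(q^2))
  if (abs(nq - 1) > tol)
    stop("quaternion is not unit norm (|", format(nq), "| - 1 > tol)")
  structure(list(q = quat_canonical(q / nq), t = t),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, digits = 4, ...) {
  cat("Rigid transform\n")
  cat("  quaternion : (", paste(signif(x$q, digits), collapse = ", "), ")\n")
  cat("  rotation   :", signif(rotation_angle(x$q), digits), "rad about (",
      paste(signif(rotation_axis(x$q), digits), collapse = ", "), ")\n")
  cat("  translation: (", paste(signif(x$t, digits), collapse = ", "), ") A\n")
  invisible(x)
}

#' Identity transform
#' @return `rigid_transform` leaving every point unchanged.
#' @export
identity_transform <- function() rigid_transform()

# Canonical sign for the quaternion double cover: first nonzero of
# (a0, a1, a2, a3) made positive.
quat_canonical <- function(q) {
  nz <- which(abs(q) > 0)
  if (length(nz) && q[nz[1]] < 0) q <- -q
  q
}

rotation_angle <- function(q) 2 * acos(min(1, max(-1, abs(q[1]))))

rotation_axis <- function(q) {
  v <- q[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(0, 0, 1) else v / nv
}

#' Rotation matrix of a unit quaternion
#'
#' Diagonal entries are `a0^2 + ai^2 - aj^2 - ak^2`; off-diagonals follow
#' the standard (Horn) quaternion convention, giving a proper rotation
#' (orthogonal, determinant +1).
#'
#' @param quaternion numeric(4) of unit norm (within `tol`).
#' @param tol norm tolerance.
#' @return 3x3 rotation matrix.
#' @examples
#' rotation_matrix(c(1, 0, 0, 0))            # identity
#' rotation_matrix(c(0, 0, 0, 1))            # 180 degrees about z
#' @export
rotation_matrix <- function(quaternion, tol = 1e-6) {
  q <- as.numeric(quaternion)
  stopifnot(length(q) == 4)
  nq <- sqrt(sum(q^2))
  if (abs(nq - 1) > tol) stop("quaternion is not unit norm")
  q <- q / nq
  a0 <- q[1]; a1 <- q[2]; a2 <- q[3]; a3 <- q[4]
  matrix(c(
    a0^2 + a1^2 - a2^2 - a3^2, 2 * (a1 * a2 - a0 * a3), 2 * (a1 * a3 + a0 * a2),
    2 * (a1 * a2 + a0 * a3), a0^2 + a2^2 - a1^2 - a3^2, 2 * (a2 * a3 - a0 * a1),
    2 * (a1 * a3 - a0 * a2), 2 * (a2 * a3 + a0 * a1), a0^2 + a3^2 - a1^2 - a2^2
  ), nrow = 3, byrow = TRUE)
}

#' Apply a rigid transform to a point set
#'
#' @param transform a `rigid_transform`.
#' @param coords n x 3 numeric matrix of coordinates (Angstrom); a bare
#'   numeric(3) is treated as a single point.
#' @return Matrix of the same shape, `R %*% x + t` row-wise. Order is
#'   preserved and all pairwise distances are unchanged (isometry).
#' @export
apply_transform <- function(transform, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty point set")
  if (ncol(coords) != 3) stop("coords must be n x 3")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  R <- rotation_matrix(transform$q)
  sweep(coords %*% t(R), 2, transform$t, "+")
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` is the transform applying `b` first, then
#' `a` (i.e. `T_a(T_b(x))`).
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  qa <- a$q; qb <- b$q
  q <- c(
    qa[1] * qb[1] - qa[2] * qb[2] - qa[3] * qb[3] - qa[4] * qb[4],
    qa[1] * qb[2] + qa[2] * qb[1] + qa[3] * qb[4] - qa[4] * qb[3],
    qa[1] * qb[3] - qa[2] * qb[4] + qa[3] * qb[1] + qa[4] * qb[2],
    qa[1] * qb[4] + qa[2] * qb[3] - qa[3] * qb[2] + qa[4] * qb[1]
  )
  t <- as.numeric(rotation_matrix(a$q) %*% b$t) + a$t
  rigid_transform(q / sqrt(sum(q^2)), t)
}

#' Invert a rigid transform
#' @param a a `rigid_transform`.
#' @return The inverse transform.
#' @export
transform_invert <- function(a) {
  qi <- c(a$q[1], -a$q[2:4])
  rigid_transform(qi, as.numeric(-(rotation_matrix(qi) %*% a$t)))
}

#' Distance of a transform from the identity
#'
#' Used to judge recovery of a known ground truth: compose the estimate
#' with the inverse truth and measure how far the result is from the
#' identity (Euclidean norm of the canonical 7-vector difference).
#' @param a a `rigid_transform`.
#' @return non-negative scalar.
#' @export
transform_deviation <- function(a) {
  sqrt(sum((quat_canonical(a$q) - c(1, 0, 0, 0))^2) + sum(a$t^2))
}

#' Flatten / rebuild the 7-vector form
#' @param a a `rigid_transform`.
#' @return numeric(7): quaternion then translation.
#' @export
as_vector7 <- function(a) c(a$q, a$t)

#' Renormalize a raw candidate 7-vector
#'
#' The CRS reflection step produces a raw 7-vector whose quaternion part
#' need not be unit; the normalization divides the first four components
#' by their norm (the diagonal normalization matrix of the search step),
#' leaves the translation untouched, and canonicalizes the sign.
#'
#' @param a_raw numeric(7).
#' @return `rigid_transform`.
#' @export
normalize_candidate <- function(a_raw) {
  a_raw <- as.numeric(a_raw)
  stopifnot(length(a_raw) == 7)
  xi <- sqrt(sum(a_raw[1:4]^2))
  if (!is.finite(xi) || xi < 1e-12)
    stop("degenerate candidate: quaternion part has (near-)zero norm")
  rigid_transform(a_raw[1:4] / xi, a_raw[5:7])
}

#' Search domain for the translation component
#'
#' The quaternion component always lives on the unit 3-sphere; the
#' translation is sampled from an axis-aligned box.
#' @param lower,upper numeric(3) box bounds in Angstrom, `lower < upper`.
#' @return object of class `search_domain`.
#' @export
search_domain <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("need finite lower < upper per axis")
  structure(list(lower = lower, upper = upper), class = "search_domain")
}

#' Default translation box for aligning P onto Q
#'
#' Centered on `centroid(Q) - centroid(P)` with per-axis half-width
#' `diameter(P)/2 + diameter(Q)/2`, which strictly contains the optimal
#' translation for any rotation.
#' @param P,Q n x 3 coordinate matrices.
#' @return `search_domain`.
#' @export
default_search_domain <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  ctr <- colMeans(Q) - colMeans(P)
  diam <- function(X) {
    if (nrow(X) == 1) return(0)
    max(stats::dist(X))
  }
  hw <- max(1e-3, diam(P) / 2 + diam(Q) / 2)
  search_domain(ctr - hw, ctr + hw)
}

#' Draw a random transform from the search domain
#'
#' The quaternion is uniform on the unit 3-sphere (normalized 4D
#' standard normal, canonical sign); the translation is uniform in the
#' box. Uses R's RNG stream, so results are reproducible under
#' `set.seed()`.
#' @param domain a `search_domain`.
#' @return `rigid_transform`.
#' @export
random_transform <- function(domain) {
  repeat {
    g <- rnorm(4)
    n <- sqrt(sum(g^2))
    if (n > 1e-8) break
  }
  t <- domain$lower + runif(3) * (domain$upper - domain$lower)
  rigid_transform(g / n, t)
}

#' Optimal rigid transform for a fixed mapping (absolute orientation)
#'
#' Given a mapping `psi` sending each point of `P` to a point of `Q`,
#' returns the rigid transform minimizing the mean squared residual
#' `mean(|Q[psi[i], ] - R p_i - t|^2)` in closed form via the quaternion
#' eigenvalue method: the optimal rotation is the dominant eigenvector
#' of the 4x4 matrix built from the cross-covariance of the centered
#' point sets.
#'
#' If the mapped points are all (numerically) coincident, the rotation
#' is left at identity and only centroids are aligned.
#'
#' @param P n x 3 source coordinates.
#' @param Q m x 3 target coordinates.
#' @param psi integer vector of length n with values in `1..m`
#'   (default: identity mapping, requires `n == m`).
#' @return list with `transform` (`rigid_transform`) and `msd`, the
#'   attained mean squared residual in Angstrom^2.
#' @export
optimal_transform <- function(P, Q, psi = seq_len(nrow(P))) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  if (n < 1) stop("need at least one point")
  psi <- as.integer(psi)
  if (length(psi) != n || any(psi < 1) || any(psi > nrow(Q)))
    stop("psi must map every point of P into Q")
  Qm <- Q[psi, , drop = FALSE]
  pbar <- colMeans(P); qbar <- colMeans(Qm)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Qm, 2, qbar)
  S <- crossprod(Pc, Qc)  # S[a, b] = sum p_a q_b
  if (sqrt(sum(S^2)) < 1e-12) {
    tf <- rigid_transform(c(1, 0, 0, 0), qbar - pbar)
    return(list(transform = tf, msd = mean_sq_residual(P, Qm, tf)))
  }
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  q <- quat_canonical(q / sqrt(sum(q^2)))
  R <- rotation_matrix(q)
  tf <- rigid_transform(q, qbar - as.numeric(R %*% pbar))
  list(transform = tf, msd = mean_sq_residual(P, Qm, tf))
}

mean_sq_residual <- function(P, Qm, tf) {
  d <- Qm - apply_transform(tf, P)
  mean(rowSums(d^2))
}

#' Serialize a transform
#'
#' @param a a `rigid_transform`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON with fields `quaternion` and `translation` (invisibly,
#'   when written to file).
#' @export
transform_to_json <- function(a, path = NULL) {
  js <- jsonlite::toJSON(list(quaternion = a$q, translation = a$t),
                         auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname transform_to_json
#' @param json JSON string or file path to parse back.
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  rigid_transform(x$quaternion, x$translation)
}

#' Homogeneous 4x4 matrix form of a transform
#'
#' Interoperable with molecular viewers: top-left 3x3 rotation, last
#' column translation, bottom row (0 0 0 1).
#' @param a a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
as_homogeneous_matrix <- function(a) {
  H <- diag(4)
  H[1:3, 1:3] <- rotation_matrix(a$q)
  H[1:3, 4] <- a$t
  H
}
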