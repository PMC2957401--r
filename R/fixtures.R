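# Synthetic benchmark instances with known ground truth: point clouds
# related by a planted rigid transform, optional Gaussian noise, and
# decoy atoms, plus mock PDB output for end-to-end testing.

# residue/atom-name encoding of each atom class, chosen so that
# assign_atom_properties() reproduces the label from the names
CLASS_ENCODING <- data.frame(
  label = c("ACC", "DO", "AD", "ALI", "PI", "NONE"),
  resname = c("ASP", "LYS", "SER", "ALA", "PHE", "UNK"),
  atomname = c("OD1", "NZ", "OG", "CB", "CG", "X"),
  element = c("O", "N", "O", "C", "C", "X"),
  stringsAsFactors = FALSE
)

#' Generate a synthetic alignment instance with known ground truth
#'
#' Samples a query patch `P` uniformly in a 20 Angstrom box centered at
#' the origin, applies a (given or random) rigid transform, adds
#' isotropic Gaussian coordinate noise of standard deviation `sigma`
#' per axis, appends `decoys` distractor atoms, and shuffles the target
#' order. Decoys are kept at least `2 * sigma + 1` Angstrom away from
#' every true correspondent, so at `sigma = 0` the planted assignment
#' is the unique optimum of the matching distance at the ground-truth
#' transform.
#'
#' @param n number of true atoms (>= 3).
#' @param decoys number of decoy atoms appended to the target.
#' @param sigma per-axis Gaussian noise, Angstrom (>= 0).
#' @param transform planted `rigid_transform`, or `NULL` for a random
#'   one (rotation uniform, translation uniform in \[-10, 10\]^3).
#' @param label_scheme `"compatible"` copies each true atom's class to
#'   its correspondent (decoys get random classes); `"uniform"` draws
#'   all labels independently from the five classes.
#' @param seed optional integer seed.
#' @return object of class `synthetic_instance`: patches `P` and `Q`,
#'   `ground_truth` transform, `correspondence` (index of each P atom
#'   in Q), `sigma`, `decoys`, `seed`.
#' @export
make_instance <- function(n, decoys = 0, sigma = 0, transform = NULL,
                          label_scheme = c("compatible", "uniform"),
                          seed = NULL) {
  label_scheme <- match.arg(label_scheme)
  if (n < 3) stop("need n >= 3")
  if (sigma < 0 || decoys < 0) stop("invalid sizes")
  if (!is.null(seed)) set.seed(seed)
  classes <- setdiff(ATOM_CLASSES, "NONE")
  P <- matrix(runif(3 * n, -10, 10), ncol = 3)
  if (is.null(transform)) {
    transform <- random_transform(search_domain(rep(-10, 3), rep(10, 3)))
  }
  lab_P <- sample(classes, n, replace = TRUE)
  true_Q <- apply_transform(transform, P) +
    matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  lab_true <- if (label_scheme == "compatible") lab_P
              else sample(classes, n, replace = TRUE)
  margin <- 2 * sigma + 1
  box_lo <- apply(true_Q, 2, min); box_hi <- apply(true_Q, 2, max)
  dec <- matrix(numeric(0), ncol = 3)
  while (nrow(dec) < decoys) {
    cand <- matrix(box_lo + runif(3) * (box_hi - box_lo), ncol = 3)
    d <- sqrt(rowSums((true_Q - matrix(cand, n, 3, byrow = TRUE))^2))
    if (min(d) >= margin) dec <- rbind(dec, cand)
  }
  lab_dec <- sample(classes, decoys, replace = TRUE)
  Qc <- rbind(true_Q, dec)
  lab_Q <- c(lab_true, lab_dec)
  perm <- sample.int(nrow(Qc))
  Qc <- Qc[perm, , drop = FALSE]
  lab_Q <- lab_Q[perm]
  correspondence <- match(seq_len(n), perm)
  structure(list(
    P = surface_patch(P, lab_P, source = "synthetic query"),
    Q = surface_patch(Qc, lab_Q, source = "synthetic target"),
    ground_truth = transform,
    correspondence = correspondence,
    sigma = sigma, decoys = as.integer(decoys), seed = seed
  ), class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("Synthetic instance: n =", nrow(x$P$coords), ", decoys =", x$decoys,
      ", sigma =", x$sigma, "A\n")
  invisible(x)
}

#' Write a synthetic instance as a mock PDB file
#'
#' Patch atoms become ATOM records whose residue/atom names encode
#' their class (so [assign_atom_properties()] reproduces the labels:
#' e.g. an acceptor is written as an aspartate OD1); each atom occupies
#' its own residue. A fake HETATM ligand (`LIG`, chain `L`) is written
#' 1 Angstrom from every patch atom, so extraction with the default
#' 4.0 Angstrom shell recovers exactly the patch.
#'
#' @param instance a [make_instance()] result (or any `surface_patch`
#'   via `patch =`).
#' @param path output PDB path.
#' @param which write the query (`"P"`) or target (`"Q"`) patch.
#' @return `path`, invisibly.
#' @export
write_mock_pdb <- function(instance, path, which = c("P", "Q")) {
  which <- match.arg(which)
  patch <- instance[[which]]
  co <- patch$coords
  n <- nrow(co)
  enc <- CLASS_ENCODING[match(patch$labels, CLASS_ENCODING$label), ]
  fmt <- "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  atom_lines <- sprintf(fmt, "ATOM", seq_len(n), enc$atomname, enc$resname,
                        "A", seq_len(n), co[, 1], co[, 2], co[, 3],
                        1, 0, enc$element)
  # one ligand atom near every patch atom; alternating offsets keep the
  # default 4.0 A shell exhaustive while sub-Angstrom cutoffs select a
  # proper subset (monotonicity remains testable end-to-end)
  off <- ifelse(seq_len(n) %% 2 == 1, 0.4, 1.0)
  lig <- co + cbind(off, 0, 0)
  lig_lines <- sprintf(fmt, "HETATM", n + seq_len(n), paste0("C", seq_len(n)),
                       "LIG", "L", 1, lig[, 1], lig[, 2], lig[, 3], 1, 0, "C")
  writeLines(c(atom_lines, lig_lines, "END"), path)
  invisible(path)
}

#' Ground-truth sidecar for a synthetic instance
#' @param instance a `synthetic_instance`.
#' @param path JSON output path.
#' @export
write_instance_truth <- function(instance, path) {
  jsonlite::write_json(list(
    quaternion = instance$ground_truth$q,
    translation = instance$ground_truth$t,
    correspondence = instance$correspondence,
    sigma = instance$sigma, decoys = instance$decoys
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
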