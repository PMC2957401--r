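# Shared fixtures and independent oracles used across test files.

# Brute-force minimum-cost injective assignment by exhaustive
# enumeration (n <= m small). Independent of the package solver.
brute_force_aap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  best <- Inf; best_assign <- NULL
  # enumerate all injective maps recursively
  recurse <- function(i, used, acc, assign) {
    if (acc >= best) return(invisible())
    if (i > n) {
      best <<- acc; best_assign <<- assign
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <- TRUE
        recurse(i + 1, used, acc + cost[i, j], c(assign, j))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(m), 0, integer(0))
  list(total_cost = best, assignment = best_assign)
}

# random rigid transform with R's RNG
random_unit_quat <- function() {
  g <- rnorm(4)
  q <- g / sqrt(sum(g^2))
  if (q[1] < 0) q <- -q
  q
}

random_point_cloud <- function(n, half = 8) {
  matrix(runif(3 * n, -half, half), ncol = 3)
}

# deviation between two transforms as maps (composition with inverse)
composition_error <- function(a, b) {
  transform_deviation(transform_compose(a, transform_invert(b)))
}

# tiny 3-atom PDB text fixture: two protein atoms + one ligand atom
write_mini_pdb <- function(path,
                           prot = list(c(1, 0, 0), c(0, 0, 3.9)),
                           resnames = c("ALA", "ALA"),
                           atomnames = c("CB", "CB"),
                           lig = c(0, 0, 0)) {
  fmt <- "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- character(0)
  for (i in seq_along(prot)) {
    p <- prot[[i]]
    lines <- c(lines, sprintf(fmt, "ATOM", i, atomnames[i], resnames[i],
                              "A", i, p[1], p[2], p[3], 1, 0,
                              substr(atomnames[i], 1, 1)))
  }
  lines <- c(lines, sprintf(fmt, "HETATM", length(prot) + 1, "C1", "LIG",
                            "L", 1, lig[1], lig[2], lig[3], 1, 0, "C"),
             "END")
  writeLines(lines, path)
  path
}
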