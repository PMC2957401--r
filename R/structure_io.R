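# PDB ingestion, binding-site extraction (ligand distance shell), and
# physico-chemical atom typing.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Read a PDB structure
#'
#' Parses ATOM and HETATM records (fixed-column PDB) via `bio3d`, after
#' a pre-scan that reports malformed coordinate records by line number.
#' Alternate locations are resolved by keeping the highest-occupancy
#' altloc of each (chain, residue, insert, atom name); only the first
#' MODEL of multi-model files is used. Hydrogens and waters (HOH) are
#' kept in the record but flagged, and excluded by default downstream.
#'
#' @param path path to a PDB file.
#' @return object of class `pdb_structure`: a data frame `atoms` with
#'   columns `record`, `serial`, `atomname`, `resname`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `occupancy`, `element`,
#'   `is_water`, `is_hydrogen`, plus the source `path`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("parse error in ", path, ": no ATOM/HETATM records")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54)))))) {
      stop("parse error in ", path, " at line ", i,
           ": malformed coordinate fields")
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop("parse error in ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  atoms <- data.frame(
    record = at$type, serial = at$eleno, atomname = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o), element = elem,
    stringsAsFactors = FALSE
  )
  # altloc resolution: keep highest occupancy (first on ties) per atom id
  key <- paste(atoms$record, atoms$chain, atoms$resno, atoms$insert,
               atoms$resname, atoms$atomname)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$serial), ]
  rownames(atoms) <- NULL
  atoms$is_water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  structure(list(atoms = atoms, path = path), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("PDB structure:", x$path, "\n ", nrow(x$atoms), "atoms (",
      sum(x$atoms$record == "ATOM"), "ATOM,",
      sum(x$atoms$record == "HETATM"), "HETATM )\n")
  invisible(x)
}

#' Construct a surface patch
#'
#' A surface patch is a finite labelled point set: atom coordinates in
#' Angstrom plus a physico-chemical class per atom.
#'
#' @param coords n x 3 numeric matrix.
#' @param labels character(n) drawn from [ATOM_CLASSES] (default all
#'   `"NONE"`).
#' @param atoms optional data frame of per-atom identifiers (`chain`,
#'   `resno`, `resname`, `atomname`).
#' @param source provenance string.
#' @return object of class `surface_patch`.
#' @export
surface_patch <- function(coords, labels = NULL, atoms = NULL,
                          source = "synthetic") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || ncol(coords) != 3 || any(!is.finite(coords)))
    stop("coords must be a non-empty finite n x 3 matrix")
  n <- nrow(coords)
  if (is.null(labels)) labels <- rep("NONE", n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per atom required")
  if (!all(labels %in% ATOM_CLASSES))
    stop("labels must be in ", paste(ATOM_CLASSES, collapse = "/"))
  if (is.null(atoms)) {
    atoms <- data.frame(chain = "A", resno = seq_len(n),
                        resname = "UNK", atomname = "X",
                        stringsAsFactors = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, labels = labels, atoms = atoms,
                 source = source), class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("Surface patch:", nrow(x$coords), "atoms (", x$source, ")\n")
  print(table(factor(x$labels, levels = ATOM_CLASSES)))
  invisible(x)
}

#' @export
length.surface_patch <- function(x) nrow(x$coords)

#' @export
as.data.frame.surface_patch <- function(x, ...) {
  cbind(x$atoms,
        as.data.frame(x$coords),
        data.frame(label = x$labels, stringsAsFactors = FALSE))
}

#' Extract a binding site as the ligand distance shell
#'
#' The binding site of a ligand is the set of polymer (ATOM-record)
#' heavy atoms lying within `cutoff` Angstrom of *any* ligand atom
#' (inclusive boundary; atom-center to atom-center distance). Waters
#' and hydrogens are excluded by default. The extracted patch is typed
#' with [assign_atom_properties()].
#'
#' @param structure a [read_structure()] result.
#' @param ligand HETATM residue name of the ligand (e.g. `"ATP"`).
#' @param chain optional chain qualifier; when several copies match and
#'   no chain is given, the first by chain order is used with a warning.
#' @param cutoff shell radius in Angstrom (default 4.0).
#' @param include_waters,include_hydrogens include flagged atoms.
#' @param type assign physico-chemical labels (default `TRUE`).
#' @return a [surface_patch()].
#' @export
extract_binding_site <- function(structure, ligand, chain = NULL,
                                 cutoff = 4.0, include_waters = FALSE,
                                 include_hydrogens = FALSE, type = TRUE) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- structure$atoms
  het <- at[at$record == "HETATM" & !at$is_water, , drop = FALSE]
  lig <- het[het$resname == toupper(ligand), , drop = FALSE]
  if (nrow(lig) == 0) {
    stop("ligand ", ligand, " not found; available HETATM residues: ",
         paste(sort(unique(het$resname)), collapse = ", "))
  }
  if (!is.null(chain)) {
    lig <- lig[lig$chain == chain, , drop = FALSE]
    if (nrow(lig) == 0) stop("ligand ", ligand, " not found on chain ", chain)
  } else {
    copies <- unique(paste(lig$chain, lig$resno))
    if (length(copies) > 1) {
      warning("multiple copies of ", ligand, "; using the first (",
              copies[1], ")")
      first <- strsplit(copies[1], " ")[[1]]
      lig <- lig[lig$chain == first[1] & lig$resno == as.integer(first[2]), ,
                 drop = FALSE]
    }
  }
  prot <- at[at$record == "ATOM", , drop = FALSE]
  if (!include_waters) prot <- prot[!prot$is_water, , drop = FALSE]
  if (!include_hydrogens) prot <- prot[!prot$is_hydrogen, , drop = FALSE]
  if (nrow(prot) == 0) stop("no protein atoms in structure")
  pc <- as.matrix(prot[, c("x", "y", "z")])
  lc <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * (pc %*% t(lc))
  keep <- apply(d2, 1, min) <= cutoff^2 + 1e-12
  if (!any(keep)) stop("empty binding site at cutoff ", cutoff, " A")
  sel <- prot[keep, , drop = FALSE]
  patch <- surface_patch(
    as.matrix(sel[, c("x", "y", "z")]),
    atoms = sel[, c("chain", "resno", "resname", "atomname")],
    source = paste0(structure$path, " | ligand ", ligand,
                    if (!is.null(chain)) paste0(" chain ", chain),
                    " | cutoff ", cutoff, " A")
  )
  if (type) assign_atom_properties(patch) else patch
}

#' The shipped atom-typing rule table
#'
#' Lookup table keyed by (residue name, atom name); `*` rows apply to
#' any residue (backbone atoms). Edit the TSV under
#' `inst/extdata/atom_property_rules.tsv` to change the chemistry
#' without touching code.
#' @return data frame with columns `resname`, `atomname`, `label`.
#' @export
default_atom_rules <- function() {
  utils::read.table(
    system.file("extdata", "atom_property_rules.tsv", package = "surfalign"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
}

#' Assign physico-chemical classes to patch atoms
#'
#' Pure lookup in the rule table: exact (residue, atom) rows take
#' precedence over wildcard backbone rows; for standard amino acids an
#' element-based fallback applies (C -> ALI, O -> ACC, N -> DO);
#' anything else becomes `NONE` with a warning. Deterministic and
#' idempotent.
#'
#' @param patch a [surface_patch()].
#' @param rules rule table (default [default_atom_rules()]).
#' @return the patch with `labels` filled in.
#' @export
assign_atom_properties <- function(patch, rules = default_atom_rules()) {
  stopifnot(inherits(patch, "surface_patch"))
  res <- toupper(trimws(patch$atoms$resname))
  atm <- toupper(trimws(patch$atoms$atomname))
  lab <- rep(NA_character_, length(res))
  exact <- match(paste(res, atm), paste(rules$resname, rules$atomname))
  lab[!is.na(exact)] <- rules$label[exact[!is.na(exact)]]
  wild <- rules[rules$resname == "*", ]
  w <- match(atm, wild$atomname)
  fill <- is.na(lab) & !is.na(w)
  lab[fill] <- wild$label[w[fill]]
  # element fallback for standard residues
  open <- is.na(lab) & res %in% STANDARD_AA
  first <- substr(atm, 1, 1)
  lab[open & first == "C"] <- "ALI"
  lab[open & first == "O"] <- "ACC"
  lab[open & first == "N"] <- "DO"
  unknown <- is.na(lab)
  if (any(unknown)) {
    warning("unclassified atom(s) set to NONE: ",
            paste(unique(paste(res[unknown], atm[unknown])), collapse = ", "))
    lab[unknown] <- "NONE"
  }
  patch$labels <- lab
  patch
}

#' Write / read the patch TSV exchange format
#'
#' Tab-separated with header `chain resno resname atomname x y z label`;
#' coordinates in Angstrom written to 3 decimals, residue numbering as
#' in the source PDB.
#' @param patch a `surface_patch`.
#' @param path file path.
#' @export
write_patch <- function(patch, path) {
  df <- as.data.frame(patch)
  df$x <- sprintf("%.3f", df$x)
  df$y <- sprintf("%.3f", df$y)
  df$z <- sprintf("%.3f", df$z)
  utils::write.table(df[, c("chain", "resno", "resname", "atomname",
                            "x", "y", "z", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch
#' @return `read_patch` returns a `surface_patch`.
#' @export
read_patch <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chain = "character",
                                         resname = "character",
                                         atomname = "character",
                                         label = "character"))
  need <- c("chain", "resno", "resname", "atomname", "x", "y", "z", "label")
  if (!all(need %in% names(df)))
    stop("patch file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  surface_patch(as.matrix(df[, c("x", "y", "z")]), labels = df$label,
                atoms = df[, c("chain", "resno", "resname", "atomname")],
                source = path)
}
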