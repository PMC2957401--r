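test_that("read_structure parses a minimal PDB with correct coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, prot = list(c(1, 0, 0), c(0, 0, 3.9)))
  s <- read_structure(f)
  expect_s3_class(s, "pdb_structure")
  expect_equal(nrow(s$atoms), 3)
  prot <- s$atoms[s$atoms$record == "ATOM", ]
  expect_equal(prot$x, c(1, 0))
  expect_equal(prot$z, c(0, 3.9))
  expect_equal(s$atoms$resname[s$atoms$record == "HETATM"], "LIG")
})

test_that("read_structure reports malformed and empty files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structure(f), "no ATOM/HETATM")
  writeLines(c("ATOM      1  CB  ALA A   1        bad coords"), f)
  expect_error(read_structure(f), "line 1")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "no such")
})

test_that("altloc resolution keeps the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "CB", "A", "ALA", "A", 1, 1, 0, 0, 0.4, 0, "C"),
    sprintf(fmt, "ATOM", 2, "CB", "B", "ALA", "A", 1, 2, 0, 0, 0.6, 0, "C"),
    sprintf(fmt, "HETATM", 3, "C1", " ", "LIG", "L", 1, 0, 0, 0, 1, 0, "C"),
    "END"), f)
  s <- read_structure(f)
  cb <- s$atoms[s$atoms$atomname == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2)  # the occupancy-0.6 altloc B survives
})

test_that("binding-site extraction respects the inclusive 4 A boundary", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, prot = list(c(0, 0, 3.9), c(0, 0, 4.1)),
                 lig = c(0, 0, 0))
  s <- read_structure(f)
  patch <- extract_binding_site(s, "LIG")
  expect_equal(nrow(patch$coords), 1)
  expect_equal(patch$coords[1, 3], 3.9, ignore_attr = TRUE)
  # both inside at a wider cutoff: monotone in cutoff
  p2 <- extract_binding_site(s, "LIG", cutoff = 4.2)
  expect_equal(nrow(p2$coords), 2)
  p3 <- extract_binding_site(s, "LIG", cutoff = 3.95)
  expect_true(all(p3$coords %in% p2$coords))
  expect_error(extract_binding_site(s, "LIG", cutoff = 1), "empty")
  expect_error(extract_binding_site(s, "ATP"), "available HETATM.*LIG")
})

test_that("extraction scopes to the selected ligand copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "CB", "ALA", "A", 1, 0, 0, 1, 1, 0, "C"),
    sprintf(fmt, "ATOM", 2, "CB", "ALA", "A", 2, 50, 0, 1, 1, 0, "C"),
    sprintf(fmt, "HETATM", 3, "C1", "LIG", "L", 1, 0, 0, 0, 1, 0, "C"),
    sprintf(fmt, "HETATM", 4, "C1", "LIG", "M", 1, 50, 0, 0, 1, 0, "C"),
    "END"), f)
  s <- read_structure(f)
  pM <- extract_binding_site(s, "LIG", chain = "M")
  expect_equal(pM$coords[, 1], 50, ignore_attr = TRUE)
  expect_warning(pAll <- extract_binding_site(s, "LIG"), "multiple copies")
  expect_equal(nrow(pAll$coords), 1)  # first copy (chain L) only
})

test_that("waters and hydrogens are excluded by default", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "CB", "ALA", "A", 1, 0, 0, 1, 1, 0, "C"),
    sprintf(fmt, "ATOM", 2, "HB1", "ALA", "A", 1, 0, 0, 1.5, 1, 0, "H"),
    sprintf(fmt, "HETATM", 3, "O", "HOH", "A", 2, 0, 1, 0, 1, 0, "O"),
    sprintf(fmt, "HETATM", 4, "C1", "LIG", "L", 1, 0, 0, 0, 1, 0, "C"),
    "END"), f)
  s <- read_structure(f)
  patch <- extract_binding_site(s, "LIG")
  expect_equal(nrow(patch$coords), 1)
  expect_equal(patch$atoms$atomname, "CB")
})

test_that("atom typing follows the rule table with element fallbacks", {
  patch <- surface_patch(
    matrix(0, 7, 3) + seq_len(7),
    atoms = data.frame(
      chain = "A", resno = 1:7,
      resname = c("LYS", "ASP", "PHE", "GLY", "SER", "PRO", "XYZ"),
      atomname = c("NZ", "OD1", "CG", "O", "OG", "N", "Q1")))
  expect_warning(typed <- assign_atom_properties(patch), "unclassified")
  expect_equal(typed$labels,
               c("DO", "ACC", "PI", "ACC", "AD", "NONE", "NONE"))
  # deterministic and idempotent
  expect_identical(suppressWarnings(assign_atom_properties(typed))$labels,
                   typed$labels)
})

test_that("patch TSV round-trips coordinates and labels", {
  set.seed(81)
  patch <- surface_patch(round(random_point_cloud(9), 3),
                         labels = sample(ATOM_CLASSES, 9, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_patch(patch, f)
  back <- read_patch(f)
  expect_equal(back$coords, patch$coords, tolerance = 1e-9)
  expect_identical(back$labels, patch$labels)
  expect_identical(back$atoms$resno, patch$atoms$resno)
})
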