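# hand-written fixed-width PDB records for parser tests
pdbLine <- function(type, serial, name, resn, chain, resno, xyz,
                    occ = 1.0, elem = "C", alt = " ") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resn, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], occ, 0, elem)
}

test_that("parsing partitions atoms into protein/ligand/water", {
  f <- tempfile(fileext = ".pdb")
  rc <- adenineCoords()
  lines <- c(
    vapply(1:6, function(i)
      pdbLine("ATOM", i, c("N", "CA", "C", "O", "N", "CA")[i], "GLY",
              "A", 10L + (i > 4L),
              c(10 + i, 0, 0), elem = c("N", "C", "C", "O", "N", "C")[i]),
      character(1L)),
    vapply(seq_len(nrow(rc)), function(i)
      pdbLine("HETATM", 6L + i, rownames(rc)[i], "ATP", "L", 1L, rc[i, ],
              elem = substr(rownames(rc)[i], 1L, 1L)), character(1L)),
    pdbLine("HETATM", 17L, "O", "HOH", "W", 1L, c(30, 0, 0), elem = "O"),
    "END")
  writeLines(lines, f)
  cs <- readComplex(f)
  expect_equal(nrow(atoms(cs)), 17L)
  expect_equal(as.integer(table(atoms(cs)$category)[c("protein", "ligand",
                                                      "water")]),
               c(6L, 10L, 1L))
  expect_equal(nrow(ligandInstances(cs)), 1L)
  expect_equal(ligandInstances(cs)$residue_name, "ATP")
  expect_true(all(atoms(cs)$is_backbone[atoms(cs)$category == "protein"]))
})

test_that("altloc policy keeps the highest occupancy, ties to A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdbLine("ATOM", 1L, "N", "GLY", "A", 10L, c(0, 0, 0), elem = "N"),
    pdbLine("ATOM", 2L, "CA", "GLY", "A", 10L, c(1.5, 0, 0), occ = 0.4,
            elem = "C", alt = "A"),
    pdbLine("ATOM", 3L, "CA", "GLY", "A", 10L, c(1.7, 0, 0), occ = 0.6,
            elem = "C", alt = "B"),
    pdbLine("ATOM", 4L, "CB", "GLY", "A", 10L, c(2.5, 0, 0), occ = 0.5,
            elem = "C", alt = "B"),
    pdbLine("ATOM", 5L, "CB", "GLY", "A", 10L, c(2.4, 0, 0), occ = 0.5,
            elem = "C", alt = "A"),
    "END"), f)
  cs <- readComplex(f)
  at <- atoms(cs)
  expect_equal(nrow(at), 3L)
  expect_equal(at$x[at$atom_name == "CA"], 1.7)  # occupancy 0.6 wins
  expect_equal(at$x[at$atom_name == "CB"], 2.4)  # tie -> altloc A
})

test_that("multi-model files reduce to model 1", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdbLine("ATOM", 1L, "N", "GLY", "A", 1L, c(1, 2, 3), elem = "N"),
    "ENDMDL",
    "MODEL        2",
    pdbLine("ATOM", 1L, "N", "GLY", "A", 1L, c(9, 9, 9), elem = "N"),
    "ENDMDL", "END"), f)
  cs <- readComplex(f)
  expect_equal(cs@modelNumber, 1L)
  expect_equal(nrow(atoms(cs)), 1L)
  expect_equal(atoms(cs)$x, 1)
})

test_that("read/write round trip is the identity on the atom table", {
  g <- generateSite(sitePlan(data.frame(
    fragment_atom = c("N1", "N6", "N7"),
    descriptor = c("backbone_N", "backbone_O", "backbone_O"),
    distance = 2.9, in_plane_angle = c(0, 55, 0),
    mediated = c(FALSE, FALSE, TRUE)), seed = 5L))
  f <- tempfile(fileext = ".pdb")
  writeComplex(g$structure, f)
  cs2 <- readComplex(f, id = complexId(g$structure))
  a1 <- atoms(g$structure); a2 <- atoms(cs2)
  expect_identical(a1$atom_name, a2$atom_name)
  expect_identical(a1$residue_name, a2$residue_name)
  expect_identical(a1$residue_seq, a2$residue_seq)
  expect_identical(a1$chain_id, a2$chain_id)
  expect_identical(a1$category, a2$category)
  expect_equal(unname(as.matrix(a1[, c("x", "y", "z")])),
               unname(as.matrix(a2[, c("x", "y", "z")])),
               tolerance = 1e-9)
})

test_that("blank chain ids survive a round trip", {
  df <- data.frame(atom_name = "N", element = "N", residue_name = "GLY",
                   residue_seq = 1L, chain_id = "", x = 1, y = 2, z = 3,
                   category = "protein", stringsAsFactors = FALSE)
  cs <- makeStructure("blank", df)
  f <- tempfile(fileext = ".pdb")
  writeComplex(cs, f)
  cs2 <- readComplex(f)
  expect_equal(atoms(cs2)$chain_id, "")
  expect_equal(atoms(cs2)$x, 1)
})

test_that("out-of-range coordinates and empty files are rejected", {
  df <- data.frame(atom_name = "N", element = "N", residue_name = "GLY",
                   residue_seq = 1L, chain_id = "A", x = 10000, y = 0,
                   z = 0, category = "protein", stringsAsFactors = FALSE)
  expect_error(writeComplex(makeStructure("big", df), tempfile()),
               "fixed-width range")
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(readComplex(f))
  expect_error(readComplex(tempfile(fileext = ".pdb")), "no such file")
})

test_that("the PyMOL script marks partners, waters distinctly, and is stable", {
  plan <- sitePlan(data.frame(
    fragment_atom = c("N1", "N6", "N7"),
    descriptor = c("backbone_N", "backbone_O", "backbone_O"),
    distance = 2.9, in_plane_angle = c(0, 55, 0),
    mediated = c(FALSE, FALSE, TRUE)), seed = 9L)
  g <- generateSite(plan)
  s <- buildSite(g$structure, matchFragment(g$structure)[[1L]])
  f1 <- tempfile(fileext = ".pml"); f2 <- tempfile(fileext = ".pml")
  writePymolScript(list(s), f1)
  writePymolScript(list(s), f2)
  lines <- readLines(f1)
  expect_identical(lines, readLines(f2))          # deterministic
  markers <- grep("pseudoatom site", lines, value = TRUE)
  expect_length(markers, nrow(hbonds(s)))         # one marker per partner
  expect_true(any(grepl("show nonbonded", lines)))  # water "+" marker
  # empty input still yields a valid script with a header
  f3 <- tempfile(fileext = ".pml")
  writePymolScript(list(), f3)
  expect_gt(length(readLines(f3)), 1L)
})
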