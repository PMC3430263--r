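pdb_line <- function(rec, serial, name, resn, chain, resno, x, y, z,
                     elem = "C", alt = " ") {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          x, y, z, 1, 0, elem)
}

test_that("PDB parsing separates polymer, hetero and water and drops H/altLoc", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line("ATOM", 3, "H", "ALA", "A", 1, 2, 2, 2, elem = "H"),
    pdb_line("ATOM", 4, "CA", "GLY", "A", 2, 3, 0, 0, alt = "B"),
    pdb_line("HETATM", 5, "O", "HOH", "A", 100, 9, 9, 9, elem = "O"),
    pdb_line("HETATM", 6, "C1", "LIG", "B", 1, 5, 5, 5),
    "END"
  ), f)
  s <- read_pdb(f)
  expect_equal(sum(s$record == "polymer"), 2) # H and altLoc B dropped
  expect_equal(sum(s$record == "water"), 1)
  expect_equal(sum(s$record == "hetero"), 1)
  expect_false(any(polymer_atoms(s)$resname == "HOH"))
})

test_that("structures with no polymer atoms or missing files are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("HETATM", 1, "C1", "LIG", "A", 1, 0, 0, 0), "END"), f)
  expect_error(read_pdb(f), class = "pocketrank_empty_structure")
  expect_error(read_pdb(tempfile()), class = "pocketrank_io_error")
})

test_that("PDB round-trip preserves atom count, keys and coordinates to 3 dp", {
  fx <- make_structure(fixture_spec(seed = 21))
  f <- tempfile(fileext = ".pdb")
  write_pdb(fx$structure, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2), nrow(fx$structure))
  expect_equal(s2$chain, fx$structure$chain)
  expect_equal(s2$resno, fx$structure$resno)
  expect_equal(s2$resname, fx$structure$resname)
  expect_equal(s2$record, fx$structure$record)
  expect_equal(s2$x, fx$structure$x, tolerance = 1e-3)
  expect_equal(s2$z, fx$structure$z, tolerance = 1e-3)
})

test_that("protein centroid is the unweighted polymer mean", {
  expect_equal(protein_centroid(atoms_tbl(rbind(c(0, 0, 0), c(2, 0, 0)))),
               c(x = 1, y = 0, z = 0))
  expect_equal(protein_centroid(atoms_tbl(matrix(c(4, -1, 7), 1))),
               c(x = 4, y = -1, z = 7))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(protein_centroid(atoms_tbl(cube)), c(x = .5, y = .5, z = .5))
  # hetero atoms must not contribute
  s <- dplyr::bind_rows(atoms_tbl(rbind(c(0, 0, 0), c(2, 0, 0))),
                        atoms_tbl(matrix(c(100, 0, 0), 1), record = "hetero"))
  expect_equal(unname(protein_centroid(s)), c(1, 0, 0))
  expect_error(protein_centroid(atoms_tbl(matrix(c(0, 0, 0), 1),
                                          record = "hetero")),
               class = "pocketrank_empty_structure")
})

test_that("centroid is translation-equivariant", {
  withr::with_seed(5, {
    base <- matrix(stats::runif(60, -10, 10), ncol = 3)
    for (i in 1:10) {
      v <- stats::rnorm(3, sd = 20)
      shifted <- sweep(base, 2, v, "+")
      expect_equal(unname(protein_centroid(atoms_tbl(shifted))),
                   unname(protein_centroid(atoms_tbl(base))) + v,
                   tolerance = 1e-12)
    }
  })
})

test_that("ligand extraction applies the size and water rules", {
  het20 <- atoms_tbl(matrix(stats::runif(60), ncol = 3), resno = 1,
                     resname = "NAD", chain = "B", record = "hetero")
  poly <- atoms_tbl(matrix(c(0, 0, 0), 1))
  lig <- extract_ligands(dplyr::bind_rows(poly, het20))
  expect_equal(nrow(lig), 1)
  expect_equal(lig$n_atoms, 20L)
  expect_equal(lig$het_code, "NAD")

  waters <- atoms_tbl(matrix(stats::runif(30), ncol = 3), resno = 1:10,
                      resname = "HOH", record = "water")
  expect_equal(nrow(extract_ligands(dplyr::bind_rows(poly, waters))), 0)

  # five-atom group falls under the default heavy-atom minimum
  het5 <- atoms_tbl(matrix(stats::runif(15), ncol = 3), resno = 2,
                    resname = "SO4", record = "hetero")
  expect_equal(nrow(extract_ligands(dplyr::bind_rows(poly, het5))), 0)
  expect_equal(nrow(extract_ligands(dplyr::bind_rows(poly, het5),
                                    min_heavy_atoms = 5)), 1)
})

test_that("the planted fixture ligand is recovered exactly", {
  fx <- make_structure(fixture_spec(seed = 33, ligand_size = 10))
  lig <- extract_ligands(fx$structure, min_heavy_atoms = 6)
  expect_equal(nrow(lig), 1)
  expect_equal(lig$n_atoms, 10L)
  ctr <- fx$truth$cavity_centers[[fx$truth$ligand_cavity]]
  expect_lt(sqrt(sum((colMeans(as.matrix(lig$atoms[[1]][, c("x", "y", "z")])) -
                      ctr)^2)), 1e-6)
})

test_that("conservation profiles parse, reject duplicates and bad lines", {
  f <- tempfile()
  writeLines(c("# comment", "A\t1\t-0.5", "A 2 0.25", "B\t7\t1.75"), f)
  prof <- read_conservation(f)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$score, c(-0.5, 0.25, 1.75))

  writeLines(c("A 10 0.1", "A 10 0.2"), f)
  expect_error(read_conservation(f), class = "pocketrank_parse_error")

  writeLines(c("A 1 0.1", "A 2"), f)
  expect_error(read_conservation(f), regexp = "line 2",
               class = "pocketrank_parse_error")

  writeLines(c("A 1 zero"), f)
  expect_error(read_conservation(f), class = "pocketrank_parse_error")
})

test_that("fixture conservation plants conserved residues below the mean", {
  fx <- make_structure(fixture_spec(seed = 8))
  prof <- make_conservation(fx$truth, seed = 9)
  lining <- fx$truth$lining_residues[[1]]
  planted <- prof$score[match(paste(lining$chain, lining$resno),
                              paste(prof$chain, prof$resno))]
  expect_true(mean(planted) < mean(prof$score))
})

test_that("ConSurf grades files import into the common profile form", {
  f <- tempfile()
  writeLines(c(
    " POS SEQ 3LATOM SCORE COLOR",
    "   1   M  MET1:A  -1.234   9",
    "   2   K  LYS2:A   0.567   3",
    "   3   G       -   0.100   5",  # unmapped residue is skipped
    "legend: conserved 9"
  ), f)
  prof <- read_consurf_grades(f)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$chain, c("A", "A"))
  expect_equal(prof$resno, c("1", "2"))
  expect_equal(prof$score, c(-1.234, 0.567))
})
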