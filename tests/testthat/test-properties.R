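test_that("hull volume matches closed forms and flags degenerate inputs", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(pocket_volume(cube), 1, tolerance = 1e-4)
  expect_equal(pocket_volume(as.matrix(expand.grid(0:5, 0:5, 0:5))), 125,
               tolerance = 1e-4)
  # regular tetrahedron edge sqrt(2): volume 1/3
  tet <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(0, 0, 0))
  expect_equal(pocket_volume(tet), 1 / 3, tolerance = 1e-4)
  expect_warning(v <- pocket_volume(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
                 "degenerate|fewer")
  expect_equal(v, 0)
  expect_warning(v2 <- pocket_volume(as.matrix(expand.grid(0:3, 0:3, 0))),
                 "degenerate")
  expect_equal(v2, 0)
})

test_that("hull volume agrees with an independent Qhull computation", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      pts <- matrix(stats::runif(150, 0, 10), ncol = 3)
      expect_equal(pocket_volume(pts), scipy_hull_volume(pts),
                   tolerance = 5e-2)
    }
    # degenerate-rich grid points, as produced by the pocket finder
    sph <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
    sph <- sph[rowSums(sph^2) <= 16, ]
    expect_equal(pocket_volume(sph), scipy_hull_volume(sph), tolerance = 5e-2)
  })
})

test_that("centroid distance is plain Euclidean distance", {
  expect_equal(centroid_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(centroid_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- stats::rnorm(3); b <- stats::rnorm(3)
      expect_equal(centroid_distance(a, b), sqrt(sum((a - b)^2)))
    }
  })
})

test_that("pocket conservation is the mean over lining residues in the profile", {
  prof <- tibble::tibble(chain = "A", resno = as.character(1:4),
                         score = c(-1, 0, 1, -1.2))
  res3 <- tibble::tibble(chain = "A", resno = as.character(1:3))
  expect_equal(as.numeric(conservation_score(res3, prof)), 0)
  res1 <- tibble::tibble(chain = "A", resno = "4")
  expect_equal(as.numeric(conservation_score(res1, prof)), -1.2)
  # residues missing from the profile are skipped but counted
  res_mix <- tibble::tibble(chain = "A", resno = c("1", "99"))
  sc <- conservation_score(res_mix, prof)
  expect_equal(as.numeric(sc), -1)
  expect_equal(attr(sc, "n_missing"), 1)
  res_none <- tibble::tibble(chain = "Z", resno = "1")
  expect_error(conservation_score(res_none, prof),
               class = "pocketrank_missing_conservation")
})

test_that("hydrophobic residue counting uses the 8-member set", {
  res <- tibble::tibble(resname = c("ALA", "GLY", "LEU", "SER", "TRP"))
  expect_equal(hydrophobic_count(res), 3)
  expect_equal(hydrophobic_count(tibble::tibble(resname = rep("GLY", 5))), 0)
  expect_equal(hydrophobic_count(tibble::tibble(resname = c("VAL", "ILE",
                                                            "PRO", "PHE",
                                                            "MET"))), 5)
})

test_that("ranking directions and tie-breaks follow the property semantics", {
  scores <- tibble::tibble(pocket_id = c(0L, 1L),
                           volume = c(100, 50), distance = c(8, 2),
                           conservation = c(0.5, -1), n_hydrophobic = c(3L, 7L))
  expect_equal(rank_by_property(scores, "volume")$pocket_id, c(0L, 1L))
  expect_equal(rank_by_property(scores, "distance")$pocket_id, c(1L, 0L))
  expect_equal(rank_by_property(scores, "conservation")$pocket_id, c(1L, 0L))
  expect_equal(rank_by_property(scores, "hydrophobic")$pocket_id, c(1L, 0L))
  ties <- tibble::tibble(pocket_id = c(3L, 1L), volume = c(10, 10),
                         distance = 1, conservation = 0, n_hydrophobic = 0L)
  expect_equal(rank_by_property(ties, "volume")$pocket_id, c(1L, 3L))
  expect_error(rank_by_property(scores, "depth"),
               class = "pocketrank_config_error")
})

test_that("every ranking is a permutation of the scored pockets", {
  withr::with_seed(29, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      scores <- tibble::tibble(
        pocket_id = sample(0:(n * 2), n),
        volume = stats::runif(n, 0, 500),
        distance = stats::runif(n, 0, 30),
        conservation = stats::rnorm(n),
        n_hydrophobic = sample(0:20, n, replace = TRUE)
      )
      for (p in c("volume", "distance", "conservation", "hydrophobic")) {
        rk <- rank_by_property(scores, p)
        expect_setequal(rk$pocket_id, scores$pocket_id)
        expect_equal(rk$rank, seq_len(n))
      }
    }
  })
})

test_that("pockets lacking conservation data drop out of that ranking only", {
  scores <- tibble::tibble(pocket_id = 0:2, volume = c(3, 2, 1),
                           distance = c(1, 2, 3),
                           conservation = c(-1, NA, 0.5),
                           n_hydrophobic = c(1L, 2L, 3L))
  expect_warning(rk <- rank_by_property(scores, "conservation"), "excluding")
  expect_equal(rk$pocket_id, c(0L, 2L))
  expect_equal(attr(rk, "k"), 2)
  expect_equal(rank_by_property(scores, "volume")$pocket_id, 0:2)
})

test_that("volume ranking is invariant under rigid motion", {
  fx <- make_structure(random_cavity_spec(57))
  pk <- find_pockets(fx$structure)
  props <- pocket_properties(pk, fx$structure)
  pk_rot <- find_pockets(rotate_structure_z90(fx$structure))
  props_rot <- pocket_properties(pk_rot, rotate_structure_z90(fx$structure))
  expect_equal(rank_by_property(props_rot, "volume")$score,
               rank_by_property(props, "volume")$score, tolerance = 1e-3)
  # distance ranking is invariant under translation
  shifted <- fx$structure
  shifted$x <- shifted$x + 30; shifted$y <- shifted$y - 12
  pk_sh <- find_pockets(shifted)
  props_sh <- pocket_properties(pk_sh, shifted)
  expect_equal(rank_by_property(props_sh, "distance")$score,
               rank_by_property(props, "distance")$score, tolerance = 1e-6)
})

test_that("a planted large conserved pocket ranks first on volume and conservation", {
  spec <- fixture_spec(
    n_residues = 900,
    cavities = list(
      list(offset = c(4.75, 0, 0), radius = 4.5, conserved = TRUE,
           has_ligand = TRUE),
      list(offset = c(-6.2, 0, 0), radius = 3.5)
    ),
    seed = 101
  )
  fx <- make_structure(spec)
  pk <- find_pockets(fx$structure)
  prof <- make_conservation(fx$truth, seed = 102)
  props <- pocket_properties(pk, fx$structure, prof)
  ctr <- fx$truth$cavity_centers[[1]]
  d <- sqrt((pk$x - ctr[1])^2 + (pk$y - ctr[2])^2 + (pk$z - ctr[3])^2)
  true_id <- pk$pocket_id[which.min(d)]
  expect_equal(rank_by_property(props, "volume")$pocket_id[1], true_id)
  expect_equal(rank_by_property(props, "conservation")$pocket_id[1], true_id)
})
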