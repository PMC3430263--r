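ring_atoms <- function(center = c(0, 0, 0), r = 1.5, n = 8) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(element = "C", x = center[1] + r * cos(ang),
                 y = center[2] + r * sin(ang), z = center[3])
}

test_that("the hit criterion is inclusive at the cutoff", {
  lig <- tibble::tibble(element = "C", x = c(3.9, 20), y = 0, z = 0)
  expect_true(is_hit(c(0, 0, 0), lig, cutoff = 4))
  expect_true(is_hit(c(0, 0, 0), tibble::tibble(x = 4, y = 0, z = 0)))
  expect_false(is_hit(c(0, 0, 0), tibble::tibble(x = 10, y = 0, z = 0)))
  expect_error(is_hit(c(0, 0, 0), tibble::tibble(x = numeric(), y = numeric(),
                                                 z = numeric())),
               class = "pocketrank_config_error")
})

test_that("hit_rank returns the first hitting rank over all ligands", {
  pockets <- tibble::tibble(pocket_id = 0:2,
                            x = c(50, 30, 1), y = 0, z = 0)
  ligands <- tibble::tibble(het_code = "LIG", chain = "L", resno = "1",
                            n_atoms = 8L, atoms = list(ring_atoms()))
  ranked <- tibble::tibble(rank = 1:3, pocket_id = c(0L, 1L, 2L))
  expect_equal(hit_rank(ranked, pockets, ligands), 3)
  ranked2 <- tibble::tibble(rank = 1:3, pocket_id = c(2L, 0L, 1L))
  expect_equal(hit_rank(ranked2, pockets, ligands), 1)
  far <- tibble::tibble(pocket_id = 0L, x = 99, y = 0, z = 0)
  expect_equal(hit_rank(ranked[1, ], far, ligands), Inf)
})

test_that("TOP-n success counts non-hits in the denominator", {
  preds <- tibble::tibble(protein = 1:4, hit_rank = c(1, 3, Inf, 1))
  expect_equal(top_n_success(preds, 1), 0.5)
  expect_equal(top_n_success(preds, 3), 0.75)
  all_hit <- tibble::tibble(protein = 1:3, hit_rank = 1)
  expect_equal(top_n_success(all_hit, 1), 1)
  rank3 <- tibble::tibble(protein = 1, hit_rank = 3)
  expect_equal(top_n_success(rank3, 1), 0)
  expect_equal(top_n_success(rank3, 3), 1)
  expect_error(top_n_success(preds[0, ], 1), class = "pocketrank_config_error")
})

test_that("TOP-n success is monotone in n", {
  withr::with_seed(31, {
    for (i in 1:20) {
      hr <- sample(c(1:6, Inf), 15, replace = TRUE)
      preds <- tibble::tibble(protein = 1:15, hit_rank = hr)
      expect_lte(top_n_success(preds, 1), top_n_success(preds, 3))
      expect_lte(top_n_success(preds, 3), top_n_success(preds, 5))
    }
  })
})

test_that("confusion counts partition the polymer residues", {
  # 10 residues on a line, ligand ring at the origin end
  s <- atoms_tbl(cbind(seq(0, 27, 3), 0, 0), resno = 1:10)
  ligands <- tibble::tibble(het_code = "LIG", chain = "L", resno = "1",
                            n_atoms = 8L, atoms = list(ring_atoms(c(0, 0, 0))))
  # actual binding residues: any atom within 4 A of the ring (x <= 5.5)
  actual <- c("1", "2")
  cc <- confusion_counts(s, tibble::tibble(chain = "A", resno = actual),
                         ligands)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp, 2)
  expect_equal(cc$tn, 8)
  empty <- confusion_counts(s, tibble::tibble(chain = character(),
                                              resno = character()), ligands)
  expect_equal(empty$tp, 0)
  expect_equal(empty$fp, 0)
  expect_equal(empty$fn, 2)
  expect_equal(with(empty, tp + tn + fp + fn), 10)
  expect_error(confusion_counts(s, tibble::tibble(chain = "A", resno = "1"),
                                ligands[0, ]),
               class = "pocketrank_config_error")
})

test_that("confusion counts match set algebra on fixture lining residues", {
  fx <- make_structure(fixture_spec(seed = 14))
  pk <- find_pockets(fx$structure)
  lig <- extract_ligands(fx$structure)
  pred <- pk$residues[[1]]
  cc <- confusion_counts(fx$structure, pred, lig)
  # independent set computation
  poly <- polymer_atoms(fx$structure)
  la <- lig$atoms[[1]]
  actual <- unique(poly$resno[vapply(seq_len(nrow(poly)), function(i) {
    any(sqrt((la$x - poly$x[i])^2 + (la$y - poly$y[i])^2 +
             (la$z - poly$z[i])^2) <= 4)
  }, logical(1))])
  predicted <- unique(pred$resno)
  universe <- unique(poly$resno)
  expect_equal(cc$tp, length(intersect(predicted, actual)))
  expect_equal(cc$fp, length(setdiff(predicted, actual)))
  expect_equal(cc$fn, length(setdiff(actual, predicted)))
  expect_equal(cc$tn, length(setdiff(universe, union(predicted, actual))))
})

test_that("MCC matches its closed forms", {
  expect_equal(mcc(c(tp = 10, tn = 90, fp = 0, fn = 0)), 1.0)
  expect_equal(mcc(c(tp = 5, tn = 5, fp = 5, fn = 5)), 0.0)
  expect_equal(mcc(c(tp = 5, tn = 90, fp = 2, fn = 3)),
               444 / sqrt(7 * 8 * 92 * 93), tolerance = 1e-12)
  expect_equal(mcc(c(tp = 0, tn = 0, fp = 3, fn = 4)), -1)
  expect_equal(mcc(c(tp = 0, tn = 10, fp = 0, fn = 4)), 0) # TP+FP = 0: defined as 0
  expect_equal(mcc(tibble::tibble(tp = 0, tn = 10, fp = 10, fn = 0)), 0)
  # (0*10 - 5*5) / sqrt(5 * 5 * 15 * 15) = -25/75
  expect_equal(mcc(c(tp = 0, tn = 10, fp = 5, fn = 5)), -1 / 3)
})

test_that("MCC is symmetric under class swap", {
  withr::with_seed(37, {
    for (i in 1:50) {
      cts <- sample(0:40, 4, replace = TRUE)
      a <- mcc(c(cts[1], cts[2], cts[3], cts[4]))
      b <- mcc(c(cts[2], cts[1], cts[4], cts[3])) # TP<->TN, FP<->FN
      expect_equal(a, b, tolerance = 1e-12)
      expect_gte(a, -1); expect_lte(a, 1)
    }
  })
})

test_that("method comparison uses a one-sided paired signed-rank test", {
  x <- seq(0.3, 0.8, length.out = 20)
  expect_error(compare_methods(x, x), class = "pocketrank_degenerate_test")
  expect_lt(compare_methods(x + 0.2, x), 0.05)
  expect_error(compare_methods(x[1:5], x[1:5] + 1),
               class = "pocketrank_config_error")
  expect_error(compare_methods(x, x[1:10]), class = "pocketrank_config_error")
  # p-value agrees with a Monte-Carlo sign-flip oracle
  withr::with_seed(41, {
    base <- stats::rnorm(30, 0.5, 0.1)
    a <- base + 0.1 + stats::rnorm(30, 0, 0.05)
    b <- base + stats::rnorm(30, 0, 0.05)
    p_pkg <- compare_methods(a, b)
    p_perm <- perm_signed_rank_p(a - b, B = 20000, seed = 8)
    expect_lt(abs(p_pkg - p_perm), 0.01)
    # moderate-signal case where p sits away from 0 and 1
    a2 <- base + 0.01 + stats::rnorm(30, 0, 0.05)
    p2 <- compare_methods(a2, b)
    p2_perm <- perm_signed_rank_p(a2 - b, B = 20000, seed = 9)
    expect_lt(abs(p2 - p2_perm), 3 * sqrt(p2_perm * (1 - p2_perm) / 20000) + 0.005)
  })
})
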