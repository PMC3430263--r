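# Independent oracles and small builders used across the suite.

# Convex-hull volume via scipy's Qhull binding (independent of the
# package's own hull code).
scipy_hull_volume <- function(pts) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(as.data.frame(pts), f, row.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pandas as pd; from scipy.spatial import ConvexHull; ",
    "print(ConvexHull(pd.read_csv('", f, "').values).volume)"
  ))), stdout = TRUE)
  as.numeric(out[length(out)])
}

# Plain enumeration of the truncated footrule distance, written against the
# definition (per-item rank lookup), independent of the package code path.
enum_footrule <- function(li, lj, k) {
  total <- 0L
  for (t in union(li, lj)) {
    ri <- match(t, li); if (is.na(ri) || ri > k) ri <- k + 1L
    rj <- match(t, lj); if (is.na(rj) || rj > k) rj <- k + 1L
    total <- total + abs(ri - rj)
  }
  total
}

# Exhaustive ray-walk PSP oracle on a raw occupancy array.
psp_oracle <- function(occ) {
  dims <- dim(occ)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  inside <- function(v) all(v >= 1) && all(v <= dims)
  blocked <- function(v, d) {
    w <- v + d
    while (inside(w)) {
      if (occ[w[1], w[2], w[3]]) return(TRUE)
      w <- w + d
    }
    FALSE
  }
  psp <- array(NA_integer_, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (occ[i, j, k]) next
    v <- c(i, j, k)
    psp[i, j, k] <- sum(apply(dirs, 1, function(d) blocked(v, d) && blocked(v, -d)))
  }
  psp
}

# Wrap a hand-built occupancy array as a pocket_grid object.
grid_from_occ <- function(occ, origin = c(0, 0, 0), spacing = 1) {
  g <- list(origin = origin, spacing = spacing, dims = dim(occ),
            occupancy = occ, psp = NULL)
  class(g) <- "pocket_grid"
  g
}

# Minimal polymer atom table builder.
atoms_tbl <- function(xyz, resno = seq_len(nrow(xyz)), resname = "GLY",
                      chain = "A", record = "polymer") {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(chain = chain, resno = as.character(resno),
                 resname = resname, elety = "CA", element = "C",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], record = record)
}

# Monte-Carlo permutation (sign-flip) oracle for the one-sided paired
# signed-rank test.
perm_signed_rank_p <- function(d, B = 20000, seed = 1) {
  d <- d[d != 0]
  r <- rank(abs(d))
  stat <- sum(r[d > 0])
  withr::with_seed(seed, {
    ge <- 0L
    n <- length(d)
    for (b in seq_len(B)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (sum(r[s > 0]) >= stat) ge <- ge + 1L
    }
    (ge + 1) / (B + 1)
  })
}

# Single-cavity fixture with a randomised cavity axis.
random_cavity_spec <- function(seed) {
  ax <- withr::with_seed(seed * 13 + 1, {
    u <- stats::rnorm(3)
    u / sqrt(sum(u^2))
  })
  fixture_spec(cavities = list(list(offset = 3.5 * ax, radius = 4,
                                    conserved = TRUE, has_ligand = TRUE)),
               seed = seed)
}

rotate_structure_z90 <- function(structure) {
  out <- structure
  out$x <- -structure$y
  out$y <- structure$x
  out
}
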