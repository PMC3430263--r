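#' Build the occupancy grid around a structure
#'
#' Lays a cubic voxel grid over the polymer atoms plus a solvent margin and
#' marks every voxel within `atom_radius` of a polymer heavy atom as
#' protein; all other voxels are solvent. The grid origin is snapped to the
#' global `spacing` lattice so that voxel centres sit on integer multiples
#' of the spacing — a 90-degree rotation of the input about a lattice axis
#' then maps voxel centres onto voxel centres exactly, which keeps pocket
#' detection equivariant under such rotations.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param spacing Grid spacing in Angstrom (default 1.0).
#' @param margin Solvent margin beyond the atom bounding box (default 8).
#' @param atom_radius Protein-occupancy radius per heavy atom (default 2.0).
#' @return A `pocket_grid` object: list with `origin`, `spacing`, `dims`,
#'   logical array `occupancy` and (after [scan_psp()]) integer array `psp`.
#' @export
build_grid <- function(structure, spacing = 1.0, margin = 8.0, atom_radius = 2.0) {
  if (!is.numeric(spacing) || spacing <= 0) {
    abort("grid spacing must be > 0", class = "pocketrank_config_error")
  }
  poly <- polymer_atoms(structure)
  if (nrow(poly) == 0) {
    abort("structure has no polymer atoms", class = "pocketrank_empty_structure")
  }
  coords <- as.matrix(poly[, c("x", "y", "z")])
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  origin <- spacing * floor(lo / spacing)
  dims <- as.integer(floor((hi - origin) / spacing)) + 1L
  occ <- cpp_mark_occupancy(dims, origin, spacing, coords, atom_radius)
  dim(occ) <- dims
  grid <- list(origin = unname(origin), spacing = spacing, dims = dims,
               occupancy = occ, psp = NULL)
  class(grid) <- "pocket_grid"
  grid
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf("<pocket_grid> %d x %d x %d voxels @ %.2f A, %d protein voxels%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$occupancy),
              if (is.null(x$psp)) "" else ", PSP scanned"))
  invisible(x)
}

#' Scan protein-solvent-protein events
#'
#' For every solvent voxel, counts along how many of 7 scan axes (x, y, z
#' and the four cube diagonals) the voxel is flanked by protein voxels on
#' both sides. High counts mark buried, pocket-like solvent.
#'
#' @param grid A `pocket_grid` from [build_grid()].
#' @return The grid with an integer `psp` array (NA on protein voxels).
#' @export
scan_psp <- function(grid) {
  stopifnot(inherits(grid, "pocket_grid"))
  psp <- cpp_scan_psp(as.logical(grid$occupancy), grid$dims)
  dim(psp) <- grid$dims
  grid$psp <- psp
  grid
}

#' Cluster buried solvent voxels into candidate pockets
#'
#' Solvent voxels with a PSP count at or above `psp_threshold` are grouped
#' into 26-connected components; components of at least `min_size` voxels
#' become pockets. Pocket ids start at 0 and are assigned in decreasing
#' size order (ties broken by the lexicographically smallest member voxel),
#' so downstream rankings are reproducible.
#'
#' @param grid A PSP-scanned `pocket_grid`.
#' @param psp_threshold Minimum PSP count (default 5 of 7).
#' @param min_size Minimum component size in voxels (default 30).
#' @return A `pocket_set` tibble: `pocket_id`, centre `x`,`y`,`z`,
#'   `n_points`, and list-column `grid_pts` (n x 3 coordinate matrices).
#' @export
cluster_pockets <- function(grid, psp_threshold = 5, min_size = 30) {
  stopifnot(inherits(grid, "pocket_grid"))
  if (is.null(grid$psp)) grid <- scan_psp(grid)
  mask <- !is.na(grid$psp) & grid$psp >= psp_threshold
  lab <- cpp_label_components(as.logical(mask), grid$dims)
  dim(lab) <- grid$dims

  empty <- tibble::tibble(pocket_id = integer(), x = numeric(), y = numeric(),
                          z = numeric(), n_points = integer(), grid_pts = list())
  ids <- setdiff(unique(as.integer(lab)), 0L)
  if (length(ids) == 0) return(new_pocket_set(empty, grid))

  comps <- purrr::map(ids, function(l) which(lab == l, arr.ind = TRUE))
  sizes <- lengths(comps) / 3L
  keep <- sizes >= min_size
  comps <- comps[keep]; sizes <- sizes[keep]
  if (length(comps) == 0) return(new_pocket_set(empty, grid))

  # deterministic ordering: size desc, then lexicographic smallest voxel
  minvox <- purrr::map_chr(comps, function(m) {
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    paste(m[1, ], collapse = ",")
  })
  ord <- order(-sizes, minvox)
  comps <- comps[ord]; sizes <- sizes[ord]

  pts <- purrr::map(comps, function(m) {
    p <- sweep((m - 1) * grid$spacing, 2, grid$origin, "+")
    colnames(p) <- c("x", "y", "z")
    p[order(p[, 1], p[, 2], p[, 3]), , drop = FALSE]
  })
  centers <- purrr::map(pts, colMeans)
  out <- tibble::tibble(
    pocket_id = seq_along(pts) - 1L,
    x = purrr::map_dbl(centers, 1),
    y = purrr::map_dbl(centers, 2),
    z = purrr::map_dbl(centers, 3),
    n_points = as.integer(sizes),
    grid_pts = pts
  )
  new_pocket_set(out, grid)
}

new_pocket_set <- function(tbl, grid = NULL) {
  if (!is.null(grid)) {
    attr(tbl, "spacing") <- grid$spacing
  }
  class(tbl) <- unique(c("pocket_set", class(tbl)))
  tbl
}

#' Assign lining residues to pockets
#'
#' A residue lines a pocket when any of its heavy atoms lies within
#' `residue_cutoff` (inclusive) of any pocket grid point. Lining residues
#' feed the conservation and hydrophobicity ranking properties.
#'
#' @param pockets A `pocket_set` tibble from [cluster_pockets()].
#' @param structure Atom tibble from [read_pdb()].
#' @param residue_cutoff Distance cutoff in Angstrom (default 5.0).
#' @return `pockets` with a list-column `residues` of tibbles
#'   (`chain`, `resno`, `resname`).
#' @export
assign_residues <- function(pockets, structure, residue_cutoff = 5.0) {
  poly <- polymer_atoms(structure)
  coords <- as.matrix(poly[, c("x", "y", "z")])
  cutoff2 <- residue_cutoff^2
  pockets$residues <- purrr::map(pockets$grid_pts, function(pts) {
    near <- rep(FALSE, nrow(poly))
    # pockets are local: prefilter atoms by the pocket bounding box
    lo <- apply(pts, 2, min) - residue_cutoff
    hi <- apply(pts, 2, max) + residue_cutoff
    cand <- which(coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
                  coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
                  coords[, 3] >= lo[3] & coords[, 3] <= hi[3])
    for (a in cand) {
      d2 <- (pts[, 1] - coords[a, 1])^2 + (pts[, 2] - coords[a, 2])^2 +
            (pts[, 3] - coords[a, 3])^2
      if (min(d2) <= cutoff2) near[a] <- TRUE
    }
    dplyr::distinct(poly[near, c("chain", "resno", "resname")])
  })
  pockets
}

#' Detect pockets on a structure in one call
#'
#' Convenience wrapper chaining [build_grid()], [scan_psp()],
#' [cluster_pockets()] and [assign_residues()].
#'
#' @inheritParams build_grid
#' @inheritParams cluster_pockets
#' @inheritParams assign_residues
#' @return A `pocket_set` tibble with centres, sizes, grid points and
#'   lining residues.
#' @examples
#' fx <- make_structure(fixture_spec(seed = 7))
#' pockets <- find_pockets(fx$structure)
#' head(tidy(pockets))
#' @export
find_pockets <- function(structure, spacing = 1.0, margin = 8.0,
                         atom_radius = 2.0, psp_threshold = 5,
                         min_size = 30, residue_cutoff = 5.0) {
  grid <- scan_psp(build_grid(structure, spacing, margin, atom_radius))
  pockets <- cluster_pockets(grid, psp_threshold, min_size)
  assign_residues(pockets, structure, residue_cutoff)
}

#' @export
tidy.pocket_set <- function(x, ...) {
  out <- tibble::as_tibble(x[, setdiff(names(x), c("grid_pts", "residues"))])
  if ("residues" %in% names(x)) {
    out$n_residues <- purrr::map_int(x$residues, nrow)
  }
  out
}
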