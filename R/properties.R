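#' Convex-hull volume of a point set
#'
#' Volume (in cubic Angstrom) of the convex hull of a pocket's grid
#' points, the "pocket size" ranking property. Degenerate point sets
#' (fewer than 4 points, or all collinear/coplanar) have zero volume and
#' raise a warning.
#'
#' @param points Numeric matrix (n x 3) or data frame of x/y/z coordinates.
#' @return Volume in Angstrom^3.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' pocket_volume(cube) # 1
#' @export
pocket_volume <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4) {
    warn("fewer than 4 points: hull volume is 0")
    return(0)
  }
  v <- cpp_hull_volume(pts)
  if (v == 0) warn("degenerate (collinear/coplanar) point set: hull volume is 0")
  v
}

#' Distance from a pocket centre to the protein centroid
#'
#' Euclidean distance between the pocket's geometric centre and the
#' protein centroid; a proxy for pocket depth (buried pockets sit close
#' to the centroid).
#'
#' @param center Numeric xyz of the pocket centre.
#' @param centroid Numeric xyz of the protein centroid
#'   (see [protein_centroid()]).
#' @return Distance in Angstrom.
#' @export
centroid_distance <- function(center, centroid) {
  sqrt(sum((as.numeric(center)[1:3] - as.numeric(centroid)[1:3])^2))
}

#' Mean conservation score of a pocket's lining residues
#'
#' Arithmetic mean of the normalised conservation scores over the pocket's
#' assigned residues. Scores follow the ConSurf convention (mean 0, SD 1
#' over the protein; negative = conserved), so more negative pocket means
#' indicate more conserved pockets. Residues absent from the profile are
#' skipped; the number skipped is reported via the `n_missing` attribute.
#'
#' @param residues Tibble with `chain` and `resno` columns (a pocket's
#'   lining residues).
#' @param profile Conservation tibble from [read_conservation()].
#' @return Mean score (numeric scalar) with attribute `n_missing`.
#' @export
conservation_score <- function(residues, profile) {
  key <- paste(residues$chain, residues$resno)
  pkey <- paste(profile$chain, profile$resno)
  hit <- match(key, pkey)
  n_missing <- sum(is.na(hit))
  if (all(is.na(hit))) {
    abort("no lining residue found in the conservation profile",
          class = "pocketrank_missing_conservation")
  }
  out <- mean(profile$score[hit[!is.na(hit)]])
  attr(out, "n_missing") <- n_missing
  out
}

#' Number of hydrophobic lining residues
#'
#' Counts assigned residues whose 3-letter code belongs to the 8-member
#' hydrophobic set ALA, VAL, LEU, ILE, PRO, PHE, TRP, MET.
#'
#' @param residues Tibble with a `resname` column.
#' @return Integer count.
#' @export
hydrophobic_count <- function(residues) {
  sum(residues$resname %in% HYDROPHOBIC_RESIDUES)
}

#' Score all pockets on the four ranking properties
#'
#' @param pockets A `pocket_set` with assigned residues
#'   (see [find_pockets()]).
#' @param structure Atom tibble the pockets were detected on.
#' @param conservation Optional conservation tibble; when `NULL` the
#'   conservation column is `NA`.
#' @return A tibble `pocket_id`, `volume`, `distance`, `conservation`,
#'   `n_hydrophobic` (one row per pocket).
#' @export
pocket_properties <- function(pockets, structure, conservation = NULL) {
  centroid <- protein_centroid(structure)
  cons <- rep(NA_real_, nrow(pockets))
  if (!is.null(conservation)) {
    cons <- purrr::map_dbl(pockets$residues, function(res) {
      tryCatch(as.numeric(conservation_score(res, conservation)),
               pocketrank_missing_conservation = function(e) NA_real_)
    })
    if (anyNA(cons)) {
      warn(sprintf("%d pocket(s) have no conservation data and are excluded from the conservation ranking",
                   sum(is.na(cons))))
    }
  }
  tibble::tibble(
    pocket_id = pockets$pocket_id,
    volume = suppressWarnings(purrr::map_dbl(pockets$grid_pts, pocket_volume)),
    distance = purrr::map_dbl(seq_len(nrow(pockets)), function(i) {
      centroid_distance(c(pockets$x[i], pockets$y[i], pockets$z[i]), centroid)
    }),
    conservation = cons,
    n_hydrophobic = purrr::map_int(pockets$residues, hydrophobic_count)
  )
}

#' Rank pockets by one property
#'
#' Sort direction per property: `volume` descending (largest first),
#' `distance` ascending (closest to the centroid first), `conservation`
#' ascending (most negative = most conserved first), `hydrophobic`
#' descending. Ties are broken by ascending pocket id. Pockets with no
#' conservation value are excluded (with a warning) from the conservation
#' ranking only.
#'
#' @param scores Property tibble from [pocket_properties()].
#' @param property One of `"volume"`, `"distance"`, `"conservation"`,
#'   `"hydrophobic"`.
#' @return A `ranked_list` tibble `rank`, `pocket_id`, `score`, with the
#'   truncation length as attribute `k`.
#' @examples
#' scores <- tibble::tibble(pocket_id = 0:2, volume = c(100, 50, 75),
#'                          distance = c(3, 9, 1),
#'                          conservation = c(0.5, -1, 0),
#'                          n_hydrophobic = c(2L, 5L, 5L))
#' rank_by_property(scores, "conservation")$pocket_id # 1 2 0
#' @export
rank_by_property <- function(scores, property) {
  cols <- c(volume = "volume", distance = "distance",
            conservation = "conservation", hydrophobic = "n_hydrophobic")
  if (length(property) != 1 || !property %in% names(cols)) {
    abort(paste0("unknown ranking property: ", paste(property, collapse = ", "),
                 " (expected one of ", paste(names(cols), collapse = ", "), ")"),
          class = "pocketrank_config_error")
  }
  val <- scores[[cols[[property]]]]
  keep <- !is.na(val)
  if (!all(keep)) {
    if (property != "conservation") {
      abort(paste0("missing ", property, " values"), class = "pocketrank_config_error")
    }
    warn(sprintf("excluding %d pocket(s) without conservation data", sum(!keep)))
  }
  val <- val[keep]
  ids <- scores$pocket_id[keep]
  asc <- property %in% c("distance", "conservation")
  ord <- order(if (asc) val else -val, ids)
  out <- tibble::tibble(rank = seq_along(ord), pocket_id = ids[ord],
                        score = as.numeric(val[ord]))
  attr(out, "k") <- nrow(out)
  attr(out, "property") <- property
  class(out) <- c("ranked_list", class(out))
  out
}
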