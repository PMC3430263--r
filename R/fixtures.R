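#' Specification of a synthetic test structure
#'
#' Describes a toy protein for the fixture generator: pseudo-atoms on a
#' jittered cubic lattice filling a ball, with one or more spherical
#' cavities carved out by atom deletion, an optional ring-shaped ligand
#' planted in one cavity, and flags controlling which cavities are lined
#' with hydrophobic or conserved residues.
#'
#' @param n_residues Approximate number of pseudo-residues (one heavy atom
#'   each); sets the ball radius together with `lattice_spacing`. Note the
#'   2 Angstrom default lattice packs heavy atoms about as densely as a
#'   real protein interior, so a fixture of a few hundred pseudo-residues
#'   is physically the size of a much smaller real chain.
#' @param lattice_spacing Lattice constant in Angstrom (default 2.0; at
#'   this spacing the 2 Angstrom occupancy radius seals the interior, so
#'   only carved cavities read as buried solvent).
#' @param jitter Uniform coordinate jitter amplitude in Angstrom
#'   (default 0.25); kept small so cavity walls stay sealed.
#' @param cavities List of cavity descriptions, each a list with `offset`
#'   (xyz of the cavity centre relative to the ball centre), `radius`
#'   (carving radius, Angstrom), and logical flags `hydrophobic`,
#'   `conserved`, `has_ligand`.
#' @param ligand_size Number of ligand ring atoms (default 10).
#' @param seed Mandatory integer seed; fixtures are fully reproducible
#'   from `(spec, seed)`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 500, lattice_spacing = 2.0, jitter = 0.25,
                         cavities = list(list(offset = c(3.5, 0, 0), radius = 4,
                                              hydrophobic = FALSE,
                                              conserved = TRUE,
                                              has_ligand = TRUE)),
                         ligand_size = 10, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("fixture_spec() requires an integer seed", class = "pocketrank_config_error")
  }
  radius <- (3 * n_residues * lattice_spacing^3 / (4 * pi))^(1 / 3)
  cavities <- purrr::map(cavities, function(cv) {
    utils::modifyList(list(offset = c(0, 0, 0), radius = 5,
                           hydrophobic = FALSE, conserved = FALSE,
                           has_ligand = FALSE), cv)
  })
  # cavities must not touch each other or breach the surface
  ctrs <- purrr::map(cavities, "offset")
  for (i in seq_along(cavities)) {
    if (sqrt(sum(ctrs[[i]]^2)) + cavities[[i]]$radius > radius - lattice_spacing) {
      abort("cavity extends beyond the protein ball; shrink offset or radius",
            class = "pocketrank_config_error")
    }
    for (j in seq_len(i - 1)) {
      gap <- sqrt(sum((ctrs[[i]] - ctrs[[j]])^2))
      if (gap < cavities[[i]]$radius + cavities[[j]]$radius + lattice_spacing) {
        abort("cavities overlap", class = "pocketrank_config_error")
      }
    }
  }
  spec <- list(n_residues = n_residues, radius = radius,
               lattice_spacing = lattice_spacing, jitter = jitter,
               cavities = cavities, ligand_size = ligand_size,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Generate a synthetic structure with known cavities
#'
#' Builds the toy protein described by a [fixture_spec()]: carbon
#' pseudo-atoms (one per residue, atom name CA) on a jittered lattice ball,
#' cavities carved by deleting atoms, residue names drawn uniformly from
#' the 20 amino acids except in hydrophobic-lined cavities (80% from the
#' 8-member hydrophobic set), and a planar carbon ring written as HETATM
#' records in the designated cavity. The returned truth record is the
#' ground reference the test-suite checks detection and ranking against.
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (atom tibble), `pdb` (PDB text lines) and
#'   `truth`: cavity centres, per-cavity lining residue keys, ligand cavity
#'   index, atom counts.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    s <- spec$lattice_spacing
    r <- ceiling(spec$radius / s)
    g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
    pts <- as.matrix(g) * s
    keep <- sqrt(rowSums(pts^2)) <= spec$radius
    pts <- pts[keep, , drop = FALSE]
    pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
    pts <- pts + matrix(stats::runif(length(pts), -spec$jitter, spec$jitter),
                        ncol = 3)

    carved <- rep(FALSE, nrow(pts))
    lining <- vector("list", length(spec$cavities))
    for (ci in seq_along(spec$cavities)) {
      cv <- spec$cavities[[ci]]
      d <- sqrt(rowSums(sweep(pts, 2, cv$offset)^2))
      carved <- carved | d < cv$radius
      lining[[ci]] <- which(d >= cv$radius & d <= cv$radius + 2.0)
    }
    atoms_xyz <- pts[!carved, , drop = FALSE]
    # re-index lining sets into the surviving atoms
    surv <- which(!carved)
    lining <- purrr::map(lining, function(ix) match(intersect(ix, surv), surv))

    n <- nrow(atoms_xyz)
    resname <- sample(AMINO_ACIDS, n, replace = TRUE)
    for (ci in seq_along(spec$cavities)) {
      if (!spec$cavities[[ci]]$hydrophobic) next
      ix <- lining[[ci]]
      hydro <- stats::runif(length(ix)) < 0.8
      resname[ix[hydro]] <- sample(HYDROPHOBIC_RESIDUES, sum(hydro), replace = TRUE)
    }

    structure_tbl <- tibble::tibble(
      chain = "A", resno = as.character(seq_len(n)), resname = resname,
      elety = "CA", element = "C",
      x = atoms_xyz[, 1], y = atoms_xyz[, 2], z = atoms_xyz[, 3],
      record = "polymer"
    )

    ligand_cavity <- which(purrr::map_lgl(spec$cavities, "has_ligand"))[1]
    if (!is.na(ligand_cavity)) {
      ctr <- spec$cavities[[ligand_cavity]]$offset
      ang <- 2 * pi * (seq_len(spec$ligand_size) - 1) / spec$ligand_size
      lig <- tibble::tibble(
        chain = "L", resno = "1", resname = "LIG", elety = "C", element = "C",
        x = ctr[1] + 1.5 * cos(ang), y = ctr[2] + 1.5 * sin(ang), z = ctr[3],
        record = "hetero"
      )
      structure_tbl <- dplyr::bind_rows(structure_tbl, lig)
    }
    class(structure_tbl) <- c("prot_structure", class(structure_tbl))

    truth <- list(
      cavity_centers = purrr::map(spec$cavities, "offset"),
      cavity_radii = purrr::map_dbl(spec$cavities, "radius"),
      lining_residues = purrr::map(lining, function(ix) {
        tibble::tibble(chain = "A", resno = as.character(ix))
      }),
      conserved = purrr::map_lgl(spec$cavities, "conserved"),
      hydrophobic = purrr::map_lgl(spec$cavities, "hydrophobic"),
      ligand_cavity = if (is.na(ligand_cavity)) NULL else ligand_cavity,
      n_polymer_atoms = n,
      n_atoms = nrow(structure_tbl)
    )
    list(structure = structure_tbl, pdb = format_pdb_lines(structure_tbl),
         truth = truth)
  })
}

#' Generate a conservation profile with planted conserved cavities
#'
#' Background scores are standard-normal; lining residues of cavities
#' flagged `conserved` are shifted by `conserved_mu` (negative = more
#' conserved). The whole profile is then re-standardised to mean 0 / SD 1,
#' matching the ConSurf normalisation the ranking consumes.
#'
#' @param truth Truth record from [make_structure()].
#' @param conserved_mu Shift applied to conserved lining residues
#'   (default -2, i.e. two background SDs toward conservation).
#' @param background_sigma SD of the background scores before
#'   re-standardisation (default 1).
#' @param seed Integer seed.
#' @return Conservation tibble `chain`, `resno`, `score` with mean 0 and
#'   SD 1.
#' @export
make_conservation <- function(truth, conserved_mu = -2, background_sigma = 1,
                              seed) {
  if (missing(seed)) abort("make_conservation() requires a seed",
                           class = "pocketrank_config_error")
  withr::with_seed(seed, {
    n <- truth$n_polymer_atoms
    score <- stats::rnorm(n, 0, background_sigma)
    for (ci in seq_along(truth$conserved)) {
      if (!truth$conserved[ci]) next
      ix <- as.integer(truth$lining_residues[[ci]]$resno)
      score[ix] <- score[ix] + conserved_mu
    }
    score <- (score - mean(score)) / sd(score)
    tibble::tibble(chain = "A", resno = as.character(seq_len(n)), score = score)
  })
}

#' Write a complete fixture to disk
#'
#' Emits `structure.pdb`, `conservation.tsv` and `truth.json` for one
#' fixture, the same files the CLI `synth` subcommand writes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param conserved_mu Passed to [make_conservation()].
#' @return Invisibly, the truth record.
#' @export
write_fixture <- function(spec, dir, conserved_mu = -2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_structure(spec)
  writeLines(fx$pdb, file.path(dir, "structure.pdb"))
  prof <- make_conservation(fx$truth, conserved_mu = conserved_mu,
                            seed = spec$seed + 1L)
  write_conservation(prof, file.path(dir, "conservation.tsv"))
  jsonlite::write_json(
    list(cavity_centers = fx$truth$cavity_centers,
         cavity_radii = fx$truth$cavity_radii,
         conserved = fx$truth$conserved,
         hydrophobic = fx$truth$hydrophobic,
         ligand_cavity = fx$truth$ligand_cavity,
         n_polymer_atoms = fx$truth$n_polymer_atoms,
         n_atoms = fx$truth$n_atoms,
         lining_residues = purrr::map(fx$truth$lining_residues,
                                      function(t) t$resno),
         seed = spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(fx$truth)
}

#' Generate an ensemble of noisy ranked lists with known consensus
#'
#' Draws a random consensus ordering of `universe_size` items and derives
#' `m` input lists by applying `noise` random adjacent transpositions to
#' each copy. Used to exercise the aggregation optimiser against the
#' enumeration oracle.
#'
#' @param universe_size Number of items (small, so enumeration stays
#'   feasible).
#' @param m Number of lists.
#' @param noise Adjacent transpositions applied per list.
#' @param seed Integer seed.
#' @return List with `lists` (character vectors), `consensus`, `weights`,
#'   `k`.
#' @export
make_list_ensemble <- function(universe_size = 6, m = 4, noise = 3, seed) {
  if (missing(seed)) abort("make_list_ensemble() requires a seed",
                           class = "pocketrank_config_error")
  withr::with_seed(seed, {
    items <- paste0("P", seq_len(universe_size) - 1)
    consensus <- sample(items)
    lists <- purrr::map(seq_len(m), function(i) {
      l <- consensus
      for (t in seq_len(noise)) {
        j <- sample.int(universe_size - 1, 1)
        l[c(j, j + 1)] <- l[c(j + 1, j)]
      }
      l
    })
    list(lists = lists, consensus = consensus,
         weights = rep(1, m), k = universe_size)
  })
}
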