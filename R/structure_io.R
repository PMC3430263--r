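#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a flat atom table. Hydrogens (and
#' deuterium) are dropped, alternate locations other than blank/'A' are
#' dropped, and waters are flagged so they never enter the polymer set.
#' Only the first model of multi-model (NMR) entries is read.
#'
#' @param path Path to a PDB-format text file.
#' @return A tibble of class `prot_structure` with one row per heavy atom:
#'   `chain`, `resno` (residue number as character, insertion code appended
#'   if present), `resname` (3-letter code), `elety` (atom name), `element`,
#'   `x`, `y`, `z` (Angstrom), and `record` (`"polymer"`, `"hetero"` or
#'   `"water"`).
#' @examples
#' fx <- make_structure(fixture_spec(seed = 1))
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(fx$pdb, pdb)
#' atoms <- read_pdb(pdb)
#' dplyr::count(atoms, record)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "pocketrank_io_error")
  }
  pdb <- tryCatch(
    { # bio3d chats on stdout about altLoc handling; keep parsing quiet
      utils::capture.output(
        p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                              verbose = FALSE))
      )
      p
    },
    error = function(e) {
      abort(paste0("failed to parse PDB file '", path, "': ", conditionMessage(e)),
            class = "pocketrank_io_error")
    }
  )
  at <- pdb$atom
  elem <- as.character(at$elesy)
  # fall back on the atom-name convention when the element column is blank
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[blank])), 1, 1)
  elem <- toupper(trimws(elem))

  alt <- trimws(ifelse(is.na(at$alt), "", as.character(at$alt)))
  keep <- alt %in% c("", "A") & !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  insert <- trimws(ifelse(is.na(at$insert), "", as.character(at$insert)))
  resname <- toupper(trimws(as.character(at$resid)))
  record <- ifelse(resname %in% WATER_RESNAMES, "water",
                   ifelse(at$type == "ATOM", "polymer", "hetero"))
  out <- tibble::tibble(
    chain   = trimws(as.character(at$chain)),
    resno   = paste0(at$resno, insert),
    resname = resname,
    elety   = trimws(as.character(at$elety)),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    record = record
  )
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("non-finite atom coordinates in PDB input", class = "pocketrank_io_error")
  }
  if (!any(out$record == "polymer")) {
    abort(paste0("no polymer (ATOM) atoms in '", path, "'"),
          class = "pocketrank_empty_structure")
  }
  class(out) <- c("prot_structure", class(out))
  out
}

#' Write an atom table back to PDB format
#'
#' Inverse of [read_pdb()] for structures that fit the plain single-model
#' PDB layout; coordinates are written at the format's native 3-decimal
#' precision.
#'
#' @param structure Atom tibble as returned by [read_pdb()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  writeLines(format_pdb_lines(structure), path)
  invisible(path)
}

# fixed-width ATOM/HETATM formatter (also used by the fixture generator)
format_pdb_lines <- function(structure) {
  rec <- ifelse(structure$record == "polymer", "ATOM", "HETATM")
  num <- sub("^(-?[0-9]+).*$", "\\1", structure$resno)
  icode <- substr(structure$resno, nchar(num) + 1L, nchar(structure$resno))
  icode <- ifelse(icode == "", " ", icode)
  name <- ifelse(nchar(structure$elety) >= 4,
                 substr(structure$elety, 1, 4),
                 sprintf(" %-3s", structure$elety))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(structure)), name, " ",
    structure$resname, structure$chain, as.integer(num), icode,
    structure$x, structure$y, structure$z, 1, 0, structure$element
  )
  c(lines, "END")
}

#' Polymer subset of an atom table
#' @param structure Atom tibble.
#' @return Rows with `record == "polymer"`.
#' @export
polymer_atoms <- function(structure) {
  structure[structure$record == "polymer", , drop = FALSE]
}

#' Geometric centre of the protein
#'
#' The unweighted arithmetic mean of the polymer heavy-atom coordinates,
#' the reference point for the pocket-depth (centroid distance) property.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @examples
#' s <- tibble::tibble(chain = "A", resno = c("1", "2"), resname = "GLY",
#'                     elety = "CA", element = "C",
#'                     x = c(0, 2), y = 0, z = 0, record = "polymer")
#' protein_centroid(s) # (1, 0, 0)
#' @export
protein_centroid <- function(structure) {
  poly <- polymer_atoms(structure)
  if (nrow(poly) == 0) {
    abort("structure has no polymer atoms; centroid undefined",
          class = "pocketrank_empty_structure")
  }
  c(x = mean(poly$x), y = mean(poly$y), z = mean(poly$z))
}

#' Extract ligands from the hetero atoms of a structure
#'
#' A ligand is a non-water hetero group with at least `min_heavy_atoms`
#' heavy atoms (groups are keyed by het code, chain and residue number).
#' The size rule automatically discards single-atom entities such as
#' buffer ions.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param min_heavy_atoms Minimum heavy-atom count; default 6.
#' @return A tibble with one row per ligand: `het_code`, `chain`, `resno`,
#'   `n_atoms`, and a list-column `atoms` of per-atom coordinate tibbles.
#'   May have zero rows.
#' @export
extract_ligands <- function(structure, min_heavy_atoms = 6) {
  het <- structure[structure$record == "hetero", , drop = FALSE]
  if (nrow(het) == 0) {
    return(tibble::tibble(het_code = character(), chain = character(),
                          resno = character(), n_atoms = integer(),
                          atoms = list()))
  }
  het |>
    dplyr::group_by(het_code = .data$resname, chain = .data$chain,
                    resno = .data$resno) |>
    tidyr::nest(atoms = c("element", "x", "y", "z")) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_atoms = purrr::map_int(.data$atoms, nrow)) |>
    dplyr::filter(.data$n_atoms >= min_heavy_atoms) |>
    dplyr::select("het_code", "chain", "resno", "n_atoms", "atoms")
}
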