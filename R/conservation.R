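#' Read a per-residue conservation profile
#'
#' Reads the package's conservation dialect: whitespace- or tab-separated
#' text with three columns, `chain  resnum  score`, one residue per line
#' (lines starting with `#` are ignored). Scores follow the ConSurf
#' convention: normalised over the protein to mean 0 / SD 1, with low
#' (negative) values marking the conserved positions.
#'
#' @param path Path to the profile file.
#' @return A tibble `chain`, `resno` (character), `score` (numeric).
#' @seealso [read_consurf_grades()] for importing raw ConSurf grades files.
#' @export
read_conservation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("conservation file not found: ", path),
          class = "pocketrank_io_error")
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed conservation line %d: '%s' (expected: chain resnum score)",
                  keep[bad[1]], lines[keep[bad[1]]]),
          class = "pocketrank_parse_error")
  }
  mat <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(!is.finite(score))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric conservation score on line %d: '%s'",
                  keep[bad[1]], lines[keep[bad[1]]]),
          class = "pocketrank_parse_error")
  }
  out <- tibble::tibble(chain = mat[, 1], resno = mat[, 2], score = score)
  key <- paste(out$chain, out$resno)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate residue key in conservation profile: ",
                 key[which(duplicated(key))[1]]),
          class = "pocketrank_parse_error")
  }
  out
}

#' Import a ConSurf grades file
#'
#' Normalises the tabular `consurf.grades` layout (columns POS, SEQ,
#' 3LATOM, SCORE, ...) into the package's three-column profile. The 3LATOM
#' field (`MET1:A`) supplies chain and residue number; the normalised SCORE
#' column supplies the value. Header, legend and unmapped (`-`) rows are
#' skipped.
#'
#' @param path Path to a ConSurf grades file.
#' @return A conservation tibble as from [read_conservation()].
#' @export
read_consurf_grades <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("ConSurf grades file not found: ", path),
          class = "pocketrank_io_error")
  }
  lines <- readLines(path)
  rows <- purrr::map(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 4) return(NULL)
    if (!grepl("^[0-9]+$", f[1])) return(NULL)          # data rows start with POS
    m <- regmatches(f[3], regexec("^[A-Z]{3}([0-9]+[A-Za-z]?):(\\S+)$", f[3]))[[1]]
    if (length(m) != 3) return(NULL)                    # '-' = not in structure
    score <- suppressWarnings(as.numeric(f[4]))
    if (!is.finite(score)) return(NULL)
    tibble::tibble(chain = m[3], resno = m[2], score = score)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no residue rows recognised in ConSurf grades file",
          class = "pocketrank_parse_error")
  }
  key <- paste(out$chain, out$resno)
  out[!duplicated(key), , drop = FALSE]
}

#' Write a conservation profile in the package dialect
#' @param profile Tibble `chain`, `resno`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(profile, path) {
  writeLines(sprintf("%s\t%s\t%.6f", profile$chain, profile$resno, profile$score),
             path)
  invisible(path)
}
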