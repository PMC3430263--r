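#' Does a pocket centre hit a ligand?
#'
#' A prediction counts as a hit when the pocket's geometric centre lies
#' within `cutoff` (inclusive) of any heavy atom of the ligand.
#'
#' @param center Numeric xyz of the pocket centre.
#' @param ligand_atoms Data frame of ligand heavy-atom coordinates
#'   (columns `x`, `y`, `z`), e.g. one element of
#'   `extract_ligands(...)$atoms`.
#' @param cutoff Hit distance in Angstrom (default 4.0).
#' @return Logical scalar.
#' @export
is_hit <- function(center, ligand_atoms, cutoff = 4.0) {
  if (cutoff <= 0) abort("cutoff must be > 0", class = "pocketrank_config_error")
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0) {
    abort("ligand has no atoms", class = "pocketrank_config_error")
  }
  ctr <- as.numeric(center)[1:3]
  d2 <- (ligand_atoms$x - ctr[1])^2 + (ligand_atoms$y - ctr[2])^2 +
        (ligand_atoms$z - ctr[3])^2
  min(d2) <= cutoff^2
}

#' First hitting rank of a ranked pocket list
#'
#' Walks a ranked list of pockets and returns the first rank whose pocket
#' centre hits any of the ligands; `Inf` when no ranked pocket hits.
#'
#' @param ranked A `ranked_list` tibble (or consensus tibble) with a
#'   `pocket_id` column, best first.
#' @param pockets `pocket_set` tibble carrying the pocket centres.
#' @param ligands Ligand tibble from [extract_ligands()] (non-empty).
#' @param cutoff Hit distance in Angstrom (default 4.0).
#' @return Numeric scalar: the first hitting rank, or `Inf`.
#' @export
hit_rank <- function(ranked, pockets, ligands, cutoff = 4.0) {
  if (nrow(ligands) == 0) {
    abort("no ligands to evaluate against", class = "pocketrank_config_error")
  }
  ids <- ranked$pocket_id
  for (r in seq_along(ids)) {
    i <- match(ids[r], pockets$pocket_id)
    if (is.na(i)) next
    ctr <- c(pockets$x[i], pockets$y[i], pockets$z[i])
    hit <- any(purrr::map_lgl(ligands$atoms, function(a) is_hit(ctr, a, cutoff)))
    if (hit) return(r)
  }
  Inf
}

#' TOP-n success rate over a set of proteins
#'
#' Fraction of proteins for which at least one of the top-n ranked pockets
#' hits a ligand. The denominator is all proteins submitted: proteins
#' whose best hit comes later than rank n (or never) count as failures.
#'
#' @param predictions Tibble with one row per protein and a `hit_rank`
#'   column (from [hit_rank()]; `Inf` = never hits).
#' @param n Rank depth (default 1).
#' @return Success rate in \[0, 1\].
#' @examples
#' preds <- tibble::tibble(protein = 1:4, hit_rank = c(1, 3, Inf, 1))
#' top_n_success(preds, 1) # 0.5
#' top_n_success(preds, 3) # 0.75
#' @export
top_n_success <- function(predictions, n = 1) {
  if (n < 1) abort("n must be >= 1", class = "pocketrank_config_error")
  if (is.null(predictions) || nrow(predictions) == 0) {
    abort("empty prediction set", class = "pocketrank_config_error")
  }
  mean(predictions$hit_rank <= n)
}

#' Residue-level confusion counts for a predicted binding site
#'
#' Actual binding residues are the polymer residues with any heavy atom
#' within `binding_cutoff` of any ligand heavy atom; predicted residues
#' are those assigned to the evaluated pocket (normally the rank-1
#' pocket). Counts partition all polymer residues, so
#' TP + TN + FP + FN equals the protein's residue count.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param predicted_residues Tibble with `chain`, `resno` columns (may
#'   have zero rows).
#' @param ligands Ligand tibble from [extract_ligands()] (non-empty).
#' @param binding_cutoff Heavy-atom distance defining actual binding
#'   residues (default 4.0 Angstrom).
#' @return One-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(structure, predicted_residues, ligands,
                             binding_cutoff = 4.0) {
  if (nrow(ligands) == 0) {
    abort("no ligand: actual binding site undefined", class = "pocketrank_config_error")
  }
  poly <- polymer_atoms(structure)
  lig <- dplyr::bind_rows(ligands$atoms)
  d2min <- rep(Inf, nrow(poly))
  for (j in seq_len(nrow(lig))) {
    d2 <- (poly$x - lig$x[j])^2 + (poly$y - lig$y[j])^2 + (poly$z - lig$z[j])^2
    d2min <- pmin(d2min, d2)
  }
  key <- paste(poly$chain, poly$resno)
  all_res <- unique(key)
  actual <- unique(key[d2min <= binding_cutoff^2])
  predicted <- if (nrow(predicted_residues) == 0) character(0) else {
    intersect(unique(paste(predicted_residues$chain, predicted_residues$resno)),
              all_res)
  }
  tibble::tibble(
    tp = length(intersect(predicted, actual)),
    tn = length(setdiff(setdiff(all_res, predicted), actual)),
    fp = length(setdiff(predicted, actual)),
    fn = length(setdiff(actual, predicted))
  )
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' When any factor of the denominator is zero the coefficient is defined
#' as 0 (the usual convention for degenerate confusion tables).
#'
#' @param counts One-row data frame with `tp`, `tn`, `fp`, `fn` (as from
#'   [confusion_counts()]), or a numeric vector of the four counts in
#'   that order.
#' @return Value in \[-1, 1\].
#' @examples
#' mcc(c(tp = 10, tn = 90, fp = 0, fn = 0)) # 1
#' @export
mcc <- function(counts) {
  if (is.data.frame(counts)) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts[[1]]; tn <- counts[[2]]; fp <- counts[[3]]; fn <- counts[[4]]
  }
  tp <- as.double(tp); tn <- as.double(tn); fp <- as.double(fp); fn <- as.double(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Paired one-sided comparison of two ranking methods
#'
#' One-sided Wilcoxon signed-rank test on paired per-protein MCC scores,
#' alternative: method A scores higher than method B. Zero differences are
#' dropped before testing, following the standard signed-rank treatment.
#'
#' @param mcc_a,mcc_b Equal-length (>= 6) numeric vectors of per-protein
#'   MCC scores for the two methods, aligned by protein.
#' @return The p-value.
#' @export
compare_methods <- function(mcc_a, mcc_b) {
  if (length(mcc_a) != length(mcc_b)) {
    abort("paired MCC vectors must have equal length", class = "pocketrank_config_error")
  }
  if (length(mcc_a) < 6) {
    abort("need at least 6 paired proteins", class = "pocketrank_config_error")
  }
  d <- mcc_a - mcc_b
  d <- d[d != 0]
  if (length(d) == 0) {
    abort("all paired differences are zero; the signed-rank test is degenerate",
          class = "pocketrank_degenerate_test")
  }
  suppressWarnings(
    wilcox.test(d, alternative = "greater", mu = 0, paired = FALSE)$p.value
  )
}
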