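#' @noRd
as_rank_items <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("pocket_id", "item"), names(x))
    if (length(col) == 0) {
      abort("ranked data frame needs a 'pocket_id' or 'item' column",
            class = "pocketrank_config_error")
    }
    x <- x[[col[1]]]
  }
  items <- as.character(x)
  if (anyDuplicated(items)) {
    abort("ranked list contains duplicate items", class = "pocketrank_config_error")
  }
  items
}

#' Truncated rank of items in an ordered list
#'
#' The rank of `t` in `items` (1-based, best first) when `t` is within the
#' top k, and k + 1 otherwise. This truncation convention lets the footrule
#' distance compare lists that do not contain the same items.
#'
#' @param items Ordered list (character/integer vector, best first), or a
#'   `ranked_list` tibble.
#' @param t Item(s) to look up.
#' @param k Truncation length; defaults to the list length.
#' @return Integer vector of ranks, one per element of `t`.
#' @examples
#' truncated_rank(c("A", "B", "C"), "B") # 2
#' truncated_rank(c("A", "B", "C"), "Z") # 4
#' @export
truncated_rank <- function(items, t, k = NULL) {
  items <- as_rank_items(items)
  if (is.null(k)) k <- length(items)
  pos <- match(as.character(t), items)
  out <- ifelse(is.na(pos) | pos > k, k + 1L, pos)
  as.integer(out)
}

#' Spearman footrule distance between two truncated ranked lists
#'
#' Sum, over the union of both lists' items, of the absolute difference of
#' truncated ranks (items absent from a list rank k + 1). Zero iff the two
#' lists rank every union item identically; symmetric and non-negative.
#'
#' @param list_i,list_j Ordered lists (vectors or `ranked_list` tibbles).
#' @param k Shared truncation length. Defaults to the common list length;
#'   lists of different length must state `k` explicitly.
#' @return Non-negative integer distance.
#' @examples
#' footrule_distance(c("A", "B"), c("B", "A")) # 2
#' @export
footrule_distance <- function(list_i, list_j, k = NULL) {
  li <- as_rank_items(list_i)
  lj <- as_rank_items(list_j)
  if (is.null(k)) {
    ki <- attr(list_i, "k") %||% length(li)
    kj <- attr(list_j, "k") %||% length(lj)
    if (ki != kj) {
      abort("lists have different truncation lengths; pass a shared k",
            class = "pocketrank_config_error")
    }
    k <- ki
  }
  u <- union(li, lj)
  sum(abs(truncated_rank(li, u, k) - truncated_rank(lj, u, k)))
}

#' Weighted footrule objective of a candidate consensus list
#'
#' @param delta Candidate ordered list of length k.
#' @param lists List of input ranked lists.
#' @param weights Non-negative importance weights, recycled to
#'   `length(lists)`; default 1 (all lists treated equally).
#' @param k Truncation length; defaults to `length(delta)`.
#' @return Weighted sum of footrule distances from `delta` to each list.
#' @export
objective_phi <- function(delta, lists, weights = 1, k = NULL) {
  delta <- as_rank_items(delta)
  if (is.null(k)) k <- length(delta)
  w <- rep_len(weights, length(lists))
  if (any(w < 0)) abort("weights must be non-negative", class = "pocketrank_config_error")
  sum(purrr::map2_dbl(lists, w, function(l, wi) {
    wi * footrule_distance(delta, l, k = k)
  }))
}

# Shared problem normalisation: universe, per-list truncated-rank matrix.
#' @noRd
normalize_problem <- function(lists, weights, k) {
  if (length(lists) < 1) abort("need at least one ranked list",
                               class = "pocketrank_config_error")
  charlists <- purrr::map(lists, as_rank_items)
  universe <- sort(unique(unlist(charlists)))
  n <- length(universe)
  if (is.null(k)) k <- n
  if (k < 1 || k > n) {
    abort(sprintf("k = %d outside [1, %d] (size of the item universe)", k, n),
          class = "pocketrank_config_error")
  }
  w <- rep_len(weights, length(lists))
  if (any(w < 0)) abort("weights must be non-negative", class = "pocketrank_config_error")
  ranks <- do.call(rbind, purrr::map(charlists, function(l) {
    truncated_rank(l, universe, k)
  }))
  list(universe = universe, lists = charlists, ranks = ranks, W = w, k = k, n = n)
}

#' @noRd
restore_item_type <- function(items, lists) {
  proto <- if (is.data.frame(lists[[1]])) {
    col <- intersect(c("pocket_id", "item"), names(lists[[1]]))[1]
    lists[[1]][[col]]
  } else {
    lists[[1]]
  }
  if (is.numeric(proto)) {
    suppressWarnings(as.integer(items))
  } else {
    items
  }
}

#' Exhaustive rank aggregation (oracle)
#'
#' Enumerates every ordered top-k list over the shared item universe and
#' returns all minimisers of the weighted footrule objective. Intended as
#' the exact reference for small problems; use [ce_aggregate()] beyond the
#' enumeration cap.
#'
#' @inheritParams objective_phi
#' @param lists List of ranked lists (vectors or `ranked_list` tibbles).
#' @param k Consensus length; default = size of the item universe.
#' @param cap Maximum number of orderings to enumerate (default 1e6).
#' @return List with `optima` (list of optimal ordered item vectors),
#'   `phi` (the minimal objective) and `n_evaluated`.
#' @examples
#' brute_force_aggregate(list(c("A", "B", "C"), c("C", "B", "A")))$phi # 4
#' @export
brute_force_aggregate <- function(lists, weights = 1, k = NULL, cap = 1e6) {
  prob <- normalize_problem(lists, weights, k)
  n_orderings <- prod(seq(prob$n, prob$n - prob$k + 1))
  if (n_orderings > cap) {
    abort(sprintf("%.3g orderings exceed the enumeration cap (%.3g); use ce_aggregate()",
                  n_orderings, cap),
          class = "pocketrank_enumeration_cap")
  }
  cand <- k_permutations(prob$n, prob$k)
  phi <- cpp_phi_batch(cand, prob$ranks, prob$W, prob$k)
  best <- min(phi)
  hits <- which(phi == best)
  optima <- purrr::map(hits, function(i) {
    restore_item_type(prob$universe[cand[i, ]], lists)
  })
  list(optima = optima, phi = best, n_evaluated = nrow(cand))
}

# All ordered selections of k items out of 1..n, as a matrix of indices.
#' @noRd
k_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  sub <- k_permutations(n - 1, k - 1)
  blocks <- purrr::map(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    if (ncol(sub) == 0) return(matrix(first, nrow = 1))
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  })
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  out
}

#' Cross-Entropy rank aggregation
#'
#' Stochastic search for the consensus list minimising the weighted
#' Spearman footrule objective. A k x n matrix of position/item
#' probabilities is maintained; each stage samples `N` candidate lists
#' (positions filled sequentially, without replacement), keeps the elite
#' fraction `rho` with the best objective, and re-estimates the matrix from
#' the elite with multiplicative smoothing. The best list ever sampled is
#' returned; the run is declared converged when the best objective has not
#' improved for `stall_limit` consecutive stages.
#'
#' Defaults follow the usual CE guidance for permutation problems:
#' `N = max(10 k^2, 100)` samples per stage and `rho = 0.01` for
#' `N >= 100` (0.1 for smaller N).
#'
#' @inheritParams brute_force_aggregate
#' @param N Samples per stage; default `max(10 * k^2, 100)`.
#' @param rho Elite (rarity) fraction in (0, 1).
#' @param max_stages Hard stage limit (default 100).
#' @param stall_limit Stages without improvement before stopping
#'   (default 10).
#' @param smoothing Weight of the elite re-estimate in the probability
#'   update, in (0, 1]; default 0.7.
#' @param seed Integer seed; with a fixed seed the result is
#'   bit-reproducible.
#' @param restarts Independent optimiser restarts (best result kept).
#' @return A `rank_aggregation` object: `consensus` (tibble `rank`,
#'   `pocket_id`), `phi`, `stages_run`, `converged`, `trace` (best
#'   objective per stage), plus the problem dimensions. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' fit <- ce_aggregate(list(c("A", "B", "C"), c("C", "B", "A")), seed = 1)
#' glance(fit)
#' @export
ce_aggregate <- function(lists, weights = 1, k = NULL, N = NULL, rho = NULL,
                         max_stages = 100, stall_limit = 10, smoothing = 0.7,
                         seed = NULL, restarts = 1) {
  prob <- normalize_problem(lists, weights, k)
  if (is.null(N)) N <- max(10 * prob$k^2, 100)
  if (is.null(rho)) rho <- if (N < 100) 0.1 else 0.01
  if (N < 1 || rho <= 0 || rho >= 1 || smoothing <= 0 || smoothing > 1 ||
      max_stages < 1 || stall_limit < 1 || restarts < 1) {
    abort("invalid CE configuration", class = "pocketrank_config_error")
  }
  run <- function() {
    best_phi <- Inf
    best <- NULL
    trace <- numeric(0)
    total_stages <- 0L
    best_converged <- FALSE
    n_elite <- max(1L, ceiling(rho * N))
    for (r in seq_len(restarts)) {
      P <- matrix(1 / prob$n, nrow = prob$k, ncol = prob$n)
      stall <- 0L
      local_best <- Inf
      converged <- FALSE
      for (stage in seq_len(max_stages)) {
        total_stages <- total_stages + 1L
        cand <- cpp_ce_sample(P, N)
        phi <- cpp_phi_batch(cand, prob$ranks, prob$W, prob$k)
        i_min <- which.min(phi)
        if (phi[i_min] < local_best) {
          local_best <- phi[i_min]
          stall <- 0L
          if (phi[i_min] < best_phi) {
            best_phi <- phi[i_min]
            best <- cand[i_min, ]
          }
        } else {
          stall <- stall + 1L
        }
        trace <- c(trace, local_best)
        if (stall >= stall_limit) { converged <- TRUE; break }
        elite <- cand[order(phi)[seq_len(n_elite)], , drop = FALSE]
        Phat <- matrix(0, nrow = prob$k, ncol = prob$n)
        for (pos in seq_len(prob$k)) {
          tab <- tabulate(elite[, pos], nbins = prob$n)
          Phat[pos, ] <- tab / n_elite
        }
        P <- smoothing * Phat + (1 - smoothing) * P
      }
      if (local_best <= best_phi) best_converged <- converged
    }
    list(best = best, phi = best_phi, stages = total_stages,
         converged = best_converged, trace = trace)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  items <- prob$universe[res$best]
  phi_exact <- objective_phi(items, prob$lists, prob$W, k = prob$k)
  stopifnot(phi_exact == res$phi) # sampled score must equal the exact objective
  out <- list(
    consensus = tibble::tibble(rank = seq_along(items),
                               pocket_id = restore_item_type(items, lists)),
    phi = phi_exact,
    stages_run = res$stages,
    converged = res$converged,
    trace = res$trace,
    k = prob$k, m = length(prob$lists), n_items = prob$n,
    weights = prob$W,
    config = list(N = N, rho = rho, max_stages = max_stages,
                  stall_limit = stall_limit, smoothing = smoothing,
                  seed = seed, restarts = restarts)
  )
  class(out) <- "rank_aggregation"
  out
}

#' @export
print.rank_aggregation <- function(x, ...) {
  cat(sprintf("<rank_aggregation> consensus of %d lists over %d items (k = %d)\n",
              x$m, x$n_items, x$k))
  cat(sprintf("  Phi = %g after %d stage(s)%s\n", x$phi, x$stages_run,
              if (x$converged) " (converged)" else ""))
  print(x$consensus, ...)
  invisible(x)
}

#' @export
tidy.rank_aggregation <- function(x, ...) x$consensus

#' @export
glance.rank_aggregation <- function(x, ...) {
  tibble::tibble(phi = x$phi, stages_run = x$stages_run,
                 converged = x$converged, k = x$k, m = x$m,
                 n_items = x$n_items)
}
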