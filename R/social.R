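#' Co-detection grouping events in clock-aligned hour bins
#'
#' Applies the gambit of the group: individuals detected at the same
#' receiver within the same time bin are taken to be associated. Detections
#' are bucketed into consecutive non-overlapping clock-aligned bins of
#' `window` hours; each (bin, receiver) combination with at least one
#' individual is a grouping event. An individual detected at two receivers
#' within one bin contributes to two distinct groups.
#'
#' @param dataset A `bay_dataset`.
#' @param window Bin width in whole hours (default 1).
#' @param period Optional date pair restricting the analysis window
#'   (inclusive), e.g. one year of data.
#' @return Tibble of group memberships with columns `sampling_period`
#'   (integer bin index), `receiver_id`, `transmitter_id`.
#' @export
group_by_window <- function(dataset, window = 1, period = NULL) {
  stopifnot(inherits(dataset, "bay_dataset"))
  det <- dataset$detections
  if (!is.null(period)) {
    period <- as.Date(period)
    det <- det %>% filter(.data$date >= period[1], .data$date <= period[2])
    if (nrow(det) == 0) abort("no detections in the requested period")
  }
  det %>%
    mutate(sampling_period =
             as.integer(floor(as.numeric(.data$timestamp) / (3600 * window)))) %>%
    distinct(.data$sampling_period, .data$receiver_id, .data$transmitter_id) %>%
    arrange(.data$sampling_period, .data$receiver_id, .data$transmitter_id)
}

#' Simple-ratio association index network
#'
#' For each pair of individuals, over the sampling periods in which at
#' least one of the two was observed: `x` periods saw them in the same
#' group (same receiver, same bin), `y_AB` periods saw both observed but
#' never together, and `y_A` / `y_B` periods saw only one of them. The
#' simple-ratio index `x / (x + y_AB + y_A + y_B)` is 0 for pairs that
#' never co-occurred and 1 for pairs that co-occurred in every period
#' either was seen. Pairs with an empty denominator (possible only when
#' `individuals` includes animals never observed) get index 0 and are
#' flagged.
#'
#' @param groups Group-membership tibble from [group_by_window()].
#' @param individuals Optional character vector fixing the node set (and
#'   matrix order); defaults to all individuals appearing in `groups`.
#' @return An `association_network`: list with the symmetric `sri` matrix
#'   (zero diagonal), a `pairs` tibble holding the `x`, `y_ab`, `y_a`,
#'   `y_b` tallies per pair, and `individuals`.
#' @export
simple_ratio_index <- function(groups, individuals = NULL) {
  groups <- as_tibble(groups)
  stop_missing_cols(groups, c("sampling_period", "receiver_id",
                              "transmitter_id"), "group table")
  if (is.null(individuals)) {
    individuals <- sort(unique(groups$transmitter_id))
  }
  m <- length(individuals)
  if (m < 2) abort("need at least two individuals")
  groups <- groups %>% filter(.data$transmitter_id %in% individuals)

  # periods in which each individual was observed (any receiver)
  obs <- groups %>% distinct(.data$transmitter_id, .data$sampling_period)
  periods <- sort(unique(obs$sampling_period))
  P <- matrix(0L, m, length(periods),
              dimnames = list(individuals, as.character(periods)))
  P[cbind(match(obs$transmitter_id, individuals),
          match(obs$sampling_period, periods))] <- 1L
  both_obs <- P %*% t(P)                  # periods with both observed
  n_obs <- diag(both_obs)

  # periods in which a pair shared at least one group (counted once per bin)
  co <- groups %>%
    inner_join(groups, by = c("sampling_period", "receiver_id"),
               relationship = "many-to-many", suffix = c("_a", "_b")) %>%
    filter(.data$transmitter_id_a < .data$transmitter_id_b) %>%
    distinct(.data$transmitter_id_a, .data$transmitter_id_b,
             .data$sampling_period) %>%
    count(.data$transmitter_id_a, .data$transmitter_id_b, name = "x")
  X <- matrix(0, m, m, dimnames = list(individuals, individuals))
  if (nrow(co) > 0) {
    ia <- match(co$transmitter_id_a, individuals)
    ib <- match(co$transmitter_id_b, individuals)
    X[cbind(ia, ib)] <- co$x
    X[cbind(ib, ia)] <- co$x
  }

  either <- outer(n_obs, n_obs, "+") - both_obs
  sri <- ifelse(either > 0, X / ifelse(either > 0, either, 1), 0)
  diag(sri) <- 0

  pair_idx <- which(upper.tri(sri), arr.ind = TRUE)
  pairs <- tibble(
    id_a = individuals[pair_idx[, 1]],
    id_b = individuals[pair_idx[, 2]],
    x = X[pair_idx],
    y_ab = both_obs[pair_idx] - X[pair_idx],
    y_a = n_obs[pair_idx[, 1]] - both_obs[pair_idx],
    y_b = n_obs[pair_idx[, 2]] - both_obs[pair_idx],
    sri = sri[pair_idx],
    zero_denominator = either[pair_idx] == 0
  )
  out <- list(sri = sri, pairs = pairs, individuals = individuals,
              n_periods = length(periods))
  class(out) <- "association_network"
  out
}

#' @export
print.association_network <- function(x, ...) {
  nz <- sum(x$sri[upper.tri(x$sri)] > 0)
  cat(sprintf("<association_network> %d individuals | %d sampling periods | %d nonzero dyads | mean SRI %.3f\n",
              length(x$individuals), x$n_periods, nz,
              mean(x$sri[upper.tri(x$sri)])))
  invisible(x)
}

# resolve a weight matrix from an association_network or a bare matrix
as_weight_matrix <- function(net) {
  w <- if (inherits(net, "association_network")) net$sri else as.matrix(net)
  if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-12) {
    abort("weights must form a symmetric square matrix")
  }
  diag(w) <- 0
  w
}

#' Weighted categorical assortativity coefficient
#'
#' Builds the weighted mixing matrix `e_ij` (fraction of total edge weight,
#' both directions counted, connecting class `i` to class `j`) and returns
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` with `a` and
#' `b` the row and column margins. `r` is 1 when all weight lies within
#' classes, negative when like avoids like, and invariant to rescaling all
#' weights by a constant.
#'
#' @param net An `association_network` or a symmetric weight matrix.
#' @param trait Categorical labels aligned with the network's individuals.
#' @return The assortativity coefficient, a number in `[-1, 1]`.
#' @export
assortativity_coef <- function(net, trait) {
  w <- as_weight_matrix(net)
  trait <- as.character(trait)
  if (length(trait) != nrow(w)) {
    abort("trait must supply one label per individual")
  }
  if (length(unique(trait)) < 2) abort("trait is constant: r is undefined")
  tw <- sum(w)
  if (tw == 0) abort("empty network: all edge weights are zero")
  Z <- stats::model.matrix(~ factor(trait) - 1)
  E <- t(Z) %*% w %*% Z / tw
  a <- rowSums(E)
  b <- colSums(E)
  (sum(diag(E)) - sum(a * b)) / (1 - sum(a * b))
}

#' Node-permutation test for trait assortment
#'
#' Holds the network's edge structure and weights fixed while reallocating
#' trait labels across nodes (the label multiset is preserved), recomputing
#' the assortativity coefficient each time. The default one-tailed p-value
#' addresses the positive-assortment alternative:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams assortativity_coef
#' @param n_perm Number of label permutations (values below 100 warn).
#' @param seed Optional RNG seed.
#' @param alternative `"greater"` (assortment above null, default) or
#'   `"two.sided"` (on `|r|`).
#' @return An `assortativity_test`: list with `observed_r`, `permuted_r`
#'   (full null sample), `p_value`, `n_perm`, `seed`, `alternative`. Has
#'   [tidy()] and [glance()] methods.
#' @export
node_permutation_test <- function(net, trait, n_perm = 1000, seed = NULL,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  w <- as_weight_matrix(net)
  trait <- as.character(trait)
  if (n_perm < 100) warn("n_perm < 100 gives a coarse p-value resolution")
  r_obs <- assortativity_coef(w, trait)
  if (!is.null(seed)) set.seed(seed)
  tw <- sum(w)
  Zfull <- stats::model.matrix(~ factor(trait) - 1)
  r_of <- function(Z) {
    E <- crossprod(Z, w %*% Z) / tw
    ab <- sum(rowSums(E) * colSums(E))
    (sum(diag(E)) - ab) / (1 - ab)
  }
  n <- nrow(w)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    r_of(Zfull[sample.int(n), , drop = FALSE])
  }, 0)
  p <- if (alternative == "greater") {
    (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  } else {
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  }
  out <- list(observed_r = r_obs, permuted_r = r_perm, p_value = p,
              n_perm = n_perm, seed = seed, alternative = alternative)
  class(out) <- "assortativity_test"
  out
}

#' @export
print.assortativity_test <- function(x, ...) {
  cat(sprintf("Assortativity r = %.3f, node-permutation p = %.4g (%d permutations, %s)\n",
              x$observed_r, x$p_value, x$n_perm, x$alternative))
  invisible(x)
}

#' Co-occurrence social network for a dataset
#'
#' Convenience wrapper: bins detections into hour windows over the given
#' period, builds the simple-ratio network over the individuals detected in
#' that period, and attaches their traits.
#'
#' @param dataset A `bay_dataset`.
#' @inheritParams group_by_window
#' @return An `association_network` with a `traits` tibble
#'   (`transmitter_id`, `species`, `life_stage`) aligned with the matrix.
#' @export
cooccurrence_network <- function(dataset, window = 1, period = NULL) {
  groups <- group_by_window(dataset, window = window, period = period)
  net <- simple_ratio_index(groups)
  net$traits <- tibble(transmitter_id = net$individuals) %>%
    left_join(dataset$tags %>%
                select("transmitter_id", "species", "life_stage"),
              by = "transmitter_id")
  net
}
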