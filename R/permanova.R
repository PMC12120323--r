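#' Distance-matrix PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squared Euclidean distances among
#' multivariate profiles by a sequence of categorical terms, in the order
#' given (sequential, Type I). For each term the pseudo-F statistic is
#' `(SS_term / df_term) / (SS_resid / df_resid)` and its p-value comes from
#' free permutation of observations: `p = (1 + #\{F_perm >= F_obs\}) /
#' (1 + n_perm)`. Sums of squares are computed from the Gower-centered
#' inner-product form of the squared distance matrix, so the same machinery
#' applies to any distance matrix supplied directly.
#'
#' Aliased (rank-deficient) design columns — e.g. interaction cells that do
#' not occur — are dropped with a warning and degrees of freedom are
#' reported as realized.
#'
#' @param profiles Data frame of multivariate responses, one row per
#'   observation: either all-numeric or with a leading `transmitter_id`
#'   column (as from [receiver_use_profiles()]), or a `dist` object.
#' @param data Data frame of factors, rows aligned with `profiles`.
#' @param terms Character vector of model terms in fitting order; main
#'   effects as column names of `data`, interactions as `"a:b"`.
#' @param n_perm Number of random permutations.
#' @param seed Optional seed for the permutation stream.
#' @param permutations Optional integer matrix of explicit orderings (one
#'   row per permutation of `1:n`); if supplied, `p` is the fraction of the
#'   provided orderings (taken as the complete reference set, e.g. an exact
#'   enumeration) with `F >= F_obs`, and `n_perm`/`seed` are ignored.
#' @return A `permanova` object whose `table` is a tibble with rows for
#'   each term plus `Residual` and `Total`: columns `term`, `df`, `SS`,
#'   `F`, `R2`, `p`. Has [tidy()] and [glance()] methods.
#' @export
permanova <- function(profiles, data, terms, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  if (inherits(profiles, "dist")) {
    d2 <- as.matrix(profiles)^2
  } else {
    profiles <- as.data.frame(profiles)
    if ("transmitter_id" %in% names(profiles)) {
      profiles <- profiles[, setdiff(names(profiles), "transmitter_id"),
                           drop = FALSE]
    }
    Y <- as.matrix(profiles)
    if (!is.numeric(Y)) abort("profiles must be numeric")
    d2 <- as.matrix(stats::dist(Y))^2
  }
  n <- nrow(d2)
  data <- as.data.frame(data)
  if (nrow(data) != n) abort("data must have one row per observation")

  # Gower-centered inner-product matrix
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% d2 %*% C

  # cumulative projections, intercept first
  term_cols <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(data))
    if (length(missing) > 0) {
      abort(sprintf("term '%s' references unknown factor(s): %s",
                    term, paste(missing, collapse = ", ")))
    }
    mats <- lapply(parts, function(p) {
      f <- factor(data[[p]])
      stats::model.matrix(~ f - 1)
    })
    out <- Reduce(function(a, b) {
      res <- matrix(0, n, ncol(a) * ncol(b))
      k <- 0
      for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
        k <- k + 1
        res[, k] <- a[, i] * b[, j]
      }
      res
    }, mats)
    out
  }

  X_cum <- matrix(1, n, 1)
  rank_prev <- 1L
  H_prev <- matrix(1 / n, n, n)
  H_diff <- list()
  df <- integer(length(terms))
  for (t in seq_along(terms)) {
    blk <- term_cols(terms[t])
    parts <- strsplit(terms[t], ":", fixed = TRUE)[[1]]
    df_nominal <- prod(vapply(parts,
                              function(p) length(unique(data[[p]])) - 1L, 0L))
    X_cum <- cbind(X_cum, blk)
    qrX <- qr(X_cum)
    rank_now <- qrX$rank
    if (rank_now - rank_prev < df_nominal) {
      # aliasing is expected with unbalanced designs / missing cells;
      # degrees of freedom are reported as realized
      warn(sprintf("term '%s': %d aliased column(s) dropped",
                   terms[t], df_nominal - (rank_now - rank_prev)))
    }
    Q <- qr.Q(qrX)[, seq_len(rank_now), drop = FALSE]
    H_now <- tcrossprod(Q)
    H_diff[[t]] <- H_now - H_prev
    df[t] <- rank_now - rank_prev
    H_prev <- H_now
    rank_prev <- rank_now
  }
  if (any(df == 0)) {
    drop_t <- terms[df == 0]
    warn(sprintf("term(s) fully aliased and dropped: %s",
                 paste(drop_t, collapse = ", ")))
    keep <- df > 0
    H_diff <- H_diff[keep]
    terms <- terms[keep]
    df <- df[keep]
  }
  df_res <- n - 1L - sum(df)
  if (df_res <= 0) abort("more model degrees of freedom than observations")

  ss_total <- sum(diag(G))
  ss_of <- function(Gp) vapply(H_diff, function(H) sum(H * Gp), 0)
  ss_obs <- ss_of(G)
  ss_res_obs <- ss_total - sum(ss_obs)
  F_obs <- (ss_obs / df) / (ss_res_obs / df_res)
  # permuted statistics equal to the observed one up to floating-point noise
  # (e.g. permutations preserving the group partition) count as ties
  f_tol <- 1e-8 * pmax(1, abs(F_obs))

  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n) abort("permutation rows must have length n")
    F_perm <- apply(permutations, 1, function(idx) {
      Gp <- G[idx, idx]
      ssp <- ss_of(Gp)
      (ssp / df) / ((ss_total - sum(ssp)) / df_res)
    })
    F_perm <- matrix(F_perm, nrow = length(terms))
    p <- rowMeans(F_perm >= F_obs - f_tol)
    n_perm_used <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count_ge <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Gp <- G[idx, idx]
      ssp <- ss_of(Gp)
      Fp <- (ssp / df) / ((ss_total - sum(ssp)) / df_res)
      count_ge <- count_ge + (Fp >= F_obs - f_tol)
    }
    p <- (1 + count_ge) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  tab <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss_obs, ss_res_obs, ss_total),
    F = c(F_obs, NA, NA),
    R2 = c(ss_obs, ss_res_obs, ss_total) / ss_total,
    p = c(p, NA, NA)
  )
  out <- list(table = tab, n = n, n_perm = n_perm_used, seed = seed)
  class(out) <- "permanova"
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d free permutations, n = %d)\n",
              x$n_perm, x$n))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}
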