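#' Periodic cubic B-spline basis over the months of the year
#'
#' Evaluates a cyclic cubic B-spline basis on the circle of month values
#' `[1, 13)`: knots are equally spaced, the basis wraps around the year
#' boundary with continuity up to the second derivative, and each row sums
#' to one (partition of unity). Month 12 + m evaluates identically to month
#' m, so December joins January smoothly.
#'
#' @param month Numeric vector of month positions; any real value is mapped
#'   onto `[1, 13)` modulo 12.
#' @param k Number of basis functions (>= 4).
#' @return Numeric matrix, `length(month)` rows by `k` columns.
#' @export
cyclic_spline_basis <- function(month, k = 12) {
  if (k < 4) abort("k must be >= 4 for a cubic basis")
  period <- 12
  x <- ((month - 1) %% period) + 1
  h <- period / k
  knots <- 1 + h * (-3:(k + 3))
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
  # columns k+1..k+3 are the period-shifted copies of columns 1..3: fold
  out <- B[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(B) - k)) out[, j] <- out[, j] + B[, k + j]
  out
}

# cyclic second-difference penalty, k x k
cyclic_penalty <- function(k) {
  D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    D[i, i] <- 1
    D[i, (i %% k) + 1] <- -2
    D[i, ((i + 1) %% k) + 1] <- 1
  }
  crossprod(D)
}

# sum-to-zero reparameterization for a cyclic smooth: columns of Z span the
# subspace of coefficient vectors orthogonal to 1 (removes the confound with
# the species intercept, since the basis rows sum to 1)
sum_zero_Z <- function(k) {
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' Fit a cyclic-seasonal detection model
#'
#' Models per-individual monthly detection-day counts as overdispersed
#' Poisson with a log link and a month-length offset:
#' `log E(count) = species intercept + f_species(month) + b_individual +
#' log(days in month)`, where each `f_species` is a periodic cubic spline
#' over the months of the year (sum-to-zero constrained, cyclic
#' second-difference penalty) and the individual intercepts are a
#' ridge-penalized block (the classical random-intercept-as-penalty
#' equivalence). Fitting is penalized iteratively reweighted least squares;
#' the two smoothing parameters are chosen by grid-search GCV on the
#' deviance; the dispersion is the Pearson statistic over residual degrees
#' of freedom, and per-species smooth terms get an approximate Wald-type F
#' test on the penalized coefficients (rounded effective degrees of
#' freedom), flagged as approximate in the output.
#'
#' @param monthly Monthly table from [monthly_detection_table()] (needs
#'   `transmitter_id`, `species`, `month`, `days_detected`, `days_in_month`).
#' @param k Cyclic basis size per species.
#' @param lambda_smooth Optional fixed smoothing parameter; `NULL` selects
#'   by GCV over `lambda_grid`.
#' @param lambda_re Optional fixed ridge parameter for individual
#'   intercepts; `NULL` selects by GCV over `lambda_re_grid`.
#' @param lambda_grid,lambda_re_grid Log-spaced search grids.
#' @param max_iter,tol IRLS iteration cap and relative-deviance tolerance.
#' @return A `seasonal_fit` object with per-species intercepts and smooth
#'   coefficients, selected smoothing parameters, quasi-Poisson dispersion,
#'   effective degrees of freedom, approximate term tests, and the fitted
#'   species-by-month detection probabilities with pointwise standard
#'   errors. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_seasonal_model <- function(monthly, k = 12,
                               lambda_smooth = NULL, lambda_re = NULL,
                               lambda_grid = 10^seq(-3, 6, length.out = 10),
                               lambda_re_grid = 10^seq(-1, 3, length.out = 5),
                               max_iter = 50, tol = 1e-8) {
  monthly <- as_tibble(monthly)
  stop_missing_cols(monthly, c("transmitter_id", "species", "month",
                               "days_detected", "days_in_month"),
                    "monthly table")
  species <- sort(unique(monthly$species))
  if (length(species) < 2) abort("need at least two species to fit")
  per_sp <- table(monthly$species)
  if (any(per_sp < 24)) {
    abort("each species needs at least 24 individual-months")
  }
  ids <- sort(unique(monthly$transmitter_id))
  n <- nrow(monthly)
  y <- monthly$days_detected
  off <- log(monthly$days_in_month)

  zero_sp <- species[tapply(y, monthly$species, sum)[species] == 0]
  if (length(zero_sp) > 0) {
    warn(sprintf("species never detected (%s): fitted probability driven to 0",
                 paste(zero_sp, collapse = ", ")))
  }

  # design: species intercepts | per-species constrained cyclic smooths |
  # individual intercepts (ridge)
  Z <- sum_zero_Z(k)
  Bm <- cyclic_spline_basis(monthly$month, k) %*% Z
  S_sp <- outer(monthly$species, species, "==") * 1
  smooth_blocks <- lapply(species, function(s) Bm * (monthly$species == s))
  U <- outer(monthly$transmitter_id, ids, "==") * 1
  X <- cbind(S_sp, do.call(cbind, smooth_blocks), U)
  p_sp <- length(species)
  p_sm <- ncol(Z)
  idx_sp <- seq_len(p_sp)
  idx_sm <- lapply(seq_along(species), function(j) {
    p_sp + (j - 1) * p_sm + seq_len(p_sm)
  })
  idx_re <- p_sp + length(species) * p_sm + seq_along(ids)
  P_sm <- t(Z) %*% cyclic_penalty(k) %*% Z

  penalty_matrix <- function(ls, lr) {
    S <- matrix(0, ncol(X), ncol(X))
    for (ii in idx_sm) S[ii, ii] <- ls * P_sm
    diag(S)[idx_re] <- diag(S)[idx_re] + lr
    S
  }

  pirls <- function(S, eta0 = NULL) {
    eta <- if (is.null(eta0)) log(pmax(y, 0.25)) else eta0
    eta <- pmax(pmin(eta, 15), -15)
    dev_old <- Inf
    XtWX <- NULL
    for (it in seq_len(max_iter)) {
      mu <- exp(eta + off)
      w <- mu
      z <- eta + (y - mu) / mu
      Xw <- X * w
      XtWX <- crossprod(X, Xw)
      beta <- tryCatch(
        solve(XtWX + S, crossprod(Xw, z)),
        error = function(e) abort(paste("seasonal model failed to solve the",
                                        "penalized system:", conditionMessage(e)))
      )
      eta <- pmax(pmin(drop(X %*% beta), 15), -15)
      mu <- exp(eta + off)
      dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      if (is.finite(dev_old) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
        return(list(beta = drop(beta), eta = eta, mu = mu, dev = dev,
                    XtWX = XtWX, iter = it, converged = TRUE))
      }
      dev_old <- dev
    }
    list(beta = drop(beta), eta = eta, mu = mu, dev = dev_old, XtWX = XtWX,
         iter = max_iter, converged = FALSE)
  }

  ls_grid <- if (is.null(lambda_smooth)) lambda_grid else lambda_smooth
  lr_grid <- if (is.null(lambda_re)) lambda_re_grid else lambda_re
  best <- NULL
  eta_warm <- NULL
  for (lr in lr_grid) {
    for (ls in ls_grid) {
      S <- penalty_matrix(ls, lr)
      fit <- pirls(S, eta_warm)
      eta_warm <- fit$eta
      A <- solve(fit$XtWX + S, fit$XtWX)
      edf <- sum(diag(A))
      gcv <- n * fit$dev / (n - edf)^2
      if (is.null(best) || gcv < best$gcv) {
        best <- list(fit = fit, S = S, A = A, edf = edf, gcv = gcv,
                     lambda_smooth = ls, lambda_re = lr)
      }
    }
  }
  fit <- best$fit
  if (!fit$converged) {
    abort(sprintf("seasonal model did not converge in %d IRLS iterations", max_iter))
  }

  pearson <- sum((y - fit$mu)^2 / fit$mu)
  df_resid <- max(n - best$edf, 1)
  phi <- pearson / df_resid
  Vinv <- solve(fit$XtWX + best$S)
  # sandwich covariance for the penalized estimator, scaled by dispersion
  Ve <- phi * (Vinv %*% fit$XtWX %*% Vinv)
  edf_j <- diag(best$A)

  # approximate per-species smooth tests: scaled-deviance drop test against
  # the model with that species' smooth penalized to flatness (quasi-F)
  term_tests <- purrr::map(seq_along(species), function(j) {
    S_red <- best$S
    ii <- idx_sm[[j]]
    S_red[ii, ii] <- 1e10 * P_sm
    fit_red <- pirls(S_red, fit$eta)
    A_red <- solve(fit_red$XtWX + S_red, fit_red$XtWX)
    edf_s <- max(best$edf - sum(diag(A_red)), 0.1)
    stat <- max(fit_red$dev - fit$dev, 0) / (edf_s * phi)
    tibble(species = species[j], edf = sum(edf_j[ii]), statistic = stat,
           df = edf_s,
           p_value = stats::pf(stat, edf_s, df_resid, lower.tail = FALSE))
  }) %>% list_rbind()

  months <- 1:12
  Bp <- cyclic_spline_basis(months, k) %*% Z
  fitted_monthly <- purrr::map(seq_along(species), function(j) {
    xrow <- matrix(0, 12, ncol(X))
    xrow[, idx_sp[j]] <- 1
    xrow[, idx_sm[[j]]] <- Bp
    eta <- drop(xrow %*% fit$beta)
    se_eta <- sqrt(pmax(rowSums((xrow %*% Ve) * xrow), 0))
    prob <- exp(eta)
    tibble(species = species[j], month = months,
           probability = pmin(prob, 1),
           se = prob * se_eta)
  }) %>% list_rbind()

  out <- list(
    coefficients = fit$beta,
    species = species, individuals = ids, k = k, Z = Z,
    idx = list(species = idx_sp, smooth = idx_sm, re = idx_re),
    lambda_smooth = best$lambda_smooth, lambda_re = best$lambda_re,
    gcv = best$gcv, dispersion = phi, edf = best$edf,
    deviance = fit$dev, pearson = pearson, n = n,
    covariance = Ve, term_tests = term_tests,
    fitted_monthly = fitted_monthly,
    iterations = fit$iter, converged = fit$converged
  )
  class(out) <- "seasonal_fit"
  out
}

#' Predicted monthly detection probability for one species
#'
#' Per-day detection probability by calendar month (the exponentiated
#' linear predictor with a unit offset, clipped to `[0, 1]`), with pointwise
#' delta-method standard errors.
#'
#' @param fit A `seasonal_fit`.
#' @param species Species name present in the fit.
#' @return Tibble with columns `month`, `probability`, `se`.
#' @export
predict_monthly <- function(fit, species) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (!species %in% fit$species) {
    abort(sprintf("unknown species '%s'", species))
  }
  fit$fitted_monthly %>%
    filter(.data$species == !!species) %>%
    select("month", "probability", "se")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf(paste0("<seasonal_fit> %d rows | %d species | %d individuals\n",
                     "  lambda_smooth = %.3g, lambda_re = %.3g, ",
                     "dispersion = %.3g, edf = %.1f\n"),
              x$n, length(x$species), length(x$individuals),
              x$lambda_smooth, x$lambda_re, x$dispersion, x$edf))
  cat("  approximate smooth-term tests:\n")
  print(as.data.frame(x$term_tests), row.names = FALSE)
  invisible(x)
}
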