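#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' @export
tidy.group_comparison <- function(x, ...) {
  if (nrow(x$posthoc) > 0) x$posthoc else
    tibble(pair = NA_character_, z = NA_real_, p = x$p_value,
           p_adjusted = x$p_value)
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, df = x$df,
         p.value = x$p_value)
}

#' @export
tidy.permanova <- function(x, ...) x$table

#' @export
glance.permanova <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm,
         r.squared.model = sum(x$table$R2[!x$table$term %in%
                                            c("Residual", "Total")]))
}

#' @export
tidy.seasonal_fit <- function(x, ...) x$term_tests

#' @export
glance.seasonal_fit <- function(x, ...) {
  tibble(n = x$n, deviance = x$deviance, dispersion = x$dispersion,
         edf = x$edf, lambda_smooth = x$lambda_smooth,
         lambda_re = x$lambda_re, gcv = x$gcv, converged = x$converged)
}

#' @export
tidy.assortativity_test <- function(x, ...) {
  tibble(observed_r = x$observed_r, p.value = x$p_value,
         null_mean = mean(x$permuted_r),
         null_q025 = unname(quantile(x$permuted_r, 0.025)),
         null_q975 = unname(quantile(x$permuted_r, 0.975)))
}

#' @export
glance.assortativity_test <- function(x, ...) {
  tibble(observed_r = x$observed_r, p.value = x$p_value, n_perm = x$n_perm,
         alternative = x$alternative)
}
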