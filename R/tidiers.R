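#' Tidy a fitted window VAR
#'
#' One row per coefficient: target lead, source lead, lag (in samples of the
#' decimated rate), and the least-squares estimate.
#'
#' @param x a `var_fit` from [fit_var_window()].
#' @param ... unused.
#' @return tibble: `target`, `source`, `lag`, `estimate`.
#' @export
tidy.var_fit <- function(x, ...) {
  L <- nrow(x$Sigma)
  grid <- expand.grid(target = seq_len(L), source = seq_len(L),
                      lag = seq_len(x$order))
  tibble::tibble(
    target = grid$target, source = grid$source, lag = grid$lag,
    estimate = x$coef[cbind(grid$target, grid$source, grid$lag)]
  )
}

#' Glance at a fitted window VAR
#'
#' @param x a `var_fit`.
#' @param ... unused.
#' @return one-row tibble: `n_leads`, `order`, `ns_factor`, `n_obs`,
#'   `logdet_sigma` (log-determinant of the residual covariance).
#' @export
glance.var_fit <- function(x, ...) {
  tibble::tibble(
    n_leads = nrow(x$Sigma), order = x$order, ns_factor = x$ns_factor,
    n_obs = x$n_obs,
    logdet_sigma = determinant(x$Sigma, logarithm = TRUE)$modulus[[1]]
  )
}
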