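# broom-style tidy()/glance() methods for the package's fitted objects.

#' @exportS3Method generics::tidy
tidy.gls_aicc <- function(x, ...) {
  s <- summary(x$fit)$tTable
  tibble(term = rownames(s), estimate = s[, "Value"],
         std.error = s[, "Std.Error"], statistic = s[, "t-value"],
         p.value = s[, "p-value"])
}

#' @exportS3Method generics::glance
glance.gls_aicc <- function(x, ...) {
  best <- x$candidates |> filter(.data$structure == x$structure)
  tibble(structure = x$structure, log_lik = best$log_lik, k = best$k,
         aicc = best$aicc, n = x$n, n_groups = nlevels(x$data$g))
}

#' @exportS3Method generics::tidy
tidy.posthoc_groups <- function(x, ...) x$comparisons

#' @exportS3Method generics::glance
glance.posthoc_groups <- function(x, ...) {
  tibble(n_comparisons = nrow(x$comparisons),
         n_significant = sum(x$comparisons$significant),
         alpha = x$alpha, structure = x$structure)
}

#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.pgls_fit <- function(x, ...) {
  tibble(sigma2 = x$sigma2, n = x$n, df.residual = x$df.residual,
         correlation_model = x$correlation_model)
}

#' @exportS3Method generics::tidy
tidy.pca_diag <- function(x, matrix = c("loadings", "scores", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    loadings = x$loadings |>
      tidyr::pivot_longer(-"variable", names_to = "component",
                          values_to = "loading"),
    scores = x$scores |> mutate(row = row_number(), .before = 1),
    eigenvalues = tibble(component = paste0("PC", seq_along(x$eigenvalues)),
                         eigenvalue = x$eigenvalues,
                         explained = x$explained,
                         cumulative = cumsum(x$explained)))
}

#' @exportS3Method generics::glance
glance.pca_diag <- function(x, ...) {
  tibble(kmo = x$kmo, bartlett_chi2 = x$bartlett_chi2,
         bartlett_df = x$bartlett_df, bartlett_p = x$bartlett_p,
         n = x$n, n_dropped = x$n_dropped, n_vars = length(x$vars))
}

#' @exportS3Method generics::tidy
tidy.asr_ml <- function(x, ...) x$states

#' @exportS3Method generics::glance
glance.asr_ml <- function(x, ...) {
  tibble(trait = x$trait, transform = x$transform,
         root_state = x$root_state,
         n_tips = sum(x$states$is_tip),
         n_nodes = sum(!x$states$is_tip))
}

#' @exportS3Method generics::tidy
tidy.signal_result <- function(x, ...) as_tibble(unclass(x))
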