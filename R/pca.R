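# Correlation-matrix PCA with sampling-adequacy diagnostics (KMO and
# Bartlett's sphericity test), as used to screen multi-element leaf and
# soil chemistry before ordination.

#' PCA on the correlation matrix with KMO and Bartlett diagnostics
#'
#' Spectral decomposition of the correlation matrix of the selected
#' variables (listwise deletion of incomplete rows, with a message), plus:
#' * Kaiser-Meyer-Olkin sampling adequacy,
#'   `KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over `i != j`, where
#'   `q` are the anti-image partial correlations (values > 0.6 conventionally
#'   indicate PCA suitability);
#' * Bartlett's test of sphericity,
#'   `chi2 = -(n - 1 - (2v + 5)/6) * ln det(R)`, `df = v(v-1)/2`
#'   (p < 0.05 indicates the correlation matrix is not the identity).
#'
#' A singular correlation matrix leaves KMO undefined (warning) but the PCA
#' itself is still returned; a constant column is an error naming it.
#'
#' @param data A data frame.
#' @param vars Character vector of columns to use; default all numeric.
#' @return An object of class `pca_diag` with scores, loadings, explained
#'   variance fractions, `kmo`, and the Bartlett test. Use `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
pca_diagnostics <- function(data, vars = NULL) {
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 3) abort("PCA diagnostics need at least three variables")
  X <- as.data.frame(data)[vars]
  ok <- complete.cases(X)
  if (any(!ok))
    message(sum(!ok), " incomplete row(s) dropped (listwise deletion)")
  X <- X[ok, , drop = FALSE]
  n <- nrow(X); v <- length(vars)
  if (n <= v) abort("need more complete observations than variables")
  const <- vars[vapply(X, function(col) sd(col) == 0, logical(1))]
  if (length(const))
    abort(paste0("constant column(s): ", paste(const, collapse = ", ")))

  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  loadings <- eig$vectors
  rownames(loadings) <- vars
  colnames(loadings) <- paste0("PC", seq_len(v))
  Z <- scale(as.matrix(X))
  scores <- Z %*% loadings
  explained <- eig$values / sum(eig$values)

  det_R <- det(R)
  bartlett_chi2 <- -(n - 1 - (2 * v + 5) / 6) * log(max(det_R, .Machine$double.xmin))
  bartlett_df <- v * (v - 1) / 2
  bartlett_p <- pchisq(bartlett_chi2, bartlett_df, lower.tail = FALSE)

  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || det_R < 1e-12) {
    warn("correlation matrix is (near-)singular; KMO undefined, PCA still returned")
    kmo <- NA_real_
  } else {
    Q <- -Rinv / sqrt(outer(diag(Rinv), diag(Rinv)))
    off <- upper.tri(R)
    kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  }

  structure(list(
    scores = as_tibble(scores),
    loadings = as_tibble(loadings, rownames = "variable"),
    explained = explained,
    eigenvalues = eig$values,
    kmo = kmo,
    bartlett_chi2 = bartlett_chi2, bartlett_df = bartlett_df,
    bartlett_p = bartlett_p,
    n = n, n_dropped = sum(!ok), det_r = det_R, vars = vars),
    class = "pca_diag")
}

#' @export
print.pca_diag <- function(x, ...) {
  cat("PCA on the correlation matrix:", length(x$vars), "variables,",
      x$n, "observations\n")
  cat("  explained variance (first axes):",
      paste0(round(100 * head(x$explained, 3), 1), "%", collapse = ", "), "\n")
  cat("  KMO:", round(x$kmo, 3),
      " Bartlett chi2:", round(x$bartlett_chi2, 2),
      " df:", x$bartlett_df,
      " p:", format.pval(x$bartlett_p), "\n")
  invisible(x)
}
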