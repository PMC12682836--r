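# Survey-level nutrient statistics: N:P phosphorus-limitation flags and
# log-scale Pearson correlation matrices.

#' Leaf N:P ratio with a phosphorus-limitation flag
#'
#' Adds the mass-basis leaf N:P ratio and a limitation flag to the data.
#' Ratios strictly above the threshold (default 20) are taken to indicate
#' phosphorus limitation of growth.
#'
#' @param data A data frame of leaf samples.
#' @param n,p Columns holding leaf N and P (mg g⁻¹); bare names.
#' @param threshold Limitation threshold on N:P (strict `>`).
#' @return `data` with added `np_ratio` and `p_limited` columns.
#' @export
#' @examples
#' np_ratio(tibble::tibble(N = c(16, 10.6), P = c(1, 0.4)))
np_ratio <- function(data, n = N, p = P, threshold = 20) {
  n_vals <- dplyr::pull(data, {{ n }})
  p_vals <- dplyr::pull(data, {{ p }})
  if (any(!is.na(p_vals) & p_vals == 0))
    abort("undefined N:P ratio: leaf P is zero in at least one row")
  if (any(!is.na(p_vals) & p_vals < 0) || any(!is.na(n_vals) & n_vals < 0))
    abort("negative concentration passed to np_ratio")
  data |>
    mutate(np_ratio = n_vals / p_vals,
           p_limited = .data$np_ratio > threshold)
}

#' Pairwise Pearson correlations on log-transformed variables
#'
#' Natural-log transforms the selected variables (concentrations are
#' positive and right-skewed), then computes pairwise Pearson r with
#' t-based two-sided p-values over pairwise-complete observations.
#'
#' @param data A data frame.
#' @param vars Character vector of column names; default all numeric columns.
#' @param transform `"log"` (default, natural log) or `"none"`.
#' @return A tibble of all ordered variable pairs (including the unit
#'   diagonal): `var1`, `var2`, `r`, `p`, `n`. Convert to a matrix with
#'   [cor_to_matrix()].
#' @export
correlation_matrix <- function(data, vars = NULL,
                               transform = c("log", "none")) {
  transform <- match.arg(transform)
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2) abort("need at least two variables")
  X <- as.data.frame(data)[vars]
  if (transform == "log") {
    for (v in vars) {
      bad <- which(!is.na(X[[v]]) & X[[v]] <= 0)
      if (length(bad))
        abort(paste0("cannot log-transform `", v, "`: non-positive value ",
                     "in row(s) ", paste(head(bad, 5), collapse = ", ")))
      X[[v]] <- log(X[[v]])
    }
  }
  pairs <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  res <- purrr::pmap(pairs, function(var1, var2) {
    x <- X[[var1]]; y <- X[[var2]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (var1 == var2)
      return(tibble(var1 = var1, var2 = var2, r = 1, p = NA_real_, n = n))
    if (n < 3)
      abort(paste0("fewer than 3 complete pairs for ", var1, " ~ ", var2))
    r <- cor(x[ok], y[ok])
    t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble(var1 = var1, var2 = var2, r = r, p = 2 * pt(-abs(t), n - 2), n = n)
  }) |> list_rbind()
  res
}

#' Widen a pairwise correlation tibble into a matrix
#'
#' @param cors Output of [correlation_matrix()].
#' @param value `"r"` (default) or `"p"`.
#' @return A symmetric matrix.
#' @export
cor_to_matrix <- function(cors, value = c("r", "p")) {
  value <- match.arg(value)
  vars <- unique(cors$var1)
  m <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  m[cbind(match(cors$var1, vars), match(cors$var2, vars))] <- cors[[value]]
  m
}
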