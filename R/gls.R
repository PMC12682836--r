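# Heteroscedastic group-comparison models: a group-means GLS fitted under
# candidate variance structures, selected by AICc, with studentized-range
# post-hoc comparisons and a compact letter display.

GLS_STRUCTURES <- c("constant", "per_group", "power_of_mean")

.aicc <- function(log_lik, k, n) {
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a group-means GLS under candidate variance structures, select by AICc
#'
#' Fits `response ~ group` by maximum likelihood under each candidate
#' variance structure and returns the fit with the lowest AICc
#' (`-2 logL + 2k + 2k(k+1)/(n-k-1)`), ties broken toward fewer parameters.
#' Candidate structures:
#' * `constant` — one residual variance (ordinary least squares);
#' * `per_group` — a separate variance per group (`nlme::varIdent`);
#' * `power_of_mean` — `Var = sigma^2 * |mu_g|^(2*delta)`
#'   (`nlme::varPower` on the fitted values).
#'
#' Candidates with `n <= k + 1` (AICc undefined) or failed convergence are
#' skipped with a warning; an error is raised if none survive.
#'
#' Selection uses the information-theoretic equivalence convention: among
#' candidates within `parsimony_margin` AICc units of the minimum (models
#' that the data cannot meaningfully separate), the one with fewest
#' parameters wins; `parsimony_margin = 0` reduces to the plain minimum.
#'
#' @param data A data frame.
#' @param response,group Bare column names of the response and the grouping
#'   factor.
#' @param structures Subset of the candidate structures to consider.
#' @param parsimony_margin AICc window (default 2) within which the simpler
#'   structure is preferred.
#' @return An object of class `gls_aicc`: the selected `nlme::gls` fit plus
#'   a candidate table (see `tidy()`, `glance()`, [posthoc_groups()]).
#' @export
fit_gls_aicc <- function(data, response, group,
                         structures = GLS_STRUCTURES,
                         parsimony_margin = 2) {
  structures <- match.arg(structures, GLS_STRUCTURES, several.ok = TRUE)
  y <- dplyr::pull(data, {{ response }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ok <- complete.cases(y, g)
  d <- data.frame(y = y[ok], g = g[ok])
  n <- nrow(d)
  if (nlevels(droplevels(d$g)) < 2) abort("need at least two groups")
  d$g <- droplevels(d$g)
  if ("per_group" %in% structures &&
      any(table(d$g) < 2)) {
    warn("per_group structure skipped: some group has fewer than 2 observations")
    structures <- setdiff(structures, "per_group")
  }

  weight_of <- function(s) switch(s,
    constant = NULL,
    per_group = nlme::varIdent(form = ~ 1 | g),
    power_of_mean = nlme::varPower(form = ~ fitted(.)))

  fits <- list()
  cand <- purrr::map(structures, function(s) {
    fit <- tryCatch(
      nlme::gls(y ~ g, data = d, weights = weight_of(s), method = "ML"),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warn(paste0("variance structure `", s, "` skipped: ",
                  conditionMessage(fit)))
      return(tibble(structure = s, log_lik = NA_real_, k = NA_integer_,
                    aicc = NA_real_, converged = FALSE))
    }
    ll <- logLik(fit)
    k <- as.integer(attr(ll, "df"))
    if (n <= k + 1) {
      warn(paste0("variance structure `", s, "` skipped: n <= k + 1, ",
                  "AICc undefined"))
      return(tibble(structure = s, log_lik = as.numeric(ll), k = k,
                    aicc = NA_real_, converged = FALSE))
    }
    fits[[s]] <<- fit
    tibble(structure = s, log_lik = as.numeric(ll), k = k,
           aicc = .aicc(as.numeric(ll), k, n), converged = TRUE)
  }) |> list_rbind()

  usable <- cand |> filter(.data$converged)
  if (!nrow(usable)) abort("no variance structure could be fitted")
  within_margin <- usable |>
    filter(.data$aicc <= min(.data$aicc) + parsimony_margin) |>
    arrange(.data$k, .data$aicc)
  best <- within_margin$structure[1]

  structure(list(structure = best, fit = fits[[best]], candidates = cand,
                 data = d, n = n,
                 response = as_name(enquo(response)),
                 group = as_name(enquo(group))),
            class = "gls_aicc")
}

#' @export
print.gls_aicc <- function(x, ...) {
  cat("Group-means GLS with AICc-selected variance structure\n")
  cat("  response:", x$response, " group:", x$group, " n:", x$n, "\n")
  cat("  selected structure:", x$structure, "\n\n")
  print(x$candidates)
  invisible(x)
}

# group-level moments under the selected variance structure; group means of
# a one-way layout are the per-group sample means under all three structures
.group_moments <- function(object) {
  d <- object$data
  stats_tab <- d |>
    group_by(.data$g) |>
    summarise(mean = mean(.data$y), var = var(.data$y), n = n(),
              .groups = "drop")
  k_grp <- nrow(stats_tab)
  n_tot <- object$n
  df_resid <- n_tot - k_grp
  switch(object$structure,
    constant = {
      s2_pool <- sum((d$y - stats_tab$mean[match(d$g, stats_tab$g)])^2) /
        df_resid
      stats_tab |> mutate(s2 = s2_pool, df = df_resid)
    },
    per_group = stats_tab |> mutate(s2 = .data$var, df = .data$n - 1),
    power_of_mean = {
      delta <- as.numeric(coef(object$fit$modelStruct$varStruct))
      w <- abs(stats_tab$mean[match(d$g, stats_tab$g)])^(-2 * delta)
      s2_base <- sum(w * (d$y - stats_tab$mean[match(d$g, stats_tab$g)])^2) /
        df_resid
      stats_tab |> mutate(s2 = s2_base * abs(.data$mean)^(2 * delta),
                          df = df_resid)
    })
}

#' Post-hoc pairwise comparisons with a compact letter display
#'
#' All pairwise group-mean contrasts from an AICc-selected GLS fit, with
#' family-wise control via the studentized-range criterion. Under the
#' `constant` structure this is classical Tukey HSD (Tukey-Kramer for
#' unbalanced layouts). Under `per_group` or `power_of_mean` the standard
#' errors come from the structure's group variances with Welch-Satterthwaite
#' degrees of freedom per pair (Games-Howell). Groups sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param object A `gls_aicc` fit.
#' @param alpha Family-wise significance level.
#' @return An object of class `posthoc_groups` with `$comparisons`
#'   (pairwise tibble) and `$letters` (group, mean, letter).
#' @export
posthoc_groups <- function(object, alpha = 0.05) {
  stopifnot(inherits(object, "gls_aicc"))
  gm <- .group_moments(object)
  k <- nrow(gm)
  if (k < 2) abort("post-hoc comparisons need at least two groups")
  idx <- utils::combn(k, 2)
  comp <- purrr::map(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    se2_half <- (gm$s2[i1] / gm$n[i1] + gm$s2[i2] / gm$n[i2]) / 2
    q <- abs(gm$mean[i1] - gm$mean[i2]) / sqrt(se2_half)
    df <- if (object$structure == "per_group") {
      (gm$s2[i1] / gm$n[i1] + gm$s2[i2] / gm$n[i2])^2 /
        ((gm$s2[i1] / gm$n[i1])^2 / (gm$n[i1] - 1) +
         (gm$s2[i2] / gm$n[i2])^2 / (gm$n[i2] - 1))
    } else {
      gm$df[i1]
    }
    tibble(group1 = as.character(gm$g[i1]), group2 = as.character(gm$g[i2]),
           diff = gm$mean[i1] - gm$mean[i2],
           se = sqrt(2 * se2_half), q = q, df = df,
           p = 1 - ptukey(q, k, df))
  }) |> list_rbind() |>
    mutate(significant = .data$p < alpha)

  letters_tab <- .compact_letters(as.character(gm$g), gm$mean,
                                  comp$group1, comp$group2, comp$significant)
  structure(list(comparisons = comp,
                 letters = letters_tab,
                 alpha = alpha, structure = object$structure),
            class = "posthoc_groups")
}

#' @export
print.posthoc_groups <- function(x, ...) {
  cat("Post-hoc pairwise comparisons (", x$structure,
      " variance structure, alpha = ", x$alpha, ")\n\n", sep = "")
  print(x$comparisons)
  cat("\n")
  print(x$letters)
  invisible(x)
}

# insert-and-absorb compact letter display: start from one block holding all
# groups; each significant pair splits every block containing both; absorb
# blocks that are subsets of another; letter blocks in order of group means.
.compact_letters <- function(groups, means, g1, g2, significant) {
  blocks <- list(groups)
  sig <- which(significant)
  for (j in sig) {
    a <- g1[j]; b <- g2[j]
    new_blocks <- list()
    for (blk in blocks) {
      if (a %in% blk && b %in% blk) {
        new_blocks <- c(new_blocks, list(setdiff(blk, a)), list(setdiff(blk, b)))
      } else {
        new_blocks <- c(new_blocks, list(blk))
      }
    }
    keep <- rep(TRUE, length(new_blocks))
    for (i in seq_along(new_blocks)) {
      for (i2 in seq_along(new_blocks)) {
        if (i != i2 && keep[i2] &&
            all(new_blocks[[i]] %in% new_blocks[[i2]]) &&
            (length(new_blocks[[i]]) < length(new_blocks[[i2]]) || i > i2)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    blocks <- new_blocks[keep]
  }
  ord <- order(-means)
  block_rank <- vapply(blocks, function(blk)
    min(match(blk, groups[ord])), numeric(1))
  blocks <- blocks[order(block_rank)]
  lab <- unname(vapply(groups, function(g) {
    paste(letters[which(vapply(blocks, function(blk) g %in% blk, logical(1)))],
          collapse = "")
  }, character(1)))
  tibble(group = groups, mean = means, letter = lab) |>
    arrange(desc(.data$mean))
}
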