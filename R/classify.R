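# Welch's unequal-variance t-test and the leaf-Mn exudation rubric:
#   significantly higher Mn than the negative reference -> the species
#   exudes root carboxylates; similar to or significantly above the
#   positive reference -> strong exudation capacity.

#' Welch's unequal-variance t-test
#'
#' Two-sample t-test without the equal-variance assumption:
#' `t = (mean_x - mean_y) / sqrt(s2_x/n_x + s2_y/n_y)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided Student-t p-value.
#' Degenerate inputs follow fixed conventions instead of erroring: both
#' variances zero with equal means gives `t = 0, p = 1`; both variances zero
#' with unequal means gives an infinite `t`, `p = 0`, and a warning.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
#' @examples
#' welch_t(c(5.1, 4.9, 5.3, 5.0), c(3.2, 3.0, 3.5))
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n_x <- length(x); n_y <- length(y)
  if (n_x < 2 || n_y < 2)
    abort("welch_t needs at least two observations per sample")
  m_x <- mean(x); m_y <- mean(y)
  v_x <- var(x); v_y <- var(y)
  se2 <- v_x / n_x + v_y / n_y
  if (se2 == 0) {
    if (m_x == m_y) {
      t <- 0; df <- n_x + n_y - 2; p <- 1
    } else {
      warn("welch_t: both samples have zero variance and unequal means; t is infinite")
      t <- sign(m_x - m_y) * Inf; df <- n_x + n_y - 2; p <- 0
    }
  } else {
    t <- (m_x - m_y) / sqrt(se2)
    df <- se2^2 / ((v_x / n_x)^2 / (n_x - 1) + (v_y / n_y)^2 / (n_y - 1))
    p <- 2 * pt(-abs(t), df)
  }
  tibble(t = t, df = df, p = p, mean_x = m_x, mean_y = m_y,
         n_x = n_x, n_y = n_y)
}

#' Classify species' carboxylate-exudation status from leaf Mn
#'
#' For every target species x site, runs Welch t-tests of the target leaf Mn
#' replicates against the site's resolved negative and positive reference
#' replicates and applies the rubric:
#' * `exudes`: significantly higher Mn than the negative reference
#'   (two-sided p below `alpha` and a positive mean difference);
#' * `no_evidence`: no significant difference from the negative reference;
#' * `strong_capacity` (additional flag): leaf Mn similar to or
#'   significantly above the positive reference, operationalised as target
#'   mean >= positive-reference mean, or a significant positive difference.
#'
#' No multiple-testing correction is applied by default, mirroring survey
#' practice; `holm = TRUE` applies a Holm correction across calls (separately
#' for the negative- and positive-reference test families). `one_sided =
#' TRUE` uses the one-sided (greater) p-value instead of two-sided +
#' direction.
#'
#' @param samples Leaf-sample tibble.
#' @param refs Resolved references from [resolve_references()].
#' @param alpha Significance level (default 0.05).
#' @param one_sided Use one-sided p-values (default `FALSE`).
#' @param holm Holm-adjust p-values across calls (default `FALSE`).
#' @return A tibble with one row per target species x site: test statistics
#'   against both references, `category` (`exudes`/`no_evidence`),
#'   `strong_capacity`, reference provenances and `alpha`.
#' @export
classify_exudation <- function(samples, refs = resolve_references(samples),
                               alpha = 0.05, one_sided = FALSE, holm = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  targets <- samples |>
    filter(.data$role == "target", !is.na(.data$Mn))
  if (!nrow(targets)) abort("no target samples with Mn values")
  too_few <- targets |>
    count(.data$site_id, .data$species) |>
    filter(.data$n < 2)
  if (nrow(too_few))
    abort(paste0("insufficient replication (<2 Mn replicates) for: ",
                 paste(head(paste(too_few$species, "at", too_few$site_id), 5),
                       collapse = "; ")))
  prov <- refs |>
    distinct(.data$site_id, .data$side, .data$provenance) |>
    tidyr::pivot_wider(names_from = "side", values_from = "provenance") |>
    rename(pos_provenance = "positive", neg_provenance = "negative")
  ref_list <- refs |>
    group_by(.data$site_id, .data$side) |>
    summarise(mn = list(.data$mn), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "mn")

  one_p <- function(t, p) if (t > 0) p / 2 else 1 - p / 2

  calls <- targets |>
    group_by(.data$site_id, .data$species) |>
    summarise(genus = first(.data$genus), mn = list(.data$Mn),
              .groups = "drop") |>
    left_join(ref_list, by = "site_id") |>
    mutate(
      wneg = purrr::map2(.data$mn, .data$negative, welch_t),
      wpos = purrr::map2(.data$mn, .data$positive, welch_t),
      n = lengths(.data$mn),
      target_mean_mn = map_dbl(.data$mn, mean),
      neg_mean = map_dbl(.data$negative, mean),
      pos_mean = map_dbl(.data$positive, mean),
      t_neg = map_dbl(.data$wneg, "t"), df_neg = map_dbl(.data$wneg, "df"),
      p_neg = map_dbl(.data$wneg, "p"),
      t_pos = map_dbl(.data$wpos, "t"), df_pos = map_dbl(.data$wpos, "df"),
      p_pos = map_dbl(.data$wpos, "p"))
  if (one_sided) {
    calls <- calls |>
      mutate(p_neg = purrr::map2_dbl(.data$t_neg, .data$p_neg, one_p),
             p_pos = purrr::map2_dbl(.data$t_pos, .data$p_pos, one_p))
  }
  p_neg_use <- if (holm) stats::p.adjust(calls$p_neg, "holm") else calls$p_neg
  p_pos_use <- if (holm) stats::p.adjust(calls$p_pos, "holm") else calls$p_pos
  dir_neg <- calls$target_mean_mn > calls$neg_mean
  dir_pos <- calls$target_mean_mn > calls$pos_mean
  sig_neg <- if (one_sided) p_neg_use < alpha else p_neg_use < alpha & dir_neg
  sig_pos <- if (one_sided) p_pos_use < alpha else p_pos_use < alpha & dir_pos
  calls |>
    mutate(category = ifelse(sig_neg, "exudes", "no_evidence"),
           strong_capacity = .data$target_mean_mn >= .data$pos_mean | sig_pos,
           alpha = alpha) |>
    left_join(prov, by = "site_id") |>
    select("site_id", "species", "genus", "n", "target_mean_mn",
           "neg_mean", "pos_mean", "t_neg", "df_neg", "p_neg",
           "t_pos", "df_pos", "p_pos", "category", "strong_capacity",
           "alpha", "pos_provenance", "neg_provenance") |>
    arrange(.data$site_id, .data$species)
}

#' Summarise exudation calls per species or per genus
#'
#' Per-site calls are primary; a species sampled at several sites counts
#' once in summaries, as exuding (or strong-capacity) if any site-level call
#' is positive.
#'
#' @param calls Output of [classify_exudation()].
#' @param by `"genus"` (default) for per-genus counts and percentages, or
#'   `"species"` for the deduplicated per-species table.
#' @return A tibble.
#' @export
summarize_exudation <- function(calls, by = c("genus", "species")) {
  by <- match.arg(by)
  species_tab <- calls |>
    group_by(.data$genus, .data$species) |>
    summarise(n_sites = n(),
              exudes = any(.data$category == "exudes"),
              strong_capacity = any(.data$strong_capacity),
              .groups = "drop") |>
    arrange(.data$genus, .data$species)
  if (by == "species") return(species_tab)
  species_tab |>
    group_by(.data$genus) |>
    summarise(n_species = n(),
              n_exudes = sum(.data$exudes),
              pct_exudes = 100 * mean(.data$exudes),
              n_strong = sum(.data$strong_capacity),
              pct_strong = 100 * mean(.data$strong_capacity),
              .groups = "drop")
}
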