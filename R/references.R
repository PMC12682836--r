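# Per-site resolution of positive/negative reference species and the
# reference-normalised relative leaf-Mn score.
#
# The proxy logic: carboxylate-releasing neighbours (e.g. cluster-rooted
# Proteaceae) anchor the high end of the site's leaf-Mn scale, non-releasers
# (e.g. Xanthorrhoea) the low end. A target species is placed on that scale.

#' Resolve positive and negative reference samples per site
#'
#' Applies the survey fallback rules. For each site and side
#' (positive/negative):
#' * one observed reference species -> its replicates, provenance `observed`;
#' * two or more observed reference species -> pooled, provenance `grouped`
#'   (the "PG"/"NG" case);
#' * no observed reference at the site -> the cross-site average reference
#'   (provenance `site_average`, "APR"/"ANR"): one pseudo-replicate per other
#'   site, equal to that site's observed reference mean, so downstream Welch
#'   tests remain defined;
#' * a negative reference supplied as young leaves of a target taxon
#'   (`leaf_age == "young"`) is flagged with provenance `young_leaf`.
#'
#' @param samples Leaf-sample tibble as returned by [read_leaf_table()] (or
#'   [gen_survey()]); rows with `role` `positive_ref`/`negative_ref` are the
#'   observed references.
#' @return A tibble with one row per reference replicate: `site_id`, `side`
#'   (`"positive"`/`"negative"`), `species`, `mn`, `provenance`.
#' @export
resolve_references <- function(samples) {
  stopifnot(all(c("site_id", "species", "role", "Mn") %in% names(samples)))
  if (!"leaf_age" %in% names(samples)) samples$leaf_age <- "mature"
  sites <- sort(unique(samples$site_id))

  one_side <- function(role_name, side) {
    obs <- samples |>
      filter(.data$role == role_name, !is.na(.data$Mn)) |>
      arrange(.data$site_id, .data$species, .data$replicate)
    if (!nrow(obs))
      abort(paste0("unresolvable references: no ", side,
                   " reference samples observed at any site"))
    site_means <- obs |>
      group_by(.data$site_id) |>
      summarise(mn = mean(.data$Mn), .groups = "drop")
    purrr::map(sites, function(s) {
      here <- obs |> filter(.data$site_id == s)
      if (nrow(here)) {
        prov <- if (side == "negative" && all(here$leaf_age == "young")) {
          "young_leaf"
        } else if (n_distinct(here$species) > 1) "grouped" else "observed"
        tibble(site_id = s, side = side, species = here$species,
               mn = here$Mn, provenance = prov)
      } else {
        others <- site_means |> filter(.data$site_id != s)
        if (!nrow(others))
          abort(paste0("unresolvable references: site ", s, " has no ", side,
                       " reference and no other site provides one"))
        tibble(site_id = s, side = side,
               species = if (side == "positive") "APR" else "ANR",
               mn = others$mn, provenance = "site_average")
      }
    }) |> list_rbind()
  }

  bind_rows(one_side("positive_ref", "positive"),
            one_side("negative_ref", "negative")) |>
    arrange(.data$site_id, .data$side, .data$species)
}

#' Relative leaf manganese score
#'
#' Places a target species' mean leaf Mn on a linear 0-100 % scale between
#' the site's negative (0 %) and positive (100 %) reference means:
#' `100 * (target - negative) / (positive - negative)`. Values below 0 or
#' above 100 are meaningful (below the non-releaser baseline / above the
#' known releaser). Unit-free: invariant under common rescaling.
#'
#' @param target_mean,neg_mean,pos_mean Mean leaf Mn (mg kg⁻¹); vectorised.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' relative_mn(550, 100, 400) # 150
relative_mn <- function(target_mean, neg_mean, pos_mean) {
  degenerate <- abs(pos_mean - neg_mean) <
    1e-9 * pmax(abs(pos_mean), abs(neg_mean), 1)
  if (any(degenerate, na.rm = TRUE))
    abort(paste0("degenerate references: positive and negative reference ",
                 "means coincide; relative Mn is undefined"))
  100 * (target_mean - neg_mean) / (pos_mean - neg_mean)
}

#' Per-species reference-normalised Mn scores
#'
#' For every target species x site, computes the species-mean leaf Mn, the
#' differences to the negative and positive reference means, and the
#' relative Mn score ([relative_mn()]). Sites whose reference means coincide
#' (degenerate scale) are flagged, reported with `relative_mn = NA`, and a
#' warning is raised rather than dropping them.
#'
#' @param samples Leaf-sample tibble.
#' @param refs Resolved references from [resolve_references()].
#' @return A tibble with one row per target species x site: `site_id`,
#'   `species`, `genus`, `n`, `target_mean_mn`, `neg_mean`, `pos_mean`,
#'   `diff_vs_negative`, `diff_vs_positive`, `relative_mn`,
#'   `pos_provenance`, `neg_provenance`, `degenerate`.
#' @export
mn_scores <- function(samples, refs = resolve_references(samples)) {
  ref_summ <- refs |>
    group_by(.data$site_id, .data$side) |>
    summarise(mean = mean(.data$mn), provenance = .data$provenance[1],
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("mean", "provenance"))
  targets <- samples |>
    filter(.data$role == "target", !is.na(.data$Mn)) |>
    group_by(.data$site_id, .data$species) |>
    summarise(genus = first(.data$genus), n = n(),
              target_mean_mn = mean(.data$Mn), .groups = "drop")
  if (!nrow(targets)) abort("no target samples with Mn values")
  out <- targets |>
    left_join(ref_summ, by = "site_id") |>
    mutate(neg_mean = .data$mean_negative, pos_mean = .data$mean_positive,
           diff_vs_negative = .data$target_mean_mn - .data$neg_mean,
           diff_vs_positive = .data$target_mean_mn - .data$pos_mean,
           degenerate = abs(.data$pos_mean - .data$neg_mean) <
             1e-9 * pmax(abs(.data$pos_mean), abs(.data$neg_mean), 1),
           relative_mn = ifelse(.data$degenerate, NA_real_,
                                100 * .data$diff_vs_negative /
                                  (.data$pos_mean - .data$neg_mean)),
           pos_provenance = .data$provenance_positive,
           neg_provenance = .data$provenance_negative) |>
    select("site_id", "species", "genus", "n", "target_mean_mn",
           "neg_mean", "pos_mean", "diff_vs_negative", "diff_vs_positive",
           "relative_mn", "pos_provenance", "neg_provenance", "degenerate") |>
    arrange(.data$site_id, .data$species)
  if (any(out$degenerate))
    warn(paste0("degenerate references (positive mean == negative mean) at ",
                "site(s): ",
                paste(unique(out$site_id[out$degenerate]), collapse = ", "),
                "; relative_mn reported as NA"))
  out
}
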