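# Synthetic survey / tree / trait / tip-rate generators with known ground
# truth, so every pipeline stage can be validated end to end.
#
# The default survey emulates the field design the package targets: 18
# sites in three regions, 1-6 target species per site, 5 replicate
# individuals, one positive (Proteaceae-like, ~300 mg Mn kg^-1) and one
# negative (Xanthorrhoea-like, ~40 mg Mn kg^-1) reference species per site
# with 2 sites lacking the positive and 4 lacking the negative reference
# (exercising the cross-site APR/ANR fallback), lognormal within-species
# variation, multiplicative site effects, strong exuders near 1000
# mg Mn kg^-1, and leaf N/P drawn with a log-scale correlation of 0.8
# around 10.6 mg N g^-1 and 0.4 mg P g^-1.

#' Configuration for the synthetic leaf-Mn survey
#'
#' @param n_sites Number of sites.
#' @param species_per_site Integer range (vector) of target species per site.
#' @param replicates Replicate individuals per species per site (>= 2).
#' @param exuder_fraction Fraction of target species that truly exude.
#' @param mn_neg_meanlog,mn_pos_meanlog,mn_exuder_meanlog Log-scale mean
#'   leaf Mn of negative references, positive references, and exuding
#'   targets (non-exuders share the negative baseline).
#' @param sdlog Within-species replicate lognormal sd (log scale).
#' @param site_effect_sd Sd of the multiplicative site effect (log scale).
#' @param missing_pos_ref_sites,missing_neg_ref_sites Number of sites
#'   emitted without the respective reference species.
#' @param n_meanlog,p_meanlog,np_sdlog,np_corr Log-scale mean of leaf N and
#'   P, their common sd, and their correlation.
#' @param seed Master seed; one RNG stream per artifact is derived from it.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n_sites = 18, species_per_site = 1:6,
                          replicates = 5, exuder_fraction = 0.8,
                          mn_neg_meanlog = log(40),
                          mn_pos_meanlog = log(300),
                          mn_exuder_meanlog = log(1000),
                          sdlog = 0.3, site_effect_sd = 0.3,
                          missing_pos_ref_sites = 2,
                          missing_neg_ref_sites = 4,
                          n_meanlog = log(10.6), p_meanlog = log(0.4),
                          np_sdlog = 0.25, np_corr = 0.8,
                          seed = 1) {
  stopifnot(replicates >= 2, exuder_fraction >= 0, exuder_fraction <= 1,
            n_sites >= 1, all(species_per_site >= 1),
            missing_pos_ref_sites < n_sites,
            missing_neg_ref_sites < n_sites)
  structure(as.list(environment()), class = "survey_config")
}

# independent sub-seeds per artifact so adding a stage never perturbs
# earlier output streams
.stream_seeds <- function(seed, n) {
  force(seed)   # evaluate caller expressions (possibly random) before saving state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic leaf-Mn survey with known ground truth
#'
#' Draws a species pool (four genera, exuder status assigned at the
#' configured fraction), assigns species to sites, and generates replicate
#' leaf chemistry: lognormal Mn around the role-specific baseline times a
#' lognormal site effect, leaf N and P bivariate-lognormal with the
#' configured correlation, remaining elements lognormal at field-realistic
#' scales. Designated sites are emitted without their positive/negative
#' reference rows to exercise the cross-site average fallback. A soil table
#' (5 sampling locations per site, acidic pH, low Olsen P) accompanies the
#' leaf table.
#'
#' @param config A [survey_config()].
#' @return A list: `leaf` (sample tibble in the canonical layout), `soil`,
#'   and `truth` (`$species` with true exuder flags, `$sites` with
#'   reference availability and site effects, `$config`).
#' @export
gen_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  seeds <- .stream_seeds(config$seed, 4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # --- stream 1: design (species pool, site assignment, ref availability)
  set.seed(seeds[1])
  n_sites <- config$n_sites
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  region_pool <- c("BlueMountains", "Coastal", "WesternSydney")
  regions <- region_pool[1 + (seq_len(n_sites) - 1) %% 3]

  genus_pool <- c(rep("Eucalyptus", 22), rep("Angophora", 6),
                  "Corymbia", "Blakella")
  n_pool <- length(genus_pool)
  species_pool <- tibble(
    species = sprintf("%s_sp%02d", genus_pool, seq_len(n_pool)),
    genus = genus_pool,
    exuder = runif(n_pool) < config$exuder_fraction)

  site_species <- purrr::map(seq_len(n_sites), function(s) {
    n_sp <- if (length(config$species_per_site) == 1) config$species_per_site
            else sample(config$species_per_site, 1)
    n_sp <- min(n_sp, n_pool)
    tibble(site_id = site_ids[s], region = regions[s],
           species = sample(species_pool$species, n_sp))
  }) |> list_rbind() |>
    left_join(species_pool, by = "species")

  no_pos <- if (config$missing_pos_ref_sites > 0)
    sample(site_ids, config$missing_pos_ref_sites) else character()
  no_neg <- if (config$missing_neg_ref_sites > 0)
    sample(setdiff(site_ids, no_pos), config$missing_neg_ref_sites)
    else character()
  site_effect <- setNames(rnorm(n_sites, 0, config$site_effect_sd), site_ids)

  # --- stream 2: leaf chemistry
  set.seed(seeds[2])
  rep_n <- config$replicates
  design <- bind_rows(
    site_species |> mutate(role = "target",
                           meanlog = ifelse(.data$exuder,
                                            config$mn_exuder_meanlog,
                                            config$mn_neg_meanlog)),
    tibble(site_id = site_ids, region = regions,
           species = "Banksia_ref", genus = "Banksia",
           exuder = TRUE, role = "positive_ref",
           meanlog = config$mn_pos_meanlog) |>
      filter(!.data$site_id %in% no_pos),
    tibble(site_id = site_ids, region = regions,
           species = "Xanthorrhoea_ref", genus = "Xanthorrhoea",
           exuder = FALSE, role = "negative_ref",
           meanlog = config$mn_neg_meanlog) |>
      filter(!.data$site_id %in% no_neg)) |>
    arrange(.data$site_id, .data$role, .data$species)

  leaf <- design[rep(seq_len(nrow(design)), each = rep_n), ] |>
    group_by(.data$site_id, .data$species) |>
    mutate(replicate = row_number()) |>
    ungroup()
  n_row <- nrow(leaf)
  leaf$Mn <- rlnorm(n_row,
                    leaf$meanlog + site_effect[leaf$site_id],
                    config$sdlog)
  # leaf N and P: bivariate normal on the log scale, correlation np_corr
  z1 <- rnorm(n_row); z2 <- rnorm(n_row)
  zN <- z1
  zP <- config$np_corr * z1 + sqrt(1 - config$np_corr^2) * z2
  fert <- rnorm(n_sites, 0, 0.1)[match(leaf$site_id, site_ids)]
  leaf$N <- exp(config$n_meanlog + fert + config$np_sdlog * zN)
  leaf$P <- exp(config$p_meanlog + fert + config$np_sdlog * zP)
  leaf$K <- rlnorm(n_row, log(5000), 0.25)
  leaf$Ca <- rlnorm(n_row, log(4000), 0.3)
  leaf$Mg <- rlnorm(n_row, log(1500), 0.25)
  leaf$Fe <- exp(log(60) + 0.4 * (log(leaf$Mn) - mean(log(leaf$Mn))) +
                   rnorm(n_row, 0, 0.2))
  leaf$Zn <- rlnorm(n_row, log(15), 0.3)
  leaf$Cu <- rlnorm(n_row, log(5), 0.3)
  leaf$leaf_age <- "mature"

  leaf_out <- leaf |>
    select("site_id", "region", "species", "genus", "role", "replicate",
           "leaf_age", "N", "P", "K", "Ca", "Cu", "Zn", "Mn", "Fe", "Mg")

  # --- stream 3: soil chemistry (5 sampling locations per site)
  set.seed(seeds[3])
  soil <- tibble(site_id = rep(site_ids, each = 5),
                 region = rep(regions, each = 5),
                 location = rep(1:5, n_sites)) |>
    mutate(pH_cacl2 = runif(n(), 3.4, 4.9),
           pH_water = .data$pH_cacl2 + runif(n(), 0.5, 0.8),
           ec = rlnorm(n(), log(30), 0.4),
           olsen_p = rlnorm(n(), log(2), 0.4),
           water_p = .data$olsen_p * runif(n(), 0.3, 0.5),
           total_P = rlnorm(n(), log(50), 0.6),
           total_Mn = rlnorm(n(), log(15), 0.8),
           total_Fe = rlnorm(n(), log(5000), 0.5),
           total_Ca = rlnorm(n(), log(300), 0.5),
           total_Mg = rlnorm(n(), log(200), 0.4),
           total_K = rlnorm(n(), log(400), 0.4),
           total_Cu = rlnorm(n(), log(3), 0.4),
           total_Zn = rlnorm(n(), log(8), 0.4))

  truth <- list(
    species = species_pool,
    sites = tibble(site_id = site_ids, region = regions,
                   has_pos_ref = !site_ids %in% no_pos,
                   has_neg_ref = !site_ids %in% no_neg,
                   site_effect = unname(site_effect[site_ids])),
    config = config)
  list(leaf = leaf_out, soil = soil, truth = truth)
}

#' Generate a Yule tree with a Brownian trait and trait-linked tip rates
#'
#' Simulates a pure-birth (Yule) tree, evolves a continuous trait along it
#' by root-to-tip Brownian accumulation (variance `bm_sigma2` per unit
#' branch length, root state 0), and draws per-tip speciation rates with
#' `log(rate) = rate_intercept + rate_slope * trait + N(0, rate_noise_sd)`,
#' so the tip-rate--trait correlation has known direction and strength.
#'
#' @param n_tips Number of tips (>= 4).
#' @param birth_rate Speciation rate of the Yule process.
#' @param bm_sigma2 Brownian-motion variance per unit branch length
#'   (0 gives a constant trait, the documented degenerate case).
#' @param rate_slope True slope linking the trait to log tip rate.
#' @param rate_noise_sd Sd of the log-rate noise.
#' @param rate_intercept Intercept of the log tip rate (default `log(0.2)`
#'   events Myr⁻¹).
#' @param seed Master seed.
#' @return A list: `tree` (`phylo`), `traits` (tibble `tip`, `value`),
#'   `rates` (tibble `tip`, `rate`), `truth`.
#' @export
gen_tree_traits_rates <- function(n_tips, birth_rate = 1, bm_sigma2 = 1,
                                  rate_slope = 0, rate_noise_sd = 0.5,
                                  rate_intercept = log(0.2), seed = 1) {
  stopifnot(n_tips >= 4, birth_rate > 0, bm_sigma2 >= 0, rate_noise_sd >= 0)
  seeds <- .stream_seeds(seed, 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(seeds[1])
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("t%03d", seq_len(n_tips))

  set.seed(seeds[2])
  traits_all <- sim_bm(tree, sigma2 = bm_sigma2, root_state = 0)
  traits <- tibble(tip = tree$tip.label,
                   value = traits_all[seq_len(n_tips)])

  set.seed(seeds[3])
  log_rate <- rate_intercept + rate_slope * traits$value +
    rnorm(n_tips, 0, rate_noise_sd)
  rates <- tibble(tip = tree$tip.label, rate = exp(log_rate))

  list(tree = tree, traits = traits, rates = rates,
       truth = list(bm_sigma2 = bm_sigma2, rate_slope = rate_slope,
                    rate_intercept = rate_intercept, root_state = 0,
                    birth_rate = birth_rate, seed = seed))
}

#' Simulate Brownian motion along a tree
#'
#' Root-to-tip accumulation: each node's state is its parent's state plus a
#' normal increment with variance `sigma2 * branch length`.
#'
#' @param tree A rooted `phylo`.
#' @param sigma2 Variance per unit branch length.
#' @param root_state State at the root.
#' @return Named numeric vector of states for all nodes (tips first, ape
#'   numbering).
#' @export
sim_bm <- function(tree, sigma2 = 1, root_state = 0) {
  n_node <- max(tree$edge)
  n_tip <- length(tree$tip.label)
  states <- numeric(n_node)
  states[n_tip + 1L] <- root_state
  ord <- ape::reorder.phylo(tree, "cladewise")
  inc <- rnorm(nrow(ord$edge), 0, sqrt(sigma2 * ord$edge.length))
  for (i in seq_len(nrow(ord$edge)))
    states[ord$edge[i, 2]] <- states[ord$edge[i, 1]] + inc[i]
  names(states) <- c(tree$tip.label, rep(NA, n_node - n_tip))
  states
}

#' Write the synthetic survey artifacts to plain-text files
#'
#' Writes `leaf.csv`, `soil.csv` and, when tree/trait/rate artifacts are
#' supplied, `tree.nwk`, `traits.csv`, `rates.csv`, into `dir`. Same
#' config/seed gives byte-identical files.
#'
#' @param survey Output of [gen_survey()].
#' @param dir Output directory (created if needed).
#' @param phylo Optional output of [gen_tree_traits_rates()].
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir, phylo = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(survey$leaf, file.path(dir, "leaf.csv"))
  readr::write_csv(survey$soil, file.path(dir, "soil.csv"))
  if (!is.null(phylo)) {
    write_newick(phylo$tree, file.path(dir, "tree.nwk"))
    readr::write_csv(phylo$traits, file.path(dir, "traits.csv"))
    readr::write_csv(phylo$rates, file.path(dir, "rates.csv"))
  }
  invisible(dir)
}
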