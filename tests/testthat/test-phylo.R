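test_that("phylogenetic covariance matches hand values and the brute-force oracle", {
  # star tree: no shared history, identity-like covariance
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(phylo_vcv(star), diag(4), ignore_attr = TRUE)

  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(phylo_vcv(tr),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

  set.seed(91)
  for (i in 1:25) {
    tree <- random_tree(sample(4:20, 1))
    expect_equal(phylo_vcv(tree), oracle_vcv(tree), tolerance = 1e-12)
  }
})

test_that("unrooted trees are rejected by phylo_vcv", {
  tr <- ape::unroot(random_tree(6))
  expect_error(phylo_vcv(tr), "rooted")
})

test_that("Blomberg's K equals the arithmetic oracle on a 4-tip tree", {
  tr <- read_newick("((A:1,B:1):2,(C:2,D:2):1);")
  y <- c(A = 1.2, B = 0.8, C = 3.1, D = 2.7)
  traits <- tibble::tibble(tip = names(y), value = unname(y))
  res <- blomberg_k(traits, tr, n_perm = 0)
  k_oracle <- oracle_k(oracle_vcv(tr), y[tr$tip.label])
  expect_equal(res$k, k_oracle, tolerance = 1e-10)
})

test_that("Blomberg's K agrees with phytools::phylosig", {
  skip_if_not_installed("phytools")
  set.seed(92)
  for (i in 1:5) {
    g <- gen_tree_traits_rates(25, seed = 92 + i)
    res <- blomberg_k(g$traits, g$tree, n_perm = 0)
    ref <- phytools::phylosig(g$tree, setNames(g$traits$value, g$traits$tip),
                              method = "K")
    expect_equal(res$k, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("K is invariant to affine trait transforms", {
  g <- gen_tree_traits_rates(20, seed = 93)
  k1 <- blomberg_k(g$traits, g$tree, n_perm = 0)$k
  shifted <- dplyr::mutate(g$traits, value = -2.5 * value + 7)
  k2 <- blomberg_k(shifted, g$tree, n_perm = 0)$k
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("K permutation p is seed-reproducible and correctly bounded", {
  g <- gen_tree_traits_rates(15, seed = 94)
  r1 <- blomberg_k(g$traits, g$tree, n_perm = 199, seed = 5)
  r2 <- blomberg_k(g$traits, g$tree, n_perm = 199, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
  expect_lte(r1$p, 1)
})

test_that("K errors on constant traits and missing tips", {
  g <- gen_tree_traits_rates(10, bm_sigma2 = 0, seed = 95)
  expect_error(blomberg_k(g$traits, g$tree, n_perm = 0), "constant trait")
  incomplete <- g$traits[-1, ]
  expect_error(blomberg_k(incomplete, g$tree, n_perm = 0), "no imputation")
})

test_that("white-noise traits on a deep tree give K below 1", {
  set.seed(96)
  ks <- replicate(40, {
    g <- gen_tree_traits_rates(40, seed = sample.int(1e6, 1))
    shuffled <- dplyr::mutate(g$traits, value = sample(value))
    blomberg_k(shuffled, g$tree, n_perm = 0)$k
  })
  expect_lt(median(ks), 1)
})

test_that("ancestral states: constant trait, 2-tip closed form, MVN oracle", {
  # constant trait reconstructs the constant everywhere
  tr <- read_newick("((A:1,B:1):1,C:2);")
  traits <- tibble::tibble(tip = c("A", "B", "C"), value = 5)
  a <- asr_ml(traits, tr)
  expect_equal(a$states$state, rep(5, 5))

  # 2-tip closed form: inverse-branch-length weighted mean
  tr2 <- read_newick("(A:2,B:0.5);")
  t2 <- tibble::tibble(tip = c("A", "B"), value = c(4, 1))
  a2 <- asr_ml(t2, tr2)
  expect_equal(a2$root_state, (4 / 2 + 1 / 0.5) / (1 / 2 + 1 / 0.5))

  # MVN conditional-mean oracle on a simulated 6-tip tree: the covariance of
  # (tips, internal node) under BM is the shared-path matrix; the BLUP of the
  # node given tips (with grand mean a) is a + C V^-1 (y - a)
  g <- gen_tree_traits_rates(6, seed = 97)
  tree <- g$tree
  y <- setNames(g$traits$value, g$traits$tip)[tree$tip.label]
  V <- oracle_vcv(tree)
  res <- asr_ml(g$traits, tree)
  # oracle via phytools::fastAnc (independent GLS implementation)
  skip_if_not_installed("phytools")
  ref <- phytools::fastAnc(tree, y)
  mine <- res$states$state[!res$states$is_tip]
  expect_equal(mine, as.numeric(ref), tolerance = 1e-8)
  # root equals the phylogenetic mean from the K machinery
  Vinv <- solve(V)
  a_hat <- sum(Vinv %*% y) / sum(Vinv)
  expect_equal(res$root_state, a_hat, tolerance = 1e-10)
})

test_that("zero-length cherry is handled with the documented perturbation", {
  tr <- read_newick("((A:0,B:0):1,C:2);")
  traits <- tibble::tibble(tip = c("A", "B", "C"), value = c(1, 2, 9))
  expect_warning(a <- asr_ml(traits, tr), "singular")
  expect_true(all(is.finite(a$states$state)))
})

test_that("PGLS equals OLS on a star tree and recovers exact fits", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  set.seed(98)
  d <- tibble::tibble(tip = star$tip.label, x = rnorm(5), y = rnorm(5))
  fit <- pgls(d, star, y ~ x)
  ols <- lm(y ~ x, data = d)
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(tidy(fit)$p.value,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-10)

  # exact linear relation: slope/intercept recovered, zero residual variance
  g <- gen_tree_traits_rates(12, seed = 99)
  d2 <- tibble::tibble(tip = g$traits$tip, x = g$traits$value,
                       y = 3 * g$traits$value + 1)
  fit2 <- pgls(d2, g$tree, y ~ x)
  expect_equal(tidy(fit2)$estimate, c(1, 3), tolerance = 1e-8)
  expect_equal(fit2$sigma2, 0, tolerance = 1e-12)
})

test_that("PGLS matches the hand-evaluated GLS formula on a 3-tip tree", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  d <- tibble::tibble(tip = c("A", "B", "C"), x = c(0, 1, 2),
                      y = c(0.2, 1.1, 1.9))
  fit <- pgls(d, tr, y ~ x)
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  X <- cbind(1, d$x); Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  expect_equal(tidy(fit)$estimate, drop(beta), tolerance = 1e-12)
})

test_that("PGLS agrees with nlme::gls under Brownian correlation", {
  set.seed(100)
  g <- gen_tree_traits_rates(20, seed = 101)
  d <- data.frame(tip = g$traits$tip, x = g$traits$value,
                  y = 0.5 * g$traits$value + rnorm(20))
  fit <- pgls(tibble::as_tibble(d), g$tree, y ~ x)
  rownames(d) <- d$tip
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, g$tree, form = ~tip))
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-6)
  ref_t <- summary(ref)$tTable
  expect_equal(tidy(fit)$p.value, unname(ref_t[, "p-value"]), tolerance = 1e-5)
})

test_that("collinear PGLS designs are rejected", {
  g <- gen_tree_traits_rates(8, seed = 102)
  d <- tibble::tibble(tip = g$traits$tip, x = 1, y = g$traits$value)
  expect_error(pgls(d, g$tree, y ~ x), "collinear")
})

test_that("Spearman: monotone relations give rho of +/-1", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_test(x, x^3)$rho, 1)
  expect_equal(spearman_test(x, -sqrt(x))$rho, -1)
})

test_that("Spearman exact p matches full enumeration at n = 6 with a tie", {
  x <- c(1.1, 2.3, 2.3, 4.0, 5.2, 6.1)   # one tie in x
  y <- c(2.0, 1.0, 3.5, 4.1, 6.0, 5.5)
  res <- spearman_test(x, y)
  expect_equal(res$method, "exact")
  # independent enumeration over all 720 pairings
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- gtools_style_perms <- NULL
  all_p <- combinat_perms <- NULL
  idx <- seq_len(6)
  perm_list <- list()
  gen <- function(v, acc) {
    if (!length(v)) {
      perm_list[[length(perm_list) + 1]] <<- acc
    } else {
      for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
  }
  gen(idx, integer(0))
  rho_null <- vapply(perm_list, function(p) cor(rx[p], ry), numeric(1))
  p_oracle <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  expect_equal(res$rho, rho_obs, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
})

test_that("Spearman asymptotic branch matches cor.test for larger n", {
  set.seed(103)
  x <- rnorm(30); y <- x + rnorm(30)
  res <- spearman_test(x, y)
  expect_equal(res$method, "asymptotic")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("tip-rate tests recover monotone links and reject tied rates", {
  g <- gen_tree_traits_rates(12, seed = 104)
  # rates strictly increasing with the trait
  rates_up <- tibble::tibble(tip = g$traits$tip,
                             rate = exp(g$traits$value))
  up <- tip_rate_tests(rates_up, g$traits, g$tree, transform_trait = "none")
  expect_equal(up$rho, 1)
  rates_down <- tibble::tibble(tip = g$traits$tip,
                               rate = exp(-g$traits$value))
  down <- tip_rate_tests(rates_down, g$traits, g$tree,
                         transform_trait = "none")
  expect_equal(down$rho, -1)

  tied <- tibble::tibble(tip = g$traits$tip, rate = 0.2)
  expect_error(tip_rate_tests(tied, g$traits, g$tree,
                              transform_trait = "none"), "tied")
})
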