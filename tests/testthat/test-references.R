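# Building block for the tests below: a minimal hand-laid survey
make_samples <- function() {
  tibble::tibble(
    site_id = c(rep("S1", 9), rep("S2", 6), rep("S3", 4)),
    region = "R",
    species = c(rep("Euc_a", 3), rep("Banksia_b", 3), rep("Xanth_c", 3),
                rep("Euc_a", 3), rep("Banksia_b", 3),
                rep("Euc_d", 2), rep("Banksia_e", 2)),
    genus = c(rep("Eucalyptus", 3), rep("Banksia", 3), rep("Xanthorrhoea", 3),
              rep("Eucalyptus", 3), rep("Banksia", 3),
              rep("Eucalyptus", 2), rep("Banksia", 2)),
    role = c(rep("target", 3), rep("positive_ref", 3), rep("negative_ref", 3),
             rep("target", 3), rep("positive_ref", 3),
             rep("target", 2), rep("positive_ref", 2)),
    replicate = c(1:3, 1:3, 1:3, 1:3, 1:3, 1:2, 1:2),
    leaf_age = "mature",
    Mn = c(250, 260, 240,   400, 410, 390,   40, 42, 38,
           500, 520, 480,   300, 310, 290,
           100, 110,        200, 210))
}

test_that("observed references are used directly with provenance recorded", {
  refs <- resolve_references(make_samples())
  s1_pos <- dplyr::filter(refs, site_id == "S1", side == "positive")
  expect_equal(sort(s1_pos$mn), c(390, 400, 410))
  expect_equal(unique(s1_pos$provenance), "observed")
  expect_true(all(s1_pos$species == "Banksia_b"))
})

test_that("missing references fall back to cross-site averages (APR/ANR)", {
  refs <- resolve_references(make_samples())
  # S2 and S3 have no negative reference; only S1 observes one (mean 40)
  s2_neg <- dplyr::filter(refs, site_id == "S2", side == "negative")
  expect_equal(unique(s2_neg$provenance), "site_average")
  expect_equal(s2_neg$mn, 40)          # one pseudo-replicate per other site
  expect_equal(unique(s2_neg$species), "ANR")

  # constructed positive-ref fallback: two other sites with means 200, 400
  sm <- tibble::tibble(
    site_id = c("A", "A", "B", "B", "C", "C", "C"),
    species = c("P1", "P1", "P2", "P2", "T", "T", "N1"),
    genus = "G",
    role = c("positive_ref", "positive_ref", "positive_ref", "positive_ref",
             "target", "target", "negative_ref"),
    replicate = c(1, 2, 1, 2, 1, 2, 1),
    Mn = c(150, 250, 350, 450, 100, 120, 30))
  refs2 <- resolve_references(sm)
  c_pos <- dplyr::filter(refs2, site_id == "C", side == "positive")
  expect_equal(sort(c_pos$mn), c(200, 400))
  expect_equal(mean(c_pos$mn), 300)
  expect_equal(unique(c_pos$provenance), "site_average")
})

test_that("two reference species at one site are pooled as grouped", {
  sm <- make_samples()
  extra <- dplyr::mutate(
    dplyr::filter(sm, site_id == "S1", role == "negative_ref"),
    species = "Acacia_x", Mn = Mn + 5)
  refs <- resolve_references(dplyr::bind_rows(sm, extra))
  s1_neg <- dplyr::filter(refs, site_id == "S1", side == "negative")
  expect_equal(nrow(s1_neg), 6)
  expect_equal(unique(s1_neg$provenance), "grouped")
})

test_that("young-leaf negative references are flagged", {
  sm <- make_samples()
  sm$leaf_age[sm$site_id == "S1" & sm$role == "negative_ref"] <- "young"
  refs <- resolve_references(sm)
  s1_neg <- dplyr::filter(refs, site_id == "S1", side == "negative")
  expect_equal(unique(s1_neg$provenance), "young_leaf")
})

test_that("resolution errors when a side is observed nowhere", {
  sm <- dplyr::filter(make_samples(), role != "negative_ref")
  expect_error(resolve_references(sm), "unresolvable")
})

test_that("resolution is deterministic under row shuffling", {
  sm <- make_samples()
  set.seed(99)
  shuffled <- sm[sample(nrow(sm)), ]
  expect_identical(resolve_references(sm), resolve_references(shuffled))
})

test_that("relative Mn identities, arithmetic and degenerate guard", {
  expect_equal(relative_mn(100, 100, 400), 0)
  expect_equal(relative_mn(400, 100, 400), 100)
  expect_equal(relative_mn(550, 100, 400), 150)
  expect_error(relative_mn(100, 200, 200), "degenerate")
})

test_that("relative Mn is affine in the target and scale-invariant", {
  set.seed(5)
  for (i in 1:50) {
    neg <- runif(1, 10, 100)
    pos <- neg + runif(1, 10, 500)
    f <- runif(1, -2, 3)
    target <- neg + f * (pos - neg)
    expect_equal(relative_mn(target, neg, pos), 100 * f, tolerance = 1e-10)
    s <- runif(1, 0.001, 1000)   # common rescaling: units cancel
    expect_equal(relative_mn(s * target, s * neg, s * pos), 100 * f,
                 tolerance = 1e-9)
  }
})

test_that("per-species Mn scores carry differences and relative scores", {
  sm <- tibble::tibble(
    site_id = "S1", region = "R",
    species = c(rep("T1", 2), rep("P1", 2), rep("N1", 2)),
    genus = "G",
    role = c("target", "target", "positive_ref", "positive_ref",
             "negative_ref", "negative_ref"),
    replicate = rep(1:2, 3),
    Mn = c(240, 260, 390, 410, 90, 110))
  sc <- mn_scores(sm)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$target_mean_mn, 250)
  expect_equal(sc$diff_vs_negative, 150)
  expect_equal(sc$diff_vs_positive, -150)
  expect_equal(sc$relative_mn, 50)

  # target equal to the negative mean scores zero
  sm0 <- dplyr::mutate(sm, Mn = ifelse(role == "target", 100, Mn))
  expect_equal(mn_scores(sm0)$relative_mn, 0)

  # two targets at one site give two rows
  sm2 <- dplyr::bind_rows(
    sm, dplyr::mutate(dplyr::filter(sm, role == "target"), species = "T2"))
  expect_equal(nrow(mn_scores(sm2)), 2)
})

test_that("degenerate reference scale is flagged, not dropped", {
  sm <- tibble::tibble(
    site_id = "S1",
    species = c(rep("T1", 2), rep("P1", 2), rep("N1", 2)),
    genus = "G",
    role = c("target", "target", "positive_ref", "positive_ref",
             "negative_ref", "negative_ref"),
    replicate = rep(1:2, 3),
    Mn = c(240, 260, 100, 100, 100, 100))
  expect_warning(sc <- mn_scores(sm), "degenerate")
  expect_equal(nrow(sc), 1)
  expect_true(sc$degenerate)
  expect_true(is.na(sc$relative_mn))
  expect_equal(sc$diff_vs_negative, 150)  # differences still reported
})
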