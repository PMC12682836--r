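# From-scratch phylogenetic comparative methods under Brownian motion:
# tree covariance, Blomberg's K with a randomisation test, ML ancestral
# states, PGLS, and tip-rate--trait correlation tests.

# depth (root-to-node path length) of every node, ape numbering
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depth <- numeric(n_node)
  root <- length(tree$tip.label) + 1L
  ed <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  depth[root] <- 0
  for (i in seq_len(nrow(ed)))
    depth[ed[i, 2]] <- depth[ed[i, 1]] + el[i]
  depth
}

# descendant-tip index list per node
.desc_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1]; ch <- ed[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance between two tips is the shared
#' root-to-MRCA path length; the diagonal holds root-to-tip depths. The
#' matrix is symmetric positive semidefinite.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A tips x tips matrix with tip labels as dimnames.
#' @export
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
phylo_vcv <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object")
  # a star phylogeny (single basal node, all children tips) is rooted for
  # covariance purposes even though the basal node is a polytomy
  n_tip_chk <- length(tree$tip.label)
  basal_kids <- tree$edge[tree$edge[, 1] == n_tip_chk + 1L, 2]
  is_star <- length(basal_kids) == n_tip_chk && all(basal_kids <= n_tip_chk)
  if (!ape::is.rooted(tree) && !is_star) abort("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort("tree must have non-negative branch lengths")
  n_tip <- length(tree$tip.label)
  depth <- node_depths(tree)
  desc <- .desc_tips(tree)
  V <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n_tip)]
  internal <- (n_tip + 1L):max(tree$edge)
  for (u in internal) {
    kids <- tree$edge[tree$edge[, 1] == u, 2]
    if (length(kids) < 2) next
    for (a in seq_len(length(kids) - 1)) {
      for (b in (a + 1):length(kids)) {
        ta <- desc[[kids[a]]]; tb <- desc[[kids[b]]]
        V[ta, tb] <- depth[u]
        V[tb, ta] <- depth[u]
      }
    }
  }
  V
}

# Cholesky-based inverse; singular V (e.g. zero-length cherries) triggers
# the documented perturbation of zero branch lengths by 1e-12 * tree depth
.vcv_inverse <- function(tree) {
  V <- phylo_vcv(tree)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    warn("singular phylogenetic covariance; zero branch lengths perturbed by 1e-12 * tree depth")
    depth <- max(node_depths(tree))
    tree$edge.length[tree$edge.length == 0] <- 1e-12 * depth
    V <- phylo_vcv(tree)
    ch <- chol(V)
  }
  list(V = V, Vinv = chol2inv(ch))
}

.match_trait <- function(traits, tree, value, tip) {
  tip_col <- normalize_taxon(dplyr::pull(traits, {{ tip }}))
  vals <- dplyr::pull(traits, {{ value }})
  labs <- normalize_taxon(tree$tip.label)
  extra <- setdiff(tip_col, labs)
  if (length(extra))
    abort(paste0("trait tips not in tree: ", paste(extra, collapse = ", ")))
  missing <- setdiff(labs, tip_col)
  if (length(missing))
    abort(paste0("missing trait value for tree tip(s) (no imputation): ",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(tip_col)) abort("duplicate tips in trait table")
  y <- vals[match(labs, tip_col)]
  if (any(is.na(y))) abort("missing trait value (no imputation)")
  setNames(y, tree$tip.label)
}

#' Blomberg's K with a randomisation test
#'
#' The variance-ratio statistic for phylogenetic signal in a continuous
#' trait: the ratio of the ordinary to the phylogenetically corrected mean
#' squared error, scaled by its Brownian-motion expectation, so K = 1 is
#' expected under Brownian motion and K < 1 indicates less signal than the
#' tree predicts. With phylogenetic mean
#' `a = (1' Vinv 1)^-1 1' Vinv y`:
#' `MSE0 = (y - a)'(y - a)/(n-1)`, `MSE = (y - a)' Vinv (y - a)/(n-1)`,
#' `K = (MSE0/MSE) / ((tr V - n / sum(Vinv)) / (n-1))`.
#'
#' Significance is assessed by permuting trait values across tips and
#' comparing the observed MSE0/MSE ratio with the permutation distribution
#' (upper tail, add-one correction):
#' `p = (1 + #(ratio_perm >= ratio_obs)) / (n_perm + 1)`.
#'
#' @param traits Data frame with one row per tip.
#' @param tree A rooted `phylo`, pruned to the trait tips (>= 4 tips;
#'   complete data required, no imputation).
#' @param value,tip Bare column names of the trait value and tip label
#'   (defaults `value`, `tip`).
#' @param transform `"none"` or `"log"` (natural log; positive values
#'   required).
#' @param n_perm Number of randomisations (default 10000).
#' @param seed Integer seed for the randomisation; drawn and recorded if
#'   `NULL`.
#' @return A `signal_result`: one-row tibble with `k`, `p`, `n`, `n_perm`,
#'   `seed`, `observed_msr` (MSE0/MSE) and `expected_msr` (its Brownian
#'   expectation), carrying the permutation null as an attribute.
#' @export
blomberg_k <- function(traits, tree, value = value, tip = tip,
                       transform = c("none", "log"),
                       n_perm = 10000, seed = NULL) {
  transform <- match.arg(transform)
  y <- .match_trait(traits, tree, {{ value }}, {{ tip }})
  if (transform == "log") {
    if (any(y <= 0)) abort("log transform requires positive trait values")
    y <- log(y)
  }
  n <- length(y)
  if (n < 4) abort("Blomberg's K needs at least 4 tips")
  if (sd(y) == 0)
    abort("constant trait: MSE is zero and K is undefined")
  vv <- .vcv_inverse(tree)
  V <- vv$V; Vinv <- vv$Vinv
  w <- Vinv %*% rep(1, n)
  sum_vinv <- sum(w)
  a <- sum(w * y) / sum_vinv
  r <- y - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Vinv %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_vinv) / (n - 1)
  ratio_obs <- mse0 / mse
  k <- ratio_obs / expected

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  null_ratio <- NULL
  p <- NA_real_
  if (n_perm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    wy <- drop(crossprod(w, Y)) / sum_vinv          # phylogenetic mean per perm
    Rm <- sweep(Y, 2, wy)
    mse0_p <- colSums(Rm^2) / (n - 1)
    mse_p <- colSums((Vinv %*% Rm) * Rm) / (n - 1)
    null_ratio <- mse0_p / mse_p
    p <- (1 + sum(null_ratio >= ratio_obs)) / (n_perm + 1)
  }
  out <- tibble(k = k, p = p, n = n, n_perm = n_perm, seed = seed,
                observed_msr = ratio_obs, expected_msr = expected)
  attr(out, "null_k") <- if (is.null(null_ratio)) NULL else null_ratio / expected
  class(out) <- c("signal_result", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Maximum-likelihood ancestral states for a continuous trait
#'
#' Brownian-motion (GLS) reconstruction: with phylogenetic mean `a` and tip
#' deviations `y - a`, the state at an internal node is the multivariate
#' normal conditional expectation
#' `a + c' Vinv (y - a)`, where `c[i]` is the shared path length between the
#' node and tip `i`. The root state equals the phylogenetic mean. States
#' along a branch interpolate linearly between the parent and child states.
#'
#' @inheritParams blomberg_k
#' @return An object of class `asr_ml`: `$states` is a tibble with one row
#'   per node (`node` in ape numbering, `label`, `is_tip`, `depth`,
#'   `state`); the tree and trait name are carried for plotting.
#' @export
asr_ml <- function(traits, tree, value = value, tip = tip,
                   transform = c("none", "log")) {
  transform <- match.arg(transform)
  y <- .match_trait(traits, tree, {{ value }}, {{ tip }})
  if (transform == "log") {
    if (any(y <= 0)) abort("log transform requires positive trait values")
    y <- log(y)
  }
  n <- length(y)
  vv <- .vcv_inverse(tree)
  V <- vv$V; Vinv <- vv$Vinv
  w <- Vinv %*% rep(1, n)
  a <- sum(w * y) / sum(w)
  resid_w <- Vinv %*% (y - a)

  depth <- node_depths(tree)
  desc <- .desc_tips(tree)
  n_node <- max(tree$edge)
  internal <- (n + 1L):n_node
  states <- numeric(n_node)
  states[seq_len(n)] <- y
  for (u in internal) {
    in_clade <- logical(n)
    in_clade[desc[[u]]] <- TRUE
    cvec <- numeric(n)
    cvec[in_clade] <- depth[u]
    if (any(!in_clade)) {
      rep_tip <- desc[[u]][1]
      cvec[!in_clade] <- V[rep_tip, !in_clade]
    }
    states[u] <- a + sum(cvec * resid_w)
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep(NA_character_, n_node - n))
  out <- tibble(node = seq_len(n_node), label = labels,
                is_tip = seq_len(n_node) <= n,
                depth = depth, state = states)
  structure(list(states = out, tree = tree, root_state = a,
                 trait = as_name(enquo(value)), transform = transform),
            class = "asr_ml")
}

#' @export
print.asr_ml <- function(x, ...) {
  cat("ML (Brownian) ancestral states for", x$trait,
      if (x$transform == "log") "(log scale)" else "", "\n")
  cat("  root state:", signif(x$root_state, 6), "\n")
  print(x$states)
  invisible(x)
}

#' Phylogenetic generalised least squares (Brownian motion)
#'
#' Regression whose error covariance is proportional to the tree covariance
#' `V`: `beta = (X' Vinv X)^-1 X' Vinv y`, residual variance
#' `sigma2 = r' Vinv r / (n - p)`, standard errors from
#' `sigma2 (X' Vinv X)^-1`, two-sided t-tests on `n - p` degrees of freedom.
#' On a star phylogeny (V proportional to the identity) this reduces to
#' ordinary least squares.
#'
#' @param data Data frame with one row per tip, containing the model
#'   variables and a tip-label column.
#' @param tree A rooted `phylo` whose tips all appear in `data`.
#' @param formula Model formula, e.g. `y ~ x`.
#' @param tip Bare name of the tip-label column (default `tip`).
#' @return A `pgls_fit` with `tidy()`/`glance()` methods.
#' @export
pgls <- function(data, tree, formula, tip = tip) {
  tip_col <- normalize_taxon(dplyr::pull(data, {{ tip }}))
  labs <- normalize_taxon(tree$tip.label)
  missing <- setdiff(labs, tip_col)
  if (length(missing))
    abort(paste0("missing data for tree tip(s): ",
                 paste(missing, collapse = ", ")))
  d <- as.data.frame(data)[match(labs, tip_col), , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  if (nrow(mf) != length(labs))
    abort("PGLS requires complete data for every tree tip")
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) abort("collinear design matrix")
  if (n <= p) abort("more parameters than tips")

  vv <- .vcv_inverse(tree)
  Vinv <- vv$Vinv
  XtVi <- t(X) %*% Vinv
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vinv %*% r) / (n - p)
  cov_beta <- sigma2 * solve(XtViX)
  se <- sqrt(diag(cov_beta))
  tval <- drop(beta) / se
  pval <- 2 * pt(-abs(tval), n - p)

  coefs <- tibble(term = colnames(X), estimate = unname(drop(beta)),
                  std.error = unname(se), statistic = unname(tval),
                  p.value = unname(pval))
  structure(list(coefficients = coefs, sigma2 = sigma2, n = n,
                 df.residual = n - p, formula = formula,
                 correlation_model = "brownian"),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS under Brownian motion (", deparse(x$formula), "), n = ",
      x$n, "\n", sep = "")
  print(x$coefficients)
  cat("residual sigma2:", signif(x$sigma2, 6), "\n")
  invisible(x)
}

# all permutations of 1..n (n <= 9), matrix n x n!
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (j in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      col <- col + 1L
      out[, col] <- append(sub[, j], n, after = pos - 1L)
    }
  }
  out
}

#' Spearman rank correlation with an exact small-sample null
#'
#' Rho is the Pearson correlation of the (midrank) ranks. For `n <= 9` the
#' two-sided p-value is exact, from full enumeration of all `n!` equally
#' likely rank assignments (valid with ties); for larger `n` the usual
#' t-approximation on `n - 2` degrees of freedom is used.
#'
#' @param x,y Numeric vectors.
#' @param exact `"auto"` (enumerate when `n <= 9`), `TRUE`, or `FALSE`.
#' @return One-row tibble: `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact = "auto") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman test needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort("rho undefined: a variable is constant (all values tied)")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  do_exact <- if (identical(exact, "auto")) n <= 9 else isTRUE(exact)
  if (do_exact) {
    if (n > 9) abort("exact enumeration limited to n <= 9")
    perms <- .permutations(n)
    rho_null <- apply(perms, 2, function(idx) cor(rx[idx], ry))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(t), n - 2)
    method <- "asymptotic"
  }
  tibble(rho = rho, p = p, n = n, method = method)
}

#' Tip-rate--trait correlation tests
#'
#' For each trait, tests whether per-tip speciation rates covary with the
#' trait: a Spearman rank correlation (rates log-transformed; ranks are
#' log-invariant but the transform is applied for consistency with the PGLS
#' arm) and a PGLS of log rate on log trait under Brownian motion.
#'
#' @param rates Data frame with tip labels and positive speciation rates
#'   (events Myr⁻¹).
#' @param traits Data frame with a tip column and one numeric column per
#'   trait (positive values; log-transformed for the PGLS arm).
#' @param tree A rooted `phylo` pruned to the shared tips (>= 4).
#' @param rate Bare name of the rate column (default `rate`).
#' @param tip Bare name of the tip column in both tables (default `tip`).
#' @param transform_trait `"log"` (default; for raw concentrations, which
#'   must be positive) or `"none"` (for traits already on a log or
#'   unbounded scale, e.g. Brownian simulations).
#' @return A tibble with one row per trait: `trait`, `rho`, `spearman_p`,
#'   `spearman_method`, `pgls_slope`, `pgls_p`, `n`.
#' @export
tip_rate_tests <- function(rates, traits, tree, rate = rate, tip = tip,
                           transform_trait = c("log", "none")) {
  transform_trait <- match.arg(transform_trait)
  rate_tips <- normalize_taxon(dplyr::pull(rates, {{ tip }}))
  rate_vals <- dplyr::pull(rates, {{ rate }})
  if (any(rate_vals <= 0)) abort("speciation rates must be positive")
  trait_tips <- normalize_taxon(dplyr::pull(traits, {{ tip }}))
  labs <- normalize_taxon(tree$tip.label)
  shared <- intersect(intersect(labs, rate_tips), trait_tips)
  if (length(shared) < 4) abort("rates and traits share fewer than 4 tips")
  tr <- prune_to_taxa(tree, shared)
  labs <- normalize_taxon(tr$tip.label)
  lr <- log(rate_vals[match(labs, rate_tips)])
  if (sd(lr) == 0) abort("rho undefined: all speciation rates tied")

  tip_q <- enquo(tip)
  trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                        as_name(tip_q))
  purrr::map(trait_cols, function(tc) {
    tv <- traits[[tc]][match(labs, trait_tips)]
    if (any(is.na(tv))) abort(paste0("missing values in trait `", tc, "`"))
    if (transform_trait == "log" && any(tv <= 0))
      abort(paste0("trait `", tc, "` must be positive for the log transform"))
    sp <- spearman_test(lr, tv)
    d <- tibble(tip = labs, log_rate = lr,
                log_trait = if (transform_trait == "log") log(tv) else tv)
    fit <- pgls(d, tr, log_rate ~ log_trait)
    tibble(trait = tc, rho = sp$rho, spearman_p = sp$p,
           spearman_method = sp$method,
           pgls_slope = fit$coefficients$estimate[2],
           pgls_p = fit$coefficients$p.value[2],
           n = length(labs))
  }) |> list_rbind()
}
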