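# Independent oracles used across the suite. These re-derive expected
# values from first principles (path enumeration, textbook formulas,
# reference implementations in ape/phytools/nlme) and never call the code
# paths they check.

# shared root-to-MRCA path length for every tip pair, by explicit
# ancestor-path enumeration on the raw edge table
oracle_vcv <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- n_tip + 1L
  path_to_root <- function(node) {
    path <- integer(0)
    while (node != root) {
      path <- c(path, node)
      node <- parent[node]
    }
    c(path, root)
  }
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + blen[node]
      node <- parent[node]
    }
    d
  }
  V <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n_tip), path_to_root)
  for (i in seq_len(n_tip)) {
    for (j in i:n_tip) {
      common <- intersect(paths[[i]], paths[[j]])
      mrca <- common[1]
      V[i, j] <- V[j, i] <- depth_of(mrca)
    }
  }
  V
}

# textbook Welch t: statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  t <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Blomberg's K evaluated step by step from a covariance matrix and trait
# vector (spreadsheet-style; no shared code with the package)
oracle_k <- function(V, y) {
  n <- length(y)
  Vinv <- solve(V)
  one <- rep(1, n)
  a <- drop((t(one) %*% Vinv %*% y) / (t(one) %*% Vinv %*% one))
  mse0 <- drop(t(y - a) %*% (y - a)) / (n - 1)
  mse <- drop(t(y - a) %*% Vinv %*% (y - a)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  (mse0 / mse) / expected
}

random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
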