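# ggplot2 visualisations for the main result types.

#' Plot relative leaf-Mn scores
#'
#' Dot plot of the reference-normalised relative Mn score per species and
#' site; 0 % marks the negative-reference baseline and 100 % the positive
#' reference.
#'
#' @param scores Output of [mn_scores()].
#' @return A ggplot.
#' @export
plot_relative_mn <- function(scores) {
  ggplot(scores |> filter(!.data$degenerate),
         aes(x = .data$relative_mn,
             y = stats::reorder(.data$species, .data$relative_mn),
             colour = .data$site_id)) +
    geom_vline(xintercept = c(0, 100), linetype = "dashed",
               colour = "grey50") +
    geom_point() +
    labs(x = "Relative leaf [Mn] (%)", y = NULL, colour = "Site") +
    theme_minimal()
}

#' Plot exudation calls
#'
#' Species-mean leaf Mn on a log axis against the site's reference band,
#' coloured by the exudation call.
#'
#' @param calls Output of [classify_exudation()].
#' @return A ggplot.
#' @export
plot_exudation <- function(calls) {
  ggplot(calls,
         aes(x = .data$site_id, y = .data$target_mean_mn,
             colour = .data$category, shape = .data$strong_capacity)) +
    geom_point(position = position_jitter(width = 0.15, height = 0),
               size = 2) +
    geom_point(aes(y = .data$neg_mean), colour = "grey40", shape = 95,
               size = 6) +
    geom_point(aes(y = .data$pos_mean), colour = "sienna", shape = 95,
               size = 6) +
    scale_y_log10() +
    labs(x = "Site", y = expression("Leaf [Mn] (mg kg"^-1*")"),
         colour = "Call", shape = "Strong capacity") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pca_diag <- function(object, axes = c(1, 2), ...) {
  pcs <- paste0("PC", axes)
  sc <- object$scores
  lo <- object$loadings
  arrow_scale <- 0.8 * min(
    max(abs(sc[[pcs[1]]])) / max(abs(lo[[pcs[1]]])),
    max(abs(sc[[pcs[2]]])) / max(abs(lo[[pcs[2]]])))
  ggplot(sc, aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    geom_point(alpha = 0.6) +
    geom_segment(data = lo,
                 aes(x = 0, y = 0,
                     xend = .data[[pcs[1]]] * arrow_scale,
                     yend = .data[[pcs[2]]] * arrow_scale),
                 arrow = arrow(length = unit(2, "mm")),
                 colour = "firebrick") +
    geom_text(data = lo,
              aes(x = .data[[pcs[1]]] * arrow_scale * 1.08,
                  y = .data[[pcs[2]]] * arrow_scale * 1.08,
                  label = .data$variable),
              colour = "firebrick", size = 3) +
    labs(x = sprintf("%s (%.1f%%)", pcs[1], 100 * object$explained[axes[1]]),
         y = sprintf("%s (%.1f%%)", pcs[2], 100 * object$explained[axes[2]])) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.posthoc_groups <- function(object, ...) {
  ggplot(object$letters,
         aes(x = stats::reorder(.data$group, -.data$mean), y = .data$mean)) +
    geom_col(fill = "grey80", colour = "grey30") +
    geom_text(aes(label = .data$letter), vjust = -0.5) +
    labs(x = NULL, y = "Group mean",
         subtitle = paste0("Groups sharing a letter are not significantly ",
                           "different (alpha = ", object$alpha, ")")) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.signal_result <- function(object, ...) {
  null_k <- attr(object, "null_k")
  if (is.null(null_k))
    abort("no permutation null stored (n_perm = 0)")
  ggplot(tibble(k = null_k), aes(x = .data$k)) +
    geom_histogram(bins = 50, fill = "grey80", colour = "grey40") +
    geom_vline(xintercept = object$k, colour = "firebrick") +
    labs(x = "Blomberg's K (permutation null)", y = "Count",
         subtitle = sprintf("observed K = %.3f, p = %.4g (%d permutations)",
                            object$k, object$p, object$n_perm)) +
    theme_minimal()
}

# simple rectangular tree layout: x = node depth, y = tip order / child mean
.tree_layout <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  yy <- numeric(n_node)
  yy[seq_len(n_tip)] <- seq_len(n_tip)
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1]
    kids <- ed[ed[, 1] == p, 2]
    yy[p] <- mean(yy[kids])
  }
  list(x = node_depths(tree), y = yy)
}

#' @exportS3Method ggplot2::autoplot
autoplot.asr_ml <- function(object, ...) {
  tree <- object$tree
  lay <- .tree_layout(tree)
  st <- object$states$state
  ed <- tree$edge
  segs <- tibble(
    x = lay$x[ed[, 1]], xend = lay$x[ed[, 2]],
    y = lay$y[ed[, 2]], yend = lay$y[ed[, 2]],
    state = (st[ed[, 1]] + st[ed[, 2]]) / 2)
  verts <- tibble(
    x = lay$x[ed[, 1]], xend = lay$x[ed[, 1]],
    y = lay$y[ed[, 1]], yend = lay$y[ed[, 2]],
    state = st[ed[, 1]])
  tips <- tibble(x = lay$x[seq_along(tree$tip.label)],
                 y = lay$y[seq_along(tree$tip.label)],
                 label = tree$tip.label)
  ggplot() +
    geom_segment(data = bind_rows(segs, verts),
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend,
                     colour = .data$state), linewidth = 0.8) +
    geom_text(data = tips,
              aes(x = .data$x, y = .data$y, label = .data$label),
              hjust = -0.05, size = 2.8) +
    scale_colour_viridis_c(name = object$trait) +
    expand_limits(x = max(lay$x) * 1.25) +
    labs(x = "Time", y = NULL,
         subtitle = paste("ML ancestral states:", object$trait)) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid.major.y = element_blank())
}
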