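#' Hierarchical clustering of patient signature profiles
#'
#' Euclidean distances between signature profiles, agglomerated with Ward's
#' minimum-variance criterion (`hclust` method `ward.D2`, i.e. Ward on squared
#' Euclidean distances with heights reported on the distance scale). Profiles
#' are kept in patient-ID-sorted input order, so the agglomeration is fully
#' deterministic.
#'
#' @param sig A `psp_signature` tibble with at least 2 patients.
#' @return An [stats::hclust] object with patient IDs as labels.
#' @export
cluster_patients <- function(sig) {
  if (nrow(sig) < 2) stop_data("clustering needs at least 2 patients")
  x <- sig_matrix(sig)
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

# All internal-node leaf sets of an hclust tree, as sorted integer index
# vectors (1..n in label order) plus canonical string keys built from labels
# so comparisons are invariant to patient input order.
hclust_leaf_sets <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves <- unlist(lapply(kids, function(j) if (j < 0) -j else sets[[j]]))
    sets[[k]] <- sort(leaves)
  }
  sets
}

leaf_set_keys <- function(sets, labels) {
  vapply(sets, function(s) paste(sort(labels[s]), collapse = "\r"), character(1))
}

#' Multiscale bootstrap confidence values (AU / BP) for patient clusters
#'
#' Assesses every cluster of the observed dendrogram by feature resampling.
#' For each scale factor `r`, `B` resamples of `round(r * n_features)` feature
#' columns are drawn with replacement, patients are re-clustered, and the
#' per-scale bootstrap probability `BP_r` is the fraction of resample trees
#' containing the cluster (leaf-set equality). The probit-transformed curve
#' `qnorm(1 - BP_r)` is fitted against `v * sqrt(r) + c / sqrt(r)` by weighted
#' least squares (binomial-variance weights, ordinary LS fallback), giving the
#' approximately unbiased value `AU = 100 * (1 - pnorm(v - c))`. `BP` is the
#' plain bootstrap probability at (or nearest to) scale 1.
#'
#' `BP_r` is clamped to `[1/(B+1), B/(B+1)]` before the probit transform so
#' the fit never sees infinite quantiles. A cluster never observed in any
#' resample gets `AU = 0` and is flagged.
#'
#' With a single scale of 1 the multiscale fit is refused and plain bootstrap
#' probabilities alone are reported (`au = NA`), with a warning.
#'
#' @param sig A `psp_signature` tibble.
#' @param scales Resampling scale factors; must straddle 1 (default
#'   `seq(0.5, 1.4, by = 0.1)`).
#' @param B Resamples per scale (default 1000; at least 100).
#' @param seed Integer RNG seed (required; the whole procedure is
#'   deterministic given it).
#' @return An object of class `psp_boot`: list with the observed `hclust`
#'   tree, a `nodes` tibble (`node`, list-column `leaves`, `au`, `bp`,
#'   `flagged`), the per-scale BP matrix, and the call parameters.
#' @export
multiscale_bootstrap <- function(sig, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000, seed) {
  stopifnot(B >= 100)
  if (missing(seed)) stop_data("multiscale_bootstrap requires an explicit seed")
  bp_only <- length(scales) == 1 && isTRUE(all.equal(scales, 1))
  if (!bp_only && (length(scales) < 2 || min(scales) >= 1 || max(scales) <= 1))
    stop_data("scales must straddle 1 (or be exactly c(1) for plain bootstrap)")
  if (bp_only)
    rlang::warn("single scale of 1: AU needs >= 2 scales; reporting BP only")

  hc <- cluster_patients(sig)
  x <- sig_matrix(sig)
  n_feat <- ncol(x)
  labels <- sig$patient_id
  obs_sets <- hclust_leaf_sets(hc)
  obs_keys <- leaf_set_keys(obs_sets, labels)
  n_nodes <- length(obs_keys)

  set.seed(seed)
  counts <- matrix(0L, n_nodes, length(scales))
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * n_feat))
    for (b in seq_len(B)) {
      cols <- sample.int(n_feat, m, replace = TRUE)
      hb <- stats::hclust(stats::dist(x[, cols, drop = FALSE]), method = "ward.D2")
      keys_b <- leaf_set_keys(hclust_leaf_sets(hb), labels)
      hit <- obs_keys %in% keys_b
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  bp_raw <- counts / B

  near1 <- which.min(abs(scales - 1))
  au <- rep(NA_real_, n_nodes)
  fit_v <- rep(NA_real_, n_nodes)
  fit_c <- rep(NA_real_, n_nodes)
  flagged <- rowSums(counts) == 0L
  if (!bp_only) {
    for (i in seq_len(n_nodes)) {
      if (flagged[i]) { au[i] <- 0; next }
      fit <- au_fit(bp_raw[i, ], scales, B)
      fit_v[i] <- fit["v"]; fit_c[i] <- fit["c"]
      au[i] <- fit["au"]
    }
  }
  nodes <- tibble::tibble(
    node = seq_len(n_nodes),
    leaves = lapply(obs_sets, function(s) sort(labels[s])),
    n_leaves = lengths(obs_sets),
    au = au,
    bp = 100 * bp_raw[, near1],
    flagged = flagged
  )
  structure(list(hclust = hc, nodes = nodes, bp_by_scale = bp_raw,
                 scales = scales, B = B, seed = seed,
                 n_features = n_feat, patient_id = labels, class = sig$class),
            class = "psp_boot")
}

# Probit WLS fit of the multiscale curve for one cluster. Scales where BP is
# exactly 0 or 1 carry no information about the curve (the probit quantile is
# infinite) and are excluded; with fewer than two informative scales the fit
# is degenerate and AU saturates by the mean-BP rule (100 when the cluster is
# essentially always recovered, 0 when essentially never). Returns
# c(v, c, au), au in [0, 100].
au_fit <- function(bp, scales, B) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 2) {
    au <- if (mean(bp) >= 0.5) 100 else 0
    return(c(v = NA_real_, c = NA_real_, au = au))
  }
  bp_u <- pmin(pmax(bp[use], 1 / (B + 1)), B / (B + 1))
  z <- stats::qnorm(1 - bp_u)
  X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
  w <- B * stats::dnorm(z)^2 / (bp_u * (1 - bp_u))
  if (!all(is.finite(w)) || sum(w > 0) < 2) w <- rep(1, length(z))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  c(v = unname(v), c = unname(cc),
    au = 100 * (1 - stats::pnorm(unname(v) - unname(cc))))
}

#' @export
print.psp_boot <- function(x, ...) {
  cat(sprintf("Multiscale bootstrap over %d patients x %d features (B = %d, %d scales)\n",
              length(x$patient_id), x$n_features, x$B, length(x$scales)))
  print(x$nodes, ...)
  invisible(x)
}

#' Tidy / glance methods for bootstrap cluster confidence
#'
#' `tidy()` returns the per-node table (node id, leaf set, AU, BP, flag);
#' `glance()` one row of run-level summaries.
#'
#' @param x A `psp_boot` object.
#' @param ... Unused.
#' @method tidy psp_boot
#' @export
tidy.psp_boot <- function(x, ...) x$nodes

#' @rdname tidy.psp_boot
#' @method glance psp_boot
#' @export
glance.psp_boot <- function(x, ...) {
  tibble::tibble(
    n_patients = length(x$patient_id),
    n_features = x$n_features,
    n_scales = length(x$scales),
    B = x$B,
    min_au = suppressWarnings(min(x$nodes$au, na.rm = TRUE)),
    n_au_ge_95 = sum(x$nodes$au >= 95, na.rm = TRUE),
    seed = x$seed
  )
}

#' Export a bootstrapped dendrogram as Newick
#'
#' Internal nodes carry `AU=..|BP=..` labels so the confidence values travel
#' with the topology.
#'
#' @param boot A `psp_boot` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boot_newick <- function(boot, path) {
  phy <- ape::as.phylo(boot$hclust)
  # ape internal node numbering: node (n + k) corresponds to hclust merge row
  # order only after matching leaf sets, so map by leaf-set keys.
  n <- length(phy$tip.label)
  phy_sets <- lapply((n + 1):(n + phy$Nnode), function(nd) {
    sort(ape::extract.clade(phy, nd)$tip.label)
  })
  phy_keys <- vapply(phy_sets, paste, character(1), collapse = "\r")
  boot_keys <- vapply(boot$nodes$leaves, paste, character(1), collapse = "\r")
  idx <- match(phy_keys, boot_keys)
  lab <- ifelse(is.na(idx), "",
                sprintf("AU=%.1f|BP=%.1f", boot$nodes$au[idx], boot$nodes$bp[idx]))
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Dendrogram plot with AU/BP annotations
#'
#' @param object A `psp_boot` object.
#' @param au_threshold Nodes at or above this AU are highlighted (default 95).
#' @param ... Unused.
#' @method autoplot psp_boot
#' @export
autoplot.psp_boot <- function(object, au_threshold = 95, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # leaf x-positions in plotting order
  ord <- hc$order
  xpos <- stats::setNames(seq_along(ord), hc$labels[ord])
  segs <- dendro_segments(hc, xpos)
  node_xy <- dendro_node_positions(hc, xpos)
  node_xy$au <- object$nodes$au
  node_xy$bp <- object$nodes$bp
  leaf_df <- tibble::tibble(x = unname(xpos), y = 0,
                            label = names(xpos),
                            class = object$class[match(names(xpos), object$patient_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = node_xy,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sprintf("%.0f/%.0f", .data$au, .data$bp),
                                    colour = .data$au >= au_threshold),
                       vjust = -0.4, size = 3, show.legend = FALSE) +
    ggplot2::geom_text(data = leaf_df,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                                    colour = .data$class),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 na.value = "grey40", guide = "none") +
    ggplot2::labs(y = "Ward linkage height", x = NULL,
                  subtitle = "node labels: AU/BP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

# x-coordinates of each merge node and its segments, base-hclust geometry.
dendro_node_positions <- function(hc, xpos) {
  n <- nrow(hc$merge)
  x <- numeric(n)
  for (k in seq_len(n)) {
    kids <- hc$merge[k, ]
    cx <- vapply(kids, function(j) {
      if (j < 0) unname(xpos[hc$labels[-j]]) else x[j]
    }, numeric(1))
    x[k] <- mean(cx)
  }
  tibble::tibble(node = seq_len(n), x = x, y = hc$height)
}

dendro_segments <- function(hc, xpos) {
  node_xy <- dendro_node_positions(hc, xpos)
  segs <- list()
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    child <- lapply(kids, function(j) {
      if (j < 0) c(x = unname(xpos[hc$labels[-j]]), y = 0)
      else c(x = node_xy$x[j], y = hc$height[j])
    })
    h <- hc$height[k]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(child[[1]]["x"], child[[2]]["x"], child[[1]]["x"]),
      y = c(child[[1]]["y"], child[[2]]["y"], h),
      xend = c(child[[1]]["x"], child[[2]]["x"], child[[2]]["x"]),
      yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}
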