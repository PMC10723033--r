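# Seeded fixture generators with known ground truth. Both run under
# Mersenne-Twister / Inversion / Rejection RNG (pinned explicitly, so
# regeneration is stable across sessions and platforms) and restore the
# caller's RNG state on exit.

with_pinned_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_param("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Synthetic layered tissue with a colocalization status
#'
#' Emulates a spot-based spatial transcriptomics section of layered cortex:
#' spots sit on a Visium-like hexagonal lattice (100-unit center-to-center
#' spacing, image coordinates) inside a rectangle, a categorical `layer`
#' annotation splits the section into horizontal bands of equal height
#' labeled `L1 .. L<n-1>` plus `WM` (white matter), and a categorical
#' `coloc_status` in `none / geneA / geneB / both` is drawn per spot. In the
#' enriched layer the probability of `both` is multiplied by `enrichment`
#' and the four probabilities renormalized, mimicking a layer where two
#' ligand-receptor genes co-occur far more often than elsewhere.
#'
#' @param n_spots number of spots.
#' @param n_layers number of bands (>= 2); the last band is `WM`.
#' @param enriched_layer band to enrich: an index in `1..n_layers` or a band
#'   label such as `"L6"`.
#' @param enrichment multiplier (> 1) on the baseline probability of `both`
#'   inside the enriched band.
#' @param seed integer seed; the same seed and parameters always regenerate
#'   an identical table.
#' @param baseline_probs baseline probabilities for
#'   `none, geneA, geneB, both` (summing to 1).
#' @return an object of class `synthetic_scene`: `table` (a `point_table`
#'   with annotations `layer` and `coloc_status`), `truth` (band edges,
#'   labels, baseline probabilities, enriched label, enrichment, the implied
#'   within/outside probabilities of `both`), and `seed`.
#' @export
make_layered_tissue <- function(n_spots = 1000, n_layers = 7,
                                enriched_layer = n_layers - 1, enrichment = 4,
                                seed = 1,
                                baseline_probs = c(none = 0.70, geneA = 0.13,
                                                   geneB = 0.11, both = 0.06)) {
  if (n_layers < 2) stop_param("n_layers must be at least 2")
  if (n_spots < n_layers) stop_param("need at least one spot per layer")
  if (!is.numeric(enrichment) || enrichment <= 1) {
    stop_param("enrichment must be greater than 1")
  }
  if (!setequal(names(baseline_probs), c("none", "geneA", "geneB", "both")) ||
      abs(sum(baseline_probs) - 1) > 1e-9 || any(baseline_probs <= 0)) {
    stop_param("baseline_probs must be positive, named none/geneA/geneB/both and sum to 1")
  }
  layer_labels <- c(paste0("L", seq_len(n_layers - 1)), "WM")
  if (is.character(enriched_layer)) {
    if (!enriched_layer %in% layer_labels) {
      stop_param(sprintf("enriched_layer '%s' is not one of: %s",
                         enriched_layer, paste(layer_labels, collapse = ", ")))
    }
    enriched_label <- enriched_layer
  } else {
    if (enriched_layer < 1 || enriched_layer > n_layers) {
      stop_param("enriched_layer index out of range")
    }
    enriched_label <- layer_labels[as.integer(enriched_layer)]
  }

  spacing <- 100
  ncols <- ceiling(sqrt(n_spots))
  nrows <- ceiling(n_spots / ncols)
  row_i <- rep(seq_len(nrows), each = ncols)[seq_len(n_spots)]
  col_i <- rep(seq_len(ncols), times = nrows)[seq_len(n_spots)]
  x <- (col_i - 1) * spacing + ifelse(row_i %% 2 == 0, spacing / 2, 0)
  y <- (row_i - 1) * spacing * sqrt(3) / 2

  yr <- range(y)
  band_h <- (yr[2] - yr[1]) / n_layers
  edges <- yr[1] + band_h * seq(0, n_layers)
  band <- pmin(floor((y - yr[1]) / band_h) + 1, n_layers)
  layer <- layer_labels[band]

  probs_enriched <- baseline_probs
  probs_enriched["both"] <- probs_enriched["both"] * enrichment
  probs_enriched <- probs_enriched / sum(probs_enriched)
  statuses <- names(baseline_probs)

  coloc <- with_pinned_rng(seed, {
    out <- character(n_spots)
    in_enr <- layer == enriched_label
    # draw in fixed point order so output is independent of band layout code
    u <- stats::runif(n_spots)
    pick <- function(u1, p) statuses[findInterval(u1, cumsum(p), left.open = TRUE) + 1]
    out[!in_enr] <- pick(u[!in_enr], baseline_probs)
    out[in_enr] <- pick(u[in_enr], probs_enriched)
    out
  })

  tab <- point_table(
    ids = sprintf("spot%05d", seq_len(n_spots)),
    x = x, y = y, coord_mode = "image",
    annotations = list(
      layer = annotation_column(layer, "categorical", "layer"),
      coloc_status = annotation_column(coloc, "categorical", "coloc_status")
    )
  )
  truth <- list(
    layer_labels = layer_labels, band_edges = edges, spacing = spacing,
    baseline_probs = baseline_probs, enriched_layer = enriched_label,
    enrichment = enrichment,
    p_both_enriched = unname(probs_enriched["both"]),
    p_both_other = unname(baseline_probs["both"]),
    ratio_both = unname(probs_enriched["both"] / baseline_probs["both"])
  )
  structure(list(table = tab, truth = truth, seed = seed),
            class = "synthetic_scene")
}

#' Synthetic 2D Gaussian-mixture embedding with cluster-elevated expression
#'
#' Emulates a single-cell embedding (UMAP-like): `k` isotropic Gaussian
#' clusters with means evenly spaced on a circle, equal mixing proportions,
#' cluster labels `C1 .. Ck`, and a continuous `expr` annotation drawn from a
#' lognormal whose log-mean is elevated in the designated clusters (one
#' marker gene expressed highly in some cell types, at background elsewhere).
#'
#' @param n_cells number of cells.
#' @param k number of clusters (>= 2).
#' @param expr_high_clusters integer indices in `1..k` (or labels `"C3"`)
#'   whose cells draw from the elevated lognormal; may be empty, in which
#'   case every cluster shares the background distribution.
#' @param seed integer seed.
#' @param radius circle radius for the cluster means, in embedding units.
#' @param sigma isotropic within-cluster standard deviation.
#' @param meanlog_low,meanlog_high,sdlog lognormal parameters for background
#'   and elevated expression.
#' @return an object of class `synthetic_scene`: `table` (a cartesian
#'   `point_table` with categorical `cluster` and continuous `expr`),
#'   `truth` (cluster means, `sigma`, proportions, the lognormal parameter
#'   pairs and their closed-form means `exp(meanlog + sdlog^2/2)`), `seed`.
#' @export
make_mixture_embedding <- function(n_cells = 5000, k = 5,
                                   expr_high_clusters = 1, seed = 1,
                                   radius = 10, sigma = 1,
                                   meanlog_low = 0, meanlog_high = 1.5,
                                   sdlog = 0.5) {
  if (k < 2) stop_param("k must be at least 2")
  if (n_cells < k) stop_param("need at least one cell per cluster")
  labels <- paste0("C", seq_len(k))
  if (is.character(expr_high_clusters)) {
    bad <- setdiff(expr_high_clusters, labels)
    if (length(bad) > 0) stop_param(sprintf("unknown cluster '%s'", bad[1]))
    high_idx <- match(expr_high_clusters, labels)
  } else {
    high_idx <- as.integer(expr_high_clusters)
    if (length(high_idx) > 0 && (min(high_idx) < 1 || max(high_idx) > k)) {
      stop_param("expr_high_clusters indices must lie in 1..k")
    }
  }
  angles <- 2 * pi * (seq_len(k) - 1) / k
  mu <- cbind(x = radius * cos(angles), y = radius * sin(angles))

  gen <- with_pinned_rng(seed, {
    cl <- sample.int(k, n_cells, replace = TRUE)
    x <- mu[cl, "x"] + stats::rnorm(n_cells, sd = sigma)
    y <- mu[cl, "y"] + stats::rnorm(n_cells, sd = sigma)
    ml <- ifelse(cl %in% high_idx, meanlog_high, meanlog_low)
    expr <- stats::rlnorm(n_cells, meanlog = ml, sdlog = sdlog)
    list(cl = cl, x = x, y = y, expr = expr)
  })

  tab <- point_table(
    ids = sprintf("cell%06d", seq_len(n_cells)),
    x = gen$x, y = gen$y, coord_mode = "cartesian",
    annotations = list(
      cluster = annotation_column(labels[gen$cl], "categorical", "cluster"),
      expr = annotation_column(gen$expr, "continuous", "expr")
    )
  )
  truth <- list(
    labels = labels, means = mu, sigma = sigma,
    proportions = rep(1 / k, k), high_clusters = labels[high_idx],
    meanlog_low = meanlog_low, meanlog_high = meanlog_high, sdlog = sdlog,
    mean_expr_low = exp(meanlog_low + sdlog^2 / 2),
    mean_expr_high = exp(meanlog_high + sdlog^2 / 2)
  )
  structure(list(table = tab, truth = truth, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %d points, seed %s>\n",
              length(x$table$ids), format(x$seed)))
  invisible(x)
}
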