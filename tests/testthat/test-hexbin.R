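test_that("grid construction follows the nbins column rule", {
  g <- hex_grid(c(0, 10), c(0, 10), 10)
  expect_equal(g$size, 10 / (10 * sqrt(3)), tolerance = 1e-12)
  expect_identical(c(g$x0, g$y0), c(0, 0))
  expect_error(hex_grid(c(0, 10), c(0, 10), 0), class = "spotlayer_param_error")
  expect_error(hex_grid(c(0, 0), c(0, 1), 5), class = "spotlayer_param_error")
  # the extent's lower-left corner lies in cell (0,0)
  asg <- assign_hex(list(x = 0, y = 0), g)
  expect_identical(c(asg$q, asg$r), c(0L, 0L))
})

test_that("a point at a cell center maps to that cell", {
  g <- hex_grid(c(0, 10), c(0, 10), 7)
  ctr <- hex_centers(g, 2, 3)
  asg <- assign_hex(list(x = ctr$x, y = ctr$y), g)
  expect_identical(c(asg$q, asg$r), c(2L, 3L))
})

test_that("edge-midpoint ties resolve to the lexicographically smaller cell", {
  g <- hex_grid(c(0, 10), c(0, 10), 5)
  c1 <- hex_centers(g, 0, 0); c2 <- hex_centers(g, 1, 0)
  mid <- c((c1$x + c2$x) / 2, (c1$y + c2$y) / 2)
  asg <- assign_hex(list(x = mid[1], y = mid[2]), g)
  expect_identical(c(asg$q, asg$r), c(0L, 0L))
  # and between (0,1) and (1,0): (0,1) is lexicographically smaller
  c3 <- hex_centers(g, 0, 1); c4 <- hex_centers(g, 1, 0)
  mid2 <- c((c3$x + c4$x) / 2, (c3$y + c4$y) / 2)
  asg2 <- assign_hex(list(x = mid2[1], y = mid2[2]), g)
  expect_identical(c(asg2$q, asg2$r), c(0L, 1L))
})

test_that("assignment matches the brute-force nearest-center oracle", {
  set.seed(7)
  for (trial in 1:3) {
    x <- runif(400, 0, 12); y <- runif(400, -3, 9)
    g <- hex_grid(c(0, 12), c(-3, 9), sample(4:15, 1))
    expect_identical(assign_hex(list(x = x, y = y), g), oracle_assign(x, y, g))
  }
})

test_that("every point lands in exactly one cell and counts conserve", {
  emb <- make_mixture_embedding(n_cells = 800, k = 3, seed = 4)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 12)
  asg <- assign_hex(emb$table, g)
  expect_identical(nrow(asg), 800L)
  expect_false(anyNA(asg))
  agg <- hex_aggregate(emb$table, g, "expr", "cluster")
  expect_identical(sum(agg$cells$count), 800L)
  expect_true(all(agg$cells$count >= 1))
})

test_that("aggregation equals an independent group-by", {
  emb <- make_mixture_embedding(n_cells = 500, k = 3, expr_high_clusters = 1,
                                seed = 11)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 10)
  agg <- hex_aggregate(emb$table, g, continuous = "expr",
                       categorical = "cluster")
  ora <- oracle_groupby(get_annotation(emb$table, "expr")$values,
                        get_annotation(emb$table, "cluster")$values,
                        oracle_assign(emb$table$x, emb$table$y, g))
  expect_identical(nrow(agg$cells), length(ora))
  for (i in seq_len(nrow(agg$cells))) {
    k <- paste(agg$cells$q[i], agg$cells$r[i])
    expect_identical(agg$cells$count[i], as.integer(ora[[k]]$count))
    expect_equal(agg$means$expr[i], ora[[k]]$mean, tolerance = 1e-12)
    expect_identical(agg$majority$cluster[i], ora[[k]]$majority)
    expect_identical(agg$tally$cluster[[i]], ora[[k]]$tally)
  }
})

test_that("count equals the tally total and the majority attains its maximum", {
  emb <- make_mixture_embedding(n_cells = 600, k = 4, seed = 2)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 9)
  agg <- hex_aggregate(emb$table, g, categorical = "cluster")
  for (i in seq_len(nrow(agg$cells))) {
    tt <- agg$tally$cluster[[i]]
    expect_identical(sum(tt), agg$cells$count[i])
    expect_identical(unname(tt[agg$majority$cluster[i]]), max(tt))
  }
})

test_that("majority ties break to the lexicographically smallest label", {
  g <- hex_grid(c(0, 10), c(0, 10), 5)
  ctr <- hex_centers(g, 1, 1)
  tab <- point_table(
    ids = c("p1", "p2"), x = rep(ctr$x, 2) + c(-0.01, 0.01), y = rep(ctr$y, 2),
    annotations = list(lab = annotation_column(c("B", "A"), "categorical", "lab")))
  agg <- hex_aggregate(tab, g, categorical = "lab")
  expect_identical(agg$majority$lab, "A")
  expect_identical(agg$tally$lab[[1]], c(A = 1L, B = 1L))
})

test_that("unknown or mis-kinded aggregation columns fail loudly", {
  emb <- make_mixture_embedding(n_cells = 50, k = 2, seed = 1)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 4)
  expect_error(hex_aggregate(emb$table, g, continuous = "nope"),
               class = "spotlayer_name_error")
  expect_error(hex_aggregate(emb$table, g, continuous = "cluster"),
               class = "spotlayer_kind_error")
  expect_error(hex_aggregate(emb$table, g, categorical = "expr"),
               class = "spotlayer_kind_error")
})

test_that("an isolated cell yields its 6 edges; adjacent pairs 10 or 12", {
  g <- hex_grid(c(0, 10), c(0, 10), 6)
  one <- aggregate_from_pattern(g, data.frame(q = 2, r = 2, label = "A"))
  b1 <- extract_label_boundaries(one, g, "lab")
  expect_identical(nrow(b1$segments$A), 6L)

  same <- aggregate_from_pattern(g, data.frame(q = c(2, 3), r = c(2, 2),
                                               label = c("A", "A")))
  b2 <- extract_label_boundaries(same, g, "lab")
  expect_identical(nrow(b2$segments$A), 10L) # shared edge suppressed

  diff2 <- aggregate_from_pattern(g, data.frame(q = c(2, 3), r = c(2, 2),
                                                label = c("A", "B")))
  b3 <- extract_label_boundaries(diff2, g, "lab")
  expect_identical(nrow(b3$segments$A) + nrow(b3$segments$B), 12L)
  # the shared edge appears once in EACH label's set
  shared <- intersect(boundary_keys(b3)$A, boundary_keys(b3)$B)
  expect_length(shared, 1L)
})

test_that("boundaries equal brute-force per-edge classification on random patterns", {
  set.seed(3)
  for (trial in 1:20) {
    side <- sample(4:12, 1)
    g <- hex_grid(c(0, side), c(0, side), side)
    cells <- expand.grid(q = 0:(side - 1), r = 0:(side - 1))
    keep <- runif(nrow(cells)) < 0.5
    if (!any(keep)) next
    cells <- cells[keep, , drop = FALSE]
    cells$label <- sample(c("A", "B", "C"), nrow(cells), replace = TRUE)
    agg <- aggregate_from_pattern(g, cells)
    got <- boundary_keys(extract_label_boundaries(agg, g, "lab"))
    want <- oracle_boundaries(g, cells)
    expect_setequal(names(got), names(want))
    for (lab in names(want)) expect_setequal(got[[lab]], want[[lab]])
  }
})

test_that("a simply-connected region's outline closes: every vertex has even degree", {
  g <- hex_grid(c(0, 10), c(0, 10), 6)
  blob <- data.frame(q = c(2, 3, 2, 3, 4, 2), r = c(2, 2, 3, 3, 2, 4),
                     label = "A")
  agg <- aggregate_from_pattern(g, blob)
  b <- extract_label_boundaries(agg, g, "lab")
  df <- b$segments$A
  verts <- c(paste(df$i1, df$j1), paste(df$i2, df$j2))
  expect_true(all(table(verts) %% 2 == 0))
})

test_that("no boundary segment separates two occupied same-majority cells", {
  set.seed(9)
  side <- 10
  g <- hex_grid(c(0, side), c(0, side), side)
  cells <- expand.grid(q = 0:(side - 1), r = 0:(side - 1))
  cells <- cells[runif(nrow(cells)) < 0.6, ]
  cells$label <- sample(c("A", "B"), nrow(cells), replace = TRUE)
  agg <- aggregate_from_pattern(g, cells)
  b <- extract_label_boundaries(agg, g, "lab")
  keys <- boundary_keys(b)
  # interior same-label edges were suppressed on both sides: the same segment
  # may appear in two different labels' sets, never twice in one label's set
  for (lab in names(keys)) expect_false(anyDuplicated(keys[[lab]]) > 0)
  want <- oracle_boundaries(g, cells)
  for (lab in names(keys)) expect_setequal(keys[[lab]], want[[lab]])
})

test_that("doubling nbins never decreases the number of occupied cells", {
  emb <- make_mixture_embedding(n_cells = 1000, k = 4, seed = 13)
  xr <- range(emb$table$x); yr <- range(emb$table$y)
  occupied <- function(nb) {
    nrow(hex_aggregate(emb$table, hex_grid(xr, yr, nb))$cells)
  }
  for (nb in c(4, 8, 16, 32)) expect_gte(occupied(2 * nb), occupied(nb))
})

test_that("hex figures render fills below label-colored boundary strokes", {
  emb <- make_mixture_embedding(n_cells = 400, k = 2, expr_high_clusters = 1,
                                seed = 6)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 8)
  agg <- hex_aggregate(emb$table, g, "expr", "cluster")
  b <- extract_label_boundaries(agg, g, "cluster")
  els <- svg_elements(render_tmp_svg(hex_plot(agg, b, "expr", legend = FALSE)))
  cells <- which(els$class == "hexcell")
  bnd <- which(els$class == "boundary")
  expect_identical(length(cells), nrow(agg$cells))
  expect_gt(length(bnd), 0)
  expect_true(min(bnd) > max(cells)) # strokes above fills
  expect_length(unique(els$stroke[bnd]), 2L) # one color per label
  # distinct means map to distinct fills
  expect_gt(length(unique(els$fill[cells])), 1L)
  # empty boundary set: fills only
  els0 <- svg_elements(render_tmp_svg(hex_plot(agg, NULL, "expr", legend = FALSE)))
  expect_false(any(els0$class == "boundary"))
})

test_that("hex figure construction validates its variables", {
  emb <- make_mixture_embedding(n_cells = 100, k = 2, seed = 1)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 5)
  agg <- hex_aggregate(emb$table, g, "expr", "cluster")
  expect_error(hex_plot(agg, NULL, "nope"), class = "spotlayer_name_error")
  expect_error(extract_label_boundaries(agg, g, "expr"),
               class = "spotlayer_name_error")
})

test_that("the aggregate TSV table sums to the input point count", {
  emb <- make_mixture_embedding(n_cells = 300, k = 3, seed = 8)
  g <- hex_grid(range(emb$table$x), range(emb$table$y), 7)
  agg <- hex_aggregate(emb$table, g, "expr", "cluster")
  path <- tempfile(fileext = ".tsv")
  write_hex_table(agg, path)
  df <- read.delim(path)
  expect_identical(sum(df$count), 300L)
  expect_true(all(c("q", "r", "count", "mean_expr", "majority_cluster",
                    "tally_cluster") %in% names(df)))
})
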