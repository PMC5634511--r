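test_that("water balance is rainfall minus evapotranspiration, floored at zero", {
  expect_equal(water_balance(100, 40), 60)
  expect_equal(water_balance(30, 50), 0)
  set.seed(1)
  p <- matrix(runif(200, 0, 150), 10, 20)
  a <- matrix(runif(200, 0, 100), 10, 20)
  r <- water_balance(p, a)
  # elementwise oracle by direct loop
  for (i in sample(200, 25))
    expect_identical(r[i], max(p[i] - a[i], 0))
  expect_equal(sum(r), sum(pmax(p - a, 0)))
  expect_error(water_balance(-1, 0), "non-negative")
  expect_error(water_balance(0, -1), "non-negative")
})

test_that("contamination tagging applies the per-person footprint and pasture rule", {
  expect_equal(contaminated_fraction(0, 0, 0.7, 100), 0)
  expect_equal(contaminated_fraction(1, 0, 0, 100), 0.0365)
  expect_equal(contaminated_fraction(10, 5, 0.5, 100), 0.865)
  # pasture counts only when cattle are present
  expect_equal(contaminated_fraction(0, 0, 0.5, 100), 0)
  expect_equal(contaminated_fraction(0, 1, 0.5, 100), 0.5)
  # capped at the full cell
  expect_equal(contaminated_fraction(1e6, 10, 1, 100), 1)
  expect_error(contaminated_fraction(1, 0, 0, 0), "positive")
  expect_error(contaminated_fraction(-1, 0, 0, 100), "non-negative")
})

test_that("accumulation on a chain dilutes the tagged headwater", {
  net <- make_chain_network(3)
  acc <- accumulate_flow(net, runoff = c(1, 1, 1), source_frac = c(1, 0, 0))
  expect_equal(acc$tagged[3] / acc$total[3], 1 / 3)
  full <- accumulate_flow(net, runoff = c(1, 1, 1), source_frac = c(1, 1, 1))
  expect_equal(full$tagged, full$total)
  dry <- accumulate_flow(net, runoff = c(0, 0, 0), source_frac = c(1, 1, 1))
  expect_true(all(dry$total == 0) && all(dry$tagged == 0))
})

test_that("a cyclic network is rejected", {
  net <- make_chain_network(3)
  net$downstream <- c(2L, 3L, 1L)  # cycle
  expect_error(accumulate_flow(net, c(1, 1, 1), c(0, 0, 0)), "cyclic")
  expect_error(validate_flow_network(net))
})

test_that("index boundary semantics: full tagging gives 100, no water gives 0", {
  expect_equal(index_from_accumulation(5, 5), 100)
  expect_equal(index_from_accumulation(0, 0), 0)
  expect_equal(index_from_accumulation(1, 3), 100 / 3)
  expect_error(index_from_accumulation(4, 3), "exceeds")
})

test_that("D8 pointers on a tilted plane all share the downslope direction", {
  g <- make_tilted_grid(8, 6, seed = 1)  # elevation increases with row
  net <- derive_flow_network(g)
  nr <- g$n_rows
  cell <- function(r, c) as.integer(r + (c - 1) * nr)
  for (c in 1:6) for (r in 2:8)
    expect_identical(net$downstream[cell(r, c)], cell(r - 1, c))
  expect_true(all(is.na(net$downstream[cell(1, 1:6)])))
})

test_that("on a cone all paths reach the single low corner", {
  nr <- 9; nc <- 9
  elev <- outer(seq_len(nr), seq_len(nc),
                function(r, c) sqrt((r - 1)^2 + (c - 1)^2))
  net <- derive_flow_network(list(elevation = elev, cell_size = 1))
  for (start in seq_len(nr * nc)) {
    cell <- start
    while (!is.na(net$downstream[cell])) cell <- net$downstream[cell]
    expect_identical(cell, 1L)  # corner (1,1)
  }
})

test_that("derived networks on random pit-filled grids are acyclic and consistent", {
  for (seed in c(3, 12)) {
    g <- generate_landscape(30, 30, seed = seed)
    net <- derive_flow_network(g)
    expect_true(validate_flow_network(net))
  }
  # a raw pit must be refused
  elev <- matrix(1, 5, 5); elev[3, 3] <- 0
  expect_error(derive_flow_network(list(elevation = elev, cell_size = 1)),
               "pit_fill")
})

test_that("pipeline indices equal the upstream-enumeration oracle everywhere", {
  for (seed in c(21, 22)) {
    g <- generate_landscape(25, 25, seed = seed)
    net <- derive_flow_network(g)
    runoff <- water_balance(g$precip, g$aet)
    frac <- contaminated_fraction(g$population, g$cattle, g$pasture_frac,
                                  g$cell_size^2)
    acc <- accumulate_flow(net, runoff, frac)
    idx <- index_from_accumulation(acc$tagged, acc$total)
    oracle <- vapply(seq_len(625), function(cc)
      upstream_index_oracle(net, runoff, frac, cc), numeric(1))
    expect_equal(idx, oracle, tolerance = 1e-9)
  }
})

test_that("routed indices stay in [0, 100] and tagged water never exceeds total", {
  for (seed in 1:4) {
    g <- generate_landscape(15, 15, seed = seed)
    ri <- route_indices(g)
    expect_true(all(ri$human_index >= 0 & ri$human_index <= 100))
    expect_true(all(ri$tree_index >= 0 & ri$tree_index <= 100))
  }
})

test_that("more upstream tree cover never lowers a downstream tree index, and
           untagged dilution never raises it", {
  g <- generate_landscape(10, 10, seed = 6)
  net <- derive_flow_network(g)
  runoff <- water_balance(g$precip, g$aet)
  base_acc <- accumulate_flow(net, runoff, g$tree_frac)
  base <- index_from_accumulation(base_acc$tagged, base_acc$total)
  set.seed(99)
  for (cell in sample(100, 8)) {
    tf <- as.vector(g$tree_frac)
    tf[cell] <- min(1, tf[cell] + 0.3)
    acc <- accumulate_flow(net, runoff, tf)
    expect_true(all(index_from_accumulation(acc$tagged, acc$total) >=
                      base - 1e-9))
    ro <- as.vector(runoff)
    ro[cell] <- ro[cell] + 50  # extra water, tagged only by this cell's share
    acc2 <- accumulate_flow(net, ro, as.vector(g$tree_frac))
    # cells downstream of an added untagged source cannot gain index
    downstream_set <- function(c0) {
      out <- integer(0)
      while (!is.na(net$downstream[c0])) { c0 <- net$downstream[c0]; out <- c(out, c0) }
      out
    }
    ds <- downstream_set(cell)
    if (length(ds) && g$tree_frac[cell] < min(base[ds]) / 100) {
      idx2 <- index_from_accumulation(acc2$tagged, acc2$total)
      expect_true(all(idx2[ds] <= base[ds] + 1e-9))
    }
  }
})

test_that("mass is conserved at every outlet", {
  g <- generate_landscape(20, 20, seed = 13)
  net <- derive_flow_network(g)
  runoff <- as.vector(water_balance(g$precip, g$aet))
  acc <- accumulate_flow(net, runoff, rep(0, 400))
  area <- g$cell_size^2
  for (outlet in which(is.na(net$downstream))) {
    catchment <- c(outlet, watershedd:::upstream_cells(net, outlet))
    expect_equal(acc$total[outlet], sum(runoff[catchment]) * area,
                 tolerance = 1e-9)
  }
})

test_that("cluster aggregation averages the cells inside the window", {
  g <- make_tilted_grid(6, 6, cell_size = 1000, seed = 2)
  ri <- route_indices(g)
  # window that covers exactly the center cell of (3,3)
  one <- aggregate_at_cluster(ri, data.frame(cluster_id = 1, x_true = 2500,
                                             y_true = 2500), window = 999)
  expect_equal(one$n_cells, 1)
  expect_equal(one$human_index, ri$human_index[3, 3])
  # 3x3 window: arithmetic mean of the 9 values
  nine <- aggregate_at_cluster(ri, data.frame(cluster_id = 1, x_true = 2500,
                                              y_true = 2500), window = 3000)
  expect_equal(nine$n_cells, 9)
  expect_equal(nine$tree_index, mean(ri$tree_index[2:4, 2:4]))
  # a uniform field is window-invariant
  ones <- ri
  ones$human_index[] <- 42
  for (w in c(1500, 5000, 11000))
    expect_equal(aggregate_at_cluster(ones, data.frame(
      cluster_id = 1, x_true = 3000, y_true = 3000), w)$human_index, 42)
  expect_error(aggregate_at_cluster(ri, data.frame(cluster_id = 7, x_true = 1e6,
                                                   y_true = 1e6), 1000),
               "no grid cells")
})
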