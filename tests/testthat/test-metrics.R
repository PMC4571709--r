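test_that("linkage density and connectance follow their identities", {
  chain <- make_web(c("a", "b"), c("b", "c"))
  expect_equal(linkage_density(chain), 2 / 3)
  full <- food_web(expand.grid(prey = letters[1:4], predator = letters[1:4],
                               stringsAsFactors = FALSE))
  expect_equal(connectance(full), 1)
  for (s in 1:5) {
    w <- random_web(9, 0.3, seed = s, allow_self = TRUE)
    expect_identical(linkage_density(w) * n_species(w), as.numeric(n_links(w)))
    expect_identical(connectance(w) * n_species(w)^2, as.numeric(n_links(w)))
    deg_in <- mean(table(factor(w$links$predator, levels = w$nodes)))
    expect_equal(deg_in, linkage_density(w))
  }
})

test_that("percent of cannibals counts self-links against S", {
  w <- make_web(c("a", "a"), c("a", "b"), c("b", "c"), nodes = letters[1:4])
  expect_equal(percent_cannibals(w), 25)
  expect_equal(percent_cannibals(make_web(c("a", "b"))), 0)
  for (s in 1:5) {
    w <- random_web(8, 0.3, seed = 50 + s, allow_self = TRUE)
    direct <- sum(w$links$prey == w$links$predator)
    expect_equal(percent_cannibals(w), 100 * direct / 8)
  }
})

test_that("percent in loops counts members of directed cycles, not cannibals", {
  w <- make_web(c("a", "b"), c("b", "a"), nodes = c("a", "b", "c"))
  expect_equal(percent_in_loops(w), 100 * 2 / 3, tolerance = 1e-12)
  acyclic <- make_web(c("a", "b"), c("b", "c"), c("a", "c"))
  expect_equal(percent_in_loops(acyclic), 0)
  selfy <- make_web(c("a", "a"), c("a", "b"))
  expect_equal(percent_in_loops(selfy), 0)
  w6 <- make_web(c("a", "b"), c("b", "c"), c("c", "a"),
                 c("c", "d"), c("d", "e"), c("e", "f"))
  expect_equal(percent_in_loops(w6), 50)
  for (s in 1:20) {
    w <- random_web(10, 0.2, seed = 200 + s, allow_self = TRUE)
    expect_equal(percent_in_loops(w), 100 * oracle_loop_nodes(w) / 10)
  }
})

test_that("mean path length matches the all-pairs oracle", {
  full <- food_web(expand.grid(prey = letters[1:4], predator = letters[1:4],
                               stringsAsFactors = FALSE))
  expect_equal(mean_path_length(full), 1)
  path3 <- make_web(c("a", "b"), c("b", "c"))
  expect_equal(mean_path_length(path3), 4 / 3)
  expect_error(mean_path_length(food_web(nodes = c("a", "b"))), "no")
  for (s in 1:15) {
    w <- random_web(12, 0.15, seed = 300 + s)
    if (nrow(trophoweb:::undirected_edge_matrix(w)) == 0) next
    expect_equal(mean_path_length(w), oracle_mean_path(w), tolerance = 1e-12)
  }
})

test_that("mean clustering matches the triangle-counting oracle", {
  tri <- make_web(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_equal(mean_clustering(tri), 1)
  star <- make_web(c("a", "b"), c("a", "c"), c("a", "d"))
  expect_equal(mean_clustering(star), 0)
  for (s in 1:15) {
    w <- random_web(10, 0.25, seed = 400 + s, allow_self = TRUE)
    expect_equal(mean_clustering(w), oracle_mean_clustering(w),
                 tolerance = 1e-12)
  }
})

test_that("short-weighted trophic levels average shortest and prey-averaged", {
  w <- make_web(c("b1", "herb"), c("b1", "cons"), c("herb", "cons"))
  tl <- trophic_levels(w)
  expect_equal(unname(tl[c("b1", "herb", "cons")]), c(1, 2, 2.25))

  chain <- make_web(c("a", "b"), c("b", "c"))
  expect_equal(as.numeric(trophic_levels(chain)), c(1, 2, 3))

  # self-links excluded from the prey set
  cann <- make_web(c("a", "b"), c("b", "b"))
  expect_equal(as.numeric(trophic_levels(cann)), c(1, 2))

  expect_error(trophic_levels(make_web(c("a", "b"), c("b", "a"))), "basal")
  island <- make_web(c("a", "b"), c("c", "d"), c("d", "c"))
  expect_error(trophic_levels(island), "c|d")
})

test_that("on acyclic webs the linear system equals topological propagation", {
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 8
    ids <- sprintf("n%02d", 1:n)
    # random DAG: links only from lower to higher index
    idx <- which(upper.tri(matrix(TRUE, n, n)) &
                   matrix(runif(n * n) < 0.35, n, n), arr.ind = TRUE)
    if (!nrow(idx)) next
    w <- food_web(data.frame(prey = ids[idx[, 1]], predator = ids[idx[, 2]]),
                  nodes = ids)
    if (percent_in_loops(w) != 0) fail("DAG construction broken")
    tl <- attr(trophic_levels(w), "prey_averaged")
    # oracle: propagate in index order
    prey_of <- split(w$links$prey, w$links$predator)
    oracle <- stats::setNames(rep(1, n), ids)
    for (i in ids) {
      if (!is.null(prey_of[[i]])) {
        oracle[i] <- 1 + mean(oracle[prey_of[[i]]])
      }
    }
    expect_equal(tl, oracle, tolerance = 1e-10)
  }
})

test_that("omnivory indexes the spread of prey trophic levels", {
  # consumer with one prey: index 0, not an omnivore
  w1 <- make_web(c("a", "b"))
  o1 <- omnivory(w1)
  expect_equal(unname(o1$index["b"]), 0)
  expect_equal(o1$pct_omni, 0)

  # consumer eating TL 1 and TL 3: population SD = 1, counted as omnivore
  w <- make_web(c("a", "b"), c("b", "c"), c("a", "d"), c("c", "d"))
  o <- omnivory(w)
  expect_equal(unname(o$index["d"]), 1)
  expect_equal(o$pct_omni, 25)

  # six-node web, indices match direct evaluation
  w6 <- make_web(c("p1", "h1"), c("p2", "h1"), c("p1", "h2"),
                 c("h1", "c1"), c("h2", "c1"), c("p1", "c1"),
                 c("c1", "top"), c("h1", "top"))
  tl <- trophic_levels(w6)
  o6 <- omnivory(w6, tl)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(unname(o6$index["c1"]),
               pop_sd(tl[c("h1", "h2", "p1")]))
  expect_equal(unname(o6$index["top"]), pop_sd(tl[c("c1", "h1")]))
  expect_equal(o6$mean_omni, mean(o6$index[c("h1", "c1", "top")]))
})

test_that("degree summary tabulates survival and fits the exponential rate", {
  # 4-cycle: all degrees 1 in each direction
  w <- make_web(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))
  ds <- degree_summary(w)
  expect_equal(ds$in_deg$survival$p, 1)
  expect_equal(ds$in_deg$lambda, 1)

  w2 <- make_web(c("a", "e"), c("b", "e"), c("c", "e"), c("d", "e"),
                 c("a", "f"), c("b", "f"), c("a", "g"), nodes = letters[1:7])
  d2 <- degree_summary(w2)
  # in-degrees {4,2,1} over e,f,g: P(K >= 2) among all seven nodes
  surv <- d2$in_deg$survival
  expect_equal(surv$p[surv$k == 2], 2 / 7)
  expect_equal(d2$in_deg$lambda, 1 / mean(c(4, 2, 1)))
})

test_that("the MLE recovers a known exponential rate from discretized draws", {
  set.seed(7)
  deg <- pmax(1L, round(stats::rexp(500, rate = 0.2)))
  lambda_hat <- 1 / mean(deg)
  expect_lt(abs(lambda_hat - 0.2) / 0.2, 0.15)
})

test_that("metric reports expose the full key set and survive edge cases", {
  w <- two_triangles()
  expect_error(metrics_report(w), NA)  # no basal nodes: TL entries become NA
  rep <- metrics_report(w)
  expect_true(is.na(rep$meanSWTL))
  expect_equal(rep$S, 6)
  keys <- c("S", "L", "LD", "C", "pctOmni", "pctCan", "pctLoops",
            "meanPath", "meanOmni", "meanSWTL", "meanClust", "modularity")
  expect_true(all(keys %in% names(rep)))
})

test_that("removing a link never increases density-type metrics", {
  w <- random_web(8, 0.35, seed = 901, allow_self = TRUE)
  for (r in sample(n_links(w), 5)) {
    smaller <- food_web(w$links[-r, , drop = FALSE], nodes = w$nodes)
    expect_lte(connectance(smaller), connectance(w))
    expect_lte(linkage_density(smaller), linkage_density(w))
    expect_lte(percent_cannibals(smaller), percent_cannibals(w))
    expect_lte(percent_in_loops(smaller), percent_in_loops(w))
  }
})
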