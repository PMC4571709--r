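test_that("modularity closed forms hold exactly", {
  tri <- two_triangles()
  expect_equal(modularity_value(tri, triangle_partition()), 0.5)
  one <- stats::setNames(rep(1, 6), letters[1:6])
  expect_equal(modularity_value(tri, one), 0)
  # uncovered node errors
  expect_error(modularity_value(tri, stats::setNames(1:5, letters[1:5])),
               "cover")
})

test_that("modularity matches a term-by-term oracle and igraph on random webs", {
  for (s in 1:15) {
    w <- random_web(9, 0.3, seed = 600 + s, allow_self = TRUE)
    if (nrow(trophoweb:::undirected_edge_matrix(w)) == 0) next
    m <- stats::setNames(sample(1:3, 9, replace = TRUE), w$nodes)
    expect_equal(modularity_value(w, m), oracle_modularity(w, m),
                 tolerance = 1e-12)
    g <- trophoweb:::undirected_projection(w)
    expect_equal(modularity_value(w, m),
                 igraph::modularity(g, m[w$nodes]), tolerance = 1e-12)
  }
})

test_that("modularity is invariant under module relabeling", {
  w <- random_web(10, 0.3, seed = 777)
  m <- stats::setNames(sample(1:4, 10, replace = TRUE), w$nodes)
  perm <- sample(4)
  m2 <- stats::setNames(perm[m], names(m))
  expect_equal(modularity_value(w, m), modularity_value(w, m2))
})

test_that("annealing recovers planted cliques and beats random partitions", {
  # two disjoint 5-cliques
  ids <- sprintf("n%02d", 1:10)
  block <- function(off) {
    idx <- t(utils::combn(5, 2)) + off
    data.frame(prey = ids[idx[, 1]], predator = ids[idx[, 2]])
  }
  w <- food_web(rbind(block(0), block(5)), nodes = ids)
  truth <- stats::setNames(rep(1:2, each = 5), ids)
  hits <- 0
  for (s in 1:20) {
    p <- anneal_partition(w, reduced_schedule(), seed = s)
    nmi <- igraph::compare(p$assignment, truth[names(p$assignment)],
                           method = "nmi")
    hits <- hits + (nmi == 1)
    rnd <- stats::setNames(sample(1:2, 10, replace = TRUE), ids)
    expect_gte(p$M, modularity_value(w, rnd))
  }
  expect_gte(hits, 19)
})

test_that("a complete graph is best left unpartitioned (M = 0)", {
  ids <- letters[1:5]
  idx <- t(utils::combn(5, 2))
  w <- food_web(data.frame(prey = ids[idx[, 1]], predator = ids[idx[, 2]]),
                nodes = ids)
  p <- anneal_partition(w, seed = 3)
  expect_equal(p$M, 0, tolerance = 1e-12)
})

test_that("annealed partitions carry consistent bookkeeping", {
  w <- random_web(15, 0.25, seed = 12)
  p <- anneal_partition(w, reduced_schedule(), seed = 5)
  el <- trophoweb:::undirected_edge_matrix(w)
  Lp <- nrow(el)
  expect_equal(sum(p$d_s), 2 * Lp)
  m <- p$assignment[w$nodes]
  between <- sum(m[el[, 1]] != m[el[, 2]])
  expect_equal(sum(p$I_s) + between, Lp)
  expect_equal(p$M, modularity_value(w, p$assignment))
  expect_true(p$M >= -1 && p$M <= 1)
})

test_that("replicate ensembles are deterministic under the master seed", {
  w <- random_web(12, 0.3, seed = 8)
  e1 <- replicate_partitions(w, 5, seed = 99, schedule = reduced_schedule())
  e2 <- replicate_partitions(w, 5, seed = 99, schedule = reduced_schedule())
  expect_identical(e1$M, e2$M)
  expect_identical(e1$designated_index, e2$designated_index)
  expect_identical(e1$designated$assignment, e2$designated$assignment)
  e3 <- replicate_partitions(w, 1, seed = 1)
  expect_identical(e3$designated_index, 1L)
})

test_that("degree-preserving randomization is degree-exact and loop-free", {
  for (s in 1:10) {
    w <- random_web(12, 0.25, seed = 700 + s, allow_self = TRUE)
    g <- trophoweb:::undirected_projection(w)
    if (igraph::ecount(g) < 2) next
    r <- randomize_degree_preserving(w, seed = s)
    gr <- trophoweb:::undirected_projection(r)
    expect_identical(igraph::degree(g), igraph::degree(gr))
    expect_equal(sum(r$links$prey == r$links$predator), 0)
    expect_false(any(duplicated(r$links)))
  }
})

test_that("a triangle cannot be rewired; a 4-cycle stays 2-regular", {
  tri <- make_web(c("a", "b"), c("b", "c"), c("c", "a"))
  r <- randomize_degree_preserving(tri, seed = 1)
  g <- trophoweb:::undirected_projection(r)
  expect_equal(unname(igraph::degree(g)), rep(2, 3))
  cyc <- make_web(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))
  for (s in 1:5) {
    rc <- randomize_degree_preserving(cyc, seed = s)
    expect_equal(unname(sort(igraph::degree(
      trophoweb:::undirected_projection(rc)))), rep(2, 4))
  }
  lone <- make_web(c("a", "b"))
  expect_warning(randomize_degree_preserving(lone), "few")
})

test_that("null test p-value follows the +1 exceedance formula", {
  w <- random_web(14, 0.25, seed = 21)
  nt <- null_modularity_test(w, n = 19, seed = 4,
                             schedule = reduced_schedule(),
                             null_schedule = reduced_schedule())
  expect_equal(nt$p_value,
               (1 + sum(nt$replicates >= nt$M_emp)) / (19 + 1))
  expect_gt(nt$p_value, 0)
  expect_lte(nt$p_value, 1)
  expect_equal(length(nt$replicates), 19)
  expect_equal(nt$mean, mean(nt$replicates))
  # supplied M_emp below every null value gives the complement extreme
  nt2 <- null_modularity_test(w, n = 4, seed = 4, M_emp = -1,
                              null_schedule = reduced_schedule())
  expect_equal(nt2$p_value, 1)
})

test_that("a strongly modular planted web is significant against its nulls", {
  pw <- planted_module_web(seed = 31)
  nt <- null_modularity_test(pw$web, n = 49, seed = 5,
                             schedule = reduced_schedule(),
                             null_schedule = reduced_schedule())
  expect_lte(nt$p_value, 0.02)
  # every null replicate is below the planted-structure modularity
  expect_lt(nt$mean + 3 * nt$sd, nt$M_emp)
})

test_that("exhaustive search equals the annealer on small webs", {
  for (s in 1:10) {
    w <- niche_model_web(4 + (s %% 4), 0.25, seed = 800 + s)
    ex <- tryCatch(exhaustive_partition(w), error = function(e) NULL)
    if (is.null(ex)) next
    an <- anneal_partition(w, seed = 900 + s)
    expect_equal(an$M, ex$M, tolerance = 1e-12)
  }
  expect_error(exhaustive_partition(random_web(11, 0.3, seed = 1)), "10")
})
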