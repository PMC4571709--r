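test_that("construction registers nodes, links, and isolated species", {
  w <- make_web(c("a", "b"), c("b", "c"))
  expect_s3_class(w, "food_web")
  expect_equal(n_species(w), 3)
  expect_equal(n_links(w), 2)

  w2 <- food_web(data.frame(prey = "a", predator = "b"), nodes = c("a", "b", "z"))
  expect_equal(n_species(w2), 3)
  expect_true("z" %in% w2$nodes)
})

test_that("duplicate links collapse with a warning", {
  expect_warning(
    w <- make_web(c("a", "b"), c("a", "b")),
    "duplicate")
  expect_equal(n_links(w), 1)
})

test_that("self-links (cannibals) are permitted and counted once", {
  w <- make_web(c("a", "a"), c("a", "b"))
  expect_equal(n_links(w), 2)
  expect_equal(percent_cannibals(w), 50)
})

test_that("read_web validates headers, rows and attribute codes", {
  edge <- tempfile(fileext = ".csv")
  writeLines(c("prey,predator", "alga,krill", "krill,cod"), edge)
  w <- read_web(edge)
  expect_equal(n_species(w), 3)
  expect_equal(n_links(w), 2)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("prey,predator", "alga,krill", ",cod"), bad)
  expect_error(read_web(bad), "line 3")

  attrs <- tempfile(fileext = ".csv")
  writeLines(c("id,habitat,group", "alga,P,basal", "krill,P,zooplankton",
               "cod,BP,fish", "worm,B,benthos"), attrs)
  w2 <- read_web(edge, attrs)
  expect_equal(n_species(w2), 4)  # worm joins as an isolated node
  expect_equal(w2$attributes$habitat[w2$attributes$id == "cod"], "BP")

  badattr <- tempfile(fileext = ".csv")
  writeLines(c("id,habitat,group", "alga,X,basal"), badattr)
  expect_error(read_web(edge, badattr), "habitat")
})

test_that("induced_subweb keeps exactly the within-subset links", {
  meta <- make_web(c("a", "b"), c("b", "c"), c("a", "c"), name = "meta")
  sub <- induced_subweb(meta, c("a", "b"))
  expect_setequal(sub$nodes, c("a", "b"))
  expect_equal(sub$links, data.frame(prey = "a", predator = "b"))

  all_sub <- induced_subweb(meta, meta$nodes)
  expect_setequal(all_sub$nodes, meta$nodes)
  expect_equal(nrow(all_sub$links), n_links(meta))

  expect_error(induced_subweb(meta, c("a", "zz")), "zz")
  expect_error(induced_subweb(meta, character(0)), "empty")
})

test_that("induced_subweb matches the brute-force link filter and is monotone", {
  for (s in 1:10) {
    meta <- random_web(10, 0.25, seed = s, allow_self = TRUE)
    members <- sample(meta$nodes, 5)
    sub <- induced_subweb(meta, members)
    orc <- oracle_induced_links(meta, members)
    expect_setequal(paste(sub$links$prey, sub$links$predator),
                    paste(orc$prey, orc$predator))
    # monotonicity: links of a subset are a subset of a superset's links
    sup <- induced_subweb(meta, union(members, sample(meta$nodes, 3)))
    expect_true(all(paste(sub$links$prey, sub$links$predator) %in%
                      paste(sup$links$prey, sup$links$predator)))
    # degree never exceeds the meta-web degree
    dm <- trophoweb:::total_degree(meta)
    ds <- trophoweb:::total_degree(sub)
    expect_true(all(ds[names(ds)] <= dm[names(ds)]))
  }
})

test_that("add_species equals induction on the union, for all small cases", {
  for (s in 1:20) {
    meta <- random_web(8, 0.3, seed = 100 + s)
    x <- sample(meta$nodes, sample(2:6, 1))
    y <- sample(meta$nodes, sample(1:3, 1))
    left <- add_species(induced_subweb(meta, x), meta, y)
    right <- induced_subweb(meta, union(x, y))
    expect_setequal(left$nodes, right$nodes)
    expect_setequal(paste(left$links$prey, left$links$predator),
                    paste(right$links$prey, right$links$predator))
  }
})

test_that("add_species is idempotent for resident species and counts new links", {
  meta <- make_web(c("a", "b"), c("b", "c"), c("x", "b"), c("c", "x"),
                   name = "meta")
  sub <- induced_subweb(meta, c("a", "b", "c"))
  same <- add_species(sub, meta, c("a", "b"))
  expect_setequal(same$nodes, sub$nodes)
  expect_equal(n_links(same), n_links(sub))
  # newcomer x has one link into the residents and one from them
  grown <- add_species(sub, meta, "x")
  expect_equal(n_links(grown), n_links(sub) + 2)
  expect_error(add_species(sub, meta, "nope"), "nope")
})

test_that("shared_unique counts intersections and symmetric differences", {
  a <- make_web(c("a", "b"), c("b", "c"))
  expect_equal(shared_unique(a, a), c(shared = 3, unique = 0))
  b <- make_web(c("x", "y"))
  expect_equal(shared_unique(a, b), c(shared = 0, unique = 5))
  c_ <- make_web(c("b", "c"), c("c", "d"))
  expect_equal(shared_unique(a, c_), c(shared = 2, unique = 2))
})

test_that("GraphML round-trips nodes, links and attributes", {
  attrs <- data.frame(id = c("a", "b", "c"),
                      habitat = c("B", "P", NA),
                      group = c("basal", "fish", NA))
  w <- food_web(data.frame(prey = c("a", "a"), predator = c("b", "c")),
                attributes = attrs, name = "toy")
  path <- tempfile(fileext = ".graphml")
  write_graphml(w, path)
  w2 <- read_graphml(path)
  expect_setequal(w2$nodes, w$nodes)
  expect_setequal(paste(w2$links$prey, w2$links$predator),
                  paste(w$links$prey, w$links$predator))
  a2 <- w2$attributes[match(w$attributes$id, w2$attributes$id), ]
  expect_equal(a2$habitat, w$attributes$habitat)
  expect_equal(a2$group, w$attributes$group)
})

test_that("GraphML re-imported by an independent XML parser agrees on S and L", {
  skip_if_not_installed("xml2")
  w <- random_web(7, 0.3, seed = 42)
  path <- tempfile(fileext = ".graphml")
  write_graphml(w, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", ns)), n_species(w))
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", ns)), n_links(w))
})

test_that("JSON reports carry the metric keys at full precision", {
  w <- make_web(c("a", "b"), c("b", "c"))
  rep <- metrics_report(w)
  path <- tempfile(fileext = ".json")
  write_report(unclass(rep), path)
  back <- jsonlite::read_json(path)
  expect_true(all(c("S", "L", "LD", "C") %in% names(back)))
  expect_equal(back$LD, 2 / 3)
})

test_that("species sets deduplicate and read from one-per-line files", {
  s <- species_set(c("a", "b", "a"))
  expect_equal(length(s$members), 2)
  expect_error(species_set(character(0)), "empty")
  f <- tempfile()
  writeLines(c("cod", "", "# comment", "haddock", "cod"), f)
  s2 <- read_species_set(f)
  expect_setequal(s2$members, c("cod", "haddock"))
})
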