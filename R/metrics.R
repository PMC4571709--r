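#' Linkage density and connectance
#'
#' Linkage density LD = L/S (links per species). Connectance C = L/S^2, the
#' fraction of possible directed links realized; the S^2 denominator counts
#' ordered pairs including self-links, appropriate for webs with cannibals.
#'
#' @param web a [food_web].
#' @return a single numeric value at full precision (reports round to 2 dp).
#' @export
linkage_density <- function(web) {
  stopifnot(inherits(web, "food_web"))
  n_links(web) / n_species(web)
}

#' @rdname linkage_density
#' @export
connectance <- function(web) {
  stopifnot(inherits(web, "food_web"))
  n_links(web) / n_species(web)^2
}

#' Percentage of cannibals
#'
#' Cannibals are species with a self-link (feeding on their own
#' trophospecies).
#'
#' @param web a [food_web].
#' @return percentage of S, in `[0, 100]`.
#' @export
percent_cannibals <- function(web) {
  stopifnot(inherits(web, "food_web"))
  100 * sum(web$links$prey == web$links$predator) / n_species(web)
}

#' Percentage of species in loops
#'
#' A species is "in a loop" when it lies on a directed feeding cycle of
#' length >= 2 (mutual predation or longer cycles); self-links are excluded.
#' Computed as membership of a strongly connected component of size >= 2.
#'
#' @param web a [food_web].
#' @return percentage of S.
#' @export
percent_in_loops <- function(web) {
  100 * loop_node_count(web) / n_species(web)
}

loop_node_count <- function(web) {
  stopifnot(inherits(web, "food_web"))
  keep <- web$links$prey != web$links$predator
  g <- igraph::graph_from_data_frame(web$links[keep, , drop = FALSE],
                                     directed = TRUE,
                                     vertices = data.frame(name = web$nodes))
  comp <- igraph::components(g, mode = "strong")
  sum(comp$csize[comp$membership] >= 2)
}

#' Mean shortest path length
#'
#' Average shortest-path length over all ordered pairs of distinct nodes in
#' the largest connected component of the undirected projection (self-links
#' dropped, mutual links collapsed).
#'
#' @param web a [food_web] with at least one non-self link.
#' @return mean path length (>= 1).
#' @export
mean_path_length <- function(web) {
  g <- undirected_projection(web)
  if (igraph::ecount(g) == 0) {
    stop("mean path length undefined: web has no (non-self) links",
         call. = FALSE)
  }
  comp <- igraph::components(g)
  lcc <- which(comp$membership == which.max(comp$csize))
  d <- igraph::distances(g, v = lcc, to = lcc)
  mean(d[row(d) != col(d)])
}

#' Mean clustering coefficient
#'
#' Average of local clustering coefficients on the undirected projection;
#' nodes with fewer than two neighbours contribute 0.
#'
#' @param web a [food_web].
#' @return mean clustering in `[0, 1]`.
#' @export
mean_clustering <- function(web) {
  g <- undirected_projection(web)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Short-weighted trophic levels
#'
#' SWTL_i = (shortest_i + preyavg_i) / 2, where shortest_i is 1 plus the
#' length of the shortest directed chain from any basal node (in-degree 0
#' after removing self-links) to i, and preyavg solves the prey-averaged
#' system TL_i = 1 + mean over prey j of TL_j with basal levels fixed at 1
#' (self-links excluded from the prey set; solved exactly as a linear
#' system).
#'
#' @param web a [food_web] containing at least one basal node; every node
#'   must be reachable from some basal node.
#' @return named numeric vector of SWTL values (basal nodes are exactly 1),
#'   with attributes `"shortest"` and `"prey_averaged"` carrying the two
#'   component level vectors.
#' @export
trophic_levels <- function(web) {
  stopifnot(inherits(web, "food_web"))
  n <- n_species(web)
  ids <- web$nodes
  lk <- web$links[web$links$prey != web$links$predator, , drop = FALSE]
  pi <- match(lk$prey, ids)
  ci <- match(lk$predator, ids)
  indeg <- tabulate(ci, nbins = n)
  basal <- which(indeg == 0L)
  if (!length(basal)) {
    stop("no basal node (in-degree 0 after removing self-links)",
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lk$prey, to = lk$predator), directed = TRUE,
    vertices = data.frame(name = ids))
  d <- igraph::distances(g, v = ids[basal], to = ids, mode = "out")
  short_chain <- apply(d, 2, min)
  unreach <- which(!is.finite(short_chain))
  if (length(unreach)) {
    stop("node(s) with no directed path from a basal node: ",
         paste(ids[unreach], collapse = ", "), call. = FALSE)
  }
  shortest <- short_chain + 1
  # prey-averaged levels: (I - A) x = 1, A row i averages over prey of i
  A <- matrix(0, n, n)
  cons <- setdiff(seq_len(n), basal)
  if (length(pi)) {
    w <- 1 / indeg[ci]
    for (k in seq_along(pi)) A[ci[k], pi[k]] <- A[ci[k], pi[k]] + w[k]
  }
  A[basal, ] <- 0
  M <- diag(n) - A
  preyavg <- tryCatch(solve(M, rep(1, n)),
                      error = function(e)
                        stop("prey-averaged trophic levels not solvable: ",
                             conditionMessage(e), call. = FALSE))
  swtl <- (shortest + preyavg) / 2
  names(swtl) <- names(shortest) <- names(preyavg) <- ids
  attr(swtl, "shortest") <- shortest
  attr(swtl, "prey_averaged") <- preyavg
  swtl
}

#' Omnivory indices
#'
#' Per consumer (>= 1 prey, self-links excluded) the omnivory index is the
#' population standard deviation of its prey's short-weighted trophic
#' levels. `mean_omni` averages the index over consumers with >= 2 prey; a
#' consumer counts as an omnivore when its prey span >= 1 trophic level, and
#' `pct_omni` is the percentage of S that are omnivores.
#'
#' @param web a [food_web].
#' @param tl optional precomputed [trophic_levels] vector.
#' @return list with `pct_omni`, `mean_omni` and the per-consumer `index`
#'   (named vector, consumers with >= 1 prey).
#' @export
omnivory <- function(web, tl = NULL) {
  stopifnot(inherits(web, "food_web"))
  if (is.null(tl)) tl <- trophic_levels(web)
  lk <- web$links[web$links$prey != web$links$predator, , drop = FALSE]
  prey_of <- split(lk$prey, lk$predator)
  if (!length(prey_of)) {
    return(list(pct_omni = 0, mean_omni = NA_real_,
                index = setNames(numeric(0), character(0))))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  idx <- vapply(prey_of, function(p) pop_sd(tl[p]), numeric(1))
  spans <- vapply(prey_of, function(p) diff(range(tl[p])), numeric(1))
  nprey <- lengths(prey_of)
  mean_omni <- if (any(nprey >= 2)) mean(idx[nprey >= 2]) else NA_real_
  list(pct_omni = 100 * sum(spans >= 1) / n_species(web),
       mean_omni = mean_omni,
       index = idx)
}

#' Degree sequences, cumulative distributions and exponential fit
#'
#' In-degree counts a species' prey (generality), out-degree its predators
#' (vulnerability). For each direction the cumulative survival P(K >= k) is
#' tabulated at every observed degree, and an exponential rate is fitted to
#' the positive degrees: by maximum likelihood `lambda = 1/mean(k)` (default)
#' or by log-linear regression of the survival curve (`fit = "loglinear"`),
#' useful for comparing steepness between webs.
#'
#' @param web a [food_web] with at least one link.
#' @param fit `"mle"` or `"loglinear"`.
#' @return list of class `degree_summary` with elements `in_deg` and
#'   `out_deg`, each a list (`degrees`, `survival` data frame `k`,`p`,
#'   `lambda`), plus `fit`.
#' @export
degree_summary <- function(web, fit = c("mle", "loglinear")) {
  stopifnot(inherits(web, "food_web"))
  fit <- match.arg(fit)
  if (n_links(web) < 1) stop("degree summary needs at least one link",
                             call. = FALSE)
  ids <- web$nodes
  indeg <- tabulate(match(web$links$predator, ids), nbins = length(ids))
  outdeg <- tabulate(match(web$links$prey, ids), nbins = length(ids))
  one <- function(deg) {
    ks <- sort(unique(deg))
    surv <- vapply(ks, function(k) mean(deg >= k), numeric(1))
    pos <- deg[deg >= 1]
    lambda <- if (length(pos)) {
      if (fit == "mle") {
        1 / mean(pos)
      } else {
        kk <- sort(unique(pos))
        pp <- vapply(kk, function(k) mean(pos >= k), numeric(1))
        keep <- pp > 0
        -unname(stats::coef(stats::lm(log(pp[keep]) ~ kk[keep]))[2])
      }
    } else NA_real_
    list(degrees = setNames(deg, ids),
         survival = data.frame(k = ks, p = surv),
         lambda = lambda)
  }
  structure(list(in_deg = one(indeg), out_deg = one(outdeg), fit = fit),
            class = "degree_summary")
}

# total degree in the directed web, self-link counted once
total_degree <- function(web) {
  ids <- web$nodes
  indeg <- tabulate(match(web$links$predator, ids), nbins = length(ids))
  outdeg <- tabulate(match(web$links$prey, ids), nbins = length(ids))
  selfd <- tabulate(match(web$links$prey[web$links$prey == web$links$predator],
                          ids), nbins = length(ids))
  setNames(indeg + outdeg - selfd, ids)
}

#' Structural metric report
#'
#' Computes the standard topological metric suite for one web: S, L, linkage
#' density, connectance, percentages of omnivores, cannibals and species in
#' loops, mean path length, mean omnivory, mean short-weighted trophic level
#' and mean clustering. The `modularity` slot is `NA` until filled from an
#' annealed partition (see [anneal_partition]).
#'
#' @param web a [food_web].
#' @param tl optional precomputed [trophic_levels]; when the web has no basal
#'   node the trophic-level-dependent entries are `NA`.
#' @return list of class `metrics_report` with keys
#'   `S,L,LD,C,pctOmni,pctCan,pctLoops,loopNodeCount,meanPath,meanOmni,
#'   meanSWTL,meanClust,modularity`.
#' @export
metrics_report <- function(web, tl = NULL) {
  stopifnot(inherits(web, "food_web"))
  if (is.null(tl)) {
    tl <- tryCatch(trophic_levels(web), error = function(e) NULL)
  }
  om <- if (!is.null(tl)) omnivory(web, tl)
        else list(pct_omni = NA_real_, mean_omni = NA_real_)
  mp <- tryCatch(mean_path_length(web), error = function(e) NA_real_)
  structure(list(
    S = n_species(web),
    L = n_links(web),
    LD = linkage_density(web),
    C = connectance(web),
    pctOmni = om$pct_omni,
    pctCan = percent_cannibals(web),
    pctLoops = percent_in_loops(web),
    loopNodeCount = loop_node_count(web),
    meanPath = mp,
    meanOmni = om$mean_omni,
    meanSWTL = if (!is.null(tl)) mean(tl) else NA_real_,
    meanClust = mean_clustering(web),
    modularity = NA_real_
  ), class = "metrics_report", web_name = web$name)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metric report for '%s'\n", attr(x, "web_name")))
  show <- function(k, v) cat(sprintf("  %-12s %s\n", k,
                                     if (is.na(v)) "--"
                                     else format(round(v, 2), nsmall = 0)))
  for (k in c("S", "L")) show(k, x[[k]])
  for (k in c("LD", "C", "pctOmni", "pctCan", "pctLoops", "meanPath",
              "meanOmni", "meanSWTL", "meanClust", "modularity")) {
    show(k, x[[k]])
  }
  invisible(x)
}
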