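#' Modularity of a partition
#'
#' For a partition of the undirected projection (self-links removed, mutual
#' predation collapsed) into modules s = 1..N_M,
#' \deqn{M = \sum_s \left[ \frac{I_s}{L} - \left(\frac{d_s}{2L}\right)^2 \right]}
#' where L is the undirected link count, I_s the number of links between
#' nodes of module s and d_s the summed degree of its members. M is 0 for a
#' single-module partition and, in expectation, for a random partition.
#'
#' @param web a [food_web] with at least one non-self link.
#' @param membership module assignment: a vector of module ids named by
#'   node, or in the order of `web$nodes`; every node must be covered.
#' @return modularity value in `[-1, 1]`.
#' @export
modularity_value <- function(web, membership) {
  m <- align_membership(web, membership)
  el <- undirected_edge_matrix(web)
  if (nrow(el) == 0) {
    stop("modularity undefined: web has no (non-self) links", call. = FALSE)
  }
  modularity_from_edges(el, m, length(web$nodes))
}

# membership as dense integer vector in web$nodes order
align_membership <- function(web, membership) {
  if (inherits(membership, "module_partition")) {
    membership <- membership$assignment
  }
  if (!is.null(names(membership))) {
    miss <- setdiff(web$nodes, names(membership))
    if (length(miss)) {
      stop("partition does not cover node(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    membership <- membership[web$nodes]
  } else if (length(membership) != length(web$nodes)) {
    stop("unnamed membership must have one entry per node", call. = FALSE)
  }
  if (anyNA(membership)) stop("membership contains NA", call. = FALSE)
  as.integer(factor(membership))
}

modularity_from_edges <- function(el, m, n) {
  L <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  within <- m[el[, 1]] == m[el[, 2]]
  nm <- max(m)
  I_s <- tabulate(m[el[, 1]][within], nbins = nm)
  d_s <- vapply(seq_len(nm), function(s) sum(deg[m == s]), numeric(1))
  sum(I_s / L - (d_s / (2 * L))^2)
}

# per-module link and degree bookkeeping for a partition object
module_stats <- function(web, m) {
  el <- undirected_edge_matrix(web)
  n <- length(web$nodes)
  L <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  nm <- max(m)
  within <- if (L) m[el[, 1]] == m[el[, 2]] else logical(0)
  I_s <- tabulate(m[el[, 1]][within], nbins = nm)
  d_s <- vapply(seq_len(nm), function(s) sum(deg[m == s]), numeric(1))
  list(I_s = I_s, d_s = d_s, L_undirected = L)
}

new_module_partition <- function(web, m, seed = NULL) {
  st <- module_stats(web, m)
  M <- if (st$L_undirected > 0) {
    sum(st$I_s / st$L_undirected - (st$d_s / (2 * st$L_undirected))^2)
  } else 0
  structure(list(
    assignment = setNames(as.integer(m), web$nodes),
    n_modules = max(m),
    M = M,
    I_s = st$I_s,
    d_s = st$d_s,
    L_undirected = st$L_undirected,
    seed = seed,
    web_name = web$name
  ), class = "module_partition")
}

#' Build a module partition from a given assignment
#'
#' @param web a [food_web].
#' @param membership node to module assignment (named or in node order).
#' @return a `module_partition`: assignment (named, dense ids 1..N_M),
#'   module count, modularity `M`, per-module within-link counts `I_s` and
#'   degree sums `d_s`.
#' @export
module_partition <- function(web, membership) {
  new_module_partition(web, align_membership(web, membership))
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition of '%s': %d modules, M = %.4f>\n",
              x$web_name, x$n_modules, x$M))
  invisible(x)
}

#' Annealing schedules
#'
#' `sa_schedule()` is the full (headline) schedule: the initial temperature
#' is calibrated from trial moves so early acceptance is about 0.8, cooling
#' factor 0.995, S^2 single-node moves plus S collective (merge/split) moves
#' per temperature, stopping at `tmin` or after `stagnation` temperatures
#' without improvement. `reduced_schedule()` is a quarter-strength variant
#' (fewer moves, faster cooling) intended for null-model replicates, where
#' thousands of anneals are needed.
#'
#' @param t0 initial temperature (`NULL` = calibrate from trial moves).
#' @param cooling multiplicative cooling factor in (0,1).
#' @param fmove node moves per temperature as a multiple of S^2.
#' @param fcollective merge/split moves per temperature as a multiple of S.
#' @param tmin temperature floor.
#' @param stagnation stop after this many temperatures without improvement.
#' @return a list of class `sa_schedule`.
#' @export
sa_schedule <- function(t0 = NULL, cooling = 0.995, fmove = 1,
                        fcollective = 1, tmin = 1e-6, stagnation = 50) {
  stopifnot(cooling > 0, cooling < 1, fmove > 0, fcollective >= 0,
            tmin > 0, stagnation >= 1)
  structure(list(t0 = t0, cooling = cooling, fmove = fmove,
                 fcollective = fcollective, tmin = tmin,
                 stagnation = stagnation), class = "sa_schedule")
}

#' @rdname sa_schedule
#' @export
reduced_schedule <- function(t0 = NULL, cooling = 0.98, fmove = 0.25,
                             fcollective = 0.5, tmin = 1e-6,
                             stagnation = 20) {
  sa_schedule(t0, cooling, fmove, fcollective, tmin, stagnation)
}

#' Find a modularity-maximizing partition by simulated annealing
#'
#' Stochastic search over partitions of the undirected projection: single
#' node reassignments plus module merges and splits, accepted with
#' probability min(1, exp(dM/T)) along a geometric temperature ladder. The
#' best partition encountered is returned.
#'
#' @param web a [food_web] with at least one non-self link.
#' @param schedule an [sa_schedule].
#' @param seed integer seed (recorded in the result); `NULL` uses the
#'   current RNG state.
#' @return a `module_partition` (see [module_partition]).
#' @export
anneal_partition <- function(web, schedule = sa_schedule(), seed = NULL) {
  stopifnot(inherits(web, "food_web"), inherits(schedule, "sa_schedule"))
  el <- undirected_edge_matrix(web)
  if (nrow(el) == 0) {
    stop("annealing needs at least one (non-self) link", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- anneal_sa_cpp(length(web$nodes), el - 1L,
                       if (is.null(schedule$t0)) -1 else schedule$t0,
                       schedule$cooling, schedule$fmove,
                       schedule$fcollective, schedule$tmin,
                       schedule$stagnation)
  new_module_partition(web, res$membership, seed = seed)
}

#' Replicate annealing runs
#'
#' Runs `n` independently seeded annealing searches and designates one
#' randomly chosen replicate whose module membership is used for reporting
#' (role tables, trait association); role statistics are averaged over all
#' replicates to absorb optimizer stochasticity.
#'
#' @param web a [food_web].
#' @param n number of replicates.
#' @param seed master seed; replicate seeds are drawn from it, so the same
#'   master seed reproduces the whole ensemble exactly.
#' @param schedule an [sa_schedule].
#' @return list of class `partition_ensemble`: `partitions` (list of
#'   `module_partition`), `designated`, `designated_index`, `M` (vector),
#'   `seed`.
#' @export
replicate_partitions <- function(web, n, seed = NULL,
                                 schedule = sa_schedule()) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2147483646L, n)
  parts <- lapply(seeds, function(s) anneal_partition(web, schedule, s))
  idx <- if (n == 1) 1L else sample.int(n, 1)
  structure(list(partitions = parts,
                 designated = parts[[idx]],
                 designated_index = idx,
                 M = vapply(parts, `[[`, numeric(1), "M"),
                 seed = seed),
            class = "partition_ensemble")
}

#' Degree-preserving randomization
#'
#' Rewires the undirected projection by repeated double-edge swaps
#' (no self-links or multi-links introduced), preserving every node's degree
#' exactly. `swaps_per_link * L` swaps are attempted.
#'
#' @param web a [food_web].
#' @param swaps_per_link attempted swaps per undirected link.
#' @param seed integer seed.
#' @return a [food_web] whose undirected structure is the rewired graph
#'   (links stored with arbitrary orientation); attributes are copied. If
#'   the web has fewer than two links it is returned unchanged with a
#'   warning.
#' @export
randomize_degree_preserving <- function(web, swaps_per_link = 10,
                                        seed = NULL) {
  stopifnot(inherits(web, "food_web"))
  g <- undirected_projection(web)
  L <- igraph::ecount(g)
  if (L < 2) {
    warning("too few links to swap; returning input web", call. = FALSE)
    return(web)
  }
  if (!is.null(seed)) set.seed(seed)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = swaps_per_link * L))
  el <- igraph::as_edgelist(g2, names = TRUE)
  food_web(data.frame(prey = el[, 1], predator = el[, 2],
                      stringsAsFactors = FALSE),
           nodes = web$nodes, attributes = web$attributes,
           name = paste0(web$name, "_rewired"))
}

#' Null-model test of modularity
#'
#' Compares the annealed modularity of the empirical web with the annealed
#' modularity of `n` degree-preserving randomizations. The p-value uses the
#' standard permutation-test small-sample correction
#' p = (1 + #\{M_null >= M_emp\}) / (n + 1), so it is never exactly 0.
#'
#' @param web a [food_web].
#' @param n number of null replicates (>= 100 recommended).
#' @param seed master seed.
#' @param schedule schedule for the empirical anneal.
#' @param null_schedule schedule for the null replicates (defaults to the
#'   quarter-strength [reduced_schedule], since the nulls are the compute
#'   bottleneck; pass `sa_schedule()` for full-strength nulls).
#' @param swaps_per_link see [randomize_degree_preserving].
#' @param M_emp optionally supply the empirical modularity (e.g. the best of
#'   an existing replicate ensemble) instead of re-annealing.
#' @return list of class `null_ensemble`: `replicates` (null M values),
#'   `mean`, `sd`, `p_value`, `n_replicates`, `M_emp`, `seed`.
#' @export
null_modularity_test <- function(web, n = 100, seed = NULL,
                                 schedule = sa_schedule(),
                                 null_schedule = reduced_schedule(),
                                 swaps_per_link = 10, M_emp = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(M_emp)) {
    M_emp <- anneal_partition(web, schedule,
                              seed = sample.int(2147483646L, 1))$M
  }
  seeds <- sample.int(2147483646L, n)
  Ms <- vapply(seeds, function(s) {
    nullweb <- randomize_degree_preserving(web, swaps_per_link, seed = s)
    anneal_partition(nullweb, null_schedule)$M
  }, numeric(1))
  structure(list(replicates = Ms,
                 mean = mean(Ms),
                 sd = stats::sd(Ms),
                 p_value = (1 + sum(Ms >= M_emp)) / (n + 1),
                 n_replicates = n,
                 M_emp = M_emp,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble: n = %d, M_emp = %.4f, null %.4f +/- %.4f, p = %.4g>\n",
    x$n_replicates, x$M_emp, x$mean, x$sd, x$p_value))
  invisible(x)
}

#' Exhaustive modularity optimum (cross-check utility)
#'
#' Enumerates every set partition of the nodes (Bell-number search, S <= 10)
#' and returns the global modularity optimum. Intended as an independent
#' check of the annealer on small webs, not for analysis.
#'
#' @param web a [food_web] with S <= 10 and at least one non-self link.
#' @return a `module_partition` at the global optimum.
#' @export
exhaustive_partition <- function(web) {
  n <- length(web$nodes)
  if (n > 10) stop("exhaustive search limited to S <= 10", call. = FALSE)
  el <- undirected_edge_matrix(web)
  if (nrow(el) == 0) {
    stop("modularity undefined: web has no (non-self) links", call. = FALSE)
  }
  L <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  best <- NULL
  bestM <- -Inf
  m <- integer(n)
  recurse <- function(k, maxused) {
    if (k > n) {
      within <- m[el[, 1]] == m[el[, 2]]
      I_s <- tabulate(m[el[, 1]][within], nbins = maxused)
      d_s <- vapply(seq_len(maxused), function(s) sum(deg[m == s]),
                    numeric(1))
      M <- sum(I_s / L - (d_s / (2 * L))^2)
      if (M > bestM) {
        bestM <<- M
        best <<- m
      }
      return(invisible())
    }
    for (s in seq_len(maxused + 1L)) {
      m[k] <<- s
      recurse(k + 1L, max(maxused, s))
    }
  }
  recurse(1L, 0L)
  new_module_partition(web, best)
}
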