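round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentage difference between reported metric values
#'
#' The reporting convention for pairwise web comparisons: metrics are first
#' rounded to report precision (2 decimals), the difference is taken
#' relative to the first-named web, 100 * (a - b) / a, and the result is
#' rounded half-away-from-zero to a whole percent. `NA` is returned when the
#' denominator rounds to 0.
#'
#' @param a metric value of the first-named web (the denominator).
#' @param b metric value of the second web.
#' @param digits report precision applied before differencing.
#' @return whole-percent difference (numeric, possibly `NA`).
#' @examples
#' table_diff(1546, 848)   # 45
#' table_diff(8.59, 5.33)  # 38
#' table_diff(0.27, 0.35)  # -30
#' @export
table_diff <- function(a, b, digits = 2) {
  a <- round(a, digits)
  b <- round(b, digits)
  ifelse(is.na(a) | is.na(b) | a == 0, NA_real_,
         round_half_away(100 * (a - b) / a))
}

#' Configuration for a full web comparison
#'
#' Replicate counts sized for interactive use; set `n_replicates` and
#' `n_null` to 1000 for publication-strength runs.
#'
#' @param n_replicates annealing replicates per web (role CIs).
#' @param n_null degree-preserving null replicates per web.
#' @param n_perm label permutations for the trait association test.
#' @param seed master seed for the whole comparison.
#' @param schedule headline annealing schedule.
#' @param null_schedule schedule for null replicates.
#' @return list of class `comparison_config`.
#' @export
comparison_config <- function(n_replicates = 25, n_null = 99, n_perm = 199,
                              seed = 1L, schedule = sa_schedule(),
                              null_schedule = reduced_schedule()) {
  structure(list(n_replicates = n_replicates, n_null = n_null,
                 n_perm = n_perm, seed = as.integer(seed),
                 schedule = schedule, null_schedule = null_schedule),
            class = "comparison_config")
}

#' Run the full two-region food-web comparison
#'
#' Reproduces the comparison workflow end to end: induces the two regional
#' sub-webs from the meta-web, optionally builds an updated second-region
#' web by adding newcomer species, then for each web computes the structural
#' metric suite, annealed modularity with replicate ensemble and
#' degree-preserving null test, per-species role profiles, and the
#' module-trait association test. Pairwise whole-percent differences follow
#' the [table_diff] convention (first-named web in the denominator).
#'
#' @param meta the meta-web.
#' @param region1,region2 [species_set]s (or character vectors) of the two
#'   regional pools.
#' @param newcomers optional species to add to region 2's web (the
#'   "region 2 updated" scenario); `NULL` skips it.
#' @param config a [comparison_config].
#' @return list of class `comparison_report`: `webs` (per-web results:
#'   `metrics`, `partition` (designated), `M_best`, `null`, `roles`,
#'   `association`), `diffs` (data frame of whole-percent differences),
#'   `seed`.
#' @export
run_comparison <- function(meta, region1, region2, newcomers = NULL,
                           config = comparison_config()) {
  stopifnot(inherits(meta, "food_web"), inherits(config, "comparison_config"))
  if (!inherits(region1, "species_set")) region1 <- species_set(region1, "region1")
  if (!inherits(region2, "species_set")) region2 <- species_set(region2, "region2")
  webs <- list(induced_subweb(meta, region1), induced_subweb(meta, region2))
  if (!is.null(newcomers)) {
    webs[[3]] <- add_species(webs[[2]], meta, newcomers,
                             name = paste0(region2$web_name, "_updated"))
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646L, 4 * length(webs))
  analysed <- vector("list", length(webs))
  for (i in seq_along(webs)) {
    w <- webs[[i]]
    s <- stage_seeds[(4 * (i - 1) + 1):(4 * i)]
    message(sprintf("[%s] metrics (S=%d, L=%d)", w$name, n_species(w),
                    n_links(w)))
    tl <- trophic_levels(w)
    met <- metrics_report(w, tl)
    message(sprintf("[%s] annealing %d replicates (seed %d)", w$name,
                    config$n_replicates, s[1]))
    ens <- replicate_partitions(w, config$n_replicates, seed = s[1],
                                schedule = config$schedule)
    M_best <- max(ens$M)
    met$modularity <- M_best
    message(sprintf("[%s] null model, n=%d (seed %d)", w$name,
                    config$n_null, s[2]))
    nul <- null_modularity_test(w, config$n_null, seed = s[2],
                                null_schedule = config$null_schedule,
                                M_emp = M_best)
    roles <- role_profiles(w, ens)
    traits <- data.frame(id = w$nodes, habitat = w$attributes$habitat,
                         swtl = unname(tl), stringsAsFactors = FALSE)
    assoc <- tryCatch(
      module_trait_association(ens$designated, traits,
                               n_perm = config$n_perm, seed = s[3]),
      error = function(e) {
        message(sprintf("[%s] association test skipped: %s", w$name,
                        conditionMessage(e)))
        NULL
      })
    analysed[[i]] <- list(name = w$name, metrics = met,
                          partition = ens$designated, M_best = M_best,
                          M_replicates = ens$M, null = nul, roles = roles,
                          association = assoc, seeds = s)
  }
  names(analysed) <- vapply(analysed, `[[`, character(1), "name")

  diff_metrics <- c("S", "L", "LD", "C", "pctOmni", "pctCan", "pctLoops",
                    "meanPath", "meanOmni", "meanSWTL", "meanClust",
                    "modularity")
  m1 <- analysed[[1]]$metrics
  m2 <- analysed[[2]]$metrics
  diffs <- data.frame(
    metric = diff_metrics,
    diff_1_2 = vapply(diff_metrics,
                      function(k) table_diff(m1[[k]], m2[[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  if (length(analysed) == 3) {
    m3 <- analysed[[3]]$metrics
    diffs$diff_3_2 <- vapply(diff_metrics,
                             function(k) table_diff(m3[[k]], m2[[k]]),
                             numeric(1))
  }
  structure(list(webs = analysed, diffs = diffs, seed = config$seed,
                 config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  nms <- names(x$webs)
  cat("Food-web comparison report\n")
  keys <- x$diffs$metric
  header <- sprintf("  %-12s %s", "metric",
                    paste(sprintf("%10s", nms), collapse = " "))
  cat(header, "\n")
  for (k in keys) {
    vals <- vapply(x$webs, function(w) {
      v <- w$metrics[[k]]
      if (is.na(v)) "--" else format(round(v, 2), nsmall = 0)
    }, character(1))
    cat(sprintf("  %-12s %s\n", k,
                paste(sprintf("%10s", vals), collapse = " ")))
  }
  cat("  Whole-percent differences (first-named web as denominator):\n")
  print(x$diffs, row.names = FALSE)
  for (w in x$webs) {
    if (!is.null(w$null)) {
      cat(sprintf("  %s: M = %.2f, null %.2f +/- %.3f, p = %.3g\n",
                  w$name, w$M_best, w$null$mean, w$null$sd, w$null$p_value))
    }
  }
  invisible(x)
}

#' Flatten a comparison report for JSON export
#'
#' @param report a `comparison_report`.
#' @return a plain list safe for [write_report].
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  webs <- lapply(report$webs, function(w) {
    list(name = w$name,
         metrics = unclass(w$metrics)[c("S", "L", "LD", "C", "pctOmni",
                                        "pctCan", "pctLoops",
                                        "loopNodeCount", "meanPath",
                                        "meanOmni", "meanSWTL", "meanClust",
                                        "modularity")],
         modularity = list(M_best = w$M_best,
                           replicates = length(w$M_replicates),
                           null_mean = w$null$mean, null_sd = w$null$sd,
                           p_value = w$null$p_value,
                           seeds = w$seeds),
         association = if (!is.null(w$association)) {
           list(statistic = w$association$statistic,
                p_value = w$association$p_value,
                n_permutations = w$association$n_permutations)
         },
         roles = w$roles)
  })
  list(seed = report$seed, webs = webs, diffs = report$diffs)
}
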