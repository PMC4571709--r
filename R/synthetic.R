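#' Niche-model random food web
#'
#' The classical one-dimensional niche model: each species gets a niche
#' value n ~ U(0,1) and eats every species whose niche value falls inside a
#' feeding interval of width r = x * n, x ~ Beta(1, (1-2C)/(2C)), centred at
#' c ~ U(r/2, min(n, 1 - r/2)). The species with the smallest niche value is
#' forced basal (r = 0), so expected connectance is approximately C.
#' Realized webs containing species with no links at all are regenerated, up
#' to `retry` attempts.
#'
#' @param S species count.
#' @param C target connectance, 0 < C < 0.5.
#' @param seed integer seed.
#' @param retry maximum regeneration attempts for connectivity.
#' @return a [food_web]; node ids `sp001...` are ordered by niche value.
#' @export
niche_model_web <- function(S, C, seed = NULL, retry = 100) {
  stopifnot(S >= 2)
  if (C <= 0 || C >= 0.5) stop("niche model needs 0 < C < 0.5", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  beta <- (1 - 2 * C) / (2 * C)
  for (attempt in seq_len(max(1, retry))) {
    n <- sort(runif(S))
    x <- rbeta(S, 1, beta)
    r <- x * n
    r[1] <- 0
    cc <- runif(S, r / 2, pmin(n, 1 - r / 2))
    prey <- integer(0)
    pred <- integer(0)
    for (i in seq_len(S)) {
      if (r[i] <= 0) next
      hit <- which(n >= cc[i] - r[i] / 2 & n <= cc[i] + r[i] / 2)
      prey <- c(prey, hit)
      pred <- c(pred, rep.int(i, length(hit)))
    }
    linked <- unique(c(prey[prey != pred], pred[prey != pred]))
    if (length(linked) == S || attempt == retry) break
  }
  ids <- sprintf("sp%03d", seq_len(S))
  grp <- ifelse(!(seq_len(S) %in% unique(pred)), "basal",
                ifelse(n < 1 / 3, "zooplankton",
                       ifelse(n < 2 / 3, "benthos", "fish")))
  attrs <- data.frame(id = ids,
                      habitat = sample(habitat_codes, S, replace = TRUE,
                                       prob = c(0.4, 0.4, 0.2)),
                      group = grp, stringsAsFactors = FALSE)
  lk <- if (length(prey)) {
    data.frame(prey = ids[prey], predator = ids[pred],
               stringsAsFactors = FALSE)
  } else NULL
  food_web(lk, nodes = ids, attributes = attrs,
           name = sprintf("niche_S%d_C%g", S, C))
}

#' Planted-module benchmark web
#'
#' Directed random web with known block structure: an ordered pair of
#' distinct nodes is linked with probability `p_in` when the two nodes share
#' a module and `p_out` otherwise. The ground-truth labels are returned, so
#' the web serves as a recovery benchmark for the annealer.
#'
#' @param sizes integer vector of module sizes (>= 2 modules).
#' @param p_in,p_out link probabilities, `p_in > p_out >= 0`.
#' @param seed integer seed.
#' @return list with `web` (a [food_web]) and `membership` (named integer
#'   vector of true modules).
#' @export
planted_module_web <- function(sizes = rep(10, 4), p_in = 0.5, p_out = 0.02,
                               seed = NULL) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1), p_in > p_out, p_out >= 0)
  if (!is.null(seed)) set.seed(seed)
  S <- sum(sizes)
  mem <- rep(seq_along(sizes), sizes)
  ids <- sprintf("sp%03d", seq_len(S))
  same <- outer(mem, mem, "==")
  p <- ifelse(same, p_in, p_out)
  diag(p) <- 0
  draw <- matrix(runif(S * S), S, S) < p
  idx <- which(draw, arr.ind = TRUE)
  lk <- if (nrow(idx)) {
    data.frame(prey = ids[idx[, 1]], predator = ids[idx[, 2]],
               stringsAsFactors = FALSE)
  } else NULL
  web <- food_web(lk, nodes = ids,
                  name = sprintf("planted_%s", paste(sizes, collapse = "x")))
  list(web = web, membership = setNames(mem, ids))
}

#' Configuration for the synthetic meta-web generator
#'
#' Defaults emulate a shelf-sea meta-web of roughly 230 trophospecies and
#' 2200 feeding links: nine producers (detritus + basal taxa), six consumer
#' modules with habitat-assorted membership (three benthic, two pelagic, one
#' benthopelagic), two overlapping regional species pools, and a few planted
#' super-generalist fish confined to region 1 with diets spanning all
#' modules (>= 50 prey).
#'
#' @param module_sizes consumer module sizes.
#' @param p_in within-module link probability (applied to trophically
#'   ordered pairs).
#' @param p_out baseline between-module link probability.
#' @param overlap probability that a consumer belongs to both regions.
#' @param region1_boost multiplier on `p_out` for predators unique to
#'   region 1, mirroring the broader diets of the warm-region pool.
#' @param n_generalists number of planted super-generalists.
#' @param gen_frac_home,gen_frac_other fraction of a module's members a
#'   generalist eats, for its home module and for every other module.
#' @param p_basal_match,p_basal_other probability a consumer eats a producer
#'   of matching / non-matching habitat.
#' @param p_cannibal self-link probability for fish.
#' @param p_mutual probability of a reverse (mutual predation) link within a
#'   module between fish.
#' @param n_stations,station_species station count (split over two spatial
#'   blocks) and species sampled per station.
#' @return list of class `metaweb_spec`.
#' @export
metaweb_spec <- function(module_sizes = c(37, 37, 37, 37, 36, 33),
                         p_in = 0.22, p_out = 0.015, overlap = 0.45,
                         region1_boost = 3, n_generalists = 4,
                         gen_frac_home = 0.7, gen_frac_other = 0.25,
                         p_basal_match = 0.35, p_basal_other = 0.08,
                         p_cannibal = 0.1, p_mutual = 0.01,
                         n_stations = 40, station_species = 12) {
  stopifnot(length(module_sizes) >= 2, p_in > p_out, p_out >= 0,
            overlap >= 0, overlap <= 1, n_generalists >= 0)
  structure(as.list(environment()), class = "metaweb_spec")
}

#' Generate a synthetic meta-web with two regional pools
#'
#' Builds a meta-web according to a [metaweb_spec]: habitat-labelled
#' consumers arranged in trophically layered modules, producers shared by
#' both regions, planted super-generalists present only in region 1, and a
#' station presence table spread over two spatial blocks (region-1 species
#' in the south-western block, region-2 species in the north-eastern one).
#' Region 1 plays the role of the warmer, better-connected pool: it holds
#' the generalists and its unique consumers link across modules more freely,
#' so its induced sub-web has higher connectance and lower modularity than
#' region 2's.
#'
#' @param spec a [metaweb_spec].
#' @param seed integer seed.
#' @return list with `meta` (the [food_web]), `region1` and `region2`
#'   ([species_set]s), `stations` (data frame `station,lon,lat,species`),
#'   `modules` (named ground-truth membership; producers form their own
#'   block), `generalists` (character vector of planted hub ids).
#' @export
synthetic_metaweb <- function(spec = metaweb_spec(), seed = NULL) {
  stopifnot(inherits(spec, "metaweb_spec"))
  if (!is.null(seed)) set.seed(seed)
  nm <- length(spec$module_sizes)
  n_cons <- sum(spec$module_sizes)

  producers <- data.frame(
    id = c("detritus", sprintf("bas%02d", 1:8)),
    habitat = c("B", rep("P", 4), rep("B", 4)),
    group = c("detritus", rep("basal", 8)),
    stringsAsFactors = FALSE)

  mod_of <- rep(seq_len(nm), spec$module_sizes)
  mod_hab <- function(m) {
    if (m <= 3) c(B = 0.7, P = 0.1, BP = 0.2)        # benthic modules
    else if (m <= 5) c(B = 0.1, P = 0.7, BP = 0.2)   # pelagic modules
    else c(B = 0.25, P = 0.25, BP = 0.5)             # benthopelagic module
  }
  mod_grp <- function(m) {
    if (m <= 3) c(benthos = 0.6, fish = 0.35, mammal = 0.05)
    else if (m <= 5) c(zooplankton = 0.5, fish = 0.4, seabird = 0.1)
    else c(fish = 0.6, benthos = 0.2, mammal = 0.1, seabird = 0.1)
  }
  cons <- data.frame(
    id = sprintf("m%d_sp%02d", mod_of,
                 unlist(lapply(spec$module_sizes, seq_len))),
    habitat = vapply(mod_of, function(m) {
      p <- mod_hab(m); sample(names(p), 1, prob = p)
    }, character(1)),
    group = vapply(mod_of, function(m) {
      p <- mod_grp(m); sample(names(p), 1, prob = p)
    }, character(1)),
    stringsAsFactors = FALSE)
  height <- runif(n_cons, 0.05, 1)

  k_gen <- spec$n_generalists
  gens <- if (k_gen > 0) {
    data.frame(id = sprintf("gen%d", seq_len(k_gen)),
               habitat = "BP", group = "fish", stringsAsFactors = FALSE)
  } else NULL
  gen_home <- if (k_gen > 0) {
    # alternate benthic and pelagic home modules where available
    homes <- intersect(c(1, 2, 4, 5, 3, 6), seq_len(nm))
    rep(homes, length.out = k_gen)
  } else integer(0)

  # regional membership: producers shared; consumers shared with prob
  # `overlap`, otherwise split evenly; generalists in region 1 only
  reg <- sample(c("both", "r1", "r2"), n_cons, replace = TRUE,
                prob = c(spec$overlap, (1 - spec$overlap) / 2,
                         (1 - spec$overlap) / 2))

  prey <- character(0)
  pred <- character(0)
  add_links <- function(p, q) {
    prey <<- c(prey, p)
    pred <<- c(pred, q)
  }

  is_fish <- cons$group == "fish"
  for (j in seq_len(n_cons)) {
    boost <- if (reg[j] == "r1") spec$region1_boost else 1
    same <- mod_of == mod_of[j]
    lower <- height < height[j]
    cand_in <- which(same & lower)
    cand_out <- which(!same & lower)
    eat_in <- cand_in[runif(length(cand_in)) < spec$p_in]
    eat_out <- cand_out[runif(length(cand_out)) <
                          pmin(1, spec$p_out * boost)]
    if (length(eat_in)) add_links(cons$id[eat_in], rep(cons$id[j],
                                                       length(eat_in)))
    if (length(eat_out)) add_links(cons$id[eat_out], rep(cons$id[j],
                                                         length(eat_out)))
    # mutual predation among fish of the same module
    if (is_fish[j] && length(eat_in)) {
      rev <- eat_in[is_fish[eat_in] & runif(length(eat_in)) < spec$p_mutual]
      if (length(rev)) add_links(rep(cons$id[j], length(rev)), cons$id[rev])
    }
    # producer links, habitat-assorted
    match_b <- producers$habitat == "B"
    ph <- cons$habitat[j]
    pmatch <- if (ph == "BP") rep(TRUE, nrow(producers))
              else (producers$habitat == ph)
    pr <- ifelse(pmatch, spec$p_basal_match, spec$p_basal_other)
    eat_p <- which(runif(nrow(producers)) < pr)
    if (length(eat_p)) add_links(producers$id[eat_p],
                                 rep(cons$id[j], length(eat_p)))
    if (!length(eat_in) && !length(eat_out) && !length(eat_p)) {
      fallback <- sample(producers$id[pmatch | match_b], 1)
      add_links(fallback, cons$id[j])
    }
    if (is_fish[j] && runif(1) < spec$p_cannibal) {
      add_links(cons$id[j], cons$id[j])
    }
  }

  # planted super-generalists: broad diets concentrated on a home module
  if (k_gen > 0) {
    for (g in seq_len(k_gen)) {
      home <- gen_home[g]
      for (m in seq_len(nm)) {
        frac <- if (m == home) spec$gen_frac_home else spec$gen_frac_other
        members <- cons$id[mod_of == m]
        take <- members[runif(length(members)) < frac]
        if (length(take)) add_links(take, rep(gens$id[g], length(take)))
      }
      eat_p <- producers$id[runif(nrow(producers)) < 0.5]
      if (length(eat_p)) add_links(eat_p, rep(gens$id[g], length(eat_p)))
      # a couple of apex predators from the home module eat the generalist
      top <- cons$id[mod_of == home][order(height[mod_of == home],
                                           decreasing = TRUE)[1:2]]
      add_links(rep(gens$id[g], 2), top)
    }
  }

  attrs <- rbind(producers, cons, gens)
  lk <- unique(data.frame(prey = prey, predator = pred,
                          stringsAsFactors = FALSE))
  meta <- food_web(lk, nodes = attrs$id, attributes = attrs,
                   name = "synthetic_meta")

  r1 <- c(producers$id, cons$id[reg %in% c("both", "r1")],
          if (k_gen > 0) gens$id)
  r2 <- c(producers$id, cons$id[reg %in% c("both", "r2")])
  modules <- setNames(c(rep(nm + 1L, nrow(producers)), mod_of, gen_home),
                      attrs$id)

  # station table over two spatial blocks
  ns <- spec$n_stations
  n_sw <- ceiling(ns / 2)
  block <- rep(c("sw", "ne"), c(n_sw, ns - n_sw))
  lon <- ifelse(block == "sw", runif(ns, 20, 35), runif(ns, 35, 50))
  lat <- ifelse(block == "sw", runif(ns, 70, 74), runif(ns, 75, 79))
  pool_sw <- setdiff(r1, producers$id)
  pool_ne <- setdiff(r2, producers$id)
  rows <- lapply(seq_len(ns), function(i) {
    pool <- if (block[i] == "sw") pool_sw else pool_ne
    sp <- sample(pool, min(spec$station_species, length(pool)))
    # the generalists are common throughout their (south-western) range
    if (block[i] == "sw" && k_gen > 0) sp <- unique(c(sp, gens$id))
    data.frame(station = sprintf("st%03d", i), lon = lon[i], lat = lat[i],
               species = sp, stringsAsFactors = FALSE)
  })
  stations <- do.call(rbind, rows)

  list(meta = meta,
       region1 = species_set(r1, "region1"),
       region2 = species_set(r2, "region2"),
       stations = stations,
       modules = modules,
       generalists = if (k_gen > 0) gens$id else character(0))
}
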