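# node x module link-count matrix on the undirected projection
module_link_matrix <- function(web, m) {
  n <- length(web$nodes)
  nm <- max(m)
  el <- undirected_edge_matrix(web)
  k <- matrix(0, n, nm, dimnames = list(web$nodes, NULL))
  if (nrow(el)) {
    tab <- table(factor(c(el[, 1], el[, 2]), levels = seq_len(n)),
                 factor(c(m[el[, 2]], m[el[, 1]]), levels = seq_len(nm)))
    k <- k + unclass(tab)
  }
  k
}

#' Standardized within-module degree (z)
#'
#' z_i = (k_is - mean_s) / SD_s, where k_is is node i's number of links to
#' other members of its own module s, and mean_s, SD_s are the mean and
#' population standard deviation of k_is over all members of s. Modules in
#' which every member has the same within-degree (SD_s = 0) give z = 0.
#' Degrees are taken on the undirected projection with self-links dropped.
#'
#' @param web a [food_web].
#' @param partition a `module_partition` or membership vector.
#' @param nodes optional node ids to return (default: all).
#' @return named numeric vector of z-scores.
#' @export
within_module_z <- function(web, partition, nodes = NULL) {
  m <- align_membership(web, partition)
  k <- module_link_matrix(web, m)
  k_is <- k[cbind(seq_along(m), m)]
  z <- numeric(length(m))
  for (s in seq_len(max(m))) {
    mem <- which(m == s)
    mu <- mean(k_is[mem])
    sdv <- sqrt(mean((k_is[mem] - mu)^2))
    z[mem] <- if (sdv > 0) (k_is[mem] - mu) / sdv else 0
  }
  names(z) <- web$nodes
  if (is.null(nodes)) z else pick_nodes(z, nodes, web)
}

#' Participation coefficient (PC)
#'
#' PC_i = 1 - sum_t (k_it / k_i)^2, summed over all modules t (including
#' node i's own), where k_it is the number of links from i to members of
#' module t and k_i its total (projected) degree. PC is 0 when all links are
#' internal and approaches 1 as links spread evenly over many modules.
#' Isolated nodes get PC = 0 by convention.
#'
#' The quadratic form is the classical one to which the role thresholds
#' belong; `form = "ratio"` gives the simpler fraction of external links,
#' 1 - k_is/k_i.
#'
#' @param web a [food_web].
#' @param partition a `module_partition` or membership vector.
#' @param nodes optional node ids to return.
#' @param form `"quadratic"` (default) or `"ratio"`.
#' @return named numeric vector of PC values in `[0, 1]`.
#' @export
participation_coefficient <- function(web, partition, nodes = NULL,
                                      form = c("quadratic", "ratio")) {
  form <- match.arg(form)
  m <- align_membership(web, partition)
  k <- module_link_matrix(web, m)
  k_i <- rowSums(k)
  pc <- numeric(length(m))
  pos <- k_i > 0
  if (form == "quadratic") {
    pc[pos] <- 1 - rowSums((k[pos, , drop = FALSE] / k_i[pos])^2)
  } else {
    k_is <- k[cbind(seq_along(m), m)]
    pc[pos] <- 1 - k_is[pos] / k_i[pos]
  }
  names(pc) <- web$nodes
  if (is.null(nodes)) pc else pick_nodes(pc, nodes, web)
}

pick_nodes <- function(x, nodes, web) {
  miss <- setdiff(nodes, web$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x[nodes]
}

#' Classify topological roles in the z-PC plane
#'
#' Four regions with thresholds z = 2.5 and PC = 0.625 (both inclusive on
#' the hub/connector side): peripheral (z < 2.5, PC < 0.625), connector
#' (z < 2.5, PC >= 0.625), module hub (z >= 2.5, PC < 0.625) and network
#' hub (z >= 2.5, PC >= 0.625) — the super-generalists that couple modules.
#'
#' @param z within-module degree z-score(s).
#' @param pc participation coefficient(s).
#' @return factor with levels peripheral, connector, module_hub,
#'   network_hub.
#' @export
classify_role <- function(z, pc) {
  stopifnot(length(z) == length(pc))
  out <- ifelse(z >= 2.5,
                ifelse(pc >= 0.625, "network_hub", "module_hub"),
                ifelse(pc >= 0.625, "connector", "peripheral"))
  factor(out, levels = c("peripheral", "connector", "module_hub",
                         "network_hub"))
}

#' Per-species role profiles over an ensemble of partitions
#'
#' Computes z and PC for every node under every replicate partition,
#' summarizes each by its mean and percentile 95% CI (2.5 and 97.5
#' percentiles over replicates), classifies roles from the means, and
#' attaches the module id of the designated partition for reporting.
#'
#' @param web a [food_web].
#' @param partitions a `partition_ensemble` from [replicate_partitions], or
#'   a list of `module_partition` objects.
#' @param designated partition supplying the reported module membership
#'   (default: the ensemble's designated replicate, else the first).
#' @param pc_form passed to [participation_coefficient].
#' @return data frame of class `role_profiles` with columns `id`, `module`,
#'   `z_mean`, `z_lo`, `z_hi`, `pc_mean`, `pc_lo`, `pc_hi`, `role`,
#'   `degree` (total number of trophic interactions in the directed web,
#'   self-links counted once).
#' @export
role_profiles <- function(web, partitions, designated = NULL,
                          pc_form = c("quadratic", "ratio")) {
  pc_form <- match.arg(pc_form)
  if (inherits(partitions, "partition_ensemble")) {
    if (is.null(designated)) designated <- partitions$designated
    partitions <- partitions$partitions
  }
  if (inherits(partitions, "module_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1)
  if (is.null(designated)) designated <- partitions[[1]]
  zs <- vapply(partitions, function(p) within_module_z(web, p),
               numeric(length(web$nodes)))
  pcs <- vapply(partitions,
                function(p) participation_coefficient(web, p,
                                                      form = pc_form),
                numeric(length(web$nodes)))
  zs <- matrix(zs, nrow = length(web$nodes))
  pcs <- matrix(pcs, nrow = length(web$nodes))
  qlo <- function(x) unname(quantile(x, 0.025))
  qhi <- function(x) unname(quantile(x, 0.975))
  z_mean <- rowMeans(zs)
  pc_mean <- rowMeans(pcs)
  out <- data.frame(
    id = web$nodes,
    module = unname(align_membership(web, designated)),
    z_mean = z_mean,
    z_lo = apply(zs, 1, qlo),
    z_hi = apply(zs, 1, qhi),
    pc_mean = pc_mean,
    pc_lo = apply(pcs, 1, qlo),
    pc_hi = apply(pcs, 1, qhi),
    role = classify_role(z_mean, pc_mean),
    degree = unname(total_degree(web)),
    stringsAsFactors = FALSE)
  class(out) <- c("role_profiles", "data.frame")
  out
}
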