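#' Permutation test of module association with habitat and trophic level
#'
#' Tests whether modules segregate by species traits. Predictors are
#' indicator-coded habitat (B / P / BP as a three-level factor) and/or the
#' short-weighted trophic level; the grouping variable is module membership.
#' The observed statistic is the discriminant (Pillai-type) separation
#' \eqn{tr(B T^{-1})}: the trace of the between-module scatter matrix
#' against the total scatter of the centred predictors. Significance comes
#' from permuting module labels across species.
#'
#' @param partition a `module_partition` or named membership vector
#'   (>= 2 modules required).
#' @param traits data frame with columns `id`, `habitat` (B/P/BP) and
#'   `swtl` (finite trophic level), covering every node of the partition.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @param mode `"joint"` (habitat + trophic level, default), `"habitat"`
#'   or `"swtl"` for separate tests.
#' @param statistic `"scatter"` (deterministic trace statistic, default) or
#'   `"accuracy"` (leave-one-out LDA classification accuracy; needs MASS).
#' @return list of class `association_result`: `statistic`, `p_value`
#'   (with the (1 + exceedances)/(n_perm + 1) correction), `n_permutations`,
#'   `composition` (per-module habitat fractions and mean SWTL), `mode`.
#' @export
module_trait_association <- function(partition, traits, n_perm = 999,
                                     seed = NULL,
                                     mode = c("joint", "habitat", "swtl"),
                                     statistic = c("scatter", "accuracy")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (inherits(partition, "module_partition")) {
    membership <- partition$assignment
  } else {
    membership <- partition
  }
  if (is.null(names(membership))) {
    stop("partition must carry node names", call. = FALSE)
  }
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  need <- c("id", if (mode != "swtl") "habitat", if (mode != "habitat") "swtl")
  if (!all(need %in% names(traits))) {
    stop("traits must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mi <- match(names(membership), traits$id)
  if (anyNA(mi)) {
    stop("traits missing for node(s): ",
         paste(names(membership)[is.na(mi)], collapse = ", "), call. = FALSE)
  }
  traits <- traits[mi, , drop = FALSE]
  g <- as.integer(factor(membership))
  if (max(g) < 2) stop("association test needs at least 2 modules",
                       call. = FALSE)

  X <- NULL
  if (mode != "swtl") {
    hab <- traits$habitat
    if (anyNA(hab) || !all(hab %in% habitat_codes)) {
      stop("every node needs a habitat code in B/P/BP", call. = FALSE)
    }
    hf <- factor(hab, levels = intersect(habitat_codes, unique(hab)))
    if (nlevels(hf) < 2) {
      stop("constant predictor(s): habitat", call. = FALSE)
    }
    Xh <- stats::model.matrix(~hf)[, -1, drop = FALSE]
    colnames(Xh) <- paste0("habitat", levels(hf)[-1])
    X <- cbind(X, Xh)
  }
  if (mode != "habitat") {
    sw <- as.numeric(traits$swtl)
    if (anyNA(sw) || any(!is.finite(sw))) {
      stop("every node needs a finite SWTL", call. = FALSE)
    }
    X <- cbind(X, swtl = sw)
  }
  const <- apply(X, 2, function(col) max(col) == min(col))
  if (any(const)) {
    stop("constant predictor(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }

  stat_fun <- if (statistic == "scatter") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Tot <- crossprod(Xc)
    Tinv <- solve(Tot)
    function(g) {
      nm <- max(g)
      Bm <- matrix(0, ncol(Xc), ncol(Xc))
      for (s in seq_len(nm)) {
        rows <- g == s
        mu <- colMeans(Xc[rows, , drop = FALSE])
        Bm <- Bm + sum(rows) * tcrossprod(mu)
      }
      sum(diag(Bm %*% Tinv))
    }
  } else {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("statistic = 'accuracy' requires the MASS package", call. = FALSE)
    }
    function(g) {
      fit <- MASS::lda(X, grouping = factor(g), CV = TRUE)
      mean(fit$class == factor(g))
    }
  }

  obs <- stat_fun(g)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat_fun(sample(g)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)

  comp <- lapply(sort(unique(g)), function(s) {
    rows <- g == s
    out <- list(n = sum(rows))
    if (mode != "swtl") {
      tab <- table(factor(traits$habitat[rows], levels = habitat_codes))
      out$habitat_fractions <- as.list(tab / sum(tab))
    }
    if (mode != "habitat") out$mean_swtl <- mean(as.numeric(traits$swtl)[rows])
    out
  })
  names(comp) <- paste0("module_", sort(unique(g)))

  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 composition = comp, mode = mode,
                 statistic_type = statistic, seed = seed),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result (%s, %s): statistic = %.4f, p = %.4g (%d perms)>\n",
    x$mode, x$statistic_type, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
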