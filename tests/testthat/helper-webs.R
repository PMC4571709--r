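# small fixtures built in code

make_web <- function(..., nodes = NULL, name = "toy") {
  pairs <- list(...)
  if (length(pairs) == 1 && is.data.frame(pairs[[1]])) {
    lk <- pairs[[1]]
  } else if (length(pairs)) {
    lk <- data.frame(prey = vapply(pairs, `[[`, "", 1),
                     predator = vapply(pairs, `[[`, "", 2),
                     stringsAsFactors = FALSE)
  } else {
    lk <- NULL
  }
  food_web(lk, nodes = nodes, name = name)
}

# directed Erdos-Renyi-ish web on `n` nodes, link prob p, no self-links
# unless allow_self
random_web <- function(n, p, seed = NULL, allow_self = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  m <- matrix(runif(n * n) < p, n, n)
  if (!allow_self) diag(m) <- FALSE
  idx <- which(m, arr.ind = TRUE)
  lk <- if (nrow(idx)) {
    data.frame(prey = ids[idx[, 1]], predator = ids[idx[, 2]],
               stringsAsFactors = FALSE)
  } else NULL
  food_web(lk, nodes = ids, name = "random")
}

# two disjoint directed triangles a->b->c->a, d->e->f->d
two_triangles <- function() {
  make_web(c("a", "b"), c("b", "c"), c("c", "a"),
           c("d", "e"), c("e", "f"), c("f", "d"), name = "triangles")
}

triangle_partition <- function() {
  stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
}
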