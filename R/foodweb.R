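#' @useDynLib trophoweb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd quantile rbeta runif setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

habitat_codes <- c("B", "P", "BP")
group_codes <- c("detritus", "basal", "zooplankton", "benthos",
                 "fish", "seabird", "mammal")

#' Construct a directed food web
#'
#' A food web is a directed graph of trophospecies in which every link points
#' from prey to predator (the direction of energy flow). A node's in-degree is
#' therefore its number of prey (generality) and its out-degree its number of
#' predators (vulnerability). Self-links record cannibalism and are allowed;
#' duplicate links are collapsed with a warning.
#'
#' @param links a data frame (or two-column matrix) with columns `prey` and
#'   `predator`, one row per feeding link. May be `NULL` for a linkless web.
#' @param nodes optional character vector of node identifiers; nodes named
#'   here or in `attributes` but absent from `links` become isolated nodes.
#' @param attributes optional data frame with columns `id`, `habitat`
#'   (one of `"B"`, `"P"`, `"BP"`) and `group` (one of `r toString(group_codes)`).
#' @param name label for the web.
#' @return an object of class `food_web`: a list with elements `name`,
#'   `nodes` (character), `links` (data frame `prey`, `predator`) and
#'   `attributes` (data frame `id`, `habitat`, `group`, aligned with `nodes`).
#' @examples
#' w <- food_web(data.frame(prey = c("alga", "krill"),
#'                          predator = c("krill", "cod")))
#' n_species(w); n_links(w)
#' @export
food_web <- function(links = NULL, nodes = NULL, attributes = NULL,
                     name = "web") {
  if (is.null(links)) {
    links <- data.frame(prey = character(), predator = character(),
                        stringsAsFactors = FALSE)
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!all(c("prey", "predator") %in% names(links))) {
    if (ncol(links) >= 2) {
      names(links)[1:2] <- c("prey", "predator")
    } else {
      stop("'links' must have columns 'prey' and 'predator'", call. = FALSE)
    }
  }
  links <- data.frame(prey = as.character(links$prey),
                      predator = as.character(links$predator),
                      stringsAsFactors = FALSE)
  bad <- which(is.na(links$prey) | is.na(links$predator) |
                 links$prey == "" | links$predator == "")
  if (length(bad)) {
    stop("malformed link row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(links)
  if (any(dup)) {
    warning(sum(dup), " duplicate link(s) collapsed", call. = FALSE)
    links <- links[!dup, , drop = FALSE]
    rownames(links) <- NULL
  }
  ids <- unique(c(as.character(nodes), links$prey, links$predator,
                  if (!is.null(attributes)) as.character(attributes$id)))
  if (length(ids) < 1L) stop("a food web needs at least one node", call. = FALSE)
  attrs <- data.frame(id = ids, habitat = NA_character_,
                      group = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
    if (!all(c("id", "habitat", "group") %in% names(attributes))) {
      stop("'attributes' must have columns id, habitat, group", call. = FALSE)
    }
    hab <- as.character(attributes$habitat)
    grp <- as.character(attributes$group)
    bad_h <- !is.na(hab) & !(hab %in% habitat_codes)
    if (any(bad_h)) {
      stop("unknown habitat code(s): ",
           paste(unique(hab[bad_h]), collapse = ", "),
           " (allowed: ", paste(habitat_codes, collapse = ", "), ")",
           call. = FALSE)
    }
    bad_g <- !is.na(grp) & !(grp %in% group_codes)
    if (any(bad_g)) {
      stop("unknown functional group(s): ",
           paste(unique(grp[bad_g]), collapse = ", "),
           " (allowed: ", paste(group_codes, collapse = ", "), ")",
           call. = FALSE)
    }
    m <- match(attrs$id, as.character(attributes$id))
    attrs$habitat <- hab[m]
    attrs$group <- grp[m]
  }
  structure(list(name = name, nodes = ids, links = links, attributes = attrs),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web '%s': S = %d, L = %d>\n",
              x$name, n_species(x), n_links(x)))
  invisible(x)
}

#' Number of species (S) and links (L)
#' @param web a `food_web`.
#' @return integer count.
#' @export
n_species <- function(web) length(web$nodes)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$links)

#' Read a food web from edge-list and attribute CSV files
#'
#' The edge list must have a header row `prey,predator`; the optional
#' attribute table a header `id,habitat,group` with habitat in B/P/BP.
#' Nodes present only in the attribute file are kept as isolated nodes.
#'
#' @param edge_list_path path to the link CSV.
#' @param attributes_path optional path to the attribute CSV.
#' @param name web label (defaults to the edge-list file name).
#' @return a [food_web].
#' @export
read_web <- function(edge_list_path, attributes_path = NULL, name = NULL) {
  if (!file.exists(edge_list_path)) {
    stop("edge list not found: ", edge_list_path, call. = FALSE)
  }
  links <- read.csv(edge_list_path, colClasses = "character",
                    strip.white = TRUE)
  if (!all(c("prey", "predator") %in% names(links))) {
    stop("edge list must have header columns 'prey,predator': ",
         edge_list_path, call. = FALSE)
  }
  bad <- which(is.na(links$prey) | is.na(links$predator) |
                 links$prey == "" | links$predator == "")
  if (length(bad)) {
    stop("malformed edge list row at line ",
         paste(bad + 1L, collapse = ", "), " of ", edge_list_path,
         call. = FALSE)
  }
  attrs <- NULL
  if (!is.null(attributes_path)) {
    if (!file.exists(attributes_path)) {
      stop("attribute file not found: ", attributes_path, call. = FALSE)
    }
    attrs <- read.csv(attributes_path, colClasses = "character",
                      strip.white = TRUE)
    if (!all(c("id", "habitat", "group") %in% names(attrs))) {
      stop("attribute file must have header columns 'id,habitat,group': ",
           attributes_path, call. = FALSE)
    }
    attrs$habitat[attrs$habitat == ""] <- NA_character_
    attrs$group[attrs$group == ""] <- NA_character_
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(edge_list_path))
  food_web(links, attributes = attrs, name = name)
}

#' Species sets
#'
#' A named set of trophospecies identifiers, used to carve regional sub-webs
#' out of a meta-web. Duplicates are collapsed.
#'
#' @param members character vector of identifiers.
#' @param web_name label for the set.
#' @return an object of class `species_set`.
#' @export
species_set <- function(members, web_name = "subset") {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & members != ""]
  if (!length(members)) stop("species set is empty", call. = FALSE)
  structure(list(web_name = web_name, members = members),
            class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf("<species_set '%s': %d members>\n", x$web_name,
              length(x$members)))
  invisible(x)
}

#' @rdname species_set
#' @param path file with one identifier per line (blank lines and `#`
#'   comments ignored).
#' @export
read_species_set <- function(path, web_name = NULL) {
  if (!file.exists(path)) stop("species set file not found: ", path,
                               call. = FALSE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[x != "" & !startsWith(x, "#")]
  if (is.null(web_name)) web_name <- sub("\\.[^.]*$", "", basename(path))
  species_set(x, web_name)
}

as_members <- function(subset) {
  if (inherits(subset, "species_set")) subset$members
  else unique(as.character(subset))
}

#' Induce a regional sub-web from a meta-web
#'
#' Keeps exactly the members of `subset` as nodes and every meta-web link
#' whose prey and predator are both members — the co-occurrence assumption:
#' species that interact in the meta-web interact wherever they co-occur.
#' Nodes left with no links are retained (optionally dropped).
#'
#' @param meta the meta-web (`food_web`).
#' @param subset a [species_set] or character vector; must be a subset of
#'   `meta`'s nodes.
#' @param drop_isolated drop nodes with no links in the sub-web?
#' @return a [food_web].
#' @export
induced_subweb <- function(meta, subset, drop_isolated = FALSE) {
  stopifnot(inherits(meta, "food_web"))
  members <- as_members(subset)
  if (!length(members)) stop("species subset is empty", call. = FALSE)
  missing <- setdiff(members, meta$nodes)
  if (length(missing)) {
    stop("subset members absent from the meta-web: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- meta$links$prey %in% members & meta$links$predator %in% members
  links <- meta$links[keep, , drop = FALSE]
  rownames(links) <- NULL
  if (drop_isolated) {
    linked <- unique(c(links$prey, links$predator))
    members <- members[members %in% linked]
    if (!length(members)) stop("all subset members are isolated", call. = FALSE)
  }
  nm <- if (inherits(subset, "species_set")) subset$web_name
        else paste0(meta$name, "_sub")
  ai <- meta$attributes[match(members, meta$attributes$id), , drop = FALSE]
  food_web(links, nodes = members, attributes = ai, name = nm)
}

#' Add newcomer species to a sub-web
#'
#' Rebuilds the induced sub-web on the union of the resident nodes and the
#' newcomers, so every meta-web link among the union appears — the operation
#' used to model poleward-shifting species entering a regional web.
#'
#' @param web the resident sub-web (nodes must be a subset of `meta`'s).
#' @param meta the meta-web.
#' @param newcomers [species_set] or character vector of species to add.
#' @param name label for the updated web.
#' @return a [food_web] equal to `induced_subweb(meta, union)`.
#' @export
add_species <- function(web, meta, newcomers, name = NULL) {
  stopifnot(inherits(web, "food_web"), inherits(meta, "food_web"))
  newcomers <- as_members(newcomers)
  missing <- setdiff(newcomers, meta$nodes)
  if (length(missing)) {
    stop("newcomer(s) absent from the meta-web: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stray <- setdiff(web$nodes, meta$nodes)
  if (length(stray)) {
    stop("resident web contains nodes unknown to the meta-web: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  if (is.null(name)) name <- paste0(web$name, "_plus")
  induced_subweb(meta, species_set(union(web$nodes, newcomers), name))
}

#' Shared and unique species between two webs
#'
#' @param a,b `food_web` objects.
#' @return named integer vector `c(shared=, unique=)`: the intersection size
#'   and the symmetric-difference size of the two node sets.
#' @export
shared_unique <- function(a, b) {
  stopifnot(inherits(a, "food_web"), inherits(b, "food_web"))
  shared <- length(intersect(a$nodes, b$nodes))
  uniq <- length(union(a$nodes, b$nodes)) - shared
  c(shared = shared, unique = uniq)
}

#' Convert a food web to an igraph object
#'
#' @param web a `food_web`.
#' @param directed keep link direction (prey -> predator)?
#' @return an `igraph` graph whose vertex order matches `web$nodes`, with
#'   vertex attributes `habitat` and `group`.
#' @export
as_igraph <- function(web, directed = TRUE) {
  stopifnot(inherits(web, "food_web"))
  v <- data.frame(name = web$nodes,
                  habitat = web$attributes$habitat,
                  group = web$attributes$group,
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(web$links, directed = directed, vertices = v)
}

# Undirected projection: self-links dropped, mutual predation collapsed to a
# single edge. Vertex order matches web$nodes. Used by path length,
# clustering, modularity and the role measures.
undirected_projection <- function(web) {
  g <- as_igraph(web, directed = TRUE)
  g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# 0/1-based integer edge matrix of the undirected projection (m x 2),
# indices into web$nodes.
undirected_edge_matrix <- function(web) {
  g <- undirected_projection(web)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

#' Export / import a food web as GraphML
#'
#' Round-trips the node set, link set and habitat/group attributes through
#' the standard GraphML format (readable by igraph, Gephi, yEd, NetworkX).
#'
#' @param web a `food_web`.
#' @param path file path.
#' @return `write_graphml` returns `path` invisibly; `read_graphml` a
#'   [food_web].
#' @export
write_graphml <- function(web, path) {
  g <- as_igraph(web, directed = TRUE)
  hab <- igraph::V(g)$habitat
  grp <- igraph::V(g)$group
  igraph::V(g)$habitat <- ifelse(is.na(hab), "", hab)
  igraph::V(g)$group <- ifelse(is.na(grp), "", grp)
  g <- igraph::set_graph_attr(g, "name", web$name)
  ok <- tryCatch({
    igraph::write_graph(g, path, format = "graphml")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write GraphML to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  ids <- igraph::V(g)$name
  va <- igraph::vertex_attr(g)
  attrs <- data.frame(
    id = ids,
    habitat = if (!is.null(va$habitat)) ifelse(va$habitat == "", NA, va$habitat)
              else NA_character_,
    group = if (!is.null(va$group)) ifelse(va$group == "", NA, va$group)
            else NA_character_,
    stringsAsFactors = FALSE)
  nm <- igraph::graph_attr(g, "name")
  if (is.null(nm)) nm <- sub("\\.[^.]*$", "", basename(path))
  food_web(data.frame(prey = el[, 1], predator = el[, 2],
                      stringsAsFactors = FALSE),
           nodes = ids, attributes = attrs, name = nm)
}

#' Write an analysis report to JSON
#'
#' Metric reports and comparison reports are stored at full precision;
#' display rounding is left to print methods.
#'
#' @param report a list (e.g. a [metrics_report]).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Analyze user-supplied web files end to end
#'
#' Convenience entry point for deposited empirical webs (edge list + attribute
#' CSVs): reads the web and returns its metric report with annealed
#' modularity. Stochastic-optimizer results on the published Barents Sea webs
#' are expected to reproduce deposited modularity values only to about
#' +/- 0.02.
#'
#' @param edge_list_path,attributes_path CSV paths as in [read_web].
#' @param seed integer seed for the annealer.
#' @param schedule annealing schedule, see [sa_schedule].
#' @return a [metrics_report] with the `modularity` field filled.
#' @export
analyze_web_files <- function(edge_list_path, attributes_path = NULL,
                              seed = 1L, schedule = sa_schedule()) {
  web <- read_web(edge_list_path, attributes_path)
  rep <- metrics_report(web)
  part <- anneal_partition(web, schedule = schedule, seed = seed)
  rep$modularity <- part$M
  rep
}
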