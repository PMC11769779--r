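PESI_CATEGORIES <- c("cancer", "heart_failure", "chronic_lung_disease")

#' Build a SNOMED CT is-a concept graph
#'
#' The PESI comorbidities (history of cancer, heart failure, chronic lung
#' disease) are flagged by hierarchical concept matching: a coded problem
#' entry counts for a category when its concept equals, or is an is-a
#' descendant of, one of the category's root concepts and is not on the
#' category's exclusion list. This constructor holds the is-a edge relation
#' plus the three category root sets.
#'
#' @param edges data frame with character columns `child`, `parent`; each row
#'   is one is-a relation. Must be acyclic (checked at load).
#' @param category_roots named list mapping each of `"cancer"`,
#'   `"heart_failure"`, `"chronic_lung_disease"` to a character vector of
#'   root concept ids.
#' @param exclusions named list mapping categories to concept ids excluded
#'   despite descent (e.g. non-metastatic skin cancer); defaults to empty,
#'   which matches plain hierarchical matching.
#' @return object of class `concept_graph`.
#' @export
concept_graph <- function(edges, category_roots, exclusions = list()) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent))
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent)))
    stop("concept_graph: empty concept id in edge list", call. = FALSE)
  nodes <- unique(c(edges$child, edges$parent))

  # Kahn's algorithm: detects cycles at load time, not per query
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$parent)        # parent in-degree under child->parent edges
  indeg[names(tab)] <- as.integer(tab)
  parents <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (w in parents[[v]] %||% character(0)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  # every node is processed iff the relation is acyclic
  if (seen < length(nodes))
    stop("concept_graph: the is-a relation contains a cycle", call. = FALSE)

  for (cat in names(category_roots)) {
    missing <- setdiff(category_roots[[cat]], nodes)
    if (length(missing))
      warning(sprintf("category '%s': root concept(s) %s absent from the edge list",
                      cat, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cat in names(exclusions)) {
    missing <- setdiff(exclusions[[cat]], nodes)
    if (length(missing))
      warning(sprintf("category '%s': exclusion concept(s) %s absent from the edge list",
                      cat, paste(missing, collapse = ", ")), call. = FALSE)
    overlap <- intersect(exclusions[[cat]], category_roots[[cat]] %||% character(0))
    if (length(overlap))
      stop(sprintf("category '%s': exclusions overlap the root set (%s)",
                   cat, paste(overlap, collapse = ", ")), call. = FALSE)
  }

  structure(list(edges = edges,
                 nodes = nodes,
                 parents = parents,
                 category_roots = lapply(category_roots, as.character),
                 exclusions = lapply(exclusions, as.character),
                 closure = new.env(parent = emptyenv())),
            class = "concept_graph")
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("<concept_graph> %d concepts, %d is-a edges; categories: %s\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s (%d roots)", names(x$category_roots),
                            lengths(x$category_roots)), collapse = ", ")))
  invisible(x)
}

#' Transitive is-a closure of a concept
#'
#' Returns every ancestor of `code` under the graph's is-a relation,
#' excluding `code` itself. A concept with no parents, or one absent from the
#' graph, has an empty ancestor set. Results are memoized on the graph.
#'
#' @param code concept id (scalar character).
#' @param graph a [concept_graph()].
#' @return character vector of ancestor concept ids.
#' @export
ancestors <- function(code, graph) {
  stopifnot(inherits(graph, "concept_graph"))
  code <- as.character(code)
  memo <- graph$closure
  walk <- function(c) {
    hit <- memo[[c]]
    if (!is.null(hit)) return(hit)
    ps <- graph$parents[[c]]
    if (is.null(ps)) {
      memo[[c]] <- character(0)
      return(character(0))
    }
    out <- ps
    for (p in ps) out <- c(out, walk(p))
    out <- unique(out)
    memo[[c]] <- out
    out
  }
  walk(code)
}

#' Descendants of a concept (roots excluded)
#'
#' Inverse view of [ancestors()]: all concepts whose ancestor set contains
#' `code`. Used by the cohort simulator to draw concrete comorbidity codes.
#'
#' @inheritParams ancestors
#' @return character vector of descendant concept ids.
#' @export
descendants <- function(code, graph) {
  stopifnot(inherits(graph, "concept_graph"))
  graph$nodes[vapply(graph$nodes, function(n) code %in% ancestors(n, graph), TRUE)]
}

# All concept ids that count for a category: the roots plus every is-a
# descendant, minus exclusions. Cached on the graph after first use so that
# category matching is a vectorized membership test.
category_members <- function(graph, category) {
  key <- paste0(".members.", category)
  hit <- graph$closure[[key]]
  if (!is.null(hit)) return(hit)
  roots <- graph$category_roots[[category]] %||% character(0)
  desc <- graph$nodes[vapply(graph$nodes,
                             function(n) any(roots %in% ancestors(n, graph)), TRUE)]
  members <- setdiff(unique(c(roots, desc)), graph$exclusions[[category]] %||% character(0))
  graph$closure[[key]] <- members
  members
}

in_category <- function(code, category, graph) {
  code %in% category_members(graph, category)
}

#' Flag a PESI comorbidity category from coded problem entries
#'
#' An entry qualifies when its status is in `statuses` and its concept is a
#' root of the category or an is-a descendant of one, and is not excluded.
#' The default statuses are `active` and `history`: comorbidities are read
#' from both the active problem list and the past medical history; resolved
#' entries count only when explicitly requested.
#'
#' @param entries data frame of problem entries ([problem_entries()]),
#'   typically the concatenated problem list and medical history.
#' @param category `"cancer"`, `"heart_failure"` or `"chronic_lung_disease"`.
#' @param graph a [concept_graph()].
#' @param statuses statuses that qualify (default `c("active", "history")`).
#' @return list with `flag` (logical) and `evidence` (the qualifying entries,
#'   in input order; empty when `flag` is `FALSE`).
#' @export
match_category <- function(entries, category, graph,
                           statuses = c("active", "history")) {
  category <- match.arg(category, PESI_CATEGORIES)
  if (is.null(entries) || nrow(entries) == 0)
    return(list(flag = FALSE, evidence = empty_problems()))
  hit <- (entries$status %in% statuses) &
    (entries$snomed_code %in% category_members(graph, category))
  list(flag = any(hit), evidence = entries[hit, , drop = FALSE])
}

#' Load a concept graph from files
#'
#' @param edges_path CSV edge list with header `child,parent`.
#' @param categories_path JSON file of the form
#'   `{"cancer": {"roots": [...], "exclusions": [...]}, ...}`.
#' @return a [concept_graph()].
#' @export
load_concept_graph <- function(edges_path, categories_path) {
  edges <- read.csv(edges_path, colClasses = "character")
  cats <- jsonlite::fromJSON(categories_path, simplifyVector = TRUE)
  roots <- lapply(cats, function(c) as.character(c$roots %||% character(0)))
  excl <- lapply(cats, function(c) as.character(c$exclusions %||% character(0)))
  concept_graph(edges, roots, excl)
}

#' The packaged illustrative concept graph
#'
#' A small, hand-built is-a graph (~40 concepts) with root sets for the three
#' PESI comorbidity categories. It is synthetic and illustrative: real
#' deployments plug in their institutional value sets via
#' [load_concept_graph()]; institutional SNOMED value sets are site-specific
#' and are not shipped here.
#'
#' @return a [concept_graph()].
#' @export
default_concept_graph <- function() {
  load_concept_graph(
    system.file("extdata", "synthetic_concept_edges.csv", package = "autopesi"),
    system.file("extdata", "synthetic_concept_categories.json", package = "autopesi"))
}
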