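#' Ontology subsumption graphs
#'
#' A minimal directed-acyclic ontology restricted to `is_a`/`subClassOf`
#' edges, sufficient for annotation-consistency quality control: term lookup,
#' ancestor/descendant closure, and subsumption tests. Terms carry a CURIE
#' identifier (e.g. `HP:0001250`), a label, and an obsolescence flag.
#'
#' When the edge set leaves more than one parentless term, a virtual root
#' (`owl:Thing`) is synthesized internally so that the ancestor closure is
#' total; the virtual root is never reported by [ancestors()] or
#' [descendants()].
#'
#' @param terms A tibble with columns `id`, `label`, `obsolete`.
#' @param parents A named list mapping each term id to a character vector of
#'   parent term ids (possibly empty).
#' @return An object of class `ontology_graph`.
#' @seealso [load_ontology()], [ancestors()], [is_ancestor()]
#' @export
ontology_graph <- function(terms, parents) {
  terms <- as_tibble(terms)
  stopifnot(all(c("id", "label", "obsolete") %in% names(terms)))
  if (anyDuplicated(terms$id)) {
    abort("duplicate term ids in ontology", class = "phenocurator_format_error")
  }
  bad <- terms$id[!is_curie(terms$id)]
  if (length(bad) > 0) {
    abort(paste0("term id is not a CURIE: ", bad[[1]]),
          class = "phenocurator_format_error")
  }
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) unique(as.character(p %||% character())))

  for (id in terms$id) {
    ps <- parents[[id]]
    if (id %in% ps) {
      abort(paste0("cycle detected in ontology: term ", id, " is its own parent"),
            class = "phenocurator_structural_error")
    }
    missing <- setdiff(ps, terms$id)
    if (length(missing) > 0) {
      abort(paste0("parent id does not resolve: ", missing[[1]], " (child ", id, ")"),
            class = "phenocurator_structural_error")
    }
  }

  roots <- terms$id[lengths(parents) == 0]
  virtual_root <- FALSE
  if (length(roots) == 0) {
    # every term has a parent: necessarily cyclic, reported below
    root <- NA_character_
  } else if (length(roots) == 1) {
    root <- roots
  } else {
    root <- "owl:Thing"
    virtual_root <- TRUE
    terms <- bind_rows(terms, tibble(id = root, label = "Thing", obsolete = FALSE))
    for (r in roots) parents[[r]] <- root
    parents[[root]] <- character()
  }

  # Kahn topological sort doubles as the cycle check
  n_parents <- lengths(parents)
  order <- character(0)
  queue <- terms$id[n_parents == 0]
  children <- invert_edges(parents)
  counts <- n_parents
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]] %||% character()) {
      counts[[ch]] <- counts[[ch]] - 1L
      if (counts[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < nrow(terms)) {
    member <- setdiff(terms$id, order)[[1]]
    abort(paste0("cycle detected in ontology involving term ", member),
          class = "phenocurator_structural_error")
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         root = root, virtual_root = virtual_root,
         topological_order = order),
    class = "ontology_graph"
  )
}

invert_edges <- function(parents) {
  children <- vector("list", length(parents))
  names(children) <- names(parents)
  for (id in names(parents)) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children
}

#' @export
print.ontology_graph <- function(x, ...) {
  n <- nrow(x$terms) - as.integer(x$virtual_root)
  cat("<ontology_graph> ", n, " terms, root ",
      if (x$virtual_root) "(virtual)" else x$root,
      ", ", sum(x$terms$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

#' Terms of an ontology graph
#'
#' @param g An `ontology_graph`.
#' @return A tibble with columns `id`, `label`, `obsolete` (the virtual root,
#'   if any, is not included).
#' @export
ontology_terms <- function(g) {
  stopifnot(inherits(g, "ontology_graph"))
  out <- g$terms
  if (g$virtual_root) out <- filter(out, .data$id != g$root)
  out
}

#' @rdname ontology_terms
#' @export
has_term <- function(g, id) {
  stopifnot(inherits(g, "ontology_graph"))
  id %in% g$terms$id & !(g$virtual_root & id == g$root)
}

term_label <- function(g, id) {
  g$terms$label[match(id, g$terms$id)]
}

term_obsolete <- function(g, id) {
  g$terms$obsolete[match(id, g$terms$id)]
}

assert_in_graph <- function(g, id) {
  if (!has_term(g, id)) {
    abort(paste0("term not in ontology: ", id),
          class = "phenocurator_lookup_error")
  }
}

#' Ancestor and descendant closure
#'
#' `ancestors()` returns the transitive closure of a term over parent
#' (`is_a`) edges; `descendants()` over child edges; `is_ancestor()` tests
#' whether `a` lies strictly above `d`. The virtual root, when one was
#' synthesized, is never included.
#'
#' @param g An `ontology_graph`.
#' @param t,a,d Term ids (CURIE strings) present in `g`.
#' @param include_self Include the query term itself in the result?
#' @return For `ancestors()`/`descendants()`, a character vector of term ids;
#'   for `is_ancestor()`, a single logical.
#' @export
ancestors <- function(g, t, include_self = FALSE) {
  stopifnot(inherits(g, "ontology_graph"))
  assert_in_graph(g, t)
  out <- closure_walk(g$parents, t)
  if (g$virtual_root) out <- setdiff(out, g$root)
  if (include_self) out <- union(t, out)
  out
}

#' @rdname ancestors
#' @export
descendants <- function(g, t, include_self = FALSE) {
  stopifnot(inherits(g, "ontology_graph"))
  assert_in_graph(g, t)
  out <- closure_walk(g$children, t)
  if (include_self) out <- union(t, out)
  out
}

#' @rdname ancestors
#' @export
is_ancestor <- function(g, a, d) {
  stopifnot(inherits(g, "ontology_graph"))
  assert_in_graph(g, a)
  assert_in_graph(g, d)
  a %in% ancestors(g, d, include_self = FALSE)
}

closure_walk <- function(edges, t) {
  seen <- character(0)
  frontier <- edges[[t]] %||% character()
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(edges[frontier], use.names = FALSE))
  }
  seen
}

# Full ancestor map (including self) for every term, computed once in
# topological order; used by the validator so rule checks stay linear.
ancestor_map <- function(g, include_self = TRUE) {
  anc <- vector("list", nrow(g$terms))
  names(anc) <- g$terms$id
  for (id in g$topological_order) {
    ps <- g$parents[[id]]
    anc[[id]] <- unique(c(if (include_self) id, ps,
                          unlist(anc[ps], use.names = FALSE)))
  }
  if (g$virtual_root) anc <- lapply(anc, setdiff, y = g$root)
  anc
}

#' Load an ontology from an obographs-style JSON file
#'
#' Reads the subset of the obographs exchange format that subsumption QC
#' needs: `graphs[[1]]$nodes` with `id`, `lbl` and `meta$deprecated`, and
#' `graphs[[1]]$edges` with `sub`/`pred`/`obj`. Only `is_a` / `subClassOf`
#' predicates become edges; other predicates are ignored (their count is
#' reported in a message). IRIs such as `.../HP_0001250` are converted to
#' CURIEs (`HP:0001250`). Obsolete terms are retained and flagged.
#'
#' @param path Path to the JSON file.
#' @param dialect Input dialect; only `"obographs"` is supported.
#' @return An `ontology_graph`.
#' @export
load_ontology <- function(path, dialect = "obographs") {
  dialect <- arg_match(dialect, "obographs")
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("cannot parse ontology file: ", conditionMessage(e)),
                              class = "phenocurator_format_error")
  )
  graph <- doc$graphs[[1]]
  if (is.null(graph) || is.null(graph$nodes)) {
    abort("ontology file has no graphs[[1]]$nodes", class = "phenocurator_format_error")
  }
  nodes <- graph$nodes
  terms <- tibble(
    id = map_chr(nodes, function(n) iri_to_curie(n$id)),
    label = map_chr(nodes, function(n) n$lbl %||% ""),
    obsolete = map_lgl(nodes, function(n) isTRUE(n$meta$deprecated))
  )
  parents <- setNames(vector("list", nrow(terms)), terms$id)
  ignored <- 0L
  for (e in graph$edges %||% list()) {
    pred <- basename_fragment(e$pred %||% "")
    if (pred %in% c("is_a", "subClassOf")) {
      sub <- iri_to_curie(e$sub)
      obj <- iri_to_curie(e$obj)
      parents[[sub]] <- c(parents[[sub]], obj)
    } else {
      ignored <- ignored + 1L
    }
  }
  if (ignored > 0) {
    inform(paste0("load_ontology: ignored ", ignored, " non-is_a edge(s)"))
  }
  ontology_graph(terms, parents)
}

#' Write an ontology as obographs-style JSON
#'
#' Emits the same subset [load_ontology()] reads, so generated ontologies can
#' round-trip through files. The virtual root, if any, is not written.
#'
#' @param g An `ontology_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(g, path) {
  stopifnot(inherits(g, "ontology_graph"))
  terms <- ontology_terms(g)
  nodes <- purrr::pmap(terms, function(id, label, obsolete) {
    n <- list(id = id, lbl = label)
    if (obsolete) n$meta <- list(deprecated = TRUE)
    n
  })
  edges <- list()
  for (id in terms$id) {
    for (p in g$parents[[id]]) {
      if (g$virtual_root && p == g$root) next
      edges <- c(edges, list(list(sub = id, pred = "is_a", obj = p)))
    }
  }
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2), path, useBytes = TRUE)
  invisible(path)
}

iri_to_curie <- function(x) {
  x <- as.character(x)
  if (grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9.]+$", x)) return(x)
  frag <- basename_fragment(x)
  sub("_", ":", frag)
}

basename_fragment <- function(x) {
  x <- sub(".*#", "", x)
  sub(".*/", "", x)
}

#' CURIE and HPO identifier patterns
#'
#' @param x Character vector of candidate identifiers.
#' @return Logical vector.
#' @export
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9.]+$", x)
}

#' @rdname is_curie
#' @export
is_hpo_id <- function(x) {
  grepl("^HP:[0-9]{7}$", x)
}

curie_prefix <- function(x) sub(":.*$", "", x)
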