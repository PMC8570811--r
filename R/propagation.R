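#' Descendant descriptors of a MeSH descriptor
#'
#' Returns the descriptor itself plus every descriptor holding at least one
#' tree number that extends one of its tree numbers by dot-suffixing
#' (MeSH parentage is dot-prefix truncation). Polyhierarchy is honoured:
#' the union runs over all tree numbers of the query descriptor.
#'
#' @param kg a [knowledge_graph()].
#' @param d descriptor CURIE.
#' @return character vector of descriptor CURIEs, including `d`.
#' @export
mesh_descendants <- function(kg, d) {
  tns <- .descriptor_tree_numbers(kg, d)
  dd <- kg$descriptors[!is.na(kg$descriptors$tree_number), , drop = FALSE]
  hit <- rep(FALSE, nrow(dd))
  for (tn in tns) {
    hit <- hit | dd$tree_number == tn |
      startsWith(dd$tree_number, paste0(tn, "."))
  }
  sort(unique(c(d, dd$id[hit])))
}

#' Descendant classes of a chemical class
#'
#' The class itself plus all classes reachable against `subclass_of` edges
#' (i.e. its transitive subclasses). The subclass relation may be a DAG with
#' multiple parents.
#'
#' @param kg a [knowledge_graph()].
#' @param cls class CURIE.
#' @return character vector of class CURIEs, including `cls`.
#' @export
class_descendants <- function(kg, cls) {
  class_ids <- unique(kg$classes$id)
  if (!cls %in% class_ids) stop("unknown class: ", cls)
  if (nrow(kg$subclass_of) == 0L) return(cls)
  g <- igraph::graph_from_data_frame(kg$subclass_of, directed = TRUE,
                                     vertices = data.frame(name = class_ids))
  # edges run child -> parent, so descendants are vertices reaching cls
  reach <- igraph::subcomponent(g, cls, mode = "in")
  sort(igraph::V(g)$name[reach])
}

# ancestors (upward closure) of a class, including itself
.class_ancestors <- function(kg, cls) {
  class_ids <- unique(kg$classes$id)
  if (!cls %in% class_ids) stop("unknown class: ", cls)
  if (nrow(kg$subclass_of) == 0L) return(cls)
  g <- igraph::graph_from_data_frame(kg$subclass_of, directed = TRUE,
                                     vertices = data.frame(name = class_ids))
  reach <- igraph::subcomponent(g, cls, mode = "out")
  sort(igraph::V(g)$name[reach])
}

# ancestor descriptors of a descriptor (proper prefixes of its tree numbers),
# including itself
.mesh_ancestors <- function(kg, d) {
  tns <- .descriptor_tree_numbers(kg, d)
  prefixes <- character()
  for (tn in tns) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    prefixes <- c(prefixes, vapply(seq_along(parts), function(i)
      paste(parts[seq_len(i)], collapse = "."), character(1L)))
  }
  sort(unique(kg$descriptors$id[kg$descriptors$tree_number %in% prefixes]))
}

#' Build explicit and propagated article corpora
#'
#' Computes, for every compound, chemical class and MeSH descriptor, the set
#' of articles supporting it. Explicit corpora come straight from the graph
#' edges: `discusses` for compounds, `subject_terms` for descriptors, and for
#' a class the union over its direct member compounds. Propagated corpora
#' apply the true-path rule: annotation of an article to a concept implicitly
#' annotates every ancestor, so an ancestor's corpus is the union of the
#' explicit corpora over its descendant closure. Compounds are leaves of both
#' hierarchies and keep their explicit corpus.
#'
#' Propagation is computed bottom-up over a topological order with set-union
#' memoisation; the result is identical to a per-node descendant-closure
#' union and independent of traversal order.
#'
#' @param kg a valid [knowledge_graph()]; an invalid graph is refused with
#'   its validation report.
#' @param use_propagation logical; when `FALSE` the propagated corpora equal
#'   the explicit corpora for every entity (the "without true-path rule"
#'   analysis mode).
#' @param universe `"all"` (default) counts every distinct article in the
#'   graph in the corpus universe N; `"mesh_annotated"` restricts N to
#'   articles carrying at least one descriptor annotation.
#' @return An object of class `corpus_index`: list with named-list members
#'   `explicit` and `propagated` (entity CURIE to character vector of article
#'   ids) and scalar `N`.
#' @export
build_corpus_index <- function(kg, use_propagation = TRUE,
                               universe = c("all", "mesh_annotated")) {
  universe <- match.arg(universe)
  .assert_valid(kg)

  aset <- function(x) {            # NULL-safe sorted article set
    if (length(x) == 0L) character() else sort(unique(x))
  }
  explicit <- list()
  # compounds
  comp_split <- split(kg$discusses$article, kg$discusses$compound)
  for (id in kg$compounds) {
    explicit[id] <- list(aset(comp_split[[id]]))
  }
  # descriptors
  desc_split <- split(kg$subject_terms$article, kg$subject_terms$descriptor)
  desc_ids <- unique(kg$descriptors$id)
  for (id in desc_ids) {
    explicit[id] <- list(aset(desc_split[[id]]))
  }
  # classes: union over direct member compounds
  class_ids <- unique(kg$classes$id)
  memb_split <- split(kg$class_membership$compound, kg$class_membership$class)
  for (id in class_ids) {
    arts <- unlist(comp_split[memb_split[[id]]], use.names = FALSE)
    explicit[id] <- list(aset(arts))
  }

  if (!use_propagation) {
    propagated <- explicit
  } else {
    propagated <- explicit
    # --- descriptors: bottom-up over the tree-number forest -------------
    dd <- kg$descriptors[!is.na(kg$descriptors$tree_number), , drop = FALSE]
    tn <- dd$tree_number
    tn_desc <- stats::setNames(dd$id, tn)               # tree numbers unique
    depth <- lengths(strsplit(tn, ".", fixed = TRUE))
    acc <- new.env(parent = emptyenv())                 # tn -> article set
    for (t in tn) assign(t, character(), envir = acc)
    # nearest existing proper prefix, climbing over missing intermediates
    nearest_parent <- function(t) {
      p <- .tree_parent(t)
      while (!is.na(p)) {
        if (p %in% names(tn_desc)) return(p)
        p <- .tree_parent(p)
      }
      NA_character_
    }
    ord <- order(depth, decreasing = TRUE)   # deepest first
    for (i in ord) {
      t <- tn[i]
      own <- union(get(t, envir = acc), explicit[[tn_desc[[t]]]])
      assign(t, own, envir = acc)
      p <- nearest_parent(t)
      if (!is.na(p)) assign(p, union(get(p, envir = acc), own), envir = acc)
    }
    for (id in desc_ids) {
      tns_d <- tn[dd$id == id]
      sets <- lapply(tns_d, get, envir = acc)
      propagated[id] <- list(aset(c(explicit[[id]],
                                    unlist(sets, use.names = FALSE))))
    }
    # --- classes: bottom-up over the subclass DAG -----------------------
    if (length(class_ids) > 0L) {
      cacc <- stats::setNames(vector("list", length(class_ids)), class_ids)
      for (id in class_ids) {
        arts <- unlist(comp_split[memb_split[[id]]], use.names = FALSE)
        cacc[id] <- list(aset(arts))
      }
      if (nrow(kg$subclass_of) > 0L) {
        g <- igraph::graph_from_data_frame(
          kg$subclass_of, directed = TRUE,
          vertices = data.frame(name = class_ids))
        ord <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]
        # edges child -> parent: visiting children before parents pushes
        # accumulated sets upward exactly once per edge
        parent_of <- split(kg$subclass_of$parent, kg$subclass_of$child)
        for (id in ord) {
          for (p in parent_of[[id]]) {
            cacc[[p]] <- union(cacc[[p]], cacc[[id]])
          }
        }
      }
      for (id in class_ids) propagated[id] <- list(aset(cacc[[id]]))
    }
  }

  N <- if (universe == "all") length(kg$articles)
       else length(unique(kg$subject_terms$article))
  structure(list(explicit = explicit, propagated = propagated, N = N,
                 universe = universe, use_propagation = use_propagation),
            class = "corpus_index")
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("<corpus_index>", length(x$explicit), "entities, N =", x$N,
      if (x$use_propagation) "(propagated)" else "(explicit only)", "\n")
  invisible(x)
}

.corpus <- function(index, e) {
  if (!e %in% names(index$propagated)) stop("entity not indexed: ", e)
  index$propagated[[e]]
}

#' Propagated co-occurrence count of two entities
#'
#' Number of articles in the intersection of the two propagated corpora.
#'
#' @param index a [build_corpus_index()] result.
#' @param e1,e2 entity CURIEs present in the index.
#' @return non-negative integer.
#' @export
cooccurrence <- function(index, e1, e2) {
  length(intersect(.corpus(index, e1), .corpus(index, e2)))
}
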