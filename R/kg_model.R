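#' Construct a chemical-literature knowledge graph
#'
#' Builds the typed in-memory graph linking scientific articles, chemical
#' compounds, chemical classes and MeSH descriptors. Node and edge inputs are
#' deduplicated (set semantics) and sorted so that two graphs built from the
#' same facts in any order compare identical.
#'
#' Entity identifiers are opaque CURIEs whose prefix determines the entity
#' kind: `compound:` for compounds, `chebi:`/`chemont:` for chemical classes
#' and `mesh:` for descriptors. Article identifiers (modelling PMIDs) are
#' free-form non-empty strings. Descriptor hierarchy is carried by
#' dot-separated MeSH tree numbers (the parent of `"C18.452.394"` is
#' `"C18.452"`); chemical-class hierarchy by explicit `subclass_of` edges,
#' which must form a DAG.
#'
#' @param articles character vector of article identifiers.
#' @param compounds character vector of compound CURIEs (`compound:` prefix).
#' @param classes data.frame with columns `id` (CURIE, `chebi:`/`chemont:`
#'   prefix) and `ontology` (`"chebi"` or `"chemont"`).
#' @param descriptors data.frame with columns `id` (`mesh:` CURIE) and
#'   `tree_number`; a descriptor with several tree numbers occupies several
#'   rows (MeSH polyhierarchy).
#' @param discusses data.frame with columns `article`, `compound`: the
#'   article discusses the compound.
#' @param subject_terms data.frame with columns `article`, `descriptor`: the
#'   article is indexed with the descriptor.
#' @param class_membership data.frame with columns `compound`, `class`.
#' @param subclass_of data.frame with columns `child`, `parent` over class
#'   CURIEs.
#' @param parent_tree_numbers optional data.frame with columns `tree_number`,
#'   `parent_tree_number`, as stated by explicit hierarchy triples; checked
#'   against dot-prefix parentage by [validate_kg()].
#' @return An object of class `knowledge_graph`.
#' @seealso [validate_kg()], [build_corpus_index()]
#' @export
knowledge_graph <- function(articles = character(),
                            compounds = character(),
                            classes = NULL,
                            descriptors = NULL,
                            discusses = NULL,
                            subject_terms = NULL,
                            class_membership = NULL,
                            subclass_of = NULL,
                            parent_tree_numbers = NULL) {
  classes <- .as_edge_df(classes, c("id", "ontology"))
  descriptors <- .as_edge_df(descriptors, c("id", "tree_number"))
  discusses <- .as_edge_df(discusses, c("article", "compound"))
  subject_terms <- .as_edge_df(subject_terms, c("article", "descriptor"))
  class_membership <- .as_edge_df(class_membership, c("compound", "class"))
  subclass_of <- .as_edge_df(subclass_of, c("child", "parent"))
  if (!is.null(parent_tree_numbers)) {
    parent_tree_numbers <- .as_edge_df(parent_tree_numbers,
                                       c("tree_number", "parent_tree_number"))
  }
  kg <- structure(list(
    articles = sort(unique(as.character(articles))),
    compounds = sort(unique(as.character(compounds))),
    classes = classes,
    descriptors = descriptors,
    discusses = discusses,
    subject_terms = subject_terms,
    class_membership = class_membership,
    subclass_of = subclass_of,
    parent_tree_numbers = parent_tree_numbers
  ), class = "knowledge_graph")
  kg
}

# normalize an edge table: coerce to character columns, dedupe, sort rows
.as_edge_df <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < length(cols)) {
    stop("expected columns ", paste(cols, collapse = ", "))
  }
  x <- x[, seq_along(cols), drop = FALSE]
  names(x) <- cols
  for (j in seq_along(x)) x[[j]] <- as.character(x[[j]])
  x <- unique(x)
  x <- x[do.call(order, x), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph>\n")
  cat("  articles:        ", length(x$articles), "\n")
  cat("  compounds:       ", length(x$compounds), "\n")
  cat("  classes:         ", length(unique(x$classes$id)), "\n")
  cat("  descriptors:     ", length(unique(x$descriptors$id)), "\n")
  cat("  discusses:       ", nrow(x$discusses), "\n")
  cat("  subject_terms:   ", nrow(x$subject_terms), "\n")
  cat("  class_membership:", nrow(x$class_membership), "\n")
  cat("  subclass_of:     ", nrow(x$subclass_of), "\n")
  invisible(x)
}

#' Entity kind of a CURIE
#'
#' Maps an identifier prefix to its entity kind: `compound:` is a compound,
#' `chebi:`/`chemont:` a chemical class, `mesh:` a MeSH descriptor.
#'
#' @param id character vector of CURIEs.
#' @return character vector with values `"compound"`, `"chemical_class"`,
#'   `"mesh_descriptor"` or `NA` for unrecognized prefixes.
#' @export
entity_kind <- function(id) {
  prefix <- sub(":.*$", "", id)
  unname(c(compound = "compound", chebi = "chemical_class",
           chemont = "chemical_class", mesh = "mesh_descriptor")[prefix])
}

#' Validate a knowledge graph
#'
#' Checks every structural invariant of the graph and reports violations as
#' data, one row each: empty identifiers, edges with unknown endpoints,
#' identifier prefixes inconsistent with node role, tree numbers shared by
#' several descriptors, cycles in the chemical-class subclass relation, and
#' explicit parent-tree-number assertions that contradict dot-prefix
#' parentage. Validation never throws for invalid data and is idempotent.
#'
#' @param kg a [knowledge_graph()].
#' @return data.frame with columns `rule`, `item`, `message`; zero rows iff
#'   the graph is valid.
#' @export
validate_kg <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  v <- list()
  add <- function(rule, item, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, item = item,
                                       message = message)
  }

  if (any(!nzchar(kg$articles))) add("empty-id", "<article>", "empty article identifier")
  for (id in kg$compounds) {
    if (!nzchar(id)) add("empty-id", "<compound>", "empty compound identifier")
    else if (!identical(entity_kind(id), "compound"))
      add("prefix-kind", id, "compound identifier must use the compound: prefix")
  }
  class_ids <- unique(kg$classes$id)
  for (id in class_ids) {
    if (!identical(entity_kind(id), "chemical_class"))
      add("prefix-kind", id, "class identifier must use a chebi:/chemont: prefix")
  }
  bad_ont <- kg$classes$id[!kg$classes$ontology %in% c("chebi", "chemont")]
  for (id in bad_ont) add("class-ontology", id, "ontology must be chebi or chemont")

  desc_ids <- unique(kg$descriptors$id)
  for (id in desc_ids) {
    if (!identical(entity_kind(id), "mesh_descriptor"))
      add("prefix-kind", id, "descriptor identifier must use the mesh: prefix")
  }
  tns_known <- kg$descriptors$tree_number[!is.na(kg$descriptors$tree_number)]
  dup_tn <- tns_known[duplicated(tns_known)]
  for (tn in unique(dup_tn))
    add("tree-number-clash", tn, "tree number assigned to several descriptors")
  bad_tn <- tns_known[!grepl("^[A-Z]([0-9]+)?(\\.[0-9A-Za-z]+)*$", tns_known)]
  for (tn in unique(bad_tn))
    add("tree-number-syntax", tn, "malformed tree number")
  n_tn <- tapply(!is.na(kg$descriptors$tree_number), kg$descriptors$id, sum)
  for (id in names(n_tn)[n_tn == 0L])
    add("missing-tree-number", id, "descriptor carries no tree number")

  .check_edges <- function(df, col1, set1, col2, set2, rule) {
    miss1 <- setdiff(df[[col1]], set1)
    miss2 <- setdiff(df[[col2]], set2)
    for (m in miss1) add(rule, m, sprintf("edge endpoint %s not a declared %s", m, col1))
    for (m in miss2) add(rule, m, sprintf("edge endpoint %s not a declared %s", m, col2))
  }
  .check_edges(kg$discusses, "article", kg$articles, "compound", kg$compounds,
               "dangling-edge")
  .check_edges(kg$subject_terms, "article", kg$articles, "descriptor", desc_ids,
               "dangling-edge")
  .check_edges(kg$class_membership, "compound", kg$compounds, "class", class_ids,
               "dangling-edge")
  .check_edges(kg$subclass_of, "child", class_ids, "parent", class_ids,
               "dangling-edge")

  if (nrow(kg$subclass_of) > 0L) {
    g <- igraph::graph_from_data_frame(kg$subclass_of, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- kg$subclass_of$child[1L]
      comp <- igraph::components(g, mode = "strong")
      in_cycle <- names(comp$membership)[comp$membership %in%
                                           which(comp$csize > 1L)]
      add("subclass-cycle", paste(sort(in_cycle), collapse = ","),
          "subclass_of relation contains a cycle")
    }
  }

  if (!is.null(kg$parent_tree_numbers) && nrow(kg$parent_tree_numbers) > 0L) {
    ptn <- kg$parent_tree_numbers
    expected <- .tree_parent(ptn$tree_number)
    bad <- which(is.na(expected) | expected != ptn$parent_tree_number)
    for (i in bad)
      add("parent-tree-number", ptn$tree_number[i],
          sprintf("asserted parent %s disagrees with prefix parent %s",
                  ptn$parent_tree_number[i],
                  ifelse(is.na(expected[i]), "<none>", expected[i])))
  }

  if (length(v) == 0L) {
    return(data.frame(rule = character(), item = character(),
                      message = character()))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

# dot-prefix parent of a tree number; NA for roots
.tree_parent <- function(tn) {
  has_dot <- grepl(".", tn, fixed = TRUE)
  out <- rep(NA_character_, length(tn))
  out[has_dot] <- sub("\\.[^.]+$", "", tn[has_dot])
  out
}

#' MeSH category letters of a descriptor
#'
#' Each MeSH tree number starts with the letter of its top-level category
#' (C for Diseases, A for Anatomy, B for Organisms, D for Chemicals and
#' Drugs, F for Psychiatry and Psychology, G for Phenomena and Processes,
#' I for Anthropology/Education/Sociology, J for Technology/Industry/
#' Agriculture, ...). A polyhierarchical descriptor may span several
#' categories.
#'
#' @param kg a [knowledge_graph()], or `NULL` when `d` is a character vector
#'   of tree numbers.
#' @param d a descriptor CURIE present in `kg`, or (with `kg = NULL`) a
#'   character vector of tree numbers.
#' @return character vector of distinct category letters.
#' @examples
#' mesh_category(NULL, c("D02.092", "C10.228"))
#' @export
mesh_category <- function(kg, d) {
  tns <- if (is.null(kg)) d else .descriptor_tree_numbers(kg, d)
  if (length(tns) == 0L) stop("descriptor has no tree numbers: ", d)
  sort(unique(substr(tns, 1L, 1L)))
}

.descriptor_tree_numbers <- function(kg, d) {
  tns <- kg$descriptors$tree_number[kg$descriptors$id == d]
  if (length(tns) == 0L) stop("unknown descriptor: ", d)
  tns[!is.na(tns)]
}

#' Transitive compound count of a chemical class
#'
#' Number of distinct compounds belonging to the class or to any of its
#' transitive subclasses. Used to exclude overly broad classes (the default
#' enrichment configuration drops classes with 1000 or more member
#' compounds).
#'
#' @param kg a [knowledge_graph()].
#' @param cls a class CURIE present in `kg`.
#' @return non-negative integer.
#' @export
class_member_count <- function(kg, cls) {
  members <- .class_members(kg, cls)
  length(members)
}

# distinct compounds of a class or any transitive subclass
.class_members <- function(kg, cls) {
  desc <- class_descendants(kg, cls)
  unique(kg$class_membership$compound[kg$class_membership$class %in% desc])
}

# stop with validation details unless the graph is valid
.assert_valid <- function(kg) {
  rep <- validate_kg(kg)
  if (nrow(rep) > 0L) {
    stop("invalid knowledge graph: ",
         paste(utils::head(rep$message, 5L), collapse = "; "),
         if (nrow(rep) > 5L) sprintf(" (and %d more)", nrow(rep) - 5L) else "")
  }
  invisible(kg)
}
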