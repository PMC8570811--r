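#' Default CURIE prefix map
#'
#' Namespaces for the RDF dialect understood by the readers and writers:
#' PubChem compounds and references, MeSH descriptors and vocabulary, ChEBI
#' and ChemOnt classes, and the CiTO/FaBiO/RDF(S)/SKOS predicates.
#'
#' @return named character vector, prefix to namespace IRI.
#' @export
default_prefixes <- function() {
  c(compound = "http://rdf.ncbi.nlm.nih.gov/pubchem/compound/",
    reference = "http://rdf.ncbi.nlm.nih.gov/pubchem/reference/",
    mesh = "http://id.nlm.nih.gov/mesh/",
    chebi = "http://purl.obolibrary.org/obo/CHEBI_",
    chemont = "http://purl.obolibrary.org/obo/CHEMONTID_",
    cito = "http://purl.org/spar/cito/",
    fabio = "http://purl.org/spar/fabio/",
    meshv = "http://id.nlm.nih.gov/mesh/vocab#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    skos = "http://www.w3.org/2004/02/skos/core#")
}

# expand prefix:local to <iri>; leave full IRIs and unknown prefixes alone
.expand_curie <- function(x, prefixes) {
  pfx <- sub(":.*$", "", x)
  local <- sub("^[^:]*:", "", x)
  known <- pfx %in% names(prefixes)
  out <- x
  out[known] <- paste0(prefixes[pfx[known]], local[known])
  out
}

# contract a full IRI to prefix:local using the longest matching namespace
.contract_iri <- function(iri, prefixes) {
  ord <- order(nchar(prefixes), decreasing = TRUE)
  for (i in ord) {
    ns <- prefixes[i]
    if (startsWith(iri, ns)) {
      return(paste0(names(prefixes)[i], ":", substring(iri, nchar(ns) + 1L)))
    }
  }
  iri
}

# tokenize one statement line into term strings
.rdf_tokens <- function(line) {
  pat <- '<[^>]*>|"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^\\S+|@[A-Za-z-]+)?|\\S+'
  regmatches(line, gregexpr(pat, line, perl = TRUE))[[1L]]
}

# normalize one term: IRIs contracted to CURIEs, literals to their lexical
# value (attribute literal = TRUE)
.rdf_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) {
    iri <- sub("^<", "", sub(">$", "", tok))
    return(list(value = .contract_iri(iri, prefixes), literal = FALSE))
  }
  if (startsWith(tok, '"')) {
    val <- sub('^"', "", sub('"(\\^\\^\\S+|@[A-Za-z-]+)?$', "", tok))
    val <- gsub('\\\\(["\\\\])', "\\1", val)
    return(list(value = val, literal = TRUE))
  }
  if (tok == "a") return(list(value = "rdf:type", literal = FALSE))
  list(value = tok, literal = FALSE)
}

# article identifiers are opaque: drop the namespace prefix added on export
.article_id <- function(curie) sub("^[^:]*:", "", curie)

.is_tree_number <- function(x) grepl("^[A-Z]([0-9]+)?(\\.[0-9A-Za-z]+)+$|^[A-Z][0-9]+$", x)

#' Parse a knowledge graph from RDF
#'
#' Reads Turtle or N-Triples restricted to one statement per line (the
#' dialect the package's writers emit; `@prefix`/`PREFIX` declarations,
#' comment lines and blank lines are handled). Recognized predicates map to
#' graph edges: `cito:discusses` (article to compound),
#' `fabio:hasSubjectTerm` (article to descriptor), `rdf:type` with an object
#' in a chemical-ontology namespace (compound to class), `rdfs:subClassOf`
#' (class hierarchy), `meshv:treeNumber` (descriptor tree number, literal or
#' mesh-namespace IRI) and `meshv:parentTreeNumber` (explicit hierarchy
#' assertions, kept for validation). All other triples are ignored and
#' counted in the `ignored_triples` attribute.
#'
#' @param path file to read.
#' @param format `"turtle"` or `"ntriples"`.
#' @param prefixes prefix map used to contract IRIs; file-level `@prefix`
#'   declarations are added to it.
#' @return a [knowledge_graph()] with attribute `ignored_triples`.
#' @export
parse_rdf <- function(path, format = c("turtle", "ntriples"),
                      prefixes = default_prefixes()) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  triples <- list()
  ignored <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^@prefix|^PREFIX", line)) {
      m <- regmatches(line,
                      regexec("^@?[Pp][Rr][Ee][Ff][Ii][Xx]\\s+([A-Za-z0-9_-]*):\\s*<([^>]*)>",
                              line))[[1L]]
      if (length(m) == 3L) prefixes[m[2L]] <- m[3L]
      next
    }
    toks <- .rdf_tokens(line)
    if (length(toks) >= 1L && toks[length(toks)] == ".") {
      toks <- toks[-length(toks)]
    } else if (length(toks) >= 1L && endsWith(toks[length(toks)], ".")) {
      toks[length(toks)] <- sub("\\.$", "", toks[length(toks)])
    }
    if (length(toks) != 3L) {
      stop(sprintf("%s:%d: cannot parse statement: %s", path, ln, line))
    }
    triples[[length(triples) + 1L]] <-
      list(s = .rdf_term(toks[1L], prefixes),
           p = .rdf_term(toks[2L], prefixes),
           o = .rdf_term(toks[3L], prefixes))
  }

  discusses <- list(); subject_terms <- list(); membership <- list()
  subclass <- list(); treenum <- list(); ptn <- list()
  desc_seen <- character(); comp_seen <- character(); class_seen <- character()
  for (t in triples) {
    pred <- t$p$value
    s <- t$s$value; o <- t$o$value
    if (pred == "cito:discusses") {
      discusses[[length(discusses) + 1L]] <- c(.article_id(s), o)
      comp_seen <- c(comp_seen, o)
    } else if (pred == "fabio:hasSubjectTerm") {
      subject_terms[[length(subject_terms) + 1L]] <- c(.article_id(s), o)
      desc_seen <- c(desc_seen, o)
    } else if (pred == "rdf:type" &&
               entity_kind(o) %in% "chemical_class") {
      membership[[length(membership) + 1L]] <- c(s, o)
      comp_seen <- c(comp_seen, s); class_seen <- c(class_seen, o)
    } else if (pred == "rdf:type" && o == "rdfs:Class" &&
               entity_kind(s) %in% "chemical_class") {
      class_seen <- c(class_seen, s)
    } else if (pred == "rdfs:subClassOf") {
      subclass[[length(subclass) + 1L]] <- c(s, o)
      class_seen <- c(class_seen, s, o)
    } else if (pred == "meshv:treeNumber") {
      tn <- if (t$o$literal) o else sub("^mesh:", "", o)
      treenum[[length(treenum) + 1L]] <- c(s, tn)
      desc_seen <- c(desc_seen, s)
    } else if (pred == "meshv:parentTreeNumber") {
      tn_child <- if (t$s$literal) s else sub("^mesh:", "", s)
      tn_parent <- if (t$o$literal) o else sub("^mesh:", "", o)
      ptn[[length(ptn) + 1L]] <- c(tn_child, tn_parent)
    } else {
      ignored <- ignored + 1L
    }
  }
  .bind2 <- function(lst, cols) {
    if (length(lst) == 0L) return(NULL)
    df <- as.data.frame(do.call(rbind, lst), stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }
  discusses <- .bind2(discusses, c("article", "compound"))
  subject_terms <- .bind2(subject_terms, c("article", "descriptor"))
  membership <- .bind2(membership, c("compound", "class"))
  subclass <- .bind2(subclass, c("child", "parent"))
  treenum <- .bind2(treenum, c("id", "tree_number"))
  ptn <- .bind2(ptn, c("tree_number", "parent_tree_number"))

  desc_seen <- sort(unique(desc_seen))
  descriptors <- if (!is.null(treenum)) treenum else
    data.frame(id = character(), tree_number = character())
  missing_desc <- setdiff(desc_seen, descriptors$id)
  if (length(missing_desc) > 0L) {
    descriptors <- rbind(descriptors,
                         data.frame(id = missing_desc,
                                    tree_number = NA_character_))
  }
  articles <- sort(unique(c(
    if (!is.null(discusses)) discusses$article,
    if (!is.null(subject_terms)) subject_terms$article)))
  class_seen <- sort(unique(class_seen))
  kg <- knowledge_graph(
    articles = articles,
    compounds = sort(unique(comp_seen)),
    classes = if (length(class_seen) > 0L)
      data.frame(id = class_seen, ontology = sub(":.*$", "", class_seen))
      else NULL,
    descriptors = descriptors,
    discusses = discusses,
    subject_terms = subject_terms,
    class_membership = membership,
    subclass_of = subclass,
    parent_tree_numbers = ptn)
  attr(kg, "ignored_triples") <- ignored
  kg
}

.fmt_term <- function(curie, prefixes, format) {
  if (format == "turtle") curie else paste0("<", .expand_curie(curie, prefixes), ">")
}

# shared triple writer; triples is a data.frame s/p/o with o_literal flag
.write_triples <- function(triples, path, prefixes, format) {
  lines <- character()
  if (format == "turtle") {
    used <- sort(names(prefixes))
    lines <- c(sprintf("@prefix %s: <%s> .", used, prefixes[used]), "")
  }
  if (nrow(triples) > 0L) {
    o <- ifelse(triples$o_literal,
                paste0('"', triples$o, '"'),
                vapply(triples$o, .fmt_term, character(1L),
                       prefixes = prefixes, format = format))
    s <- vapply(triples$s, .fmt_term, character(1L),
                prefixes = prefixes, format = format)
    p <- vapply(triples$p, .fmt_term, character(1L),
                prefixes = prefixes, format = format)
    lines <- c(lines, paste(s, p, o, "."))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a knowledge graph to Turtle or N-Triples
#'
#' Emits one statement per line using the predicates of the input dialect
#' (`cito:discusses`, `fabio:hasSubjectTerm`, `rdf:type`, `rdfs:subClassOf`,
#' `meshv:treeNumber` as string literals), with article identifiers placed
#' under the `reference:` namespace. Output ordering is deterministic, so
#' rewriting the same graph is byte-identical.
#'
#' @param kg a [knowledge_graph()].
#' @param path output file.
#' @param prefixes prefix map, see [default_prefixes()].
#' @param format `"turtle"` or `"ntriples"`.
#' @return the path, invisibly.
#' @export
write_kg_rdf <- function(kg, path, prefixes = default_prefixes(),
                         format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  tn <- kg$descriptors[!is.na(kg$descriptors$tree_number), , drop = FALSE]
  tr <- function(s, p, o, lit = FALSE) {
    data.frame(s = s, p = rep(p, length(s)), o = o,
               o_literal = rep(lit, length(s)))
  }
  class_ids <- unique(kg$classes$id)
  triples <- rbind(
    tr(paste0("reference:", kg$discusses$article), "cito:discusses",
       kg$discusses$compound),
    tr(paste0("reference:", kg$subject_terms$article), "fabio:hasSubjectTerm",
       kg$subject_terms$descriptor),
    tr(kg$class_membership$compound, "rdf:type", kg$class_membership$class),
    # declare every class so edge-isolated classes survive a round trip
    tr(class_ids, "rdf:type", rep("rdfs:Class", length(class_ids))),
    tr(kg$subclass_of$child, "rdfs:subClassOf", kg$subclass_of$parent),
    tr(tn$id, "meshv:treeNumber", tn$tree_number, lit = TRUE))
  triples <- triples[order(triples$p, triples$s, triples$o), , drop = FALSE]
  .write_triples(triples, path, prefixes, format)
}

#' Write significant associations as skos:related triples
#'
#' One `<chemical entity> skos:related <descriptor>` statement per record
#' (by default only the significant ones), in deterministic order. With
#' `rdf_stats = TRUE` the p/q/odds-ratio/chi-squared/fragility values are
#' additionally emitted as literal-valued triples under an ad-hoc
#' `assoc:` vocabulary attached to a per-pair node.
#'
#' @param records [run_enrichment()] output.
#' @param path output file.
#' @param prefixes prefix map.
#' @param only_significant keep only significant records (default TRUE).
#' @param format `"turtle"` or `"ntriples"`.
#' @param rdf_stats also emit the statistics as literals (default FALSE).
#' @return the path, invisibly.
#' @export
write_association_turtle <- function(records, path,
                                     prefixes = default_prefixes(),
                                     only_significant = TRUE,
                                     format = c("turtle", "ntriples"),
                                     rdf_stats = FALSE) {
  format <- match.arg(format)
  r <- if (only_significant) records[records$significant, , drop = FALSE]
       else records
  r <- r[order(r$chem_id, r$mesh_id), , drop = FALSE]
  triples <- data.frame(s = r$chem_id,
                        p = rep("skos:related", nrow(r)),
                        o = r$mesh_id,
                        o_literal = rep(FALSE, nrow(r)))
  if (rdf_stats && nrow(r) > 0L) {
    prefixes <- c(prefixes, assoc = "urn:chemesh:association:")
    node <- paste0("assoc:", gsub(":", "_", r$chem_id), "--",
                   gsub(":", "_", r$mesh_id))
    stat <- function(p, v) data.frame(s = node, p = p,
                                      o = sprintf("%.15g", v),
                                      o_literal = TRUE)
    triples <- rbind(triples,
                     stat("assoc:pValue", r$p_value),
                     stat("assoc:qValue", r$q_value),
                     stat("assoc:oddsRatio", r$odds_ratio),
                     stat("assoc:chiSquared", r$chi2),
                     data.frame(s = node, p = "assoc:support",
                                o = as.character(r$support), o_literal = TRUE))
  }
  .write_triples(triples, path, prefixes, format)
}

#' Parse a knowledge graph from TSV edge lists
#'
#' Tab-separated alternative to RDF ingestion with identical graph
#' semantics. `files` is a named list/vector of paths; recognized names are
#' `discusses` (article, compound), `subject_terms` (article, descriptor),
#' `class_membership` (compound, class), `subclass_of` (child, parent),
#' `descriptors` (descriptor, tree_number), plus the optional `articles`
#' (single column, declaring edge-less universe articles) and `classes`
#' (id, ontology; declares edge-isolated classes). Each file has a header
#' line; duplicate rows collapse to one edge.
#'
#' @param files named character vector of paths.
#' @return a [knowledge_graph()].
#' @export
parse_tsv <- function(files) {
  rd <- function(name, ncol_needed) {
    if (!name %in% names(files)) return(NULL)
    df <- utils::read.delim(files[[name]], header = TRUE,
                            colClasses = "character", sep = "\t",
                            quote = "", comment.char = "")
    if (ncol(df) < ncol_needed) {
      stop(sprintf("%s: expected %d tab-separated columns", files[[name]],
                   ncol_needed))
    }
    df
  }
  discusses <- rd("discusses", 2L)
  subject_terms <- rd("subject_terms", 2L)
  membership <- rd("class_membership", 2L)
  subclass <- rd("subclass_of", 2L)
  descriptors <- rd("descriptors", 2L)
  articles_file <- rd("articles", 1L)
  classes_file <- rd("classes", 1L)

  desc_seen <- sort(unique(c(
    if (!is.null(subject_terms)) subject_terms[[2L]],
    if (!is.null(descriptors)) descriptors[[1L]])))
  if (is.null(descriptors)) {
    descriptors <- data.frame(id = character(), tree_number = character())
  } else {
    names(descriptors)[1:2] <- c("id", "tree_number")
  }
  missing_desc <- setdiff(desc_seen, descriptors$id)
  if (length(missing_desc) > 0L) {
    descriptors <- rbind(descriptors[, c("id", "tree_number")],
                         data.frame(id = missing_desc,
                                    tree_number = NA_character_))
  }
  class_seen <- sort(unique(c(
    if (!is.null(membership)) membership[[2L]],
    if (!is.null(subclass)) unlist(subclass[, 1:2]),
    if (!is.null(classes_file)) classes_file[[1L]])))
  compounds <- sort(unique(c(
    if (!is.null(discusses)) discusses[[2L]],
    if (!is.null(membership)) membership[[1L]])))
  articles <- sort(unique(c(
    if (!is.null(discusses)) discusses[[1L]],
    if (!is.null(subject_terms)) subject_terms[[1L]],
    if (!is.null(articles_file)) articles_file[[1L]])))
  knowledge_graph(
    articles = articles,
    compounds = compounds,
    classes = if (length(class_seen) > 0L)
      data.frame(id = class_seen, ontology = sub(":.*$", "", class_seen))
      else NULL,
    descriptors = descriptors,
    discusses = discusses,
    subject_terms = subject_terms,
    class_membership = membership,
    subclass_of = subclass)
}

#' Write a knowledge graph as TSV edge lists
#'
#' Inverse of [parse_tsv()]: writes `discusses.tsv`, `subject_terms.tsv`,
#' `class_membership.tsv`, `subclass_of.tsv`, `descriptors.tsv` and
#' `articles.tsv` into a directory.
#'
#' @param kg a [knowledge_graph()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_kg_tsv <- function(kg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(discusses = file.path(dir, "discusses.tsv"),
           subject_terms = file.path(dir, "subject_terms.tsv"),
           class_membership = file.path(dir, "class_membership.tsv"),
           subclass_of = file.path(dir, "subclass_of.tsv"),
           descriptors = file.path(dir, "descriptors.tsv"),
           articles = file.path(dir, "articles.tsv"),
           classes = file.path(dir, "classes.tsv"))
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wr(kg$discusses, out[["discusses"]])
  wr(kg$subject_terms, out[["subject_terms"]])
  wr(kg$class_membership, out[["class_membership"]])
  wr(kg$subclass_of, out[["subclass_of"]])
  wr(kg$descriptors[!is.na(kg$descriptors$tree_number), , drop = FALSE],
     out[["descriptors"]])
  wr(data.frame(article = kg$articles), out[["articles"]])
  wr(kg$classes, out[["classes"]])
  invisible(out)
}

#' Write the association results table
#'
#' TSV with the fixed column contract `chem_id, mesh_id, support, n_chem,
#' n_mesh, N, p_value, q_value, odds_ratio, or_corrected_flag, chi2,
#' fragility, significant`, one row per tested pair in the deterministic
#' record order. The fragility column prints the integer index, `>=r` when
#' the Jeffreys cap was reached (robust association) and `NA` for
#' non-significant pairs.
#'
#' @param records [run_enrichment()] output.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results_table <- function(records, path) {
  frag <- ifelse(is.na(records$fragility), "NA",
                 ifelse(!is.na(records$fragility_capped) & records$fragility_capped,
                        paste0(">=", records$fragility),
                        as.character(records$fragility)))
  out <- data.frame(chem_id = records$chem_id, mesh_id = records$mesh_id,
                    support = records$support, n_chem = records$n_chem,
                    n_mesh = records$n_mesh, N = records$N,
                    p_value = sprintf("%.15g", records$p_value),
                    q_value = sprintf("%.15g", records$q_value),
                    odds_ratio = sprintf("%.15g", records$odds_ratio),
                    or_corrected_flag = records$or_corrected_flag,
                    chi2 = sprintf("%.15g", records$chi2),
                    fragility = frag,
                    significant = records$significant)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an association results table back
#'
#' Inverse of [write_results_table()]; reconstructs the numeric columns and
#' splits the fragility column into the integer index and the robust-cap
#' flag.
#'
#' @param path TSV written by [write_results_table()].
#' @return data.frame of class `association_records`.
#' @export
read_results_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  out <- data.frame(chem_id = df$chem_id, mesh_id = df$mesh_id,
                    support = as.integer(df$support),
                    n_chem = as.integer(df$n_chem),
                    n_mesh = as.integer(df$n_mesh),
                    N = as.integer(df$N),
                    p_value = as.numeric(df$p_value),
                    q_value = as.numeric(df$q_value),
                    odds_ratio = as.numeric(df$odds_ratio),
                    or_corrected_flag = as.logical(df$or_corrected_flag),
                    chi2 = as.numeric(df$chi2),
                    fragility = suppressWarnings(
                      as.integer(sub("^>=", "", df$fragility))),
                    fragility_capped = ifelse(df$fragility == "NA", NA,
                                              startsWith(df$fragility, ">=")),
                    significant = as.logical(df$significant))
  class(out) <- c("association_records", class(out))
  out
}

#' Write a TF-IDF importance profile
#'
#' TSV with columns `mesh_id, tf, idf, score, rank`.
#'
#' @param profile [importance_scores()] output.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  out <- data.frame(mesh_id = profile$mesh_id,
                    tf = sprintf("%.15g", profile$tf),
                    idf = sprintf("%.15g", profile$idf),
                    score = sprintf("%.15g", profile$score),
                    rank = profile$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
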