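#' Configuration for the synthetic knowledge-graph generator
#'
#' Describes a FORUM-shaped corpus: a set of articles, a MeSH-like forest of
#' descriptors (one rooted tree per category letter), a compound collection
#' attached to the leaves of a chemical-class DAG, and independent Bernoulli
#' annotation processes with optionally planted enriched pairs.
#'
#' Entity identifiers are deterministic functions of the structure
#' parameters, so planted pairs can name them either directly
#' (`"compound:CID3"`, `"mesh:D000005"`) or by integer index (the i-th
#' compound / i-th leaf descriptor).
#'
#' @param n_articles number of articles in the corpus universe.
#' @param mesh_depth levels per descriptor tree, root included.
#' @param mesh_branching children per internal descriptor.
#' @param mesh_categories tree letters, one rooted tree each.
#' @param n_compounds number of compounds.
#' @param class_levels,class_width chemical-class DAG shape: `class_levels`
#'   ranks of `class_width` classes; every class below the top rank gets one
#'   parent in the rank above, and a second one with probability 0.3
#'   (multiple inheritance, as in ChEBI/ChemOnt).
#' @param base_mesh_rate per-article annotation probability of each leaf
#'   descriptor.
#' @param base_compound_rate per-article mention probability of each
#'   compound.
#' @param planted data.frame with columns `chem` (compound or class id, or
#'   integer compound index), `mesh` (leaf descriptor id or integer leaf
#'   index) and `lambda` (enrichment multiplier >= 1 on the joint
#'   probability, capped at the smaller marginal). An entity may appear in
#'   at most one planted pair.
#' @param seed integer RNG seed; identical configurations generate identical
#'   graphs.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_articles = 2000L,
                             mesh_depth = 3L,
                             mesh_branching = 3L,
                             mesh_categories = c("C", "D"),
                             n_compounds = 60L,
                             class_levels = 3L,
                             class_width = 4L,
                             base_mesh_rate = 0.05,
                             base_compound_rate = 0.05,
                             planted = NULL,
                             seed = 1L) {
  stopifnot(n_articles >= 1, mesh_depth >= 1, mesh_branching >= 1,
            n_compounds >= 1, class_levels >= 1, class_width >= 1,
            base_mesh_rate > 0, base_mesh_rate < 1,
            base_compound_rate > 0, base_compound_rate < 1)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("chem", "mesh", "lambda") %in% names(planted)))
    if (any(planted$lambda < 1)) stop("enrichment multiplier lambda must be >= 1")
  }
  structure(list(n_articles = as.integer(n_articles),
                 mesh_depth = as.integer(mesh_depth),
                 mesh_branching = as.integer(mesh_branching),
                 mesh_categories = mesh_categories,
                 n_compounds = as.integer(n_compounds),
                 class_levels = as.integer(class_levels),
                 class_width = as.integer(class_width),
                 base_mesh_rate = base_mesh_rate,
                 base_compound_rate = base_compound_rate,
                 planted = planted,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic descriptor forest: ids, tree numbers, leaf flags
.synthetic_mesh_structure <- function(config) {
  rows <- list()
  idx <- 0L
  for (letter in config$mesh_categories) {
    level_tns <- paste0(letter, "01")
    for (lvl in seq_len(config$mesh_depth)) {
      for (tn in level_tns) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(id = sprintf("mesh:D%06d", idx),
                                  tree_number = tn,
                                  leaf = lvl == config$mesh_depth)
      }
      if (lvl < config$mesh_depth) {
        level_tns <- as.vector(vapply(level_tns, function(tn)
          paste0(tn, ".", sprintf("%03d", seq_len(config$mesh_branching))),
          character(config$mesh_branching)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic knowledge graph with planted associations
#'
#' Articles annotate each leaf descriptor with probability `base_mesh_rate`
#' and mention each compound with probability `base_compound_rate`,
#' independently across articles and entities, except for planted pairs:
#' there the per-article joint probability is `lambda` times the product of
#' the marginals (capped at the smaller marginal), while both marginal rates
#' are preserved, so the planted signal is exactly the dependence a Fisher
#' test measures. Compounds are assigned uniformly to the leaf classes of
#' the class DAG. A planted pair naming a chemical class is realized through
#' that class's first member compound, recorded in the truth table.
#'
#' The generated graph always passes [validate_kg()], and the same
#' configuration (including seed) regenerates it exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `kg` (a [knowledge_graph()]) and `truth`
#'   (data.frame of class `synthetic_truth`: planted pairs with `lambda`,
#'   the realizing compound and realized joint/marginal counts).
#' @export
generate_synthetic_kg <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  articles <- sprintf("a%05d", seq_len(config$n_articles))
  compounds <- sprintf("compound:CID%d", seq_len(config$n_compounds))
  mesh <- .synthetic_mesh_structure(config)
  leaf_desc <- mesh$id[mesh$leaf]

  # chemical-class DAG: class_levels ranks of class_width nodes
  n_classes <- config$class_levels * config$class_width
  class_ids <- sprintf("chemont:C%04d", seq_len(n_classes))
  rank_of <- rep(seq_len(config$class_levels), each = config$class_width)
  sub_child <- character(); sub_parent <- character()
  for (i in which(rank_of > 1L)) {
    above <- class_ids[rank_of == rank_of[i] - 1L]
    p1 <- sample(above, 1L)
    sub_child <- c(sub_child, class_ids[i]); sub_parent <- c(sub_parent, p1)
    if (length(above) > 1L && stats::runif(1) < 0.3) {
      p2 <- sample(setdiff(above, p1), 1L)
      sub_child <- c(sub_child, class_ids[i]); sub_parent <- c(sub_parent, p2)
    }
  }
  leaf_classes <- class_ids[rank_of == config$class_levels]
  compound_class <- sample(leaf_classes, config$n_compounds, replace = TRUE)

  # resolve planted pair identifiers
  planted <- config$planted
  if (!is.null(planted) && nrow(planted) > 0L) {
    resolve <- function(x, pool) {
      xi <- suppressWarnings(as.integer(x))
      ifelse(!is.na(xi) & !grepl(":", x), pool[xi], as.character(x))
    }
    planted$chem <- resolve(planted$chem, compounds)
    planted$mesh <- resolve(planted$mesh, leaf_desc)
    if (anyDuplicated(c(planted$chem, planted$mesh)) > 0L) {
      stop("an entity may appear in at most one planted pair")
    }
    if (!all(planted$mesh %in% leaf_desc)) {
      stop("planted descriptors must be leaves of the generated forest")
    }
  } else {
    planted <- data.frame(chem = character(), mesh = character(),
                          lambda = numeric())
  }

  # realize class-level plants through the class's first member compound
  planted$realized_compound <- planted$chem
  for (i in seq_len(nrow(planted))) {
    if (identical(entity_kind(planted$chem[i]), "chemical_class")) {
      kg_tmp_members <- compounds[compound_class == planted$chem[i]]
      # members of transitive subclasses too
      sub_cl <- planted$chem[i]
      repeat {
        more <- sub_child[sub_parent %in% sub_cl]
        if (all(more %in% sub_cl)) break
        sub_cl <- union(sub_cl, more)
      }
      members <- sort(compounds[compound_class %in% sub_cl])
      if (length(members) == 0L) stop("planted class has no member compounds")
      planted$realized_compound[i] <- members[1L]
    } else if (!planted$chem[i] %in% compounds) {
      stop("unknown planted chemical entity: ", planted$chem[i])
    }
  }

  n <- config$n_articles
  pc <- config$base_compound_rate
  pd <- config$base_mesh_rate
  comp_mat <- matrix(stats::runif(n * length(compounds)) < pc,
                     nrow = n, dimnames = list(NULL, compounds))
  desc_mat <- matrix(stats::runif(n * length(leaf_desc)) < pd,
                     nrow = n, dimnames = list(NULL, leaf_desc))

  for (i in seq_len(nrow(planted))) {
    cp <- planted$realized_compound[i]
    dp <- planted$mesh[i]
    if (planted$lambda[i] * pc * pd > 1) {
      stop("infeasible planted pair: lambda times the marginal product ",
           "exceeds 1")
    }
    p11 <- min(planted$lambda[i] * pc * pd, pc, pd)
    stopifnot(pc + pd - p11 <= 1)   # guaranteed for lambda >= 1
    u <- stats::runif(n)
    comp_mat[, cp] <- u < pc                       # marginal rate preserved
    desc_mat[, dp] <- u < p11 | (u >= pc & u < pc + (pd - p11))
  }

  discusses <- data.frame(
    article = articles[row(comp_mat)[comp_mat]],
    compound = colnames(comp_mat)[col(comp_mat)[comp_mat]])
  subject_terms <- data.frame(
    article = articles[row(desc_mat)[desc_mat]],
    descriptor = colnames(desc_mat)[col(desc_mat)[desc_mat]])

  kg <- knowledge_graph(
    articles = articles,
    compounds = compounds,
    classes = data.frame(id = class_ids, ontology = "chemont"),
    descriptors = mesh[, c("id", "tree_number")],
    discusses = discusses,
    subject_terms = subject_terms,
    class_membership = data.frame(compound = compounds,
                                  class = compound_class),
    subclass_of = data.frame(child = sub_child, parent = sub_parent))
  .assert_valid(kg)

  truth <- planted
  truth$joint_count <- rep(NA_integer_, nrow(truth))
  truth$chem_count <- rep(NA_integer_, nrow(truth))
  truth$mesh_count <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cp <- truth$realized_compound[i]; dp <- truth$mesh[i]
    truth$joint_count[i] <- sum(comp_mat[, cp] & desc_mat[, dp])
    truth$chem_count[i] <- sum(comp_mat[, cp])
    truth$mesh_count[i] <- sum(desc_mat[, dp])
  }
  attr(truth, "config") <- config
  class(truth) <- c("synthetic_truth", class(truth))
  list(kg = kg, truth = truth)
}

#' Score recovery of planted associations
#'
#' Power is the fraction of planted pairs flagged significant. The false
#' discovery proportion counts significant records that are neither planted
#' pairs nor ancestor-level versions of one: under the true-path rule an
#' association planted at (compound, leaf descriptor) genuinely holds for
#' every (ancestor chemical entity, ancestor descriptor) combination, so
#' such hits are credited as true.
#'
#' @param records [run_enrichment()] output on the generated graph.
#' @param truth the `truth` element of [generate_synthetic_kg()].
#' @param kg the generated [knowledge_graph()] (needed to walk the two
#'   hierarchies for ancestor crediting).
#' @return list with `power`, `fdp`, `n_significant`, `n_credited_true` and
#'   the significant pair table annotated with a `credited_true` flag.
#' @export
evaluate_recovery <- function(records, truth, kg) {
  sig <- records[records$significant, c("chem_id", "mesh_id"), drop = FALSE]
  sig_key <- paste(sig$chem_id, sig$mesh_id)

  if (nrow(truth) == 0L) {
    power <- NA_real_
    true_keys <- character()
  } else {
    planted_key <- paste(truth$chem, truth$mesh)
    power <- mean(planted_key %in% sig_key)
    true_keys <- unlist(lapply(seq_len(nrow(truth)), function(i) {
      rc <- truth$realized_compound[i]
      chem_true <- rc
      direct <- kg$class_membership$class[kg$class_membership$compound == rc]
      for (cl in direct) chem_true <- union(chem_true, .class_ancestors(kg, cl))
      chem_true <- union(chem_true, truth$chem[i])
      mesh_true <- .mesh_ancestors(kg, truth$mesh[i])
      as.vector(outer(chem_true, mesh_true, paste))
    }))
  }
  credited <- sig_key %in% true_keys
  fdp <- if (nrow(sig) == 0L) 0 else mean(!credited)
  sig$credited_true <- credited
  list(power = power, fdp = fdp, n_significant = nrow(sig),
       n_credited_true = sum(credited), significant_pairs = sig)
}
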