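# Small fixture graphs and independent brute-force oracles used across the
# suite. Oracles deliberately avoid the package's own code paths.

# ten-article graph around glucose/water with a two-level disease branch
tiny_kg <- function() {
  knowledge_graph(
    articles = paste0("a", 1:10),
    compounds = c("compound:CID5793", "compound:CID962"),
    classes = data.frame(id = c("chemont:0001540", "chemont:0001498"),
                         ontology = "chemont"),
    descriptors = data.frame(
      id = c("mesh:D044882", "mesh:D003924", "mesh:D006262"),
      tree_number = c("C18.452", "C18.452.394", "G11.100")),
    discusses = data.frame(
      article = c("a1", "a2", "a3", "a4", "a5", "a6"),
      compound = c("compound:CID5793", "compound:CID5793", "compound:CID5793",
                   "compound:CID962", "compound:CID962", "compound:CID962")),
    subject_terms = data.frame(
      article = c("a1", "a2", "a4", "a7", "a8"),
      descriptor = c("mesh:D003924", "mesh:D003924", "mesh:D006262",
                     "mesh:D044882", "mesh:D006262")),
    class_membership = data.frame(compound = "compound:CID5793",
                                  class = "chemont:0001498"),
    subclass_of = data.frame(child = "chemont:0001498",
                             parent = "chemont:0001540"))
}

# random FORUM-shaped graph for property tests; structure only mildly random
# so every relation type is exercised
random_kg <- function(seed, n_articles = 40, n_desc = 15, n_comp = 8,
                      n_class = 6) {
  set.seed(seed)
  articles <- sprintf("r%03d", seq_len(n_articles))
  compounds <- sprintf("compound:CID%d", seq_len(n_comp))
  # grow a random tree-number forest under two roots
  tns <- c("C01", "D01")
  while (length(tns) < n_desc) {
    parent <- sample(tns, 1L)
    child <- paste0(parent, ".", sprintf("%03d", sample.int(999, 1L)))
    if (!child %in% tns) tns <- c(tns, child)
  }
  descriptors <- data.frame(id = sprintf("mesh:D%06d", seq_along(tns)),
                            tree_number = tns)
  class_ids <- sprintf("chemont:C%04d", seq_len(n_class))
  sub <- NULL
  for (i in 2:n_class) {
    parents <- sample(class_ids[seq_len(i - 1L)],
                      size = min(i - 1L, 1L + stats::rbinom(1L, 1L, 0.3)))
    sub <- rbind(sub, data.frame(child = class_ids[i], parent = parents))
  }
  pick_edges <- function(left, right, p) {
    m <- matrix(stats::runif(length(left) * length(right)) < p,
                nrow = length(left))
    data.frame(a = left[row(m)[m]], b = right[col(m)[m]])
  }
  disc <- pick_edges(articles, compounds, 0.15)
  names(disc) <- c("article", "compound")
  subj <- pick_edges(articles, descriptors$id, 0.1)
  names(subj) <- c("article", "descriptor")
  memb <- data.frame(compound = compounds,
                     class = sample(class_ids, n_comp, replace = TRUE))
  knowledge_graph(articles = articles, compounds = compounds,
                  classes = data.frame(id = class_ids, ontology = "chemont"),
                  descriptors = descriptors, discusses = disc,
                  subject_terms = subj, class_membership = memb,
                  subclass_of = sub)
}

# breadth-first descendant closure over dot-prefix parentage
oracle_mesh_descendants <- function(kg, d) {
  tns <- kg$descriptors$tree_number[kg$descriptors$id == d]
  tns <- tns[!is.na(tns)]
  hits <- d
  for (i in seq_len(nrow(kg$descriptors))) {
    tn <- kg$descriptors$tree_number[i]
    if (is.na(tn)) next
    for (t in tns) {
      if (tn == t || startsWith(tn, paste0(t, "."))) {
        hits <- c(hits, kg$descriptors$id[i])
      }
    }
  }
  sort(unique(hits))
}

# brute-force reachability against subclass_of edges
oracle_class_descendants <- function(kg, cls) {
  out <- cls
  repeat {
    more <- kg$subclass_of$child[kg$subclass_of$parent %in% out]
    if (all(more %in% out)) return(sort(unique(out)))
    out <- union(out, more)
  }
}

# per-entity propagated corpus by naive union over the descendant closure
oracle_propagated <- function(kg, index_explicit, entity) {
  kind <- entity_kind(entity)
  if (identical(kind, "mesh_descriptor")) {
    members <- oracle_mesh_descendants(kg, entity)
    arts <- unlist(index_explicit[members], use.names = FALSE)
  } else if (identical(kind, "chemical_class")) {
    cls <- oracle_class_descendants(kg, entity)
    comps <- unique(kg$class_membership$compound[kg$class_membership$class %in% cls])
    arts <- unlist(index_explicit[comps], use.names = FALSE)
  } else {
    arts <- index_explicit[[entity]]
  }
  out <- sort(unique(arts))
  if (is.null(out)) character() else out
}

# exhaustive hypergeometric right tail with exact binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d; m <- a + c; k <- a + b
  xs <- max(0, k - (N - m)):min(k, m)
  xs <- xs[xs >= a]
  if (length(xs) == 0) return(0)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# naive Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# fragility by exhaustive re-testing of every removal count (no cap logic)
oracle_fragility_scan <- function(a, b, c, d, threshold) {
  for (r in 0:a) {
    p <- oracle_fisher(a - r, b, c, d)
    if (p > threshold) return(r)
  }
  NA_integer_
}
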