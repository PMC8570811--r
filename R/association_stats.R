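#' Construct a 2x2 contingency table
#'
#' Cell `a` counts articles supporting both entities, `b` the chemical side
#' only, `c` the MeSH side only and `d` neither; `a+b+c+d = N`, the corpus
#' universe size.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return object of class `contingency_table` with fields `a,b,c,d` and the
#'   derived margins `n_chem = a+b`, `n_mesh = a+c`, `N`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 n_chem = a + b, n_mesh = a + c, N = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

#' Contingency table for a chemical-entity/descriptor pair
#'
#' @param index a [build_corpus_index()] result.
#' @param chem,mesh entity CURIEs present in the index.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(index, chem, mesh) {
  ca <- .corpus(index, chem)
  ma <- .corpus(index, mesh)
  a <- length(intersect(ca, ma))
  b <- length(ca) - a
  c_ <- length(ma) - a
  d <- index$N - a - b - c_
  if (d < 0) stop("corpus union exceeds universe size N")
  contingency_table(a, b, c_, d)
}

#' Right-tailed Fisher exact test p-value
#'
#' Probability of observing `a` or more joint articles under the
#' hypergeometric null fixed by the table margins: population `N`, success
#' count `a+c` (the MeSH corpus), `a+b` draws (the chemical corpus). Computed
#' through the log-space hypergeometric survival function, stable for
#' universes up to at least 1e7 articles; p-values below the double-precision
#' floor (~1e-320) underflow to 0, which by convention marks "smaller than
#' representable" (ranking then falls back to the chi-squared statistic).
#'
#' @param t a [contingency_table()].
#' @return p-value in (0, 1] (or exactly 0 on underflow).
#' @export
fisher_right_tail <- function(t) {
  .fisher_right_tail(t$a, t$b, t$c, t$d)
}

.fisher_right_tail <- function(a, b, c, d) {
  # P(X >= a), X ~ Hypergeometric(N, m = a+c, k = a+b)
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Odds ratio of a contingency table
#'
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction adds
#' 0.5 to every cell and the result is flagged via the `"corrected"`
#' attribute.
#'
#' @param t a [contingency_table()].
#' @return non-negative numeric with logical attribute `corrected`.
#' @export
odds_ratio <- function(t) {
  corrected <- any(c(t$a, t$b, t$c, t$d) == 0)
  s <- if (corrected) 0.5 else 0
  out <- ((t$a + s) * (t$d + s)) / ((t$b + s) * (t$c + s))
  attr(out, "corrected") <- corrected
  out
}

#' Pearson chi-squared statistic of a contingency table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without continuity correction;
#' defined as 0 when any margin is empty. Reported for ranking associations
#' whose q-values underflow, not for inference.
#'
#' @param t a [contingency_table()].
#' @return non-negative numeric.
#' @export
chi_squared <- function(t) {
  .chi_squared(t$a, t$b, t$c, t$d)
}

.chi_squared <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)   # double arithmetic: the margin
  c <- as.numeric(c); d <- as.numeric(d)   # product overflows 32-bit ints
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- a + b + c + d
  out <- ifelse(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0, 0,
                n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment over one family of p-values; output keeps input
#' order, is capped at 1 and satisfies `q >= p` element-wise.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment run configuration
#'
#' @param q_threshold FDR significance threshold on the q-value; pairs below
#'   it are instantiated as `skos:related` (default 1e-6).
#' @param class_size_cap chemical classes with at least this many transitive
#'   member compounds are excluded as too broad (default 1000, i.e. "fewer
#'   than one thousand compounds" are kept).
#' @param allowed_categories MeSH tree letters retained for testing; default
#'   `c("A","B","C","D","F","G","I","J")` — Anatomy, Organisms, Diseases,
#'   Chemicals and Drugs, Psychiatry and Psychology, Phenomena and
#'   Processes, Anthropology/Education/Sociology, Technology/Industry/
#'   Agriculture.
#' @param min_support minimal propagated co-occurrence for a pair to be
#'   tested (default 1; a zero-support pair has p = 1 under a right tail).
#' @param use_propagation apply the true-path rule when building corpora
#'   (default TRUE).
#' @param bh_scope `"global"` adjusts all tested pairs as one family;
#'   `"per-entity-kind"` adjusts compound-MeSH, class-MeSH and MeSH-MeSH
#'   pairs separately.
#' @param mesh_mesh also test descriptor-descriptor pairs (default FALSE).
#' @param universe corpus universe mode, see [build_corpus_index()].
#' @param fragility_level confidence level of the Jeffreys interval bounding
#'   the fragility scan (default 0.95).
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(q_threshold = 1e-6,
                              class_size_cap = 1000L,
                              allowed_categories = c("A", "B", "C", "D",
                                                     "F", "G", "I", "J"),
                              min_support = 1L,
                              use_propagation = TRUE,
                              bh_scope = c("global", "per-entity-kind"),
                              mesh_mesh = FALSE,
                              universe = c("all", "mesh_annotated"),
                              fragility_level = 0.95) {
  stopifnot(q_threshold > 0, q_threshold <= 1, class_size_cap >= 1,
            min_support >= 0)
  structure(list(q_threshold = q_threshold,
                 class_size_cap = as.integer(class_size_cap),
                 allowed_categories = allowed_categories,
                 min_support = as.integer(min_support),
                 use_propagation = isTRUE(use_propagation),
                 bh_scope = match.arg(bh_scope),
                 mesh_mesh = isTRUE(mesh_mesh),
                 universe = match.arg(universe),
                 fragility_level = fragility_level),
            class = "enrichment_config")
}

#' Candidate chemical-entity/descriptor pairs
#'
#' Enumerates the pairs submitted to testing: the descriptor must hold at
#' least one tree number in an allowed category; the chemical side is any
#' compound, or any class with fewer than `class_size_cap` transitive member
#' compounds; and the propagated co-occurrence must reach `min_support`.
#' With `mesh_mesh = TRUE`, unordered descriptor-descriptor pairs (both
#' category-filtered) are appended.
#'
#' @param kg a [knowledge_graph()].
#' @param index matching [build_corpus_index()] result.
#' @param config an [enrichment_config()].
#' @return data.frame with columns `chem`, `mesh`, `support`.
#' @export
enumerate_candidate_pairs <- function(kg, index, config = enrichment_config()) {
  desc_ids <- unique(kg$descriptors$id)
  letters1 <- split(substr(kg$descriptors$tree_number, 1L, 1L),
                    kg$descriptors$id)
  allowed_mesh <- desc_ids[vapply(desc_ids, function(d)
    any(letters1[[d]] %in% config$allowed_categories), logical(1L))]

  class_ids <- unique(kg$classes$id)
  keep_class <- class_ids[vapply(class_ids, function(cl)
    class_member_count(kg, cl) < config$class_size_cap, logical(1L))]
  chems <- c(kg$compounds, keep_class)

  out <- .support_pairs(index, chems, allowed_mesh, config$min_support)
  if (config$mesh_mesh) {
    mm <- .support_pairs(index, allowed_mesh, allowed_mesh, config$min_support)
    mm <- mm[mm$chem < mm$mesh, , drop = FALSE]   # unordered pairs once
    out <- rbind(out, mm)
  }
  rownames(out) <- NULL
  out
}

# co-occurrence counts >= min_support via an article -> mesh inverted index
.support_pairs <- function(index, chems, meshes, min_support) {
  empty <- data.frame(chem = character(), mesh = character(),
                      support = integer())
  if (length(chems) == 0L || length(meshes) == 0L) return(empty)
  art_mesh <- data.frame(
    article = unlist(index$propagated[meshes], use.names = FALSE),
    mesh = rep(meshes, lengths(index$propagated[meshes])))
  art2mesh <- split(art_mesh$mesh, art_mesh$article)
  res <- vector("list", length(chems))
  for (i in seq_along(chems)) {
    arts <- index$propagated[[chems[i]]]
    if (length(arts) == 0L) next
    counts <- table(unlist(art2mesh[arts], use.names = FALSE))
    counts <- counts[counts >= max(1L, min_support)]
    if (length(counts) == 0L) next
    res[[i]] <- data.frame(chem = chems[i], mesh = names(counts),
                           support = as.integer(counts))
  }
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  if (min_support == 0L) {
    # zero-support pairs are added back explicitly (Fig-2-style comparisons)
    full <- expand.grid(chem = chems, mesh = meshes,
                        stringsAsFactors = FALSE)
    key <- paste(out$chem, out$mesh)
    miss <- full[!paste(full$chem, full$mesh) %in% key, , drop = FALSE]
    if (nrow(miss) > 0L) {
      miss$support <- 0L
      out <- rbind(out, miss)
    }
  }
  out <- out[order(out$chem, out$mesh), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full literature enrichment analysis
#'
#' For every candidate pair builds the 2x2 contingency table against the
#' corpus universe, computes the right-tailed Fisher p-value, odds ratio and
#' chi-squared statistic, adjusts p-values with Benjamini-Hochberg, flags
#' pairs with q below the threshold as significant and computes the fragility
#' index of each significant pair. Output ordering is deterministic:
#' descending chi-squared, then lexicographic `(chem, mesh)`.
#'
#' @param kg a valid [knowledge_graph()].
#' @param config an [enrichment_config()].
#' @param index optional precomputed [build_corpus_index()] consistent with
#'   `config` (built from `kg` otherwise).
#' @return data.frame of class `association_records` with columns `chem_id`,
#'   `mesh_id`, `support`, `n_chem`, `n_mesh`, `N`, `p_value`, `q_value`,
#'   `odds_ratio`, `or_corrected_flag`, `chi2`, `fragility`,
#'   `fragility_capped`, `significant`.
#' @export
run_enrichment <- function(kg, config = enrichment_config(), index = NULL) {
  if (is.null(index)) {
    index <- build_corpus_index(kg, use_propagation = config$use_propagation,
                                universe = config$universe)
  }
  cand <- enumerate_candidate_pairs(kg, index, config)
  n <- nrow(cand)
  if (n == 0L) {
    out <- data.frame(chem_id = character(), mesh_id = character(),
                      support = integer(), n_chem = integer(),
                      n_mesh = integer(), N = integer(),
                      p_value = numeric(), q_value = numeric(),
                      odds_ratio = numeric(), or_corrected_flag = logical(),
                      chi2 = numeric(), fragility = integer(),
                      fragility_capped = logical(), significant = logical())
    class(out) <- c("association_records", class(out))
    return(out)
  }
  a <- cand$support
  n_chem <- lengths(index$propagated[cand$chem])
  n_mesh <- lengths(index$propagated[cand$mesh])
  N <- index$N
  b <- n_chem - a
  cc <- n_mesh - a
  d <- N - a - b - cc
  p <- .fisher_right_tail(a, b, cc, d)
  corrected <- a == 0 | b == 0 | cc == 0 | d == 0
  s <- ifelse(corrected, 0.5, 0)
  or <- ((a + s) * (d + s)) / ((b + s) * (cc + s))
  chi2 <- .chi_squared(a, b, cc, d)

  kind <- entity_kind(cand$chem)
  q <- numeric(n)
  if (config$bh_scope == "global") {
    q <- bh_qvalues(p)
  } else {
    for (k in unique(kind)) {
      sel <- kind == k
      q[sel] <- bh_qvalues(p[sel])
    }
  }
  significant <- q < config$q_threshold

  fragility <- rep(NA_integer_, n)
  capped <- rep(NA, n)
  for (i in which(significant)) {
    fr <- fragility_index(contingency_table(a[i], b[i], cc[i], d[i]),
                          threshold = config$q_threshold,
                          level = config$fragility_level,
                          permissive = TRUE)
    fragility[i] <- fr$index
    capped[i] <- fr$capped
  }

  out <- data.frame(chem_id = cand$chem, mesh_id = cand$mesh,
                    support = as.integer(a), n_chem = as.integer(n_chem),
                    n_mesh = as.integer(n_mesh), N = as.integer(N),
                    p_value = p, q_value = q, odds_ratio = or,
                    or_corrected_flag = corrected, chi2 = chi2,
                    fragility = fragility, fragility_capped = capped,
                    significant = significant)
  out <- out[order(-out$chi2, out$chem_id, out$mesh_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("association_records", class(out))
  out
}

#' Compare two enrichment runs (lost / shared / new / novel)
#'
#' Partitions significant pairs of a run without annotation propagation and
#' a run with it: `lost` pairs are significant only without propagation,
#' `shared` in both, `new` only with propagation. Among the new pairs,
#' `novel` ones have no direct link at all in the unpropagated graph — they
#' were not even testable without the true-path rule (zero explicit
#' co-occurrence).
#'
#' @param without,with association-record tables from [run_enrichment()]
#'   (or read back via [read_results_table()]), run respectively with
#'   `use_propagation = FALSE` and `TRUE`.
#' @return list with data.frames `lost`, `shared`, `new`, `novel` (columns
#'   `chem_id`, `mesh_id`) and a `counts` named integer vector.
#' @export
compare_association_sets <- function(without, with) {
  keys <- function(df, sel) {
    df <- df[sel, c("chem_id", "mesh_id"), drop = FALSE]
    df[order(df$chem_id, df$mesh_id), , drop = FALSE]
  }
  sw <- keys(without, without$significant)
  sp <- keys(with, with$significant)
  kw <- paste(sw$chem_id, sw$mesh_id)
  kp <- paste(sp$chem_id, sp$mesh_id)
  tested_without <- paste(without$chem_id, without$mesh_id)
  lost <- sw[!kw %in% kp, , drop = FALSE]
  shared <- sp[kp %in% kw, , drop = FALSE]
  new <- sp[!kp %in% kw, , drop = FALSE]
  novel <- new[!paste(new$chem_id, new$mesh_id) %in% tested_without, ,
               drop = FALSE]
  rownames(lost) <- rownames(shared) <- rownames(new) <- rownames(novel) <- NULL
  list(lost = lost, shared = shared, new = new, novel = novel,
       counts = c(lost = nrow(lost), shared = nrow(shared),
                  new = nrow(new), novel = nrow(novel)))
}
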