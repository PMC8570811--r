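#' Jeffreys interval for a binomial proportion
#'
#' Equal-tailed credible interval under the Jeffreys Beta(1/2, 1/2) prior:
#' the (1-level)/2 and 1-(1-level)/2 quantiles of Beta(k+1/2, n-k+1/2), with
#' the standard boundary conventions low = 0 when k = 0 and high = 1 when
#' k = n.
#'
#' @param k success count, 0 <= k <= n.
#' @param n trial count, n >= 1.
#' @param level confidence level in (0, 1), default 0.95.
#' @return object of class `jeffreys_interval`: list with `k`, `n`, `level`,
#'   `estimate` (k/n), `low`, `high`.
#' @export
jeffreys_interval <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || n < 1 || k < 0 || k > n) {
    stop("need 0 <= k <= n with n >= 1")
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  low <- if (k == 0) 0 else stats::qbeta(alpha, k + 0.5, n - k + 0.5)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha, k + 0.5, n - k + 0.5)
  structure(list(k = k, n = n, level = level, estimate = k / n,
                 low = low, high = high),
            class = "jeffreys_interval")
}

#' @export
print.jeffreys_interval <- function(x, ...) {
  cat(sprintf("<jeffreys_interval> k=%d n=%d level=%.3g: [%.6g, %.6g]\n",
              x$k, x$n, x$level, x$low, x$high))
  invisible(x)
}

#' Fragility index of a significant association
#'
#' Minimal number of supporting articles that, when retracted from the
#' literature entirely, push the association's right-tailed Fisher p-value
#' above the significance threshold. Removing one supporting article
#' decrements the joint count `a`, both margins and the universe `N` (cells
#' `b`, `c`, `d` are unchanged). The scan is bounded by the Jeffreys interval
#' of the co-occurrence proportion `a / n_ref` with `n_ref = min(n_chem,
#' n_mesh)`: at most `r_max = a - ceiling(low * n_ref)` removals are
#' entertained, where `low` is the interval's lower bound. An association
#' still significant after `r_max` removals is reported as robust-capped.
#'
#' The p-value sequence over removals is checked to be non-decreasing; if a
#' numerical violation were detected the scan falls back to the global
#' minimum crossing point, so the returned index is always the smallest
#' removal count crossing the threshold.
#'
#' @param t a significant [contingency_table()] (`fisher_right_tail(t)` below
#'   `threshold`, `a >= 1`).
#' @param threshold significance threshold on the p-value (default 1e-6,
#'   matching the q-value instantiation cut; by the time fragility is
#'   computed the q-filter has been applied, and the scan uses the raw p).
#' @param level Jeffreys interval confidence level (default 0.95).
#' @param permissive when TRUE a table that is not significant yields index 0
#'   instead of an error.
#' @return list with `index` (removal count; equals `r_max` when capped),
#'   `capped` (logical), `r_max` and `p_at_index`.
#' @export
fragility_index <- function(t, threshold = 1e-6, level = 0.95,
                            permissive = FALSE) {
  p0 <- fisher_right_tail(t)
  if (p0 >= threshold || t$a < 1) {
    if (permissive) {
      return(list(index = 0L, capped = FALSE, r_max = 0L, p_at_index = p0))
    }
    stop("fragility index is defined only for significant associations")
  }
  n_ref <- min(t$n_chem, t$n_mesh)
  low <- jeffreys_interval(t$a, n_ref, level = level)$low
  r_max <- max(0L, as.integer(t$a - ceiling(low * n_ref)))
  rs <- 0:r_max
  p_r <- .fisher_right_tail(t$a - rs, t$b, t$c, t$d)
  # removals should only weaken the association; guard the scan anyway
  crossing <- which(p_r > threshold)
  if (length(crossing) == 0L) {
    return(list(index = r_max, capped = TRUE, r_max = r_max,
                p_at_index = p_r[length(p_r)]))
  }
  r <- rs[min(crossing)]
  list(index = as.integer(r), capped = FALSE, r_max = r_max,
       p_at_index = p_r[min(crossing)])
}

#' Articles supporting an association
#'
#' The intersection of the two propagated corpora: exactly the articles
#' counted in contingency cell `a`.
#'
#' @param index a [build_corpus_index()] result.
#' @param chem,mesh entity CURIEs present in the index.
#' @return sorted character vector of article ids.
#' @export
supporting_corpus <- function(index, chem, mesh) {
  sort(intersect(.corpus(index, chem), .corpus(index, mesh)))
}

#' TF-IDF-style importance profile of a supporting corpus
#'
#' Scores every MeSH descriptor explicitly annotated to at least one article
#' of the corpus: `tf` is the fraction of corpus articles carrying the
#' descriptor, `idf = log(N / |explicit corpus of the descriptor|)` (natural
#' log over the whole article universe), and the importance score is their
#' product. Descriptors appearing on most of the literature get idf near 0
#' and rank low however frequent they are in the corpus, isolating the terms
#' specific to the association. The query entities themselves can be
#' excluded via `exclude`.
#'
#' @param corpus non-empty character vector of article ids (typically from
#'   [supporting_corpus()]).
#' @param kg the [knowledge_graph()].
#' @param index matching [build_corpus_index()] result.
#' @param top_k number of top-ranked descriptors returned (default 20).
#' @param exclude entity CURIEs dropped from the profile (e.g. the two
#'   entities whose association the corpus supports).
#' @return data.frame with columns `mesh_id`, `tf`, `idf`, `score`, `rank`,
#'   ordered by descending score then id.
#' @export
importance_scores <- function(corpus, kg, index, top_k = 20L,
                              exclude = character()) {
  if (length(corpus) == 0L) stop("supporting corpus is empty")
  st <- kg$subject_terms[kg$subject_terms$article %in% corpus, , drop = FALSE]
  st <- st[!st$descriptor %in% exclude, , drop = FALSE]
  if (nrow(st) == 0L) {
    return(data.frame(mesh_id = character(), tf = numeric(), idf = numeric(),
                      score = numeric(), rank = integer()))
  }
  counts <- table(st$descriptor)
  ids <- names(counts)
  tf <- as.numeric(counts) / length(unique(corpus))
  global <- lengths(index$explicit[ids])
  idf <- log(index$N / global)
  score <- tf * idf
  out <- data.frame(mesh_id = ids, tf = tf, idf = idf, score = score)
  out <- out[order(-out$score, out$mesh_id), , drop = FALSE]
  out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
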