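#' Hypergeometric gene-set enrichment
#'
#' Exact upper-tail enrichment of a signature within a target set drawn
#' from a background universe: `p = P(X >= k)` with
#' `X ~ Hypergeometric(|background|, |signature|, |target|)` and `k` the
#' observed overlap. Both sets must be subsets of the background.
#'
#' @param target,signature,background character vectors of identifiers
#'   (duplicates are collapsed).
#' @return list of class `enrichment_result`: `n_target`, `n_signature`,
#'   `n_background`, `overlap`, `p_value`, `expected_overlap`.
#' @export
hypergeom_enrichment <- function(target, signature, background) {
  target <- unique(target); signature <- unique(signature)
  background <- unique(background)
  if (!all(target %in% background))
    stop_hw("target contains ids absent from the background",
            class = "hairwave_set_error")
  if (!all(signature %in% background))
    stop_hw("signature contains ids absent from the background",
            class = "hairwave_set_error")
  k <- length(intersect(target, signature))
  N <- length(background); m <- length(signature); n_t <- length(target)
  p <- stats::phyper(k - 1, m, N - m, n_t, lower.tail = FALSE)
  structure(list(n_target = n_t, n_signature = m, n_background = N,
                 overlap = k, expected_overlap = n_t * m / N,
                 p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> overlap %d of target %d (signature %d / background %d, expected %.2f): p = %.3g\n",
              x$overlap, x$n_target, x$n_signature, x$n_background,
              x$expected_overlap, x$p_value))
  invisible(x)
}

#' Normalized Google Distance from occurrence counts
#'
#' Co-occurrence-based semantic distance between two terms over a document
#' corpus: `NGD = (max(log f(x), log f(y)) - log f(x,y)) /
#' (log N - min(log f(x), log f(y)))`. The value is 0 for terms always used
#' together, 1 in expectation for statistically independent terms (so 1 is
#' the natural relatedness threshold), and `Inf` when the terms never
#' co-occur. The formula is a ratio of log differences, hence independent
#' of the logarithm base; natural logs are used.
#'
#' @param fx,fy documents containing each term (both >= 1).
#' @param fxy documents containing both.
#' @param n_pages corpus size, greater than `max(fx, fy)`.
#' @return The distance (possibly `Inf`).
#' @export
ngd <- function(fx, fy, fxy, n_pages) {
  if (fx < 1 || fy < 1)
    stop_hw("term counts must be >= 1", class = "hairwave_validation_error")
  if (fxy > min(fx, fy) || max(fx, fy) > n_pages)
    stop_hw("counts violate f(x,y) <= min(f(x), f(y)) <= N",
            class = "hairwave_corpus_error")
  if (n_pages <= max(fx, fy))
    stop_hw("corpus size must exceed the term counts",
            class = "hairwave_corpus_error")
  if (fxy == 0) return(Inf)
  (max(log(fx), log(fy)) - log(fxy)) /
    (log(n_pages) - min(log(fx), log(fy)))
}

#' Screen terms by semantic proximity to an anchor term
#'
#' Computes the NGD of every term to an anchor (e.g. gene symbols to
#' "hair") from supplied occurrence and co-occurrence counts, returning the
#' terms strictly below the threshold. The default threshold 1.0 is the
#' independence point of the NGD. Counts are supplied as tables, keeping
#' the operation deterministic and offline.
#'
#' @param term_counts data frame with columns `term`, `count`.
#' @param pair_counts data frame with columns `term1`, `term2`, `count`
#'   (unordered pairs; missing pairs count 0, i.e. NGD infinite).
#' @param anchor the anchor term (must appear in `term_counts`).
#' @param n_pages corpus size.
#' @param threshold strict NGD cutoff (default 1).
#' @return data frame `term`, `ngd` of the terms passing the screen,
#'   sorted by distance.
#' @export
ngd_screen <- function(term_counts, pair_counts, anchor, n_pages,
                       threshold = 1.0) {
  stopifnot(all(c("term", "count") %in% names(term_counts)))
  f_anchor <- term_counts$count[match(anchor, term_counts$term)]
  if (is.na(f_anchor))
    stop_hw("anchor term '", anchor, "' not in term counts",
            class = "hairwave_validation_error")
  others <- term_counts[term_counts$term != anchor, , drop = FALSE]
  if (!nrow(others))
    return(data.frame(term = character(0), ngd = numeric(0)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pk <- key(pair_counts$term1, pair_counts$term2)
  fxy <- pair_counts$count[match(key(anchor, others$term), pk)]
  fxy[is.na(fxy)] <- 0
  d <- mapply(function(fy, co) ngd(f_anchor, fy, co, n_pages),
              others$count, fxy)
  out <- data.frame(term = others$term, ngd = d,
                    stringsAsFactors = FALSE)
  out <- out[out$ngd < threshold, , drop = FALSE]
  out[order(out$ngd), , drop = FALSE]
}
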