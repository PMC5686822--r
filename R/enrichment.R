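#' Top-k entries of a ranking
#'
#' @param ranking data.frame from [rank_mirnas()] /
#'   [rank_for_disease()] (or a character vector already in rank
#'   order), with seeds already excluded.
#' @param k number of candidates to keep (default 100).
#' @return character vector of the first `min(k, length)` miRNA ids in
#'   rank order; a warning is issued when the ranking is shorter
#'   than `k`.
#' @export
top_k <- function(ranking, k = 100L) {
  stopifnot(k >= 0)
  ids <- if (is.data.frame(ranking)) ranking$mirna_id else
    as.character(ranking)
  if (length(ids) < k) {
    warning("ranking has only ", length(ids), " entries (< k = ", k, ")",
            call. = FALSE)
  }
  utils::head(ids, k)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k_overlap) when `n_drawn` candidates are drawn without
#' replacement from a universe of `N_universe` miRNAs of which
#' `K_reference` are in the reference set, computed by exact summation
#' of the hypergeometric mass over the tail.
#'
#' @param k_overlap observed overlap between the draw and the reference.
#' @param K_reference reference miRNAs in the universe.
#' @param n_drawn number of candidates drawn (e.g. top-k size).
#' @param N_universe size of the candidate universe.
#' @return the p-value, in (0, 1].
#' @examples
#' hypergeom_upper(2, 3, 100, 1547)  # ~0.012
#' @export
hypergeom_upper <- function(k_overlap, K_reference, n_drawn, N_universe) {
  k <- k_overlap; K <- K_reference; n <- n_drawn; N <- N_universe
  if (any(c(k, K, n, N) < 0) || k > n || k > K || K > N || n > N) {
    stop("inconsistent hypergeometric arguments (need k <= n, k <= K, ",
         "K <= N, n <= N)", call. = FALSE)
  }
  if (k == 0) return(1)
  hi <- min(n, K)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

#' Enrichment of top-ranked candidates in a reference database
#'
#' Runs the prioritization for one disease (seeds are its known miRNAs
#' and, for RWRMTN, their targets), takes the `k` top-ranked candidate
#' miRNAs, and tests whether they are enriched for the reference
#' database's miRNAs for the same disease with an upper-tail
#' hypergeometric test. The candidate universe is the network's miRNA
#' set minus the disease's seed miRNAs; reference miRNAs are counted
#' within that universe. Top candidates absent from the reference are
#' returned as novel predictions.
#'
#' @param assoc known associations (`disease_associations`), the seeds.
#' @param reference reference associations (`disease_associations`),
#'   e.g. an HMDD-style snapshot.
#' @param net a mutual `hetero_network` (for `"rwrmtn"`) or
#'   `homo_network` (for `"rwrmda"`).
#' @param disease disease id present in both sets.
#' @param method `"rwrmtn"` or `"rwrmda"`.
#' @param alpha,gamma,tol,max_iter propagation parameters.
#' @param k top-list size (default 100).
#' @param stem_match match reference miRNA names after stripping
#'   mature-arm suffixes (`-5p`/`-3p`); default exact string match.
#' @return object of class `enrichment_result`: list with `disease`,
#'   `top` (the top-k ids), `k_overlap`, `K_reference`, `n_drawn`,
#'   `N_universe`, `p_value`, `overlap` (ids), `novel` (ids).
#' @export
enrich_disease <- function(assoc, reference, net, disease,
                           method = c("rwrmtn", "rwrmda"), alpha = 0.9,
                           gamma = 0.7, k = 100L, stem_match = FALSE,
                           tol = 1e-6, max_iter = 1000L) {
  method <- match.arg(method)
  if (!disease %in% names(assoc)) {
    stop("disease absent from the association set: ", disease,
         call. = FALSE)
  }
  if (!disease %in% names(reference)) {
    stop("disease absent from the reference set: ", disease,
         call. = FALSE)
  }
  .check_method_net(method, net, NULL)
  tm <- transition_matrix(net)
  universe_all <- .mirna_ids(tm)
  seeds <- intersect(assoc[[disease]], universe_all)
  if (length(seeds) == 0L) {
    stop("no seed miRNA of ", disease, " is present in the network",
         call. = FALSE)
  }
  ranking <- propagate_rank(tm, seeds, method, alpha = alpha,
                            gamma = gamma, tol = tol,
                            max_iter = max_iter)
  top <- suppressWarnings(top_k(ranking, k))
  universe <- setdiff(universe_all, seeds)
  ref <- reference[[disease]]
  key <- if (stem_match) mirna_stem else identity
  ref_in_universe <- universe[key(universe) %in% key(ref)]
  overlap <- top[key(top) %in% key(ref)]
  p <- hypergeom_upper(length(overlap), length(ref_in_universe),
                       length(top), length(universe))
  structure(list(disease = disease, top = top,
                 k_overlap = length(overlap),
                 K_reference = length(ref_in_universe),
                 n_drawn = length(top), N_universe = length(universe),
                 p_value = p, overlap = overlap,
                 novel = setdiff(top, overlap)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result [", x$disease, "]: overlap ", x$k_overlap,
      " / reference ", x$K_reference, " (top ", x$n_drawn,
      " of ", x$N_universe, "), p = ", format(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Strip the mature-arm suffix from miRNA names
#'
#' `hsa-miR-17-5p` and `hsa-miR-17-3p` both map to `hsa-mir-17`, easing
#' matches across databases with different arm-naming conventions.
#'
#' @param x character vector of miRNA names.
#' @return stems, normalized as in [normalize_mirna_id()].
#' @export
mirna_stem <- function(x) {
  sub("-(5p|3p)$", "", normalize_mirna_id(x))
}
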