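#' RLSMDA: regularized least-squares disease-miRNA association scores
#'
#' Semi-supervised scoring needing no negative examples. Two regularized
#' least-squares classifiers are fit, one in miRNA space and one in
#' disease-phenotype space, and blended:
#' \deqn{F^* = w F_M^{*T} + (1 - w) F_D^*}
#' with \eqn{F_M^* = S_M (S_M + \eta_M I)^{-1} A^T} and
#' \eqn{F_D^* = S_D (S_D + \eta_D I)^{-1} A}. The regularized systems are
#' solved as linear systems, never by explicit inversion. The
#' inverse-free variant \eqn{S (S + \eta I) A^T} is available via
#' `smoother = "product"` for comparison.
#'
#' @param S_M n x n miRNA similarity matrix (symmetric, labeled);
#'   typically [sim_from_homogeneous()] of a homogeneous network.
#' @param S_D m x m disease phenotype similarity matrix (symmetric,
#'   labeled).
#' @param A m x n 0/1 association matrix; `rownames(A)` must match
#'   `rownames(S_D)` and `colnames(A)` must match `rownames(S_M)`.
#' @param eta_M,eta_D regularization trade-offs (> 0, default 1).
#' @param w weight on the miRNA-space classifier in `[0, 1]`
#'   (default 0.9).
#' @param smoother `"inverse"` (default, the regularized least-squares
#'   solution) or `"product"` (inverse-free variant).
#' @return m x n numeric score matrix with the labeling of `A`; ranking
#'   a disease's candidates means sorting its row.
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("d1", "d2"),
#'                                               c("m1", "m2")))
#' S <- diag(2)
#' dimnames(S) <- list(c("m1", "m2"), c("m1", "m2"))
#' D <- diag(2)
#' dimnames(D) <- list(c("d1", "d2"), c("d1", "d2"))
#' rlsmda_scores(S, D, A)   # identity similarity gives A / (1 + eta)
#' @export
rlsmda_scores <- function(S_M, S_D, A, eta_M = 1, eta_D = 1, w = 0.9,
                          smoother = c("inverse", "product")) {
  smoother <- match.arg(smoother)
  stopifnot(eta_M > 0, eta_D > 0, w >= 0, w <= 1)
  if (is.null(dimnames(A)) || is.null(rownames(S_M)) ||
      is.null(rownames(S_D))) {
    stop("S_M, S_D and A must all be labeled", call. = FALSE)
  }
  bad_m <- c(setdiff(colnames(A), rownames(S_M)),
             setdiff(rownames(S_M), colnames(A)))
  bad_d <- c(setdiff(rownames(A), rownames(S_D)),
             setdiff(rownames(S_D), rownames(A)))
  if (length(bad_m) || length(bad_d)) {
    stop("label mismatch between A and similarity matrices: ",
         paste(utils::head(unique(c(bad_m, bad_d)), 5L), collapse = ", "),
         call. = FALSE)
  }
  S_M <- S_M[colnames(A), colnames(A), drop = FALSE]
  S_D <- S_D[rownames(A), rownames(A), drop = FALSE]
  n <- ncol(A); m <- nrow(A)
  F_M <- if (smoother == "inverse") {
    S_M %*% solve(S_M + eta_M * diag(n), t(A))
  } else {
    S_M %*% (S_M + eta_M * diag(n)) %*% t(A)
  }
  F_D <- if (smoother == "inverse") {
    S_D %*% solve(S_D + eta_D * diag(m), A)
  } else {
    S_D %*% (S_D + eta_D * diag(m)) %*% A
  }
  out <- w * t(F_M) + (1 - w) * F_D
  if (any(!is.finite(out))) {
    stop("RLSMDA produced non-finite scores (singular system?)",
         call. = FALSE)
  }
  dimnames(out) <- dimnames(A)
  out
}

#' miRNA similarity matrix of a homogeneous network
#'
#' The shared-target weight matrix with unit diagonal; unconnected pairs
#' are 0. This is the S_M input of [rlsmda_scores()].
#'
#' @param net a `homo_network`.
#' @param mirnas optional node universe (ids absent from the network get
#'   zero off-diagonal similarity).
#' @return symmetric labeled matrix with unit diagonal.
#' @export
sim_from_homogeneous <- function(net, mirnas = NULL) {
  stopifnot(inherits(net, "homo_network"))
  ids <- if (is.null(mirnas)) net$nodes else sort(unique(mirnas))
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net$edges[net$edges$from %in% ids & net$edges$to %in% ids, ]
  S[cbind(e$from, e$to)] <- e$weight
  S[cbind(e$to, e$from)] <- e$weight
  diag(S) <- 1
  S
}

#' Build a 0/1 disease x miRNA association matrix
#'
#' @param assoc a `disease_associations` object.
#' @param mirnas column universe (miRNA ids).
#' @param diseases optional row universe; default all diseases in
#'   `assoc`.
#' @return 0/1 matrix with disease rows and miRNA columns.
#' @export
association_matrix <- function(assoc, mirnas, diseases = NULL) {
  if (is.null(diseases)) diseases <- names(assoc)
  mirnas <- sort(unique(mirnas))
  A <- matrix(0, length(diseases), length(mirnas),
              dimnames = list(diseases, mirnas))
  for (d in diseases) {
    hit <- intersect(assoc[[d]], mirnas)
    A[d, hit] <- 1
  }
  A
}

#' Rank a disease's candidate miRNAs from a score matrix
#'
#' @param F score matrix from [rlsmda_scores()].
#' @param disease disease row label.
#' @param exclude miRNA ids to drop (e.g. known associations).
#' @return data.frame with columns `rank`, `mirna_id`, `score`,
#'   descending score with lexicographic tie-break.
#' @export
rank_for_disease <- function(F, disease, exclude = character()) {
  if (!disease %in% rownames(F)) {
    stop("unknown disease: ", disease, call. = FALSE)
  }
  ids <- setdiff(colnames(F), normalize_mirna_id(exclude))
  sc <- F[disease, ids]
  ord <- order(-sc, ids)
  data.frame(rank = seq_along(ord), mirna_id = ids[ord],
             score = unname(sc[ord]), stringsAsFactors = FALSE)
}
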