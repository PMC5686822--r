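#' Build the transition operator of a network
#'
#' Each node's outgoing edge weights are normalized by its total outgoing
#' weight, giving the probability that a walker at node i steps to
#' neighbor j. Heterogeneous networks carry unit edge weights;
#' homogeneous networks use their shared-target similarity weights. The
#' stored operator is the transpose of the row-normalized adjacency, so
#' that multiplying it with a column probability vector propagates mass
#' from sources to their neighbors. Dangling nodes (gene nodes of a
#' directed network) have zero outgoing mass.
#'
#' @param net a `hetero_network` or `homo_network` with at least one edge.
#' @return an object of class `transition_matrix`: list with `op` (sparse
#'   column-stochastic operator, columns indexed by source node), `nodes`
#'   (data.frame `id`, `class`), `dangling` (logical per node) and `adj`
#'   (the sparse adjacency used, for seed/target lookups).
#' @export
transition_matrix <- function(net) {
  if (inherits(net, "hetero_network")) {
    nodes <- net$nodes
    n <- nrow(nodes)
    i <- match(net$edges$from, nodes$id)
    j <- match(net$edges$to, nodes$id)
    if (net$mode == "mutual") {
      adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                  dims = c(n, n),
                                  dimnames = list(nodes$id, nodes$id))
    } else {
      adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                                  dimnames = list(nodes$id, nodes$id))
    }
  } else if (inherits(net, "homo_network")) {
    ids <- net$nodes
    n <- length(ids)
    i <- match(net$edges$from, ids)
    j <- match(net$edges$to, ids)
    adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                                x = rep(net$edges$weight, 2L),
                                dims = c(n, n), dimnames = list(ids, ids))
    nodes <- data.frame(id = ids, class = "miRNA", stringsAsFactors = FALSE)
  } else {
    stop("unsupported network class", call. = FALSE)
  }
  if (length(adj@x) == 0L) stop("network has no edges", call. = FALSE)
  out_weight <- Matrix::rowSums(adj)
  dangling <- out_weight == 0
  inv <- ifelse(dangling, 0, 1 / out_weight)
  # transpose of row-normalized adjacency: op[j, i] = adj[i, j] / out(i)
  op <- Matrix::t(adj * inv)
  structure(list(op = op, nodes = nodes, dangling = dangling, adj = adj),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix: ", nrow(x$nodes), " nodes, ",
      sum(x$dangling), " dangling\n", sep = "")
  invisible(x)
}

.mirna_ids <- function(tm) tm$nodes$id[tm$nodes$class == "miRNA"]

#' Initial probability vector from disease miRNAs only
#'
#' The RWRMDA seeding policy: each seed miRNA present in the network
#' receives mass 1/|S_m|. Seeds absent from the network are dropped and
#' the remaining mass renormalized, with a warning.
#'
#' @param seeds character vector of seed miRNA ids (S_m).
#' @param tm a `transition_matrix`.
#' @return named numeric vector over all network nodes, summing to 1.
#' @export
seed_vector_mirna <- function(seeds, tm) {
  seeds <- unique(normalize_mirna_id(seeds))
  present <- intersect(seeds, .mirna_ids(tm))
  if (length(present) == 0L) {
    stop("empty seed set: no seed miRNA present in the network",
         call. = FALSE)
  }
  if (length(present) < length(seeds)) {
    warning(length(seeds) - length(present),
            " seed miRNA(s) absent from the network; dropped and mass ",
            "renormalized", call. = FALSE)
  }
  p0 <- stats::setNames(numeric(nrow(tm$nodes)), tm$nodes$id)
  p0[present] <- 1 / length(present)
  p0
}

#' Initial probability vector from disease miRNAs and their targets
#'
#' The RWRMTN seeding policy on a heterogeneous network: the seed miRNAs
#' S_m share mass `alpha` uniformly and their target genes S_g share
#' mass `1 - alpha` uniformly. By default S_g is computed as the union
#' of targets of the present seed miRNAs; it may be overridden. If S_g
#' is empty while `alpha < 1` the miRNA-only policy is used with a
#' warning.
#'
#' @param seeds character vector of seed miRNA ids (S_m).
#' @param tm a `transition_matrix` over a heterogeneous network.
#' @param alpha weight in `[0, 1]` on the miRNA seeds.
#' @param seed_genes optional explicit S_g (gene ids); default derived
#'   from the network.
#' @return named numeric vector over all network nodes, summing to 1.
#' @export
seed_vector_hetero <- function(seeds, tm, alpha = 0.9, seed_genes = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  seeds <- unique(normalize_mirna_id(seeds))
  mirnas <- .mirna_ids(tm)
  present <- intersect(seeds, mirnas)
  if (length(present) == 0L && alpha > 0) {
    stop("empty seed set: no seed miRNA present in the network",
         call. = FALSE)
  }
  if (length(present) < length(seeds)) {
    warning(length(seeds) - length(present),
            " seed miRNA(s) absent from the network; dropped",
            call. = FALSE)
  }
  gene_ids <- tm$nodes$id[tm$nodes$class == "gene"]
  if (is.null(seed_genes)) {
    # out-neighbors of present seed miRNAs that are gene nodes
    idx <- match(present, tm$nodes$id)
    nb <- which(Matrix::colSums(tm$adj[idx, , drop = FALSE] != 0) > 0)
    seed_genes <- intersect(tm$nodes$id[nb], gene_ids)
  } else {
    seed_genes <- intersect(normalize_gene_id(seed_genes), gene_ids)
  }
  if (length(seed_genes) == 0L && alpha < 1) {
    warning("no seed target genes in the network; falling back to the ",
            "miRNA-only seed vector", call. = FALSE)
    return(seed_vector_mirna(present, tm))
  }
  p0 <- stats::setNames(numeric(nrow(tm$nodes)), tm$nodes$id)
  if (length(present) > 0L) p0[present] <- alpha / length(present)
  if (length(seed_genes) > 0L) {
    p0[seed_genes] <- (1 - alpha) / length(seed_genes)
  }
  if (alpha == 0 && length(seed_genes) == 0L) {
    stop("empty seed set", call. = FALSE)
  }
  p0
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - gamma) W' p_t + gamma p_0` until the L1
#' change between successive vectors drops below `tol`. At each step the
#' walker moves to a random neighbor with probability `1 - gamma` or
#' teleports back to the seed distribution with probability `gamma`; the
#' steady state scores each node's proximity to the seeds.
#'
#' @param tm a `transition_matrix`.
#' @param p0 initial probability vector (sums to 1), e.g. from
#'   [seed_vector_mirna()] or [seed_vector_hetero()].
#' @param gamma restart probability in `[0, 1]`.
#' @param tol L1 convergence threshold (default `1e-6`).
#' @param max_iter iteration cap (default 1000); reaching it without
#'   convergence is an error carrying the last residual.
#' @return an object of class `rwr_result`: list with `p` (named steady
#'   vector), `iterations`, `residual`, `gamma` and `mass_deficient`
#'   (`TRUE` when dangling nodes absorbed probability mass, as on
#'   directed miRNA->gene networks).
#' @export
rwr <- function(tm, p0, gamma, tol = 1e-6, max_iter = 1000L) {
  stopifnot(gamma >= 0, gamma <= 1, tol > 0, max_iter >= 1L)
  if (abs(sum(p0) - 1) > 1e-8) {
    stop("initial probability vector does not sum to 1", call. = FALSE)
  }
  p0 <- unname(p0)
  op <- tm$op
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - gamma) * (op %*% p)) + gamma * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      return(structure(list(
        p = stats::setNames(p, tm$nodes$id),
        iterations = it, residual = res, gamma = gamma,
        mass_deficient = any(tm$dangling) && sum(p) < 1 - 1e-9
      ), class = "rwr_result"))
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (last residual ", format(res), ")", call. = FALSE)
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("rwr_result: ", length(x$p), " nodes, gamma = ", x$gamma,
      ", converged in ", x$iterations, " iterations",
      if (x$mass_deficient) " [mass-deficient]", "\n", sep = "")
  invisible(x)
}

#' Rank candidate miRNAs by steady-state probability
#'
#' Keeps only miRNA-class nodes, removes excluded ids (typically the
#' seeds), and orders by descending score with ties broken by ascending
#' lexicographic id for determinism.
#'
#' @param p an `rwr_result` or a named numeric score vector.
#' @param tm the `transition_matrix` the scores were computed on.
#' @param exclude character vector of node ids to drop (e.g. seed
#'   miRNAs).
#' @return data.frame with columns `rank`, `mirna_id`, `score`.
#' @export
rank_mirnas <- function(p, tm, exclude = character()) {
  if (inherits(p, "rwr_result")) p <- p$p
  ids <- intersect(setdiff(.mirna_ids(tm), normalize_mirna_id(exclude)),
                   names(p))
  sc <- p[ids]
  ord <- order(-sc, ids)
  data.frame(rank = seq_along(ord), mirna_id = ids[ord],
             score = unname(sc[ord]), stringsAsFactors = FALSE)
}

#' One-call network propagation ranking
#'
#' Convenience wrapper: builds the seed vector for the requested method,
#' runs the walk, and ranks non-seed miRNAs.
#'
#' @param tm a `transition_matrix`.
#' @param seeds known disease miRNA ids.
#' @param method `"rwrmtn"` (miRNA + target seeds, heterogeneous
#'   networks) or `"rwrmda"` (miRNA seeds only).
#' @param alpha seed weight for `"rwrmtn"`.
#' @param gamma restart probability.
#' @param tol,max_iter convergence controls, see [rwr()].
#' @return data.frame as from [rank_mirnas()], seeds excluded.
#' @export
propagate_rank <- function(tm, seeds, method = c("rwrmtn", "rwrmda"),
                           alpha = 0.9, gamma = 0.7, tol = 1e-6,
                           max_iter = 1000L) {
  method <- match.arg(method)
  p0 <- if (method == "rwrmtn") {
    seed_vector_hetero(seeds, tm, alpha = alpha)
  } else {
    seed_vector_mirna(seeds, tm)
  }
  res <- rwr(tm, p0, gamma = gamma, tol = tol, max_iter = max_iter)
  rank_mirnas(res, tm, exclude = seeds)
}
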