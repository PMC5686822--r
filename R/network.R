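#' Build a heterogeneous (bipartite) miRNA-target network
#'
#' Nodes are miRNAs and their target genes; every edge joins a miRNA to a
#' gene and carries unit weight. In `"mutual"` mode the interactions are
#' treated as reciprocal (undirected adjacency), modelling the mutual
#' regulation of miRNAs by their targets; in `"directed"` mode all edges
#' point miRNA -> gene, so gene nodes have out-degree 0 and trap a random
#' walker.
#'
#' @param interactions an `interaction_set` from [parse_interactions()].
#' @param mode `"mutual"` (default) or `"directed"`.
#' @return an object of class `hetero_network`: list with `nodes`
#'   (data.frame `id`, `class` in miRNA/gene; miRNAs sorted first, then
#'   genes sorted), `edges` (data.frame `from` = miRNA, `to` = gene) and
#'   `mode`.
#' @export
build_heterogeneous <- function(interactions, mode = c("mutual", "directed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(interactions, "interaction_set"))
  rec <- interactions$records
  if (nrow(rec) == 0L) stop("empty interaction set", call. = FALSE)
  mirnas <- sort(unique(rec$mirna_id))
  genes <- sort(unique(rec$gene_id))
  if (length(intersect(mirnas, genes)) > 0L) {
    stop("identifier namespaces overlap: ",
         paste(utils::head(intersect(mirnas, genes), 3L), collapse = ", "),
         call. = FALSE)
  }
  nodes <- data.frame(
    id = c(mirnas, genes),
    class = rep(c("miRNA", "gene"), c(length(mirnas), length(genes))),
    stringsAsFactors = FALSE
  )
  edges <- rec[order(rec$mirna_id, rec$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  names(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("hetero_network (", x$mode, "): ", nrow(x$nodes), " nodes (",
      sum(x$nodes$class == "miRNA"), " miRNAs, ",
      sum(x$nodes$class == "gene"), " genes), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# Sparse miRNA x gene incidence matrix for an interaction set or
# heterogeneous network.
.incidence <- function(edges, mirnas, genes) {
  Matrix::sparseMatrix(
    i = match(edges[[1L]], mirnas),
    j = match(edges[[2L]], genes),
    x = 1,
    dims = c(length(mirnas), length(genes)),
    dimnames = list(mirnas, genes)
  )
}

#' Build a homogeneous miRNA functional-similarity network
#'
#' Two miRNAs are connected iff they share at least one target gene; the
#' edge weight is the number of shared targets normalized by the smaller
#' of the two target-set sizes, |T_i intersect T_j| / min(|T_i|, |T_j|),
#' so weights lie in (0, 1]. miRNAs sharing no target with any other
#' miRNA are absent from the network.
#'
#' @param interactions an `interaction_set`.
#' @return an object of class `homo_network`: list with `nodes`
#'   (sorted character vector of miRNA ids) and `edges` (data.frame
#'   `from`, `to`, `weight` with `from < to`).
#' @export
build_homogeneous <- function(interactions) {
  stopifnot(inherits(interactions, "interaction_set"))
  rec <- interactions$records
  if (nrow(rec) == 0L) stop("empty interaction set", call. = FALSE)
  mirnas <- sort(unique(rec$mirna_id))
  genes <- sort(unique(rec$gene_id))
  B <- .incidence(rec, mirnas, genes)
  shared <- Matrix::tcrossprod(B)        # miRNA x miRNA shared-target counts
  tsize <- Matrix::rowSums(B)
  sh <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  i <- sh@i + 1L; j <- sh@j + 1L
  keep <- i < j & sh@x > 0
  i <- i[keep]; j <- j[keep]
  w <- sh@x[keep] / pmin(tsize[i], tsize[j])
  ord <- order(mirnas[i], mirnas[j])
  edges <- data.frame(from = mirnas[i][ord], to = mirnas[j][ord],
                      weight = w[ord], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "homo_network")
}

#' @export
print.homo_network <- function(x, ...) {
  cat("homo_network: ", length(x$nodes), " miRNAs, ", nrow(x$edges),
      " weighted edges\n", sep = "")
  invisible(x)
}

#' Target genes of a set of miRNAs
#'
#' @param net a `hetero_network` (or `interaction_set`).
#' @param mirnas character vector of miRNA ids.
#' @return sorted character vector of target gene ids.
#' @export
mirna_targets <- function(net, mirnas) {
  edges <- if (inherits(net, "hetero_network")) net$edges else
    stats::setNames(net$records, c("from", "to"))
  sort(unique(edges$to[edges$from %in% mirnas]))
}

#' Write a network as a tab-separated edge list
#'
#' Heterogeneous networks are written as two columns (miRNA, gene);
#' homogeneous networks gain a third weight column with 6 significant
#' digits. Re-parsing a written file reproduces the node and edge set.
#'
#' @param net a `hetero_network` or `homo_network`.
#' @param path file path.
#' @export
write_edgelist <- function(net, path) {
  if (inherits(net, "hetero_network")) {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (inherits(net, "homo_network")) {
    df <- net$edges
    df$weight <- formatC(df$weight, digits = 6L, format = "g")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported network class", call. = FALSE)
  }
  invisible(path)
}

#' Read a weighted homogeneous-network edge list
#'
#' @param x path or lines of a three-column tab-separated edge list
#'   (miRNA, miRNA, weight).
#' @return a `homo_network`.
#' @export
read_homogeneous <- function(x) {
  lines <- .read_tsv_lines(x)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no edges in input", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("homogeneous edge list needs 3 columns (from, to, weight)",
         call. = FALSE)
  }
  from <- normalize_mirna_id(vapply(fields, `[[`, "", 1L))
  to <- normalize_mirna_id(vapply(fields, `[[`, "", 2L))
  w <- as.numeric(vapply(fields, `[[`, "", 3L))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  ord <- order(from, to)
  edges <- data.frame(from = from[ord], to = to[ord], weight = w[ord],
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(from, to))), edges = edges),
            class = "homo_network")
}
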