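#' Normalize miRNA identifiers
#'
#' miRNA names are compared case-insensitively after trimming whitespace
#' (interaction databases differ in case conventions, e.g. "hsa-miR-17"
#' vs "hsa-mir-17").
#'
#' @param x character vector of miRNA names.
#' @return normalized (trimmed, lower-cased) character vector.
#' @export
normalize_mirna_id <- function(x) {
  tolower(trimws(x))
}

#' Normalize gene identifiers
#'
#' Gene symbols are trimmed and upper-cased.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_id <- function(x) {
  toupper(trimws(x))
}

# Header heuristics: a first line whose fields look like column names
# rather than identifiers.
.looks_like_header <- function(fields) {
  keys <- c("mirna", "mirna_id", "mir", "mir_id", "microrna", "source",
            "gene", "gene_id", "target", "target_id", "symbol", "score",
            "disease", "phenotype", "mim", "weight")
  any(tolower(trimws(fields)) %in% keys)
}

.read_tsv_lines <- function(x) {
  if (length(x) == 1L && !grepl("\t|\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

#' Parse a miRNA-target interaction edge list
#'
#' Reads a tab-separated edge list (miRNA identifier, gene identifier,
#' optional further columns such as a target-site score). Comment lines
#' starting with `#` and blank lines are skipped; a header line can be
#' auto-detected. Duplicate (miRNA, gene) pairs -- one row per evidence
#' source in most databases -- are collapsed to a single record and the
#' number collapsed is reported in the ingestion summary.
#'
#' @param x path to a file, a single string with embedded newlines, or a
#'   character vector of lines.
#' @param header `"auto"` (default), `"yes"` or `"no"`.
#' @param score_min optional numeric threshold applied to a third score
#'   column; rows below it are dropped. Default `NULL` (off, all edges
#'   kept with unit weight downstream).
#' @param quiet suppress the ingestion summary message.
#' @return an object of class `interaction_set`: a list with `records`
#'   (data.frame of unique `mirna_id`, `gene_id` pairs), `n_mirnas`,
#'   `n_genes`, `n_interactions`, `n_duplicates`.
#' @examples
#' ints <- parse_interactions(c("hsa-miR-1\tBDNF", "hsa-miR-1\tHDAC4",
#'                              "hsa-miR-206\tHDAC4"))
#' ints$n_interactions
#' @export
parse_interactions <- function(x, header = c("auto", "yes", "no"),
                               score_min = NULL, quiet = FALSE) {
  header <- match.arg(header)
  lines <- .read_tsv_lines(x)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no interactions: input contains no data lines", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  drop_header <- switch(header,
    yes  = TRUE,
    no   = FALSE,
    auto = .looks_like_header(fields[[1L]])
  )
  if (drop_header) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
    if (length(fields) == 0L) {
      stop("no interactions: input contains only a header", call. = FALSE)
    }
  }
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- line_no[which(nf < 2L)[1L]]
    stop("malformed interaction line ", bad,
         ": expected at least 2 tab-separated fields", call. = FALSE)
  }
  mirna <- normalize_mirna_id(vapply(fields, `[[`, "", 1L))
  gene  <- normalize_gene_id(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(mirna)) || any(!nzchar(gene))) {
    bad <- line_no[which(!nzchar(mirna) | !nzchar(gene))[1L]]
    stop("malformed interaction line ", bad, ": empty identifier",
         call. = FALSE)
  }
  if (!is.null(score_min)) {
    if (any(nf < 3L)) {
      stop("score_min given but a line lacks a score column", call. = FALSE)
    }
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(sc)) {
      bad <- line_no[which(is.na(sc))[1L]]
      stop("malformed interaction line ", bad, ": non-numeric score",
           call. = FALSE)
    }
    sel <- sc >= score_min
    mirna <- mirna[sel]; gene <- gene[sel]
    if (length(mirna) == 0L) {
      stop("no interactions: all rows fall below score_min", call. = FALSE)
    }
  }
  n_raw <- length(mirna)
  dup <- duplicated(paste(mirna, gene, sep = "\r"))
  records <- data.frame(mirna_id = mirna[!dup], gene_id = gene[!dup],
                        stringsAsFactors = FALSE)
  out <- structure(list(
    records        = records,
    n_mirnas       = length(unique(records$mirna_id)),
    n_genes        = length(unique(records$gene_id)),
    n_interactions = nrow(records),
    n_duplicates   = n_raw - nrow(records)
  ), class = "interaction_set")
  if (!quiet) {
    message("parsed ", out$n_interactions, " interactions (",
            out$n_mirnas, " miRNAs, ", out$n_genes, " genes; ",
            out$n_duplicates, " duplicate rows collapsed)")
  }
  out
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set: ", x$n_interactions, " interactions, ",
      x$n_mirnas, " miRNAs, ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Read disease-miRNA associations
#'
#' Reads a two-column tab-separated file (disease phenotype identifier,
#' miRNA identifier). OMIM-style numeric phenotype ids are treated as
#' opaque strings. Duplicate pairs are collapsed.
#'
#' @param x path, string with newlines, or character vector of lines.
#' @param quiet suppress the summary message.
#' @return an object of class `disease_associations`: a named list
#'   mapping disease id to a character vector of associated miRNA ids,
#'   with attributes `n_associations`, `n_diseases`, `n_mirnas`.
#' @export
read_associations <- function(x, quiet = FALSE) {
  lines <- .read_tsv_lines(x)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no associations in input", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (.looks_like_header(fields[[1L]])) {
    fields <- fields[-1L]; line_no <- line_no[-1L]
  }
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- line_no[which(nf < 2L)[1L]]
    stop("malformed association line ", bad,
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  disease <- trimws(vapply(fields, `[[`, "", 1L))
  mirna <- normalize_mirna_id(vapply(fields, `[[`, "", 2L))
  df <- unique(data.frame(disease = disease, mirna = mirna,
                          stringsAsFactors = FALSE))
  as_disease_associations(df, quiet = quiet)
}

#' Build a disease_associations object from a data frame
#'
#' @param df data.frame with columns `disease` and `mirna`.
#' @param quiet suppress the summary message.
#' @return a `disease_associations` object.
#' @export
as_disease_associations <- function(df, quiet = TRUE) {
  stopifnot(all(c("disease", "mirna") %in% names(df)))
  df <- unique(df[, c("disease", "mirna")])
  assoc <- split(df$mirna, df$disease)
  assoc <- lapply(assoc, function(v) sort(unique(v)))
  out <- structure(assoc, class = "disease_associations",
                   n_associations = nrow(df),
                   n_diseases = length(assoc),
                   n_mirnas = length(unique(df$mirna)))
  if (!quiet) {
    message("read ", nrow(df), " associations (", length(assoc),
            " phenotypes, ", length(unique(df$mirna)), " miRNAs)")
  }
  out
}

#' @export
print.disease_associations <- function(x, ...) {
  cat("disease_associations: ", attr(x, "n_associations"),
      " associations, ", attr(x, "n_diseases"), " phenotypes, ",
      attr(x, "n_mirnas"), " miRNAs\n", sep = "")
  invisible(x)
}

#' Read a labeled square similarity matrix
#'
#' Tab-separated matrix with a header row of labels and labels in the
#' first column, e.g. a disease-phenotype similarity matrix.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop("similarity matrix is not square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("similarity matrix row and column labels differ", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  m
}

#' Write a labeled square similarity matrix
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write disease-miRNA associations
#'
#' @param assoc a `disease_associations` object.
#' @param path file path.
#' @export
write_associations <- function(assoc, path) {
  df <- data.frame(
    disease = rep(names(assoc), lengths(assoc)),
    mirna = unlist(assoc, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
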