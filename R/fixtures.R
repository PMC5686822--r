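# Derive a bounded sub-seed so each generator uses its own stream and
# adding a call never perturbs earlier outputs.
.sub_seed <- function(seed, op) {
  (as.numeric(seed) * 7919 + op * 104729) %% 2147483647
}

#' Specification of a synthetic miRNA-target study
#'
#' Parameters of the seeded generators that emulate, at desk scale, the
#' inputs of a disease-miRNA prioritization study: a sparse bipartite
#' miRNA-target interaction set, disease modules of co-targeting miRNAs
#' planted into it, known/hidden association splits, and a
#' block-structured phenotype similarity matrix. The same spec and seed
#' always reproduce identical outputs.
#'
#' @param n_mirnas,n_genes node counts of the bipartite background
#'   (defaults 30 and 120).
#' @param edge_density probability of each background miRNA-gene edge
#'   (default 0.08).
#' @param n_diseases number of planted disease modules (default 3).
#' @param module_size miRNAs per disease module (default 8).
#' @param module_cohesion fraction of module miRNA - core gene pairs
#'   wired (in (0, 1], default 0.9); 0 is rejected because the module
#'   would be indistinguishable from background.
#' @param rng_seed integer master seed.
#' @return validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mirnas = 30L, n_genes = 120L,
                         edge_density = 0.08, n_diseases = 3L,
                         module_size = 8L, module_cohesion = 0.9,
                         rng_seed = 1L) {
  stopifnot(n_mirnas >= 2L, n_genes >= 2L, n_diseases >= 1L,
            edge_density > 0, edge_density <= 1,
            module_size >= 2L, module_size <= n_mirnas)
  if (module_cohesion <= 0 || module_cohesion > 1) {
    stop("module_cohesion must lie in (0, 1]: a zero-cohesion module ",
         "is indistinguishable from background", call. = FALSE)
  }
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 edge_density = edge_density,
                 n_diseases = as.integer(n_diseases),
                 module_size = as.integer(module_size),
                 module_cohesion = module_cohesion,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

.fixture_mirnas <- function(spec) {
  sprintf("sim-mir-%03d", seq_len(spec$n_mirnas))
}
.fixture_genes <- function(spec) {
  sprintf("SIMG%04d", seq_len(spec$n_genes))
}

#' Generate a random bipartite interaction set
#'
#' Each (miRNA, gene) pair is included independently with probability
#' `edge_density`; miRNAs left without any target are re-drawn (bounded
#' retries) so every miRNA has at least one target.
#'
#' @param spec a [fixture_spec()].
#' @return an `interaction_set`.
#' @export
generate_interactions <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mirnas <- .fixture_mirnas(spec)
  genes <- .fixture_genes(spec)
  .with_seed(.sub_seed(spec$rng_seed, 1L), {
    hit <- matrix(stats::runif(spec$n_mirnas * spec$n_genes) <
                    spec$edge_density,
                  nrow = spec$n_mirnas)
    for (i in which(rowSums(hit) == 0L)) {
      for (try in 1:100) {
        row <- stats::runif(spec$n_genes) < spec$edge_density
        if (any(row)) { hit[i, ] <- row; break }
      }
      if (!any(hit[i, ])) {
        stop("edge_density too low: miRNA still isolated after 100 ",
             "resampling attempts", call. = FALSE)
      }
    }
    idx <- which(hit, arr.ind = TRUE)
    lines <- paste(mirnas[idx[, 1L]], genes[idx[, 2L]], sep = "\t")
    parse_interactions(lines, header = "no", quiet = TRUE)
  })
}

#' Plant cohesive disease modules into an interaction set
#'
#' For each disease, a module of `module_size` miRNAs and an equally
#' sized core of genes are drawn; each module miRNA is wired to each
#' core gene with probability `module_cohesion`, creating the dense
#' co-targeting neighborhood that network propagation is meant to
#' exploit. A random half of each module's miRNAs is labeled as the
#' disease's known associations; the other half is hidden ground truth.
#'
#' @param interactions background `interaction_set`, e.g. from
#'   [generate_interactions()].
#' @param spec the same [fixture_spec()].
#' @return list with `interactions` (augmented `interaction_set`),
#'   `associations` (known half, `disease_associations`), `truth`
#'   (hidden half, `disease_associations`) and `modules` (list of
#'   per-disease miRNA/core-gene ids).
#' @export
plant_module <- function(interactions, spec) {
  stopifnot(inherits(interactions, "interaction_set"),
            inherits(spec, "fixture_spec"))
  mirnas <- .fixture_mirnas(spec)
  genes <- .fixture_genes(spec)
  .with_seed(.sub_seed(spec$rng_seed, 2L), {
    extra <- character()
    known <- list(); hidden <- list(); modules <- list()
    for (d in seq_len(spec$n_diseases)) {
      did <- sprintf("disease-%02d", d)
      mod_m <- sample(mirnas, spec$module_size)
      core_g <- sample(genes, spec$module_size)
      wire <- which(matrix(stats::runif(spec$module_size^2) <=
                             spec$module_cohesion,
                           nrow = spec$module_size), arr.ind = TRUE)
      extra <- c(extra, paste(mod_m[wire[, 1L]], core_g[wire[, 2L]],
                              sep = "\t"))
      lab <- sample(mod_m)
      n_known <- ceiling(spec$module_size / 2)
      known[[did]] <- sort(normalize_mirna_id(lab[seq_len(n_known)]))
      hidden[[did]] <- sort(normalize_mirna_id(lab[-seq_len(n_known)]))
      modules[[did]] <- list(mirnas = sort(mod_m), core = sort(core_g))
    }
    base_lines <- paste(interactions$records$mirna_id,
                        interactions$records$gene_id, sep = "\t")
    all_int <- parse_interactions(c(base_lines, extra), header = "no",
                                  quiet = TRUE)
    to_assoc <- function(l) as_disease_associations(data.frame(
      disease = rep(names(l), lengths(l)),
      mirna = unlist(l, use.names = FALSE), stringsAsFactors = FALSE))
    list(interactions = all_int, associations = to_assoc(known),
         truth = to_assoc(hidden), modules = modules)
  })
}

#' Generate a block-structured phenotype similarity matrix
#'
#' Symmetric with unit diagonal; background off-diagonal entries are
#' i.i.d. uniform on `[0, 0.3]`, while pairs inside a designated block
#' are drawn from `[0.6, 0.9]`, mimicking groups of clinically similar
#' phenotypes.
#'
#' @param n_diseases number of phenotypes (>= 2).
#' @param block_structure `NULL` (no blocks) or a list of integer index
#'   vectors, each a block of similar phenotypes.
#' @param rng_seed integer seed.
#' @param labels optional row/column labels (default
#'   `disease-01 ...`).
#' @return symmetric labeled matrix with entries in `[0, 1]`.
#' @export
generate_phenotype_similarity <- function(n_diseases,
                                          block_structure = NULL,
                                          rng_seed = 1L,
                                          labels = NULL) {
  stopifnot(n_diseases >= 2L)
  if (is.null(labels)) {
    labels <- sprintf("disease-%02d", seq_len(n_diseases))
  }
  .with_seed(.sub_seed(rng_seed, 3L), {
    S <- matrix(0, n_diseases, n_diseases,
                dimnames = list(labels, labels))
    up <- upper.tri(S)
    S[up] <- stats::runif(sum(up), 0, 0.3)
    if (!is.null(block_structure)) {
      for (blk in block_structure) {
        for (i in blk) for (j in blk) {
          if (i < j) S[i, j] <- stats::runif(1, 0.6, 0.9)
        }
      }
    }
    S <- S + t(S)
    diag(S) <- 1
    S
  })
}

#' Write a complete synthetic study to a directory
#'
#' Emits `interactions.tsv`, `associations.tsv`, `reference.tsv` (known
#' plus hidden associations, playing the role of a larger reference
#' database), `phenosim.tsv` and `truth.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list from [plant_module()].
#' @export
write_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- plant_module(generate_interactions(spec), spec)
  utils::write.table(fx$interactions$records,
                     file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_associations(fx$associations, file.path(dir, "associations.tsv"))
  write_associations(fx$truth, file.path(dir, "truth.tsv"))
  ref <- mapply(function(a, b) sort(unique(c(a, b))),
                fx$associations[names(fx$associations)],
                fx$truth[names(fx$associations)], SIMPLIFY = FALSE)
  write_associations(ref, file.path(dir, "reference.tsv"))
  S <- generate_phenotype_similarity(spec$n_diseases,
                                     rng_seed = spec$rng_seed)
  write_similarity_matrix(S, file.path(dir, "phenosim.tsv"))
  invisible(fx)
}
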