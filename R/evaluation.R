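# Run code with a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic rank and midrank of target id within a named score
# vector (descending scores; deterministic rank breaks ties by id).
.rank_of <- function(scores, target) {
  ids <- names(scores)
  s_t <- scores[[target]]
  det <- sum(scores > s_t | (scores == s_t & ids < target)) + 1L
  mid <- sum(scores > s_t) + (1 + sum(scores == s_t)) / 2
  c(det = det, mid = mid)
}

# Scoring closure per method; returns function(disease, held_out, seeds)
# -> named scores over the full miRNA universe.
.scorer <- function(method, net, tm, assoc, universe, alpha, gamma,
                    eta_M, eta_D, w, sim_disease, tol, max_iter) {
  if (method == "rwrmtn") {
    function(d, held, seeds) {
      p0 <- suppressWarnings(seed_vector_hetero(seeds, tm, alpha = alpha))
      res <- rwr(tm, p0, gamma = gamma, tol = tol, max_iter = max_iter)
      res$p[universe]
    }
  } else if (method == "rwrmda") {
    function(d, held, seeds) {
      p0 <- suppressWarnings(seed_vector_mirna(seeds, tm))
      res <- rwr(tm, p0, gamma = gamma, tol = tol, max_iter = max_iter)
      res$p[universe]
    }
  } else {
    A_full <- association_matrix(assoc, universe,
                                 diseases = intersect(names(assoc),
                                                      rownames(sim_disease)))
    S_M <- sim_from_homogeneous(net, universe)
    S_D <- sim_disease[rownames(A_full), rownames(A_full), drop = FALSE]
    function(d, held, seeds) {
      A <- A_full
      A[d, held] <- 0
      F <- rlsmda_scores(S_M, S_D, A, eta_M = eta_M, eta_D = eta_D, w = w)
      F[d, universe]
    }
  }
}

.check_method_net <- function(method, net, sim_disease) {
  if (method == "rwrmtn") {
    if (!inherits(net, "hetero_network")) {
      stop("rwrmtn requires a heterogeneous network", call. = FALSE)
    }
    if (net$mode != "mutual") {
      stop("rwrmtn requires a mutual heterogeneous network: on a ",
           "directed network the walker is trapped at dangling gene ",
           "nodes and non-seed nodes cannot be ranked", call. = FALSE)
    }
  } else if (method %in% c("rwrmda", "rlsmda")) {
    if (!inherits(net, "homo_network")) {
      stop(method, " requires a homogeneous miRNA network", call. = FALSE)
    }
    if (method == "rlsmda" && is.null(sim_disease)) {
      stop("rlsmda requires a disease phenotype similarity matrix",
           call. = FALSE)
    }
  }
}

#' Leave-one-out cross-validation of a prioritization method
#'
#' For each disease with at least two associated miRNAs present in the
#' network, each known miRNA is held out in turn; the remaining known
#' miRNAs seed the method (for RWRMTN, enlarged by their target genes),
#' and the held-out miRNA is ranked against all network miRNAs not known
#' to be associated with the disease. Diseases with fewer than two
#' usable associations are skipped with a logged reason. For RLSMDA the
#' held-out association is zeroed in the association matrix and the
#' closed form recomputed each round.
#'
#' @param assoc a `disease_associations` object.
#' @param net the network the method runs on: a mutual `hetero_network`
#'   for `"rwrmtn"`, a `homo_network` for `"rwrmda"` and `"rlsmda"`.
#' @param method one of `"rwrmtn"`, `"rwrmda"`, `"rlsmda"`.
#' @param alpha,gamma RWR parameters (defaults 0.9 and 0.7).
#' @param eta_M,eta_D,w RLSMDA parameters (defaults 1, 1, 0.9).
#' @param sim_disease disease similarity matrix (RLSMDA only).
#' @param tol,max_iter RWR convergence controls.
#' @param quiet suppress skip messages.
#' @return data.frame of class `holdout_records` with one row per
#'   (disease, held-out miRNA): `disease`, `mirna`, `rank` (1-based,
#'   deterministic tie-break), `midrank` (ties share their average
#'   rank), `candidates`. Skipped diseases are recorded in
#'   `attr(, "skipped")`.
#' @export
loocv <- function(assoc, net, method = c("rwrmtn", "rwrmda", "rlsmda"),
                  alpha = 0.9, gamma = 0.7, eta_M = 1, eta_D = 1,
                  w = 0.9, sim_disease = NULL, tol = 1e-6,
                  max_iter = 1000L, quiet = TRUE) {
  method <- match.arg(method)
  .check_method_net(method, net, sim_disease)
  tm <- if (method == "rlsmda") NULL else transition_matrix(net)
  universe <- if (method == "rlsmda") net$nodes else .mirna_ids(tm)
  score_fn <- .scorer(method, net, tm, assoc, universe, alpha, gamma,
                      eta_M, eta_D, w, sim_disease, tol, max_iter)
  diseases <- names(assoc)
  if (method == "rlsmda") {
    diseases <- intersect(diseases, rownames(sim_disease))
    dropped <- setdiff(names(assoc), diseases)
    if (length(dropped) && !quiet) {
      message(length(dropped),
              " disease(s) absent from the similarity matrix dropped")
    }
  }
  rows <- list()
  skipped <- list()
  for (d in diseases) {
    known <- intersect(assoc[[d]], universe)
    if (length(known) < 2L) {
      skipped[[d]] <- "fewer than 2 associated miRNAs in the network"
      if (!quiet) message("skipping ", d, ": ", skipped[[d]])
      next
    }
    non_assoc <- setdiff(universe, known)
    for (m in known) {
      seeds <- setdiff(known, m)
      candidates <- c(m, non_assoc)
      sc <- score_fn(d, m, seeds)[candidates]
      r <- .rank_of(sc, m)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, mirna = m, rank = as.integer(r[["det"]]),
        midrank = r[["mid"]], candidates = length(candidates),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), mirna = character(),
               rank = integer(), midrank = numeric(),
               candidates = integer(), stringsAsFactors = FALSE)
  structure(out,
            class = c("holdout_records", "data.frame"),
            skipped = skipped, method = method,
            params = list(alpha = alpha, gamma = gamma, eta_M = eta_M,
                          eta_D = eta_D, w = w),
            scheme = "loocv")
}

#' Per-disease ROC AUC from held-out ranks
#'
#' The ROC curve of a disease's held-out records has thresholds at every
#' achieved rank; sensitivity is the fraction of held-out miRNAs ranked
#' at or above the threshold, specificity comes from the non-associated
#' candidates. With ties interpolated through their group (midranks) the
#' trapezoidal area reduces, per record, to
#' `(candidates - midrank) / (candidates - 1)` -- the probability that
#' the held-out miRNA outranks a random non-associated candidate -- and
#' the disease AUC is the mean over its records.
#'
#' @param records a `holdout_records` data.frame.
#' @return data.frame with `disease`, `auc`, `n_records`.
#' @export
roc_auc <- function(records) {
  if (nrow(records) == 0L) stop("no holdout records", call. = FALSE)
  if (any(records$candidates < 2L)) {
    stop("AUC undefined with fewer than 2 candidates", call. = FALSE)
  }
  per <- (records$candidates - records$midrank) / (records$candidates - 1)
  agg <- tapply(per, records$disease, mean)
  data.frame(disease = names(agg), auc = as.numeric(agg),
             n_records = as.integer(table(records$disease)[names(agg)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize cross-validation performance
#'
#' @param records a `holdout_records` data.frame.
#' @return object of class `auc_summary`: list with `per_disease`
#'   (data.frame from [roc_auc()]), `grand_mean` (unweighted mean over
#'   diseases -- each disease counts once regardless of its number of
#'   associations), `method`, `params` and `scheme`.
#' @export
auc_summary <- function(records) {
  per <- roc_auc(records)
  structure(list(per_disease = per, grand_mean = mean(per$auc),
                 method = attr(records, "method"),
                 params = attr(records, "params"),
                 scheme = attr(records, "scheme")),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat("auc_summary [", x$method, ", ", x$scheme, "]: grand mean AUC ",
      sprintf("%.4f", x$grand_mean), " over ", nrow(x$per_disease),
      " diseases\n", sep = "")
  invisible(x)
}

#' k-fold cross-validation
#'
#' Only diseases with at least `k` associated miRNAs present in the
#' network are eligible. Per disease, associations are shuffled with a
#' seeded RNG and split round-robin into `k` folds; each fold is held
#' out in turn, the remaining folds seed the method, and every held-out
#' miRNA is ranked against the fold members plus all non-associated
#' network miRNAs. With `k` equal to a disease's association count this
#' reproduces LOOCV exactly.
#'
#' @inheritParams loocv
#' @param k number of folds (default 10).
#' @param rng_seed integer seed controlling the fold shuffle; the same
#'   seed yields identical folds and AUCs.
#' @return an `auc_summary`; the underlying records are in
#'   `attr(, "records")`.
#' @export
kfold <- function(assoc, net, method = c("rwrmtn", "rwrmda", "rlsmda"),
                  k = 10L, rng_seed = 1L, alpha = 0.9, gamma = 0.7,
                  eta_M = 1, eta_D = 1, w = 0.9, sim_disease = NULL,
                  tol = 1e-6, max_iter = 1000L, quiet = TRUE) {
  method <- match.arg(method)
  stopifnot(k >= 2L)
  .check_method_net(method, net, sim_disease)
  tm <- if (method == "rlsmda") NULL else transition_matrix(net)
  universe <- if (method == "rlsmda") net$nodes else .mirna_ids(tm)
  score_fn <- .scorer(method, net, tm, assoc, universe, alpha, gamma,
                      eta_M, eta_D, w, sim_disease, tol, max_iter)
  diseases <- names(assoc)
  if (method == "rlsmda") diseases <- intersect(diseases,
                                                rownames(sim_disease))
  eligible <- diseases[vapply(diseases, function(d)
    length(intersect(assoc[[d]], universe)) >= k, logical(1))]
  if (length(eligible) == 0L) {
    stop("no disease has at least ", k,
         " associated miRNAs in the network", call. = FALSE)
  }
  rows <- list()
  .with_seed(rng_seed, {
    for (d in sort(eligible)) {
      known <- sort(intersect(assoc[[d]], universe))
      shuffled <- sample(known)
      fold_of <- stats::setNames(rep_len(seq_len(k), length(known)),
                                 shuffled)
      non_assoc <- setdiff(universe, known)
      for (f in seq_len(k)) {
        held <- names(fold_of)[fold_of == f]
        seeds <- setdiff(known, held)
        candidates <- c(held, non_assoc)
        sc <- score_fn(d, held, seeds)[candidates]
        for (m in held) {
          r <- .rank_of(sc, m)
          rows[[length(rows) + 1L]] <- data.frame(
            disease = d, mirna = m, rank = as.integer(r[["det"]]),
            midrank = r[["mid"]], candidates = length(candidates),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  records <- structure(do.call(rbind, rows),
                       class = c("holdout_records", "data.frame"),
                       skipped = setdiff(diseases, eligible),
                       method = method,
                       params = list(alpha = alpha, gamma = gamma,
                                     eta_M = eta_M, eta_D = eta_D, w = w,
                                     k = k, rng_seed = rng_seed),
                       scheme = paste0(k, "-fold"))
  out <- auc_summary(records)
  attr(out, "records") <- records
  out
}

#' Grid search over the RWR parameters
#'
#' Runs LOOCV at every (alpha, gamma) grid point and reports the grand
#' mean AUC per point plus the best point. For `"rwrmda"` the alpha grid
#' is ignored (single `NA` column).
#'
#' @inheritParams loocv
#' @param alpha_grid numeric vector of seed weights (RWRMTN).
#' @param gamma_grid numeric vector of restart probabilities.
#' @return data.frame with columns `alpha`, `gamma`, `auc`; the best
#'   row's parameters in `attr(, "best")`.
#' @export
parameter_sweep <- function(assoc, net, method = c("rwrmtn", "rwrmda"),
                            alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            gamma_grid = seq(0.1, 0.9, by = 0.1),
                            tol = 1e-6, max_iter = 1000L) {
  method <- match.arg(method)
  stopifnot(length(gamma_grid) >= 1L)
  if (method == "rwrmda") alpha_grid <- NA_real_
  stopifnot(length(alpha_grid) >= 1L)
  grid <- expand.grid(alpha = alpha_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    rec <- loocv(assoc, net, method,
                 alpha = if (is.na(grid$alpha[i])) 0.9 else grid$alpha[i],
                 gamma = grid$gamma[i], tol = tol, max_iter = max_iter)
    auc_summary(rec)$grand_mean
  }, numeric(1))
  best <- grid[which.max(grid$auc), , drop = FALSE]
  structure(grid, best = best, method = method)
}

#' Trend of AUC against the restart probability
#'
#' Ordinary least-squares line through an (gamma, AUC) series; the slope
#' quantifies how performance responds to making the walk more local.
#'
#' @param gamma numeric vector of restart probabilities (>= 3 distinct
#'   values).
#' @param auc matching AUC values.
#' @return list with `slope`, `p_value` (two-sided t-test on the slope),
#'   `intercept` and the fitted `lm` object as `model`.
#' @export
gamma_trend <- function(gamma, auc) {
  stopifnot(length(gamma) == length(auc))
  if (length(gamma) < 3L) {
    stop("need at least 3 points for a trend", call. = FALSE)
  }
  if (length(unique(gamma)) == 1L) {
    stop("constant gamma values: trend undefined", call. = FALSE)
  }
  fit <- stats::lm(auc ~ gamma)
  co <- summary(fit)$coefficients
  list(slope = unname(co["gamma", "Estimate"]),
       p_value = unname(co["gamma", "Pr(>|t|)"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       model = fit)
}
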