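test_that("transition operator normalizes outgoing weight per source", {
  # path a - b - c (mutual, unit weights): from b, 1/2 to each side
  ints <- parse_interactions(c("mir-a\tGB", "mir-c\tGB"), quiet = TRUE)
  tm <- transition_matrix(build_heterogeneous(ints, "mutual"))
  op <- as.matrix(tm$op)
  expect_equal(op["mir-a", "GB"], 0.5)
  expect_equal(op["mir-c", "GB"], 0.5)
  # columns of sources with outgoing edges sum to 1
  expect_equal(unname(colSums(op)), rep(1, 3))

  # weighted homogeneous edges: w(a,b)=1, w(a,c)=3 -> 0.25 / 0.75 from a
  hom <- structure(list(
    nodes = c("mir-a", "mir-b", "mir-c"),
    edges = data.frame(from = c("mir-a", "mir-a"),
                       to = c("mir-b", "mir-c"),
                       weight = c(1, 3))), class = "homo_network")
  oph <- as.matrix(transition_matrix(hom)$op)
  expect_equal(oph["mir-b", "mir-a"], 0.25)
  expect_equal(oph["mir-c", "mir-a"], 0.75)

  # directed mode: gene nodes are dangling, zero outgoing mass
  dtm <- transition_matrix(build_heterogeneous(ints, "directed"))
  dop <- as.matrix(dtm$op)
  expect_equal(unname(dop[, "GB"]), rep(0, 3))
  expect_true(dtm$dangling[dtm$nodes$id == "GB"])

  expect_error(transition_matrix(structure(list(
    nodes = "m", edges = data.frame(from = character(),
                                    to = character(),
                                    weight = numeric())),
    class = "homo_network")), "no edges")
})

test_that("miRNA-only seed vector spreads mass uniformly", {
  ints <- random_interactions(n_m = 6, seed = 2)
  tm <- transition_matrix(build_heterogeneous(ints, "mutual"))
  p0 <- seed_vector_mirna(c("mir-a", "mir-b", "mir-c", "mir-d"), tm)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0[c("mir-a", "mir-d")]), c(0.25, 0.25))
  # absent seed dropped, remaining renormalized
  expect_warning(p1 <- seed_vector_mirna(c("mir-a", "mir-b", "mir-zz"), tm),
                 "absent")
  expect_equal(unname(p1[c("mir-a", "mir-b")]), c(0.5, 0.5))
  expect_equal(sum(p1), 1)
  # single seed gets everything; no present seed is an error
  expect_equal(max(seed_vector_mirna("mir-a", tm)), 1)
  expect_error(seed_vector_mirna("mir-zz", tm), "empty seed")
})

test_that("heterogeneous seed vector splits mass alpha / (1 - alpha)", {
  ints <- parse_interactions(
    c("mir-a\tG1", "mir-a\tG2", "mir-b\tG2", "mir-b\tG3", "mir-c\tG9"),
    quiet = TRUE)
  tm <- transition_matrix(build_heterogeneous(ints, "mutual"))
  # S_m = {a, b}, derived S_g = {G1, G2, G3}
  p0 <- seed_vector_hetero(c("mir-a", "mir-b"), tm, alpha = 0.9)
  expect_equal(unname(p0[c("mir-a", "mir-b")]), c(0.45, 0.45))
  expect_equal(unname(p0[c("G1", "G2", "G3")]), rep(0.1 / 3, 3))
  expect_equal(unname(p0["G9"]), 0)   # not a target of the seeds
  expect_equal(sum(p0), 1)

  # alpha = 1 reduces to the miRNA-only policy
  expect_equal(seed_vector_hetero(c("mir-a", "mir-b"), tm, alpha = 1),
               seed_vector_mirna(c("mir-a", "mir-b"), tm))
  # alpha = 0 puts all mass on the genes
  p_g <- seed_vector_hetero(c("mir-a", "mir-b"), tm, alpha = 0)
  expect_equal(unname(p_g[c("G1", "G2", "G3")]), rep(1 / 3, 3))
  # explicit S_g override
  p_o <- seed_vector_hetero("mir-a", tm, alpha = 0.5, seed_genes = "G3")
  expect_equal(unname(p_o[c("mir-a", "G3")]), c(0.5, 0.5))
})

test_that("walk fixed points match hand and linear-solve oracles", {
  # gamma = 1: p stays at p0 after one iteration
  ints <- random_interactions(seed = 4)
  net <- build_heterogeneous(ints, "mutual")
  tm <- transition_matrix(net)
  p0 <- seed_vector_mirna("mir-a", tm)
  r1 <- rwr(tm, p0, gamma = 1)
  expect_equal(unname(r1$p), unname(p0))
  expect_equal(r1$iterations, 1L)

  # single undirected edge, seed one end: p(seed) = 1 / (2 - gamma)
  edge <- parse_interactions("mir-a\tG1", quiet = TRUE)
  tm2 <- transition_matrix(build_heterogeneous(edge, "mutual"))
  r2 <- rwr(tm2, seed_vector_mirna("mir-a", tm2), gamma = 0.7)
  expect_equal(r2$p[["mir-a"]], 1 / 1.3, tolerance = 1e-5)

  # gamma -> 0 on a connected unit-weight (non-bipartite) graph:
  # steady state approaches the degree-proportional stationary law
  tri <- structure(list(
    nodes = c("mir-a", "mir-b", "mir-c", "mir-d"),
    edges = data.frame(from = c("mir-a", "mir-a", "mir-b", "mir-a"),
                       to = c("mir-b", "mir-c", "mir-c", "mir-d"),
                       weight = 1)), class = "homo_network")
  tm3 <- transition_matrix(tri)
  r3 <- rwr(tm3, seed_vector_mirna("mir-a", tm3), gamma = 1e-4,
            tol = 1e-12, max_iter = 100000)
  deg <- c(3, 2, 2, 1)
  expect_equal(unname(r3$p), deg / sum(deg), tolerance = 1e-3)

  # direct linear solve oracle on random small mutual networks
  for (seed in 1:5) {
    ints <- random_interactions(n_m = 4, n_g = 6, seed = seed)
    net <- build_heterogeneous(ints, "mutual")
    tmx <- transition_matrix(net)
    p0x <- seed_vector_hetero(c("mir-a", "mir-b"), tmx, alpha = 0.7)
    got <- rwr(tmx, p0x, gamma = 0.4, tol = 1e-10)
    want <- rwr_linear_solve(dense_adjacency(net), unname(p0x), 0.4)
    expect_equal(unname(got$p), unname(want), tolerance = 1e-9)
  }
})

test_that("walk conserves mass and reacts to gamma and relabeling as expected", {
  ints <- random_interactions(n_m = 6, n_g = 10, seed = 11)
  net <- build_heterogeneous(ints, "mutual")
  tm <- transition_matrix(net)
  p0 <- seed_vector_mirna(c("mir-a", "mir-c"), tm)

  # mass conservation at every iterate on a mutual network
  p <- unname(p0)
  for (i in 1:50) {
    p <- as.numeric((1 - 0.5) * (tm$op %*% p)) + 0.5 * unname(p0)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }

  # increasing gamma never decreases steady-state mass at a seed
  at_seed <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(g)
    rwr(tm, p0, gamma = g, tol = 1e-10)$p[["mir-a"]], numeric(1))
  expect_true(all(diff(at_seed) >= -1e-9))

  # relabeling invariance: permuted ids give a permuted steady state
  rec <- ints$records
  relab <- parse_interactions(
    paste(sub("^mir-", "zmir-", rec$mirna_id), rec$gene_id, sep = "\t"),
    quiet = TRUE)
  tmz <- transition_matrix(build_heterogeneous(relab, "mutual"))
  pz <- rwr(tmz, seed_vector_mirna(c("zmir-a", "zmir-c"), tmz),
            gamma = 0.5, tol = 1e-10)$p
  po <- rwr(tm, p0, gamma = 0.5, tol = 1e-10)$p
  expect_equal(unname(pz[paste0("z", names(po)[1:5])]),
               unname(po[1:5]), tolerance = 1e-12)

  # non-convergence within max_iter is an error carrying the residual
  expect_error(rwr(tm, p0, gamma = 0.1, tol = 1e-15, max_iter = 3L),
               "did not converge")
})

test_that("directed networks trap the walker at dangling gene seeds", {
  ints <- random_interactions(n_m = 5, n_g = 8, seed = 6)
  net <- build_heterogeneous(ints, "directed")
  tm <- transition_matrix(net)
  p0 <- seed_vector_hetero("mir-a", tm, alpha = 0.5)
  res <- rwr(tm, p0, gamma = 0.3, tol = 1e-10)
  expect_true(res$mass_deficient)
  # non-seed nodes end up with (near-)zero probability: everything
  # concentrates on the seeds because genes have no outgoing links
  non_seed <- setdiff(names(res$p), names(p0)[p0 > 0])
  expect_true(all(res$p[non_seed] < 0.3 * min(p0[p0 > 0])))
})

test_that("ranking filters genes, honors exclusions and breaks ties by id", {
  ints <- tiny_interactions()
  tm <- transition_matrix(build_heterogeneous(ints, "mutual"))
  p <- setNames(numeric(nrow(tm$nodes)), tm$nodes$id)
  p["hsa-mir-a"] <- 0.3; p["hsa-mir-b"] <- 0.1; p["G1"] <- 0.6
  rk <- rank_mirnas(p, tm)
  expect_equal(rk$mirna_id[1:2], c("hsa-mir-a", "hsa-mir-b"))
  expect_false(any(grepl("^G", rk$mirna_id)))
  expect_equal(rank_mirnas(p, tm, exclude = "hsa-mir-a")$mirna_id[1],
               "hsa-mir-b")
  # tie -> ascending lexicographic id
  p[c("hsa-mir-a", "hsa-mir-b", "hsa-mir-c")] <- 0.2
  expect_equal(rank_mirnas(p, tm)$mirna_id,
               c("hsa-mir-a", "hsa-mir-b", "hsa-mir-c"))
})
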