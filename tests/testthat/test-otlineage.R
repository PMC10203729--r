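test_that("timepoint assignment follows the collection-time convention", {
  cs <- cell_set(matrix(0, 4, 1), paste0("c", 1:4), "g",
                 meta = data.frame(sample = c("PSC", "PreME", "EB", "EB"),
                                   time_h = c(NA, NA, 12, 96)))
  at <- assign_times(cs)
  expect_equal(at$time_h, c(0, 12, 24, 108))
  expect_equal(at$timepoints, c(0, 12, 24, 108))
  expect_equal(at$tp, 1:4)
  # absolute mode is the identity on time_h
  cs2 <- cell_set(matrix(0, 2, 1), c("a", "b"), "g",
                  meta = data.frame(sample = c("s1", "s2"),
                                    time_h = c(5, 3)))
  expect_equal(assign_times(cs2, absolute = TRUE)$time_h, c(5, 3))
  # unresolvable times are an error
  cs3 <- cell_set(matrix(0, 1, 1), "a", "g",
                  meta = data.frame(sample = "EB", time_h = NA_real_))
  expect_error(assign_times(cs3), "resolvable")
})

test_that("entropic transport reaches its closed-form limits", {
  # large epsilon: the product coupling a x b
  tm <- compute_transport_map(matrix(0, 2, 1), matrix(0, 2, 1),
    ot_params(lambda1 = Inf, lambda2 = Inf, epsilon = 1e4,
              cost_normalisation = "none"),
    cost = matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(tm$gamma), matrix(0.25, 2, 2), tolerance = 1e-3)
  # small epsilon on an identity-favouring cost: the diagonal coupling
  tm2 <- compute_transport_map(matrix(0, 2, 1), matrix(0, 2, 1),
    ot_params(lambda1 = Inf, lambda2 = Inf, epsilon = 0.01,
              cost_normalisation = "none"),
    cost = matrix(c(0, 1, 1, 0), 2))
  expect_lt(max(abs(tm2$gamma - diag(0.5, 2))), 1e-3)
  expect_true(tm2$converged)
})

test_that("balanced transport matches a linear-programming oracle", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3), n); Y <- matrix(rnorm(n * 3), n)
  C <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  tm <- suppressWarnings(compute_transport_map(
    X, Y, ot_params(lambda1 = Inf, lambda2 = Inf,
                    epsilon = 1e-3, tol = 1e-7, max_iter = 30000)))
  Cn <- C / median(C)
  lp <- lp_transport_cost(Cn)
  got <- sum(tm$gamma * Cn)
  expect_lt(abs(got - lp) / lp, 0.01)
  expect_lt(tm$marginal_violation, 1e-5)
})

test_that("near-balanced relaxation conserves mass", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30); Y <- matrix(rnorm(24 * 4), 24)
  tm <- compute_transport_map(X, Y, ot_params(lambda1 = 1e6, lambda2 = 1e6,
                                              epsilon = 0.05))
  expect_equal(sum(tm$gamma), 1, tolerance = 1e-6)
  expect_lt(tm$source_violation, 1e-6)
  expect_lt(tm$target_violation, 1e-6)
})

test_that("the relaxation weights shape the marginal violations", {
  set.seed(8)
  for (i in 1:3) {
    X <- matrix(rnorm(25 * 3), 25); Y <- matrix(rnorm(25 * 3), 25)
    tm <- compute_transport_map(X, Y, ot_params())  # lambda2 = 50 >> lambda1
    expect_lt(tm$target_violation, tm$source_violation)
  }
})

test_that("ancestor pull-back marginalises, conserves and chains correctly", {
  set.seed(9)
  X <- matrix(rnorm(12 * 3), 12); Y <- matrix(rnorm(10 * 3), 10)
  Z <- matrix(rnorm(14 * 3), 14)
  m1 <- compute_transport_map(X, Y, ot_params(lambda1 = 1e6, lambda2 = 1e6,
                                              epsilon = 0.05))
  m2 <- compute_transport_map(Y, Z, ot_params(lambda1 = 1e6, lambda2 = 1e6,
                                              epsilon = 0.05))
  # target = all cells under a balanced map: ancestor mass = source marginal
  anc <- ancestor_contributions(list(m2), rep(TRUE, 14))
  expect_equal(anc[[1]], m2$source_marginal, tolerance = 1e-5)
  # empty target: zero mass everywhere
  anc0 <- ancestor_contributions(list(m1, m2), integer(0))
  expect_true(all(unlist(anc0) == 0))
  # chain equals pull-back through the product of the normalised maps
  S <- c(2, 5, 9)
  anc2 <- ancestor_contributions(list(m1, m2), S)
  cn <- function(g) sweep(g, 2, colSums(g), "/")
  mass <- numeric(14); mass[S] <- 1 / 3
  expect_equal(anc2[[1]], as.vector(cn(m1$gamma) %*% cn(m2$gamma) %*% mass),
               tolerance = 1e-12)
  # conservation at every step
  expect_equal(sum(anc2[[1]]), 1, tolerance = 1e-9)
  expect_equal(sum(anc2[[2]]), 1, tolerance = 1e-9)
  # chain gaps are rejected
  expect_error(ancestor_contributions(list(m2, m1), 1:3), "chain gap")
})

test_that("contribution matrix normalisations are exact on constructed maps", {
  # one cluster per timepoint: all entries 1
  g1 <- structure(list(gamma = matrix(c(.2, .1, .3, .4), 2)),
                  class = "transport_map")
  cm <- contribution_matrix(list(g1), list(c("a", "a"), c("a", "a")))
  expect_equal(unname(cm$A["a@t1", "a@t2"]), 1)
  # permutation-like block transport: a permutation matrix
  gam <- matrix(0, 4, 4)
  gam[1:2, 3:4] <- 0.25; gam[3:4, 1:2] <- 0.25
  g2 <- structure(list(gamma = gam), class = "transport_map")
  cm2 <- contribution_matrix(list(g2),
                             list(c("p", "p", "q", "q"),
                                  c("r", "r", "s", "s")))
  blk <- cm2$A[c("p@t1", "q@t1"), c("r@t2", "s@t2")]
  expect_equal(unname(blk), matrix(c(0, 1, 1, 0), 2))
  # ancestors mode: incoming entries of every target node sum to 1
  set.seed(10)
  gam3 <- matrix(runif(30), 5, 6)
  g3 <- structure(list(gamma = gam3), class = "transport_map")
  cl <- list(c("a", "a", "b", "b", "c"), c("x", "x", "y", "y", "z", "z"))
  cm3 <- contribution_matrix(list(g3), cl, normalize = "ancestors")
  expect_equal(unname(colSums(cm3$A[1:3, 4:6])), rep(1, 3))
  # descendants mode: outgoing entries of every source node sum to 1
  cm4 <- contribution_matrix(list(g3), cl, normalize = "descendants")
  expect_equal(unname(rowSums(cm4$A[1:3, 4:6])), rep(1, 3))
})

test_that("power-threshold sparsification keeps only near-certain links", {
  A <- matrix(c(1, 0.95, 0.9, 0), 2)
  As <- sparsify(A, P = 30, censor = 0.1)
  expect_equal(As[1, 1], 1)
  expect_equal(As[2, 1], 0.95^30)
  expect_gt(As[2, 1], 0.1)
  expect_equal(As[1, 2], 0)   # 0.9^30 ~ 0.042 censored
  expect_equal(As[2, 2], 0)
  # masked mode keeps original values under the same mask
  Am <- sparsify(A, P = 30, censor = 0.1, mode = "masked")
  expect_equal(Am, matrix(c(1, 0.95, 0, 0), 2))
  # never creates mass: A_sparse <= A^P, zeros preserved
  set.seed(11)
  B <- matrix(runif(64), 8)
  Bs <- sparsify(B, P = 30, censor = 0.1)
  expect_true(all(Bs <= B^30 + 1e-15))
  expect_true(all(Bs[B == 0] == 0))
})

test_that("the directed KNN graph keeps each node's top-k outgoing links", {
  A <- rbind(n1 = c(0, .5, .2, 0, 0, 0, 0),
             n2 = c(.9, .8, .7, .6, .5, .4, .3))
  colnames(A) <- paste0("m", 1:7)
  e <- build_lineage_graph(A, k_graph = 5)
  expect_equal(sum(e$from == "n1"), 2L)
  expect_equal(sum(e$from == "n2"), 5L)
  expect_setequal(e$to[e$from == "n2"], paste0("m", 1:5))
  # brute-force oracle on random sparse matrices
  set.seed(12)
  R <- matrix(runif(100), 10) * (matrix(runif(100), 10) > 0.5)
  rownames(R) <- colnames(R) <- paste0("v", 1:10)
  e2 <- build_lineage_graph(R, k_graph = 3)
  for (i in 1:10) {
    w <- R[i, ]; nz <- which(w > 0)
    want <- colnames(R)[nz[order(-w[nz])][seq_len(min(3, length(nz)))]]
    expect_setequal(e2$to[e2$from == paste0("v", i)], want)
  }
})

test_that("walktrap communities recover planted block structure", {
  skel <- function(edges, nodes) {
    structure(list(nodes = data.frame(name = nodes,
                                      cluster = nodes,
                                      tp = 1L,
                                      stringsAsFactors = FALSE),
                   A = NULL, A_sparse = NULL, edges = edges,
                   communities = NULL, annotations = NULL,
                   normalize = "ancestors"),
              class = "lineage_graph")
  }
  # two disconnected triangles
  tri <- data.frame(
    from = c("a1", "a2", "a3", "b1", "b2", "b3"),
    to = c("a2", "a3", "a1", "b2", "b3", "b1"),
    weight = 1, stringsAsFactors = FALSE)
  g <- detect_communities(skel(tri, c("a1", "a2", "a3", "b1", "b2", "b3")))
  m <- g$communities
  expect_equal(length(unique(m)), 2L)
  expect_equal(length(unique(m[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(m[c("b1", "b2", "b3")])), 1L)
  # fully connected uniform graph: one community
  full <- expand.grid(from = paste0("n", 1:5), to = paste0("n", 1:5),
                      stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  full$weight <- 1
  g2 <- detect_communities(skel(full, paste0("n", 1:5)))
  expect_equal(length(unique(g2$communities)), 1L)
  # planted two-block graph: exact recovery
  blocks <- rep(c("x", "y"), each = 10)
  nodes <- paste0(blocks, 1:10)
  pairs <- t(combn(20, 2))
  e <- data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                  weight = ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]],
                                  1, 0.01),
                  stringsAsFactors = FALSE)
  g3 <- detect_communities(skel(e, nodes))
  m3 <- g3$communities
  expect_equal(length(unique(m3)), 2L)
  expect_equal(length(unique(m3[nodes[blocks == "x"]])), 1L)
  expect_equal(length(unique(m3[nodes[blocks == "y"]])), 1L)
  # isolated nodes become singleton communities
  iso <- skel(tri, c("a1", "a2", "a3", "b1", "b2", "b3", "lonely"))
  g4 <- detect_communities(iso)
  expect_equal(sum(g4$communities == g4$communities["lonely"]), 1L)
})

test_that("meta-cluster annotation scores markers and resolves ties", {
  counts <- rbind(c(10L, 10L, 0L, 0L),
                  c(12L, 8L, 0L, 0L),
                  c(0L, 0L, 10L, 10L),
                  c(5L, 5L, 5L, 5L))
  cs <- cell_set(counts, paste0("c", 1:4),
                 c("mA1", "mA2", "mB1", "mB2"),
                 meta = data.frame(cluster = c("u", "u", "v", "w"),
                                   tp = c(1L, 1L, 1L, 1L)))
  g <- structure(list(nodes = data.frame(name = c("u@t1", "v@t1", "w@t1"),
                                         cluster = c("u", "v", "w"),
                                         tp = 1L, stringsAsFactors = FALSE),
                      A = NULL, A_sparse = NULL, edges = NULL,
                      communities = c("u@t1" = 1L, "v@t1" = 2L, "w@t1" = 3L),
                      annotations = NULL, normalize = "ancestors"),
                 class = "lineage_graph")
  markers <- list(A = c("mA1", "mA2"), B = c("mB1", "mB2"))
  out <- annotate_metaclusters(cs, g, markers)
  ann <- out$graph$annotations
  expect_equal(ann$label[ann$community == 1], "A")
  expect_equal(ann$label[ann$community == 2], "B")
  expect_equal(ann$label[ann$community == 3], "UNRESOLVED")
  expect_equal(ann$candidates[ann$community == 3], "A;B")
  expect_equal(unname(out$cell_labels[c("c1", "c3")]), c("A", "B"))
  expect_error(annotate_metaclusters(cs, g, list()), "empty")
})

test_that("the full pipeline reconstructs a small planted time course", {
  p <- synth_params(n_genes = 250, n_cells_per_cluster = 60,
                    timepoints_h = c(0, 12, 24, 30, 36, 42, 44, 52), seed = 3)
  sim <- simulate_timecourse(p)
  fit <- suppressWarnings(fit_lineage_ot(sim$emb, sim$cells$meta$time_h,
                                         sim$cells$meta$cluster))
  planted <- paste0(sim$tree$edges$from_cluster, "@t", sim$tree$edges$from_tp,
                    "->", sim$tree$edges$to_cluster, "@t", sim$tree$edges$to_tp)
  found <- paste0(fit$graph$edges$from, "->", fit$graph$edges$to)
  expect_true(all(planted %in% found))
  ann <- annotate_metaclusters(sim$cells, fit$graph, planted_markers(sim))
  expect_gte(lineage_agreement(sim$cells, sim$tree, ann$cell_labels), 0.9)
})
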