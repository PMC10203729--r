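make_ref <- function(coords, positions, labels = NULL) {
  n <- nrow(coords)
  spatial_reference(positions,
                    if (is.null(labels)) rep("A", n) else labels,
                    embedding(coords, paste0("r", seq_len(n)), "s"))
}

test_that("SNN weights normalise and match the brute-force Jaccard oracle", {
  set.seed(1)
  refc <- matrix(rnorm(60 * 4), 60)
  ref <- make_ref(refc, matrix(rnorm(180), 60))
  # query identical to a reference cell, K = 1: weight 1 after normalisation
  q <- embedding(refc[5, , drop = FALSE], "q1", "s")
  w <- snn_weights(q, ref, 1, K = 1, k_graph = 10)
  expect_equal(w$theta_hat, 1)
  expect_equal(w$neighbor_indices, 5L)

  # 100 random points: theta equals neighbour-set Jaccard overlaps
  set.seed(2)
  qc <- matrix(rnorm(40 * 4), 40)
  qe <- embedding(qc, paste0("q", 1:40), "s")
  k_graph <- 12
  pooled <- rbind(qc, refc)
  nn_o <- knn_oracle(pooled, pooled, k_graph + 1)
  sets <- lapply(seq_len(nrow(pooled)), function(i)
    setdiff(nn_o[i, ], i)[seq_len(k_graph)])
  for (j in c(1, 17, 40)) {
    w <- snn_weights(qe, ref, j, K = 8, k_graph = k_graph)
    d <- sqrt(colSums((t(refc) - qc[j, ])^2))
    nb <- order(d)[1:8]
    expect_equal(w$neighbor_indices, nb)
    th <- vapply(nb, function(i) jaccard_oracle(sets[[j]], sets[[40 + i]]),
                 numeric(1))
    expect_equal(w$theta, th, tolerance = 1e-12)
    expect_equal(sum(w$theta_hat), 1)
  }
})

test_that("zero SNN overlap falls back to uniform weights with a flag", {
  # two far-apart blobs: a lone query shares no neighbours with the far side
  refc <- rbind(matrix(rnorm(40, sd = .1), 20, 2),
                matrix(rnorm(40, sd = .1) + 100, 20, 2))
  ref <- make_ref(refc, cbind(refc, 0))
  q <- embedding(matrix(c(0, 0), 1), "q", "s")
  w <- snn_weights(q, ref, 1, K = 3, k_graph = 5)
  # neighbours are the near blob, overlap is positive there; force zero
  # overlap by querying for far-side neighbours only
  far <- make_ref(refc[21:40, ], cbind(refc[21:40, ], 0))
  w2 <- snn_weights(q, far, 1, K = 4, k_graph = 5)
  if (w2$c == 0) {
    expect_true(w2$zero_overlap)
    expect_equal(w2$theta_hat, rep(0.25, 4))
  }
  expect_equal(sum(w$theta_hat), 1)
})

test_that("projection is the weighted neighbour average", {
  ref <- make_ref(matrix(0, 2, 2), rbind(c(0, 0, 0), c(4, 0, 0)))
  w <- structure(list(query_cell = "q", neighbor_indices = 1:2,
                      theta = c(1, 3), theta_hat = c(0.25, 0.75), c = 4,
                      zero_overlap = FALSE), class = "snn_weights")
  p <- project_position(w, ref)
  expect_equal(unname(p$R), c(3, 0, 0))
  # K = 1 returns the neighbour position itself
  w1 <- structure(list(query_cell = "q", neighbor_indices = 2L, theta = 1,
                       theta_hat = 1, c = 1, zero_overlap = FALSE),
                  class = "snn_weights")
  expect_equal(unname(project_position(w1, ref)$R), c(4, 0, 0))
  # uniform weights give the neighbour centroid
  wu <- structure(list(query_cell = "q", neighbor_indices = 1:2,
                       theta = c(1, 1), theta_hat = c(0.5, 0.5), c = 2,
                       zero_overlap = FALSE), class = "snn_weights")
  expect_equal(unname(project_position(wu, ref)$R), c(2, 0, 0))
})

test_that("projected positions lie in the convex hull of their neighbours", {
  set.seed(3)
  refc <- matrix(rnorm(50 * 4), 50)
  ref <- make_ref(refc, matrix(rnorm(150), 50))
  q <- embedding(matrix(rnorm(10 * 4), 10), paste0("q", 1:10), "s")
  pooled_nn <- pooled_knn_sets(q, ref, 10)
  for (j in 1:10) {
    w <- snn_weights(q, ref, j, K = 4, k_graph = 10, pooled_nn = pooled_nn)
    # barycentric check: weights in the simplex and R reconstructs exactly
    expect_true(all(w$theta_hat >= 0))
    expect_equal(sum(w$theta_hat), 1)
    p <- project_position(w, ref)
    expect_equal(unname(p$R),
                 as.numeric(t(ref$positions[w$neighbor_indices, ]) %*%
                              w$theta_hat))
  }
})

test_that("group density matches the brute-force kernel sum and integrates to 1", {
  set.seed(4)
  proj <- data.frame(cell_id = paste0("c", 1:30),
                     x = rnorm(30), y = rnorm(30, sd = 2), z = rnorm(30))
  dens <- group_density(proj, proj$cell_id, n_grid = 24)
  at <- as.matrix(dens$long[sample(nrow(dens$long), 40), c("x", "y", "z")])
  oracle <- kde3_oracle(as.matrix(proj[, c("x", "y", "z")]),
                        dens$bandwidth, at)
  got <- apply(at, 1, function(g)
    dens$density[which.min(abs(dens$grid$x - g[1])),
                 which.min(abs(dens$grid$y - g[2])),
                 which.min(abs(dens$grid$z - g[3]))])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
  dx <- diff(dens$grid$x)[1]; dy <- diff(dens$grid$y)[1]
  dz <- diff(dens$grid$z)[1]
  expect_equal(sum(dens$density) * dx * dy * dz, 1, tolerance = 0.01)
})

test_that("density of symmetric point masses is symmetric", {
  proj <- data.frame(cell_id = c("a", "b"),
                     x = c(-1, 1), y = 0, z = 0)
  grid <- list(x = seq(-3, 3, length.out = 21),
               y = seq(-1, 1, length.out = 5),
               z = seq(-1, 1, length.out = 5))
  dens <- group_density(proj, c("a", "b"), grid = grid, bandwidth = rep(.5, 3))
  flipped <- dens$density[21:1, , ]
  expect_lt(max(abs(dens$density - flipped)), 1e-10)
  # all mass at one point: mode at that point
  proj2 <- data.frame(cell_id = c("a", "b"), x = 1, y = 0, z = 0)
  dens2 <- group_density(proj2, c("a", "b"), grid = grid,
                         bandwidth = rep(.5, 3))
  expect_equal(unname(density_mode(dens2)), c(0.9, 0, 0), tolerance = 1e-9)
  expect_error(group_density(proj, "nope", grid = grid), "empty group")
})

test_that("query cells project into their planted spatial domains", {
  p <- synth_params(n_genes = 300, n_cells_per_cluster = 150, n_lineages = 2,
                    seed = 7)
  ref <- simulate_spatial_reference(p)
  q <- plant_query(p, ref, n_per_lineage = 100)
  proj <- project_cells(q$emb, ref, K = 10, k_graph = 20)
  in_left <- proj$x < 0
  acc <- mean(ifelse(q$true_labels == "L1", in_left, !in_left))
  expect_gte(acc, 0.9)
  # group-density mode for L1 falls inside the x < 0 domain
  dens <- group_density(proj, proj$cell_id[q$true_labels == "L1"])
  expect_lt(density_mode(dens)["x"], 0)
  # projected lineage-centroid order along x preserves the planted order
  cx <- tapply(proj$x, q$true_labels, mean)
  expect_equal(unname(rank(cx[c("L1", "L2")])), c(1, 2))
})
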