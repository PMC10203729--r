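#' Parameters of the synthetic branching time course
#'
#' Bundles every knob of the generator. Defaults emulate the kind of
#' embryoid-body differentiation series the pipeline targets: a 10-point
#' collection schedule spanning 0-108 h, droplet-scale cluster sizes,
#' negative-binomial count noise and four terminal lineages branching from
#' a pluripotent root.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_cluster Cells per (cluster, timepoint) unit.
#' @param n_lineages Number of terminal lineages (1-6 supported).
#' @param timepoints_h Collection times in hours.
#' @param effect_size Lineage-marker mean shift on the natural-log scale
#'   (default 1.5, i.e. committed cells express their markers ~4.5-fold
#'   higher).
#' @param dispersion Negative-binomial overdispersion `alpha` in
#'   `var = mu + alpha * mu^2` (default 0.5).
#' @param noise_sd Gaussian jitter of embedding coordinates around the
#'   cluster trajectory (default 0.25).
#' @param seed Integer seed; all generator functions are bit-reproducible
#'   given the same params.
#' @param n_markers_per_lineage Planted marker genes per terminal lineage.
#' @param embedding_dim Dimensionality of the ground-truth embedding.
#' @param lineage_separation Distance between committed-lineage
#'   trajectories and the root axis (default 15). Together with `noise_sd`
#'   this sets the separation-to-spread ratio of the latent states; the
#'   defaults emulate the post-integration regime in which distinct germ
#'   layers form discrete, non-overlapping clusters, so that planted
#'   lineage structure is unambiguous ground truth.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 2000,
                         n_cells_per_cluster = 200,
                         n_lineages = 4,
                         timepoints_h = c(0, 12, 24, 30, 36, 42, 44, 52, 60, 108),
                         effect_size = 1.5,
                         dispersion = 0.5,
                         noise_sd = 0.25,
                         seed = 1,
                         n_markers_per_lineage = 50,
                         embedding_dim = 10,
                         lineage_separation = 15) {
  stopifnot(n_genes >= 1, n_cells_per_cluster >= 1,
            n_lineages >= 1, n_lineages <= 6,
            length(timepoints_h) >= 1, !is.unsorted(timepoints_h),
            dispersion > 0, noise_sd >= 0, effect_size >= 0,
            embedding_dim >= n_lineages + 1, lineage_separation > 0)
  structure(list(n_genes = n_genes,
                 n_cells_per_cluster = n_cells_per_cluster,
                 n_lineages = n_lineages,
                 timepoints_h = timepoints_h,
                 effect_size = effect_size,
                 dispersion = dispersion,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_markers_per_lineage = n_markers_per_lineage,
                 embedding_dim = embedding_dim,
                 lineage_separation = lineage_separation),
            class = "synth_params")
}

terminal_lineage_names <- function(n) {
  if (n == 4) c("MeLC", "DELC", "PGCLC", "AmLC") else paste0("L", seq_len(n))
}

#' Planted lineage tree of the synthetic time course
#'
#' Nodes are (cluster, timepoint-index) pairs; directed edges connect each
#' cluster to its successor(s) at the next timepoint. For the default four
#' lineages the topology mirrors a gastrulation-like series: a pluripotent
#' root from which mesoderm-like and endoderm-like branches split first,
#' with amnion-like and PGC-like lineages splitting later from a shared
#' progenitor. Other lineage counts use sequential binary splits.
#'
#' @param params A [synth_params].
#' @return A list of class `lineage_tree`: `nodes` (data.frame `cluster`,
#'   `tp`), `edges` (data.frame `from_cluster`, `from_tp`, `to_cluster`,
#'   `to_tp`), `clusters_at` (list of cluster names per timepoint index),
#'   `lineages` (terminal lineage names), `cluster_lineages` (cluster ->
#'   compatible terminal lineages), `branch_times` (terminal lineage ->
#'   hour of divergence).
#' @export
lineage_tree <- function(params) {
  T <- length(params$timepoints_h)
  L <- params$n_lineages
  lin <- terminal_lineage_names(L)
  clusters_at <- vector("list", T)
  if (L == 1) {
    for (i in seq_len(T)) clusters_at[[i]] <- lin
    cl_lin <- stats::setNames(list(lin), lin)
    branch <- stats::setNames(params$timepoints_h[1], lin)
  } else if (L == 4 && T >= 5) {
    # gastrulation-like default: root -> {MeLC, DELC, AmPGC}; AmPGC -> {PGCLC, AmLC}
    s1 <- 3L; s2 <- 5L
    for (i in seq_len(T)) {
      clusters_at[[i]] <-
        if (i < s1) "Epi"
        else if (i < s2) c("MeLC", "DELC", "AmPGC")
        else c("MeLC", "DELC", "PGCLC", "AmLC")
    }
    cl_lin <- list(Epi = lin, AmPGC = c("PGCLC", "AmLC"),
                   MeLC = "MeLC", DELC = "DELC",
                   PGCLC = "PGCLC", AmLC = "AmLC")
    branch <- c(MeLC = params$timepoints_h[s1], DELC = params$timepoints_h[s1],
                PGCLC = params$timepoints_h[s2], AmLC = params$timepoints_h[s2])
  } else {
    # sequential binary splits: progenitor P_k peels off lineage k at
    # timepoint index 2k+1; the final split yields two terminal lineages
    n_splits <- L - 1
    split_tp <- pmin(2L + 2L * (seq_len(n_splits) - 1L) + 1L, T)
    if (any(duplicated(split_tp)))
      split_tp <- pmin(seq(3L, length.out = n_splits), T)
    if (anyDuplicated(split_tp))
      stop("too few timepoints for ", L, " sequential lineage splits")
    prog <- function(k) paste0("P", k)  # progenitor carrying lineages k..L
    cl_lin <- stats::setNames(lapply(seq_len(L), function(k) lin[k]), lin)
    for (k in seq_len(n_splits)) cl_lin[[prog(k)]] <- lin[k:L]
    branch <- stats::setNames(rep(NA_real_, L), lin)
    for (i in seq_len(T)) {
      done <- sum(split_tp <= i)        # completed splits
      cls <- lin[seq_len(min(done, L - 1))]
      if (done >= n_splits) cls <- c(cls, lin[L]) else cls <- c(cls, prog(done + 1))
      clusters_at[[i]] <- cls
    }
    for (k in seq_len(n_splits)) {
      branch[lin[k]] <- params$timepoints_h[split_tp[k]]
      if (k == n_splits) branch[lin[L]] <- params$timepoints_h[split_tp[k]]
    }
  }
  nodes <- do.call(rbind, lapply(seq_len(T), function(i)
    data.frame(cluster = clusters_at[[i]], tp = i, stringsAsFactors = FALSE)))
  edges <- NULL
  for (i in seq_len(T - 1)) {
    for (cl in clusters_at[[i]]) {
      kids <- if (cl %in% clusters_at[[i + 1]]) cl
              else clusters_at[[i + 1]][
                vapply(clusters_at[[i + 1]], function(k)
                  all(cl_lin[[k]] %in% cl_lin[[cl]]) &&
                    !(k %in% clusters_at[[i]]), logical(1))]
      if (length(kids))
        edges <- rbind(edges, data.frame(from_cluster = cl, from_tp = i,
                                         to_cluster = kids, to_tp = i + 1,
                                         stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = nodes, edges = edges, clusters_at = clusters_at,
                 lineages = lin, cluster_lineages = cl_lin,
                 branch_times = branch,
                 timepoints_h = params$timepoints_h),
            class = "lineage_tree")
}

# Ground-truth embedding centroid of a cluster at a given hour.
# Axis 1 carries time (2 units per 12 h); each terminal lineage owns one
# of axes 2..(L+1); committed clusters sit at full lineage_separation along
# their axis, progenitors at the normalised mean of their compatible
# lineage directions scaled to the same separation only after commitment
# (progenitors stay on the root axis).
cluster_centroid <- function(cluster, time_h, tree, params) {
  d <- params$embedding_dim
  v <- numeric(d)
  v[1] <- 2 * time_h / 12
  lins <- tree$cluster_lineages[[cluster]]
  if (length(lins) == 1) {
    ax <- 1 + match(lins, tree$lineages)
    v[ax] <- params$lineage_separation
  } else if (length(lins) < length(tree$lineages)) {
    # committed multi-potent progenitor (e.g. the amnion/PGC progenitor):
    # mean of its children's directions, renormalised to the same separation
    ax <- 1 + match(lins, tree$lineages)
    u <- numeric(d); u[ax] <- 1 / length(ax)
    v <- v + u / sqrt(sum(u^2)) * params$lineage_separation
  }
  v
}

# Ground-truth log-mean expression of each (cluster, tp): base rate plus a
# planted marker shift in committed clusters and a smooth temporal program.
synth_gene_model <- function(params, tree) {
  g <- params$n_genes
  L <- params$n_lineages
  nm <- params$n_markers_per_lineage
  need <- L * nm + min(100, max(0, g - L * nm))
  if (g < L * nm) stop("n_genes too small for the planted markers")
  base_rate <- stats::rgamma(g, shape = 0.5, scale = 3)
  base_rate <- pmax(base_rate, 1e-3)
  marker_of <- rep(NA_character_, g)
  idx <- sample.int(g, need)
  # markers are genes a lineage actually expresses: moderate baseline,
  # rarely near zero (the fold change would otherwise be unobservable)
  base_rate[idx[seq_len(L * nm)]] <- stats::rgamma(L * nm, shape = 2,
                                                   scale = 1.5)
  for (k in seq_len(L))
    marker_of[idx[((k - 1) * nm + 1):(k * nm)]] <- tree$lineages[k]
  time_genes <- if (need > L * nm) idx[(L * nm + 1):need] else integer(0)
  list(base_rate = base_rate, marker_of = marker_of, time_genes = time_genes)
}

cluster_log_mean <- function(cluster, time_h, model, tree, params) {
  lm <- log(model$base_rate)
  lins <- tree$cluster_lineages[[cluster]]
  if (length(lins) == 1) {
    sel <- !is.na(model$marker_of) & model$marker_of == lins
    lm[sel] <- lm[sel] + params$effect_size
  }
  tmax <- max(params$timepoints_h)
  if (tmax > 0 && length(model$time_genes))
    lm[model$time_genes] <- lm[model$time_genes] + 1.0 * time_h / tmax
  lm
}

#' Simulate a branching single-cell time course with planted truth
#'
#' Counts are negative binomial (`var = mu + dispersion * mu^2`) around
#' per-cluster mean trajectories: lineages share means before their branch
#' time and committed clusters carry an `effect_size` natural-log shift on
#' their planted marker genes afterwards. The ground-truth embedding is
#' generated directly in low dimension (cluster trajectory centroid plus
#' isotropic Gaussian jitter of sd `noise_sd`), so downstream geometry is
#' decoupled from preprocessing; an end-to-end counts -> PCA path is
#' exercised separately.
#'
#' @param params A [synth_params].
#' @return A list with elements `cells` ([cell_set] whose meta carries the
#'   true `cluster`, `lineage`, `time_h`, `tp` and `sample`), `emb` (the
#'   ground-truth [embedding], tag `"truth"`), `tree` (the planted
#'   [lineage_tree]) and `truth` (generator internals: per-node log-mean
#'   matrix `mean_log`, `centroids`, `marker_of`, `params`).
#' @export
simulate_timecourse <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  tree <- lineage_tree(params)
  model <- synth_gene_model(params, tree)
  T <- length(params$timepoints_h)
  nodes <- tree$nodes
  nc <- params$n_cells_per_cluster
  n_total <- nrow(nodes) * nc
  counts <- matrix(0L, n_total, params$n_genes)
  coords <- matrix(0, n_total, params$embedding_dim)
  meta <- vector("list", nrow(nodes))
  mean_log <- matrix(NA_real_, nrow(nodes), params$n_genes)
  centroids <- matrix(NA_real_, nrow(nodes), params$embedding_dim)
  rn <- paste0(nodes$cluster, "@t", nodes$tp)
  rownames(mean_log) <- rownames(centroids) <- rn
  size <- 1 / params$dispersion
  for (r in seq_len(nrow(nodes))) {
    cl <- nodes$cluster[r]; tp <- nodes$tp[r]
    th <- params$timepoints_h[tp]
    lm <- cluster_log_mean(cl, th, model, tree, params)
    mu <- exp(lm)
    mean_log[r, ] <- lm
    rows <- ((r - 1) * nc + 1):(r * nc)
    counts[rows, ] <- matrix(
      stats::rnbinom(nc * params$n_genes, mu = rep(mu, each = nc),
                     size = size), nc, params$n_genes)
    ctr <- cluster_centroid(cl, th, tree, params)
    centroids[r, ] <- ctr
    coords[rows, ] <- matrix(rep(ctr, each = nc), nc) +
      matrix(stats::rnorm(nc * params$embedding_dim, sd = params$noise_sd),
             nc)
    lins <- tree$cluster_lineages[[cl]]
    meta[[r]] <- data.frame(
      sample = rep(sprintf("t%03dh", th), nc),
      time_h = th, tp = tp, cluster = cl,
      lineage = if (length(lins) == 1) lins else cl,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  ids <- sprintf("cell_%05d", seq_len(n_total))
  cells <- cell_set(counts, ids, sprintf("gene_%04d", seq_len(params$n_genes)),
                    meta)
  emb <- embedding(coords, ids, "truth")
  list(cells = cells, emb = emb, tree = tree,
       truth = list(mean_log = mean_log, centroids = centroids,
                    marker_of = model$marker_of,
                    time_genes = model$time_genes, params = params))
}

#' Planted marker map of a synthetic time course
#'
#' Convenience accessor turning the generator's marker assignment into the
#' `markers` argument of [annotate_metaclusters()].
#'
#' @param sim Output of [simulate_timecourse()].
#' @return Named list: terminal lineage -> character vector of gene ids.
#' @export
planted_markers <- function(sim) {
  mo <- sim$truth$marker_of
  gi <- sim$cells$gene_ids
  lapply(stats::setNames(nm = sim$tree$lineages),
         function(l) gi[!is.na(mo) & mo == l])
}

#' Agreement between inferred lineage labels and the planted truth
#'
#' Fraction of cells whose inferred terminal-lineage label is compatible
#' with their planted cluster: committed cells must receive exactly their
#' lineage, progenitor cells any of their descendant lineages (a
#' progenitor has no single true terminal fate).
#'
#' @param cells The simulated [cell_set] (meta carries `cluster`).
#' @param tree The planted [lineage_tree].
#' @param cell_labels Named character vector (cell id -> lineage), e.g.
#'   from [annotate_metaclusters()].
#' @return Fraction in `[0, 1]`.
#' @export
lineage_agreement <- function(cells, tree, cell_labels) {
  labs <- cell_labels[cells$cell_ids]
  ok <- vapply(seq_along(labs), function(i)
    labs[i] %in% tree$cluster_lineages[[cells$meta$cluster[i]]], logical(1))
  mean(ok)
}

#' Simulate a 3D spatially resolved reference
#'
#' Reference cells are placed on an ellipsoid-like shell (semi-axes
#' 100 x 50 x 50 length units) whose first axis is the anterior-posterior
#' axis; each lineage occupies a contiguous slab along it, ordered by
#' lineage index. Each cell's expression embedding is drawn from its
#' lineage's distribution (lineage centroid plus `noise_sd` jitter) so the
#' reference shares embedding space with queries from [plant_query()].
#'
#' @param params A [synth_params]; `n_cells_per_cluster` cells are placed
#'   per lineage domain.
#' @return A [spatial_reference] whose `domain_centroids` are the analytic
#'   centroids of the per-lineage domain distributions (planted ground
#'   truth for recovery tests).
#' @export
simulate_spatial_reference <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  L <- params$n_lineages
  lin <- terminal_lineage_names(L)
  nc <- params$n_cells_per_cluster
  n <- L * nc
  axes <- c(100, 50, 50)
  labels <- rep(lin, each = nc)
  xu <- numeric(n)
  for (k in seq_len(L)) {
    lo <- -1 + 2 * (k - 1) / L
    hi <- -1 + 2 * k / L
    xu[((k - 1) * nc + 1):(k * nc)] <- stats::runif(nc, lo, hi)
  }
  phi <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(pmax(0, 1 - xu^2)) * (1 + stats::rnorm(n, sd = 0.02))
  pos <- cbind(x = axes[1] * xu,
               y = axes[2] * rad * cos(phi),
               z = axes[3] * rad * sin(phi))
  d <- params$embedding_dim
  coords <- matrix(stats::rnorm(n * d, sd = params$noise_sd), n, d)
  for (k in seq_len(L))
    coords[labels == lin[k], 1 + k] <-
      coords[labels == lin[k], 1 + k] + params$lineage_separation
  ids <- sprintf("ref_%05d", seq_len(n))
  emb <- embedding(coords, ids, "aligned")
  # analytic centroids of the generating slab distributions (the planted
  # ground truth, free of sampling noise)
  centroids <- cbind(x = axes[1] * (-1 + 2 * (seq_len(L) - 0.5) / L),
                     y = 0, z = 0)
  rownames(centroids) <- lin
  spatial_reference(pos, labels, emb, domain_centroids = centroids)
}

#' Plant query cells sharing the reference's embedding space
#'
#' Query cells are drawn from the same per-lineage embedding distributions
#' as the reference cells of [simulate_spatial_reference()], with their
#' true labels held out for benchmarking label transfer and spatial
#' projection. Counts are negative binomial around the lineage's
#' marker-shifted means. A distinct random stream (seed + 1) keeps query
#' draws independent of the reference's.
#'
#' @param params The same [synth_params] used for the reference.
#' @param reference The [spatial_reference] (used for lineage names and
#'   space tag).
#' @param n_per_lineage Query cells per lineage (default
#'   `n_cells_per_cluster`); may be 0 for empty output.
#' @param lineages Lineages to draw from (default: all reference lineages).
#' @return List: `cells` ([cell_set]), `emb` ([embedding]), `true_labels`
#'   (character vector).
#' @export
plant_query <- function(params, reference,
                        n_per_lineage = params$n_cells_per_cluster,
                        lineages = NULL) {
  stopifnot(inherits(params, "synth_params"),
            inherits(reference, "spatial_reference"))
  set.seed(params$seed + 1L)
  all_lin <- terminal_lineage_names(params$n_lineages)
  if (is.null(lineages)) lineages <- all_lin
  n <- length(lineages) * n_per_lineage
  d <- params$embedding_dim
  # marker model must match the reference's lineage identities; a fresh
  # tree only supplies cluster->lineage bookkeeping
  tree <- lineage_tree(params)
  set.seed(params$seed)  # reproduce the timecourse's gene model exactly
  model <- synth_gene_model(params, tree)
  set.seed(params$seed + 1L)
  if (n == 0) {
    cells <- cell_set(matrix(0L, 0, params$n_genes), character(0),
                      sprintf("gene_%04d", seq_len(params$n_genes)))
    return(list(cells = cells,
                emb = embedding(matrix(0, 0, d), character(0),
                                reference$embedding$space_tag),
                true_labels = character(0)))
  }
  labels <- rep(lineages, each = n_per_lineage)
  coords <- matrix(stats::rnorm(n * d, sd = params$noise_sd), n, d)
  size <- 1 / params$dispersion
  counts <- matrix(0L, n, params$n_genes)
  tmax <- max(params$timepoints_h)
  for (l in unique(labels)) {
    k <- match(l, all_lin)
    sel <- labels == l
    coords[sel, 1 + k] <- coords[sel, 1 + k] + params$lineage_separation
    lm <- cluster_log_mean(l, tmax, model, tree, params)
    counts[sel, ] <- matrix(
      stats::rnbinom(sum(sel) * params$n_genes,
                     mu = rep(exp(lm), each = sum(sel)), size = size),
      sum(sel), params$n_genes)
  }
  ids <- sprintf("query_%05d", seq_len(n))
  cells <- cell_set(counts, ids, sprintf("gene_%04d", seq_len(params$n_genes)),
                    data.frame(lineage = labels, stringsAsFactors = FALSE))
  list(cells = cells,
       emb = embedding(coords, ids, reference$embedding$space_tag),
       true_labels = labels)
}
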