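#' Parameters of the unbalanced entropic transport solver
#'
#' Defaults reproduce the lineage-tracing setting: source-marginal KL weight
#' `lambda1 = 1`, target-marginal KL weight `lambda2 = 50`, entropic
#' regularisation `epsilon = 0.01` (on the median-normalised squared
#' Euclidean cost). `lambda = Inf` on both sides gives exactly balanced
#' Sinkhorn.
#'
#' @param lambda1,lambda2 KL relaxation weights (> 0, possibly `Inf`) of the
#'   source and target marginal constraints.
#' @param epsilon Entropic regularisation (> 0).
#' @param max_iter Maximum Sinkhorn sweeps (default 5000).
#' @param tol Convergence tolerance: maximum change of the log-domain
#'   scalings between sweeps (default 1e-8).
#' @param cost_normalisation `"median"` (divide the cost matrix by its
#'   median, making `epsilon` scale-free) or `"none"`.
#' @return A validated list of class `ot_params`.
#' @export
ot_params <- function(lambda1 = 1, lambda2 = 50, epsilon = 0.01,
                      max_iter = 5000, tol = 1e-8,
                      cost_normalisation = c("median", "none")) {
  stopifnot(lambda1 > 0, lambda2 > 0, epsilon > 0, max_iter >= 1, tol > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, epsilon = epsilon,
                 max_iter = max_iter, tol = tol,
                 cost_normalisation = match.arg(cost_normalisation)),
            class = "ot_params")
}

#' Unbalanced entropic optimal transport between two cell sets
#'
#' Minimises `<C, gamma> - epsilon H(gamma) + lambda1 KL(gamma 1 || a) +
#' lambda2 KL(gamma' 1 || b)` by iterative proportional scaling with
#' KL-relaxed marginals (generalised Sinkhorn), run in stabilised form:
#' multiplicative scalings with periodic absorption into log-domain
#' potentials so that `epsilon = 0.01` stays numerically safe. The cost is
#' squared Euclidean distance in the shared embedding, divided by its
#' median by default.
#'
#' @param source,target [embedding]s (or bare coordinate matrices) of the
#'   cells at the earlier and later timepoint.
#' @param params An [ot_params].
#' @param a,b Marginal weight vectors (default uniform, summing to 1 — unit
#'   growth; supply per-cell weights to encode proliferation priors).
#' @param cost Optional precomputed cost matrix overriding the embedding
#'   distances (still subject to `cost_normalisation`).
#' @return List of class `transport_map`: `gamma` (n x m, >= 0),
#'   `source_marginal`, `target_marginal`, `a`, `b`, `converged`,
#'   `iterations`, `source_violation`, `target_violation`,
#'   `marginal_violation` (max of the two, L-infinity), `params`.
#' @export
compute_transport_map <- function(source, target, params = ot_params(),
                                  a = NULL, b = NULL, cost = NULL) {
  xs <- if (inherits(source, "embedding")) source$coords else as.matrix(source)
  xt <- if (inherits(target, "embedding")) target$coords else as.matrix(target)
  if (is.null(cost)) {
    if (ncol(xs) != ncol(xt)) stop("source and target dimensionality differ")
    if (nrow(xs) == 0 || nrow(xt) == 0) stop("empty source or target set")
    C <- sqdist(xs, xt)
  } else C <- as.matrix(cost)
  n <- nrow(C); m <- ncol(C)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  if (params$cost_normalisation == "median") {
    med <- stats::median(C)
    if (med > 0) C <- C / med
  }
  eps <- params$epsilon
  k1 <- if (is.infinite(params$lambda1)) 1 else
    params$lambda1 / (params$lambda1 + eps)
  k2 <- if (is.infinite(params$lambda2)) 1 else
    params$lambda2 / (params$lambda2 + eps)
  la <- log(a); lb <- log(b)

  f <- numeric(n); g <- numeric(m)
  # log-domain half-sweeps used at start and as overflow fallback
  log_f_update <- function(f, g) {
    k1 * (eps * la - eps * row_lse(sweep(-C, 2, g, "+") / eps))
  }
  log_g_update <- function(f, g) {
    k2 * (eps * lb - eps * row_lse(sweep(-t(C), 2, f, "+") / eps))
  }
  f <- log_f_update(f, g)
  g <- log_g_update(f, g)
  Kt <- exp((outer(f, g, "+") - C) / eps)
  u <- rep(1, n); v <- rep(1, m)
  converged <- FALSE
  it <- 0
  phi_prev <- f; psi_prev <- g
  absorb <- function() {
    f <<- f + eps * log(u); g <<- g + eps * log(v)
    Kt <<- exp((outer(f, g, "+") - C) / eps)
    u <<- rep(1, n); v <<- rep(1, m)
  }
  while (it < params$max_iter) {
    it <- it + 1
    Kv <- as.vector(Kt %*% v)
    un <- (a / Kv)^k1 * exp((k1 - 1) * f / eps)
    if (any(!is.finite(un)) || any(un <= 0)) {
      f <- log_f_update(f + eps * log(u), g + eps * log(v))
      g <- log_g_update(f, g + eps * log(v))
      Kt <- exp((outer(f, g, "+") - C) / eps)
      u <- rep(1, n); v <- rep(1, m)
    } else {
      u <- un
      Ktu <- as.vector(crossprod(Kt, u))
      vn <- (b / Ktu)^k2 * exp((k2 - 1) * g / eps)
      if (any(!is.finite(vn)) || any(vn <= 0)) {
        f <- log_f_update(f + eps * log(u), g)
        g <- log_g_update(f, g)
        Kt <- exp((outer(f, g, "+") - C) / eps)
        u <- rep(1, n); v <- rep(1, m)
      } else v <- vn
    }
    phi <- f + eps * log(u); psi <- g + eps * log(v)
    last_err <- max(max(abs(phi - phi_prev)), max(abs(psi - psi_prev)))
    phi_prev <- phi; psi_prev <- psi
    if (last_err < params$tol) { converged <- TRUE; break }
    if (max(abs(log(u)), abs(log(v))) > 50 || it %% 100 == 0) absorb()
  }
  absorb()
  gamma <- Kt
  sm <- rowSums(gamma); tm <- colSums(gamma)
  sv <- max(abs(sm - a)); tv <- max(abs(tm - b))
  if (!converged)
    warning("Sinkhorn did not reach tol = ", params$tol, " within ",
            params$max_iter, " sweeps (last change ",
            format(last_err, digits = 3), ")")
  structure(list(gamma = gamma, source_marginal = sm, target_marginal = tm,
                 a = a, b = b, converged = converged, iterations = it,
                 source_violation = sv, target_violation = tv,
                 marginal_violation = max(sv, tv), params = params),
            class = "transport_map")
}

#' @export
print.transport_map <- function(x, ...) {
  cat(sprintf("transport_map: %d x %d, %s after %d sweeps, marginal violation %.2e\n",
              nrow(x$gamma), ncol(x$gamma),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$marginal_violation))
  invisible(x)
}

#' Pipeline timepoints from sample annotations
#'
#' Encodes the collection-time convention of the differentiation series:
#' pluripotent stem cells (sample `"PSC"`) sit at 0 h, the pre-mesendoderm
#' induction (`"PreME"`) at 12 h, and every embryoid-body collection at
#' 12 h plus its collection time. With `absolute = TRUE` the metadata's
#' `time_h` is used unchanged.
#'
#' @param cells A [cell_set] whose meta has `sample` and (for EB samples)
#'   `time_h` columns.
#' @param absolute Treat `time_h` as already absolute (default `FALSE`).
#' @return List: `time_h` (per-cell pipeline hours), `timepoints` (strictly
#'   increasing unique values), `tp` (per-cell timepoint index).
#' @export
assign_times <- function(cells, absolute = FALSE) {
  meta <- cells$meta
  if (absolute) {
    t <- meta$time_h
    if (any(is.na(t))) stop("cells with no resolvable time (missing time_h)")
  } else {
    if (is.null(meta$sample)) stop("meta has no 'sample' column")
    t <- ifelse(meta$sample == "PSC", 0,
                ifelse(meta$sample == "PreME", 12, 12 + meta$time_h))
    bad <- is.na(t)
    if (any(bad))
      stop("cells with no resolvable time: ",
           paste(utils::head(cells$cell_ids[bad], 5), collapse = ", "))
  }
  tps <- sort(unique(t))
  list(time_h = t, timepoints = tps, tp = match(t, tps))
}

#' Ancestor mass of a target cell set at earlier timepoints
#'
#' Pulls the target set's mass back through a chain of consecutive
#' transport maps: each step distributes every target cell's mass over its
#' ancestors in proportion to the coupling (per-target normalisation), so
#' total mass is conserved exactly at every step. With the target equal to
#' all cells under a balanced map, the ancestor mass is the map's source
#' marginal.
#'
#' @param maps List of `transport_map`s for consecutive timepoint pairs,
#'   earliest first; `ncol(gamma)` of each must equal `nrow(gamma)` of the
#'   next (a mismatch is a chain gap).
#' @param target_set Logical vector or integer indices of the target cells
#'   at the final timepoint of the chain.
#' @param target_weights Optional mass per target cell (default uniform
#'   over the set, total 1).
#' @return List of numeric mass vectors, one per timepoint covered by the
#'   chain (earliest first; last entry is the target mass itself).
#' @export
ancestor_contributions <- function(maps, target_set, target_weights = NULL) {
  nmaps <- length(maps)
  if (nmaps == 0) stop("no transport maps given")
  for (i in seq_len(nmaps - 1))
    if (ncol(maps[[i]]$gamma) != nrow(maps[[i + 1]]$gamma))
      stop("chain gap between map ", i, " (", ncol(maps[[i]]$gamma),
           " target cells) and map ", i + 1, " (",
           nrow(maps[[i + 1]]$gamma), " source cells)")
  m_last <- ncol(maps[[nmaps]]$gamma)
  mass <- numeric(m_last)
  if (is.logical(target_set)) target_set <- which(target_set)
  if (is.null(target_weights)) {
    if (length(target_set))
      mass[target_set] <- 1 / length(target_set)
  } else mass[target_set] <- target_weights
  out <- vector("list", nmaps + 1)
  out[[nmaps + 1]] <- mass
  for (i in rev(seq_len(nmaps))) {
    gam <- maps[[i]]$gamma
    cs <- colSums(gam)
    scal <- ifelse(cs > 0, 1 / cs, 0)
    out[[i]] <- as.vector(gam %*% (scal * out[[i + 1]]))
  }
  out
}

#' Cluster-to-cluster contribution matrix across a time course
#'
#' Aggregates each consecutive transport map over cluster identities into a
#' (cluster, timepoint) x (cluster, timepoint) matrix with blocks only
#' between consecutive timepoints. Under the default `"ancestors"`
#' normalisation, entry ((c, i), (c', i+1)) is the fraction of cluster c''s
#' mass at timepoint i+1 drawn from cluster c at timepoint i (each target
#' node's incoming entries sum to 1) — the ancestor-contribution reading
#' under which a cluster with a single true parent scores ~1.
#' `"descendants"` instead row-normalises each source cluster's outgoing
#' mass (outgoing entries sum to 1).
#'
#' @param maps List of consecutive `transport_map`s, earliest first.
#' @param clusters List (one element per timepoint, length `length(maps)+1`)
#'   of per-cell cluster labels, ordered as the rows/columns of the maps.
#' @param normalize `"ancestors"` (default) or `"descendants"`.
#' @return List of class `lineage_graph`: `nodes` (data.frame `name`,
#'   `cluster`, `tp`), `A` (contribution matrix), `normalize`; `A_sparse`,
#'   `edges`, `communities`, `annotations` empty until the later stages.
#' @export
contribution_matrix <- function(maps, clusters,
                                normalize = c("ancestors", "descendants")) {
  normalize <- match.arg(normalize)
  T <- length(maps) + 1
  if (length(clusters) != T)
    stop("clusters must have one element per timepoint (", T, ")")
  for (i in seq_len(T - 1)) {
    if (nrow(maps[[i]]$gamma) != length(clusters[[i]]) ||
        ncol(maps[[i]]$gamma) != length(clusters[[i + 1]]))
      stop("map ", i, " dimensions do not match the cluster vectors")
    if (anyNA(clusters[[i]])) stop("every cell must be clustered")
  }
  node_names <- unlist(lapply(seq_len(T), function(i)
    paste0(unique(clusters[[i]]), "@t", i)))
  nodes <- data.frame(
    name = node_names,
    cluster = sub("@t[0-9]+$", "", node_names),
    tp = as.integer(sub("^.*@t", "", node_names)),
    stringsAsFactors = FALSE)
  A <- matrix(0, nrow(nodes), nrow(nodes),
              dimnames = list(node_names, node_names))
  for (i in seq_len(T - 1)) {
    gam <- maps[[i]]$gamma
    M <- rowsum(t(rowsum(gam, clusters[[i]])), clusters[[i + 1]])
    M <- t(M)  # source clusters x target clusters
    blk <- if (normalize == "ancestors") {
      cs <- colSums(M)
      sweep(M, 2, ifelse(cs > 0, cs, 1), "/")
    } else {
      rs <- rowSums(M)
      sweep(M, 1, ifelse(rs > 0, rs, 1), "/")
    }
    A[paste0(rownames(blk), "@t", i), paste0(colnames(blk), "@t", i + 1)] <- blk
  }
  structure(list(nodes = nodes, A = A, A_sparse = NULL, edges = NULL,
                 communities = NULL, annotations = NULL,
                 normalize = normalize),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("lineage_graph: %d nodes (%d timepoints)%s%s\n",
              nrow(x$nodes), max(x$nodes$tp),
              if (!is.null(x$edges)) sprintf(", %d edges", nrow(x$edges)) else "",
              if (!is.null(x$communities))
                sprintf(", %d meta-clusters", length(unique(x$communities)))
              else ""))
  invisible(x)
}

#' Power-threshold sparsification of a contribution matrix
#'
#' Raises every entry to the power `P` and censors values `<= censor` to 0
#' (mode `"powered"`, the default), which keeps only near-certain
#' contributions: 0.95^30 ~ 0.21 survives the 0.1 censor while 0.90^30 ~
#' 0.042 does not. Mode `"masked"` uses the powered matrix only as a
#' sparsity mask and keeps the original values as weights.
#'
#' @param A Contribution matrix (entries in `[0, 1]`) or a `lineage_graph`.
#' @param P Power threshold (default 30).
#' @param censor Censoring level on the powered values (default 0.1).
#' @param mode `"powered"` or `"masked"`.
#' @return Same type as `A`: the sparsified matrix, or the graph with
#'   `A_sparse` filled.
#' @export
sparsify <- function(A, P = 30, censor = 0.1,
                     mode = c("powered", "masked")) {
  mode <- match.arg(mode)
  if (inherits(A, "lineage_graph")) {
    A$A_sparse <- sparsify(A$A, P = P, censor = censor, mode = mode)
    return(A)
  }
  Ap <- A^P
  out <- if (mode == "powered") Ap else A
  out[Ap <= censor] <- 0
  out
}

#' Directed KNN lineage graph from a sparsified contribution matrix
#'
#' Keeps, for every node, its `k_graph` highest-weight outgoing entries
#' (fewer if fewer are nonzero); ties broken deterministically by target
#' node order.
#'
#' @param A_sparse Sparsified matrix with node dimnames, or a
#'   `lineage_graph` with `A_sparse` filled.
#' @param k_graph Outgoing neighbours per node (default 5).
#' @return For a matrix: `data.frame` `from`, `to`, `weight`. For a graph:
#'   the graph with `edges` filled.
#' @export
build_lineage_graph <- function(A_sparse, k_graph = 5) {
  if (inherits(A_sparse, "lineage_graph")) {
    g <- A_sparse
    if (is.null(g$A_sparse)) stop("sparsify the graph first")
    g$edges <- build_lineage_graph(g$A_sparse, k_graph)
    return(g)
  }
  stopifnot(all(A_sparse >= 0))
  nms <- rownames(A_sparse)
  if (is.null(nms)) nms <- as.character(seq_len(nrow(A_sparse)))
  rows <- lapply(seq_len(nrow(A_sparse)), function(i) {
    w <- A_sparse[i, ]
    nz <- which(w > 0)
    if (!length(nz)) return(NULL)
    keep <- nz[order(-w[nz], nz)][seq_len(min(k_graph, length(nz)))]
    data.frame(from = nms[i], to = colnames(A_sparse)[keep],
               weight = w[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  rownames(out) <- NULL
  out
}

#' Random-walk meta-clusters on the lineage graph
#'
#' Walktrap (Pons-Latapy) community detection with walk length `steps`
#' (default 4). The directed edge list is symmetrised by summing weights —
#' the random-walk agglomeration is defined on undirected graphs — and
#' isolated nodes form singleton communities.
#'
#' @param graph A `lineage_graph` with `edges` filled.
#' @param steps Walk length (default 4).
#' @return The graph with `communities` filled (named integer vector,
#'   node -> meta-cluster id).
#' @export
detect_communities <- function(graph, steps = 4) {
  stopifnot(inherits(graph, "lineage_graph"))
  if (is.null(graph$edges)) stop("build the lineage graph first")
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = graph$nodes$name)
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum"))
  memb <- rep(NA_integer_, igraph::vcount(gu))
  names(memb) <- igraph::V(gu)$name
  deg <- igraph::degree(gu)
  conn <- names(deg)[deg > 0]
  if (length(conn)) {
    sub <- igraph::induced_subgraph(gu, conn)
    wt <- igraph::cluster_walktrap(sub, weights = igraph::E(sub)$weight,
                                   steps = steps)
    memb[igraph::V(sub)$name] <- igraph::membership(wt)
  }
  iso <- which(is.na(memb))
  if (length(iso))
    memb[iso] <- max(0L, memb, na.rm = TRUE) + seq_along(iso)
  graph$communities <- memb[graph$nodes$name]
  graph
}

#' Annotate meta-clusters by marker expression and map back to cells
#'
#' Labels every meta-cluster with the lineage whose marker genes have the
#' highest mean logCP10k expression over the constituent single cells of
#' its (cluster, timepoint) nodes, then propagates the labels back onto the
#' cells via their cluster identity. Exact ties are labelled `"UNRESOLVED"`
#' with both candidates reported.
#'
#' @param cells A [cell_set] whose meta has `cluster` and `tp` columns
#'   matching the graph's nodes.
#' @param graph A `lineage_graph` with `communities` filled.
#' @param markers Named list: lineage -> character vector of marker gene
#'   ids.
#' @param norm Optional precomputed `normalized_matrix` for `cells`.
#' @return List: `graph` (with `annotations`: data.frame `community`,
#'   `label`, `margin`, `candidates`), `cell_labels` (named character,
#'   cell id -> lineage), `scores` (community x lineage mean-expression
#'   matrix).
#' @export
annotate_metaclusters <- function(cells, graph, markers, norm = NULL) {
  stopifnot(inherits(graph, "lineage_graph"))
  if (is.null(graph$communities)) stop("detect communities first")
  if (!length(markers)) stop("marker map is empty")
  if (is.null(norm)) norm <- normalize_logcp10k(cells)
  node_of_cell <- paste0(cells$meta$cluster, "@t", cells$meta$tp)
  comms <- sort(unique(graph$communities))
  lins <- names(markers)
  gidx <- lapply(markers, function(gs) {
    i <- match(gs, cells$gene_ids)
    if (anyNA(i)) stop("marker genes missing from the cell set")
    i
  })
  scores <- matrix(NA_real_, length(comms), length(lins),
                   dimnames = list(as.character(comms), lins))
  ann <- data.frame(community = comms, label = NA_character_,
                    margin = NA_real_, candidates = NA_character_,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(comms)) {
    nodes <- graph$nodes$name[graph$communities == comms[ci]]
    rows <- which(node_of_cell %in% nodes)
    if (!length(rows)) stop("meta-cluster ", comms[ci],
                            " has no constituent cells")
    for (li in seq_along(lins)) {
      sub <- norm$values[rows, gidx[[li]], drop = FALSE]
      scores[ci, li] <- sum(sub) / (nrow(sub) * ncol(sub))
    }
    s <- scores[ci, ]
    top <- which(s == max(s))
    if (length(top) > 1) {
      ann$label[ci] <- "UNRESOLVED"
      ann$candidates[ci] <- paste(lins[top], collapse = ";")
      ann$margin[ci] <- 0
    } else {
      ann$label[ci] <- lins[top]
      ann$margin[ci] <- max(s) - max(s[-top])
    }
  }
  graph$annotations <- ann
  node_comm <- graph$communities
  cell_comm <- node_comm[node_of_cell]
  cell_labels <- ann$label[match(cell_comm, ann$community)]
  names(cell_labels) <- cells$cell_ids
  list(graph = graph, cell_labels = cell_labels, scores = scores)
}

#' Full OT lineage reconstruction over a time course
#'
#' Runs the whole chain: consecutive transport maps in the shared
#' embedding, cluster contribution matrix, power-threshold sparsification,
#' directed KNN lineage graph and Walktrap meta-clusters.
#'
#' @param emb An [embedding] of all cells.
#' @param time_h Per-cell time in hours (same order as the embedding).
#' @param clusters Per-cell cluster labels.
#' @param params An [ot_params].
#' @param P,censor,mode Sparsification settings (see [sparsify()]).
#' @param k_graph Outgoing edges per node (default 5).
#' @param normalize Contribution normalisation (see [contribution_matrix()]).
#' @return List: `maps` (per consecutive pair), `graph` (a `lineage_graph`
#'   with communities), `timepoints`, `cell_tp` (per-cell timepoint index),
#'   `cell_order` (list of per-timepoint cell indices, the row order of the
#'   maps).
#' @export
fit_lineage_ot <- function(emb, time_h, clusters, params = ot_params(),
                           P = 30, censor = 0.1, mode = "powered",
                           k_graph = 5, normalize = "ancestors") {
  stopifnot(length(time_h) == nrow(emb$coords),
            length(clusters) == nrow(emb$coords))
  tps <- sort(unique(time_h))
  if (length(tps) < 2) stop("need at least two timepoints")
  idx <- lapply(tps, function(t) which(time_h == t))
  maps <- vector("list", length(tps) - 1)
  for (i in seq_len(length(tps) - 1)) {
    maps[[i]] <- compute_transport_map(
      emb$coords[idx[[i]], , drop = FALSE],
      emb$coords[idx[[i + 1]], , drop = FALSE], params)
  }
  cl <- lapply(idx, function(j) as.character(clusters[j]))
  graph <- contribution_matrix(maps, cl, normalize = normalize)
  graph <- sparsify(graph, P = P, censor = censor, mode = mode)
  graph <- build_lineage_graph(graph, k_graph = k_graph)
  graph <- detect_communities(graph)
  list(maps = maps, graph = graph, timepoints = tps,
       cell_tp = match(time_h, tps), cell_order = idx)
}

#' Plumbing: modularity clustering of an embedding
#'
#' Louvain modularity clustering on the symmetrised KNN graph of the
#' embedding — a plain substitute for upstream graph clustering when no
#' cluster labels are supplied. Not a method of interest here; provided so
#' the lineage pipeline can run end to end from an embedding alone.
#'
#' @param emb An [embedding].
#' @param k Neighbours of the KNN graph (default 15).
#' @return Character vector of cluster labels, one per cell.
#' @export
cluster_cells <- function(emb, k = 15) {
  nn <- knn_index(emb$coords, emb$coords, k, exclude_self = TRUE)
  el <- cbind(rep(seq_len(nrow(nn)), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- igraph::membership(igraph::cluster_louvain(g))
  paste0("c", as.integer(memb))
}
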