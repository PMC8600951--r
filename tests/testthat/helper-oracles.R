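# Independent brute-force oracles and small fixture builders.  These
# deliberately avoid the package's vectorized code paths: plain loops,
# adjacency-list BFS, and formula-by-formula statistics.

# Pooled-variance two-sample t, straight from the textbook formula.
naive_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Connected components of an edge list by BFS over adjacency lists;
# returns the edge count of every component.
naive_component_sizes <- function(edges, n_nodes) {
  if (nrow(edges) == 0L) return(integer(0))
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n_nodes)
  cid <- 0L
  for (v in seq_len(n_nodes)) {
    if (!is.na(comp[v]) || is.null(adj[[v]])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  tabulate(comp[edges[, 1]], cid)
}

naive_max_extent <- function(edges, n_nodes) {
  sizes <- naive_component_sizes(edges, n_nodes)
  if (length(sizes) == 0L) 0L else max(sizes)
}

# Exhaustive NBS p-value: every assignment of nA subjects to group A,
# naive t per edge, strict threshold, BFS components.
naive_exhaustive_nbs <- function(groupA, groupB, tail, thr) {
  all_mats <- c(groupA, groupB)
  nA <- length(groupA)
  n <- length(all_mats)
  n_nodes <- nrow(all_mats[[1]])
  sgn <- if (tail == "A_less_B") -1 else 1
  extent_for <- function(idxA) {
    edges <- NULL
    for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
      wij <- vapply(all_mats, function(m) m[i, j], numeric(1))
      if (all(wij == 0)) next
      a <- wij[idxA]; b <- wij[-idxA]
      tv <- naive_t(a, b)
      if (!is.finite(tv)) tv <- 0
      if (sgn * tv > thr) edges <- rbind(edges, c(i, j))
    }
    if (is.null(edges)) 0L else naive_max_extent(edges, n_nodes)
  }
  sets <- combn(n, nA)
  extents <- apply(sets, 2L, extent_for)
  obs <- extent_for(seq_len(nA))
  list(extent = obs, p = mean(extents >= obs), null = extents)
}

# Step-up BH adjustment written as the literal definition.
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(p[ord[k]] * m / k, prev)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}

# --- fixtures -------------------------------------------------------

# A conn_matrix on n nodes with every off-diagonal edge present.
full_matrix <- function(values, n, id = "s1", modality = "FA") {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  conn_matrix(m + t(m), id, modality)
}

# Small dense group: baseline upper-tri weights plus N(0, sd) noise.
tiny_group <- function(n_subj, n_nodes = 6, base = NULL, sd = 0.05,
                       prefix = "s", seed = 1) {
  ne <- n_nodes * (n_nodes - 1) / 2
  base <- base %||% seq(0.3, 0.7, length.out = ne)
  withr::with_seed(seed, lapply(seq_len(n_subj), function(k)
    full_matrix(pmin(pmax(base + rnorm(ne, 0, sd), 0.01), 0.99), n_nodes,
                paste0(prefix, k))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Four-region toy atlas: pairs (1,2) and (3,4), one lobe.
toy_atlas4 <- function() {
  as_conn_atlas(data.frame(
    roi = c("A_L", "A_R", "B_L", "B_R"),
    hemisphere = c("left", "right", "left", "right"),
    homologue = c("A_R", "A_L", "B_R", "B_L"),
    lobe = "temporal"), strict = FALSE)
}

# Shared small synthetic world for the heavier module tests.
small_world <- function(seed = 42, n_controls = 12) {
  cfg <- generator_config(n_controls = n_controls, n_patients_localized = 8,
                          n_patients_widespread = 10, seed = seed)
  atlas <- aal90_atlas()
  scaffold <- make_scaffold(cfg, atlas)
  params <- netabnorm:::control_params(cfg, scaffold)
  list(cfg = cfg, atlas = atlas, scaffold = scaffold, params = params)
}
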