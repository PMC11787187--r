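# region names used to label synthetic nodes so that seeding conventions
# ("posterior_cingulate", "entorhinal", ...) map onto fixtures
region_names <- function(V) {
  base <- c("posterior_cingulate", "entorhinal", "precuneus", "hippocampus",
            "superior_frontal", "inferior_parietal", "lateral_occipital",
            "middle_temporal", "fusiform", "supramarginal", "insula",
            "caudal_anterior_cingulate", "lingual", "pericalcarine",
            "postcentral", "precentral", "superior_parietal",
            "superior_temporal", "rostral_middle_frontal", "cuneus")
  if (V <= length(base)) return(base[seq_len(V)])
  c(base, paste0("region_", seq.int(length(base) + 1L, V)))
}

#' Generate a synthetic small-world weighted connectome
#'
#' Emulates the topology class of tractography-derived brain networks: a
#' Watts-Strogatz small-world graph (high clustering, short characteristic
#' path length) with heavy-tailed positive edge weights drawn from a
#' log-normal distribution, plus one weakly attached peripheral node
#' (`"frontal_pole"`) so the network has an identifiable lowest-connectivity
#' region. Nodes carry anatomical-style labels; the generation is fully
#' deterministic given `rng_seed`. This is a synthetic stand-in — no
#' tractography data are used.
#'
#' @param V number of core nodes (>= 4), excluding the peripheral node.
#' @param mean_degree target mean degree of the ring lattice (even).
#' @param rewire_p Watts-Strogatz rewiring probability in `[0, 1]`.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters.
#' @param peripheral attach the weakly connected `"frontal_pole"` node.
#' @param rng_seed integer RNG seed; equal seeds give identical graphs.
#' @param max_attempts redraws allowed when a draw is disconnected.
#' @return A `connectome` (see [build_laplacian()]).
#' @export
generate_connectome <- function(V = 40, mean_degree = 6, rewire_p = 0.1,
                                weight_meanlog = 0, weight_sdlog = 0.75,
                                peripheral = TRUE, rng_seed = 1,
                                max_attempts = 25) {
  if (V < 4) stop("V must be >= 4", call. = FALSE)
  if (rewire_p < 0 || rewire_p > 1)
    stop("rewiring probability must lie in [0, 1]", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  g <- NULL
  for (k in seq_len(max_attempts)) {
    cand <- igraph::sample_smallworld(1, V, max(1L, round(mean_degree / 2)),
                                      rewire_p, loops = FALSE,
                                      multiple = FALSE)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g))
    stop("failed to draw a connected small-world graph in ", max_attempts,
         " attempts", call. = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  nE <- sum(A) / 2
  w <- stats::rlnorm(nE, weight_meanlog, weight_sdlog)
  ut <- upper.tri(A) & A > 0
  W <- matrix(0, V, V)
  W[ut] <- w
  W <- W + t(W)
  labels <- region_names(V)
  if (peripheral) {
    W <- rbind(cbind(W, 0), 0)
    # single weak edge to the last core node
    wmin <- min(W[W > 0]) * 1e-4
    W[V + 1L, V] <- W[V, V + 1L] <- wmin
    labels <- c(labels, "frontal_pole")
  }
  build_laplacian(W, labels = labels)
}

#' Read / write a connectome as a CSV edge list
#'
#' The edge list has header `source_label,target_label,weight`, one row per
#' undirected edge. Duplicate edges (in either orientation) and self edges
#' are rejected with the offending line numbers.
#'
#' @param path file path.
#' @return `read_edgelist()` returns a `connectome`;
#'   `write_edgelist()` returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_label", "target_label", "weight")
  if (!identical(names(df)[seq_len(3L)], need))
    stop("edge list must have header source_label,target_label,weight",
         call. = FALSE)
  bad <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad))
    stop("non-positive or missing weight on line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  self <- which(df$source_label == df$target_label)
  if (length(self))
    stop("self edge(s) on line(s) ", paste(self + 1L, collapse = ", "),
         call. = FALSE)
  key <- paste(pmin(df$source_label, df$target_label),
               pmax(df$source_label, df$target_label))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate edge(s) on line(s) ", paste(dup + 1L, collapse = ", "),
         call. = FALSE)
  labels <- sort(unique(c(df$source_label, df$target_label)))
  V <- length(labels)
  A <- matrix(0, V, V, dimnames = list(labels, labels))
  for (r in seq_len(nrow(df))) {
    i <- df$source_label[r]; j <- df$target_label[r]
    A[i, j] <- A[j, i] <- df$weight[r]
  }
  build_laplacian(A, labels = labels)
}

#' @rdname read_edgelist
#' @param connectome a `connectome` object.
#' @export
write_edgelist <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  A <- connectome$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(source_label = connectome$labels[idx[, 1L]],
                   target_label = connectome$labels[idx[, 2L]],
                   weight = A[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a connectome in GraphML
#'
#' @inheritParams read_edgelist
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  build_laplacian(A, labels = igraph::V(g)$name)
}

#' @rdname read_graphml
#' @param connectome a `connectome` object.
#' @export
write_graphml <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  g <- igraph::graph_from_adjacency_matrix(connectome$adjacency,
                                           mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- connectome$labels
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Bundled study fixtures
#'
#' Named, fully specified simulation set-ups used throughout the package's
#' examples and end-to-end tests. Each returns a configuration list
#' runnable with [run_simulation()], encoding the reference Abeta42
#' parameters (micromolar-hour units) together with the scenario's
#' clearance/damage/dosing settings; scenarios needing a connectome use the
#' synthetic small-world generator.
#'
#' * `"local_subcritical"`: single region, constant clearance
#'   `lambda = 10` (far below critical), dimer seed `p_2(0) = 1e-4 m_0`,
#'   no primary nucleation — growth to a toxic peak, relaxation to the
#'   aggregated equilibrium.
#' * `"damage_regimes"`: clearance degradation with `beta = 1e11`,
#'   basal capacity below critical — sigmoidal invasion as clearance decays.
#' * `"network_invasion"`: synthetic connectome, uniform subcritical
#'   clearance `lambda = 10`, `rho = 0.01`, mass seed `M(0) = m_0` in the
#'   posterior cingulate.
#' * `"window_sweep"`: size-windowed clearance `lambda_a = 10`,
#'   `lambda_drug = 1e5`, windows of width 10 at increasing `n0`.
#' * `"dosing_budget"`: regimen optimization with `lambda_a = 10`, `A = 1`,
#'   `t_max = 28`, budgets `C_max` in 100, 200, 400, 800, 1600.
#'
#' @param name fixture name.
#' @return A configuration list (fields depend on the scenario).
#' @export
make_fixture <- function(name = c("local_subcritical", "damage_regimes",
                                  "network_invasion", "window_sweep",
                                  "dosing_budget")) {
  name <- match.arg(name)
  base <- list(parameters = list(k_n = 1.6e-5, k_plus = 1e4, k_2 = 210,
                                 K_m = 2.3e-5, m_0 = 3, conc_scale = 1e6))
  switch(name,
    local_subcritical = c(base, list(
      model = "invivo", name = name,
      clearance = list(variant = "constant", lambda = 10),
      seed_dimer = 1e-4, include_kn = FALSE, moments = TRUE, t_end = 2)),
    damage_regimes = c(base, list(
      model = "damage", name = name,
      damage = list(beta = 1e11, mu = 10, lambda_init = 2e4),
      seed_dimer = 1e-4, include_kn = TRUE, moments = TRUE, t_end = 2)),
    network_invasion = c(base, list(
      model = "network", name = name,
      clearance = list(variant = "constant", lambda = 10),
      graph = list(V = 20, mean_degree = 6, rewire_p = 0.1, rng_seed = 42),
      rho = 0.01, diffusion_mode = "constant", moments = TRUE,
      seed_node = "posterior_cingulate", seed_type = "mass",
      t_end = 0.02)),
    window_sweep = c(base, list(
      model = "invivo", name = name,
      clearance = list(variant = "windowed", lambda_a = 10,
                       lambda_drug = 1e5, n0 = 5, n1 = 15),
      window_starts = c(3, 5, 10, 15, 20), window_width = 10,
      seed_dimer = 1e-4, include_kn = FALSE, moments = FALSE,
      N = 300, t_end = 1)),
    dosing_budget = c(base, list(
      model = "therapy", name = name,
      dosing = list(lambda_a = 10, A = 1, t_max = 28,
                    C_max = c(100, 200, 400, 800, 1600)))))
}
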