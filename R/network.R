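#' Build a connectome object from a weighted adjacency matrix
#'
#' Validates the adjacency (square, symmetric, non-negative weights, zero
#' diagonal) and derives the unnormalized graph Laplacian
#' `L_ij = -A_ij` off-diagonal with diagonal entries equal to the row sums
#' of `A` — the only graph Laplacian that conserves mass during transport
#' and produces no flux between regions at equal concentration.
#'
#' @param adjacency square numeric matrix of non-negative edge weights;
#'   symmetry is required within `1e-12` (relative to the largest weight).
#' @param labels node labels; defaults to the adjacency's row names or
#'   `node_1..node_V`.
#' @return An object of class `connectome`: `labels`, `adjacency`,
#'   `laplacian`, `V`.
#' @export
#' @examples
#' cn <- build_laplacian(matrix(c(0, 2, 2, 0), 2, 2))
#' rowSums(cn$laplacian)  # exactly zero
build_laplacian <- function(adjacency, labels = NULL) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  scale <- max(abs(A), 1e-300)
  asym <- abs(A - t(A)) > 1e-12 * scale
  if (any(asym)) {
    idx <- which(asym, arr.ind = TRUE)[1L, ]
    stop(sprintf("adjacency not symmetric at (%d, %d)", idx[1L], idx[2L]),
         call. = FALSE)
  }
  if (any(A < 0)) {
    idx <- which(A < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative weight at (%d, %d)", idx[1L], idx[2L]),
         call. = FALSE)
  }
  if (any(diag(A) != 0))
    stop("adjacency diagonal must be zero (no self edges)", call. = FALSE)
  A <- (A + t(A)) / 2                     # exact symmetry
  if (is.null(labels))
    labels <- if (!is.null(rownames(A))) rownames(A)
      else paste0("node_", seq_len(nrow(A)))
  dimnames(A) <- list(labels, labels)
  L <- -A
  diag(L) <- rowSums(A)
  structure(list(labels = labels, adjacency = A, laplacian = L,
                 V = nrow(A)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome: %d nodes, %d edges, total weight %g\n", x$V,
              sum(x$adjacency > 0) / 2, sum(x$adjacency) / 2))
  invisible(x)
}

#' Size-dependent diffusion profile
#'
#' Diffusion coefficients by aggregate size. Large assemblies barely move:
#' in the size-dependent mode the coefficient of an `i`-mer scales as the
#' reciprocal of the cube of its molecular weight, `rho_i = rho_0 / i^3`.
#'
#' @param rho0 monomer-scale diffusion coefficient (>= 0).
#' @param mode `"constant"` (`rho_i = rho0`) or `"inverse_cube"`.
#' @param N largest size.
#' @return Numeric vector of coefficients for sizes `1..N`.
#' @export
diffusion_profile <- function(rho0, mode = c("constant", "inverse_cube"),
                              N) {
  mode <- match.arg(mode)
  if (rho0 < 0) stop("`rho0` must be non-negative", call. = FALSE)
  i <- seq_len(N)
  switch(mode, constant = rep(rho0, N), inverse_cube = rho0 / i^3)
}

#' Simulate aggregation with transport on a connectome
#'
#' Couples the single-region in vivo dynamics at every node to diffusive
#' transport along weighted edges through the graph Laplacian: aggregates of
#' size `i` at node `j` obey
#' \deqn{dp_{i,j}/dt = -\rho_i \sum_k L_{jk} p_{i,k} - \lambda_{i,j} p_{i,j}
#'   + \mathrm{(local\ kinetics)},}
#' and monomers move by diffusion only, so a uniform monomer field stays
#' uniform and constant. Transport conserves each size class summed over
#' nodes; mass changes only through reaction and clearance.
#'
#' @inheritParams simulate_invivo
#' @param connectome a [build_laplacian()] / [generate_connectome()] object.
#' @param clearance a single [clearance_spec()] applied at every node, or a
#'   list of specs, one per node.
#' @param rho diffusion coefficients for sizes `1..N` (see
#'   [diffusion_profile()]); a scalar is recycled.
#' @param seed_node label (or index) of the seeded node; `NULL` seeds every
#'   node identically (homogeneous initial condition).
#' @param seed_value seed concentration (default `m_0`).
#' @param seed_type `"mass"` (`M(0) = seed_value`, deposited as dimers
#'   `p_2 = seed_value/2`) or `"dimer"` (`p_2(0) = seed_value`).
#' @param m_init initial monomer concentration per node (scalar recycled);
#'   non-uniform values are permitted but leave the constant-monomer
#'   modelling regime.
#' @param N truncation size shared by all nodes.
#' @return An object of class `network_trajectory`: `time`, matrices `m`,
#'   `P`, `M` (time x node), array `p` (time x size x node) and `meta`.
#' @export
simulate_network <- function(connectome, params, clearance, rho,
                             seed_node, seed_value = params$m_0,
                             seed_type = c("mass", "dimer"),
                             t_end = 1, N = 50, include_kn = FALSE,
                             m_init = params$m_0, times = NULL,
                             n_out = 201, rtol = 1e-8,
                             atol = 1e-12 * params$m_0) {
  stopifnot(inherits(connectome, "connectome"))
  seed_type <- match.arg(seed_type)
  V <- connectome$V
  L <- connectome$laplacian
  if (length(rho) == 1L) rho <- rep(rho, N)
  if (length(rho) != N)
    stop("`rho` must have length N (sizes 1..N) or 1", call. = FALSE)
  if (any(rho < 0)) stop("`rho` must be non-negative", call. = FALSE)
  specs <- if (inherits(clearance, "clearance_spec"))
    rep(list(clearance), V) else clearance
  if (length(specs) != V)
    stop("`clearance` must be one spec or a list of one per node",
         call. = FALSE)
  lam <- vapply(specs, clearance_vector, numeric(N - 1L), N = N)  # (N-1) x V
  sizes <- seq(2L, N)
  m0vec <- rep_len(m_init, V)
  p0 <- matrix(0, N - 1L, V)
  if (is.null(seed_node)) {
    p0[1L, ] <- if (seed_type == "mass") seed_value / 2 else seed_value
  } else {
    j <- if (is.character(seed_node)) match(seed_node, connectome$labels)
      else as.integer(seed_node)
    if (is.na(j) || j < 1L || j > V)
      stop("seed node '", seed_node, "' not found in the connectome",
           call. = FALSE)
    p0[1L, j] <- if (seed_type == "mass") seed_value / 2 else seed_value
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  kn <- if (include_kn) params$k_n else 0
  f_el <- 2 * params$k_plus
  rho_sz <- rho[sizes]
  deriv <- function(t, y, parms) {
    m <- y[seq_len(V)]
    p <- matrix(y[-seq_len(V)], N - 1L, V)
    M <- as.numeric(crossprod(p, sizes))            # per node
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m^2 * M              # per node
    f <- f_el * p * rep(m, each = N - 1L)           # elongation flux
    f[N - 1L, ] <- 0                                # reflecting boundary
    inflow <- rbind(0, f[-(N - 1L), , drop = FALSE])
    src <- matrix(0, N - 1L, V)
    src[1L, ] <- kn * m^2 + nuc2
    transport <- -(p %*% L) * rho_sz
    dp <- transport - lam * p + src + inflow - f
    dm <- -rho[1L] * as.numeric(L %*% m)
    list(c(dm, as.vector(dp)))
  }
  sol <- deSolve::ode(y = c(m0vec, as.vector(p0)), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  tgrid <- sol[, 1L]
  y <- sol[, -1L, drop = FALSE]
  if (any(y < -1e-4 * params$m_0))
    stop("integration produced concentrations below -1e-4 * m_0",
         call. = FALSE)
  y[y < 0] <- 0
  m_mat <- y[, seq_len(V), drop = FALSE]
  colnames(m_mat) <- connectome$labels
  p_arr <- array(y[, -seq_len(V)], dim = c(length(tgrid), N - 1L, V),
                 dimnames = list(NULL, sizes, connectome$labels))
  M_mat <- apply(p_arr, 3L, function(ps) ps %*% sizes)
  P_mat <- apply(p_arr, 3L, rowSums)
  colnames(M_mat) <- colnames(P_mat) <- connectome$labels
  tail_mass <- (N - 1L) * p_arr[, N - 2L, ] + N * p_arr[, N - 1L, ]
  live <- M_mat > 1e-9 * params$m_0
  if (any(live) && max(tail_mass[live] / M_mat[live]) > 0.01)
    stop("truncation overflow at one or more nodes: mass in sizes >= N-1 ",
         "exceeds 1% of M; increase N", call. = FALSE)
  structure(list(time = tgrid, m = m_mat, P = P_mat, M = M_mat, p = p_arr,
                 meta = list(model = "network", params = params,
                             clearance = specs, rho = rho, N = N,
                             labels = connectome$labels,
                             seed_node = seed_node, rtol = rtol,
                             atol = atol, method = "lsoda")),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf(
    "Network trajectory: %d nodes, N = %d, %d time points on [%g, %g]\n",
    ncol(x$M), x$meta$N, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Node invasion times and ranks
#'
#' The invasion time of a node is the first time its toxic mass, normalized
#' by the node's saturation mass, crosses a threshold. By default the
#' saturation mass is the single-region equilibrium `M_2` for the node's
#' (constant) clearance; for other clearance variants supply `M_sat`.
#'
#' @param ntraj a `network_trajectory`.
#' @param threshold normalized-mass threshold (default 0.5).
#' @param M_sat per-node saturation masses (recycled); default computed
#'   from each node's constant clearance.
#' @return A data frame with columns `node`, `invasion_time` (`NA` when the
#'   threshold is never crossed) and `rank` (ties broken by node index,
#'   with a message).
#' @export
invasion_metrics <- function(ntraj, threshold = 0.5, M_sat = NULL) {
  stopifnot(inherits(ntraj, "network_trajectory"))
  V <- ncol(ntraj$M)
  if (is.null(M_sat)) {
    M_sat <- vapply(ntraj$meta$clearance, function(sp) {
      if (sp$variant != "constant")
        stop("supply `M_sat` for non-constant clearance", call. = FALSE)
      fixed_point_constant(ntraj$meta$params, sp$lambda)$M_star
    }, numeric(1L))
  }
  M_sat <- rep_len(M_sat, V)
  if (any(M_sat <= 0))
    stop("saturation mass must be positive at every node", call. = FALSE)
  t_inv <- vapply(seq_len(V), function(j) {
    idx <- which(ntraj$M[, j] / M_sat[j] >= threshold)
    if (length(idx)) ntraj$time[idx[1L]] else NA_real_
  }, numeric(1L))
  ord <- order(t_inv, seq_len(V), na.last = TRUE)
  rk <- integer(V)
  rk[ord] <- seq_len(V)
  finite <- t_inv[!is.na(t_inv)]
  if (anyDuplicated(finite))
    message("tied invasion times broken by node index")
  data.frame(node = colnames(ntraj$M), invasion_time = t_inv, rank = rk,
             row.names = NULL)
}

#' Simulate network transport at moment level
#'
#' For size-independent diffusion and constant (size-independent) clearance
#' the networked master equations close over the per-node moments:
#' \deqn{dP_j/dt = -\rho \sum_k L_{jk} P_k - \lambda_j P_j +
#'   k_2 \sigma(M_j) m_0^2 M_j,}
#' \deqn{dM_j/dt = -\rho \sum_k L_{jk} M_k - \lambda_j M_j +
#'   2 k_+ m_0 P_j + 2 k_2 \sigma(M_j) m_0^2 M_j.}
#' This avoids any size truncation and is the tool of choice for low
#' clearance rates, where the equilibrium size distribution is extremely
#' long-tailed.
#'
#' @inheritParams simulate_network
#' @param lambda constant clearance rate, scalar or per node.
#' @param rho scalar diffusion coefficient shared by all sizes.
#' @return An object of class `network_trajectory` (without the size
#'   array `p`).
#' @export
simulate_network_moments <- function(connectome, params, lambda, rho,
                                     seed_node, seed_value = params$m_0,
                                     seed_type = c("mass", "dimer"),
                                     t_end = 1, include_kn = FALSE,
                                     times = NULL, n_out = 201,
                                     rtol = 1e-8,
                                     atol = 1e-12 * params$m_0) {
  stopifnot(inherits(connectome, "connectome"))
  seed_type <- match.arg(seed_type)
  if (length(rho) != 1L || rho < 0)
    stop("moment-level transport requires a single size-independent rho",
         call. = FALSE)
  V <- connectome$V
  L <- connectome$laplacian
  lam <- rep_len(lambda, V)
  m0 <- params$m_0
  kn_src <- if (include_kn) params$k_n * m0^2 else 0
  P0 <- M0 <- rep(0, V)
  j <- if (is.null(seed_node)) seq_len(V)
    else if (is.character(seed_node)) match(seed_node, connectome$labels)
    else as.integer(seed_node)
  if (any(is.na(j)))
    stop("seed node '", seed_node, "' not found in the connectome",
         call. = FALSE)
  if (seed_type == "mass") { M0[j] <- seed_value; P0[j] <- seed_value / 2 }
  else { P0[j] <- seed_value; M0[j] <- 2 * seed_value }
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) {
    P <- y[seq_len(V)]
    M <- y[V + seq_len(V)]
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m0^2 * M
    dP <- -rho * as.numeric(L %*% P) - lam * P + kn_src + nuc2
    dM <- -rho * as.numeric(L %*% M) - lam * M + 2 * kn_src +
      2 * params$k_plus * m0 * P + 2 * nuc2
    list(c(dP, dM))
  }
  sol <- deSolve::ode(y = c(P0, M0), times = times, func = deriv,
                      parms = NULL, method = "vode",
                      rtol = rtol, atol = atol)
  y <- sol[, -1L, drop = FALSE]
  y[y < 0 & y > -1e-12 * m0] <- 0
  P_mat <- y[, seq_len(V), drop = FALSE]
  M_mat <- y[, V + seq_len(V), drop = FALSE]
  colnames(P_mat) <- colnames(M_mat) <- connectome$labels
  specs <- lapply(lam, function(l) clearance_spec("constant", lambda = l))
  structure(list(time = sol[, 1L],
                 m = matrix(m0, nrow(sol), V,
                            dimnames = list(NULL, connectome$labels)),
                 P = P_mat, M = M_mat, p = NULL,
                 meta = list(model = "network_moments", params = params,
                             clearance = specs, rho = rho, N = NA_integer_,
                             labels = connectome$labels,
                             seed_node = seed_node, rtol = rtol,
                             atol = atol, method = "vode")),
            class = "network_trajectory")
}
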