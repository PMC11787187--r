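# shared fixtures: reference Abeta42 parameters in micromolar-hour units
# (concentration scale 1e6 relative to molar) and in molar units
p_uM <- abeta_parameters()
p_M <- abeta_parameters(conc_scale = 1)

# a small deterministic weighted tree (labels node_1..node_7):
#        1 - {2, 3}; 2 - {4, 5}; 3 - 6; 6 - 7
tree_connectome <- function() {
  A <- matrix(0, 7, 7)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6), c(6, 7))
  for (r in seq_len(nrow(edges)))
    A[edges[r, 1], edges[r, 2]] <- A[edges[r, 2], edges[r, 1]] <- 1
  build_laplacian(A)
}

# kinetics switched off (pure transport/clearance plumbing)
inert_params <- function(base = p_uM) {
  base$k_2 <- 1e-300
  base$k_plus <- 1e-300
  base$k_n <- 1e-300
  base
}
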