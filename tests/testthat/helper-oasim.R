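# shared fixtures: small grids and parameter sets used across tests

quick_grid <- function(n = 11, dt = 0.05) grid_spec(n_nodes = n, dt_days = dt)

# parameters with every reaction switched off (pure transport), used by the
# conservation / leak oracles; a non-uniform initial profile excites fluxes
transport_only_params <- function(grid, sex = "male") {
  zero <- list(A = 0, lambda_CCs = 0, lambda_CCh = 0, lambda_CsMP = 0,
               lambda_CL2 = 0, mu_C = 0, mu_Cs0 = 0, mu_Ch = 0, mu_MP = 0,
               mu_L2 = 0, mu_L2MP = 0, mu_MPL2 = 0, mu_DCs = 0, mu_CsD = 0,
               alpha_w_MP = 0, alpha_w_L2 = 0, gamma_D = 0, gamma_U2 = 0,
               omega_D = 0, lambda_ChCc = 0)
  x <- grid$x
  bump <- function(a) a * (1 + 0.5 * sin(pi * x / max(x)) +
                             0.2 * cos(3 * pi * x / max(x)))
  st <- species_state(x, C = bump(0.03), Cs = bump(4.5e-3),
                      Ch = bump(2.7e-4), Cc = bump(1e-4), MP = bump(2.6e-7),
                      L2 = bump(1.7e-4), D = bump(1e-7))
  do.call(oa_params, c(list(sex = sex), zero, list(initial_state = st)))
}

trap_mass <- function(v, dx) (sum(v) - 0.5 * (v[1] + v[length(v)])) * dx

# random valid states for property-style checks
random_state <- function(grid, seed) {
  set.seed(seed)
  n <- grid$n_nodes
  species_state(grid$x,
                C = runif(n, 0, 0.05), Cs = runif(n, 0, 0.01),
                Ch = runif(n, 0, 1e-3), Cc = runif(n, 0, 0.5),
                MP = runif(n, 0, 1e-6), L2 = runif(n, 0, 3e-4),
                D = runif(n, 0, 1e-5))
}
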