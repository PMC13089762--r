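# shared fixtures: small networks and comparison helpers

# strict linear chain with unit-free weights set explicitly
chain_net <- function(sizes, act = "linear", cond = conductances(), eta = 0,
                      sigma_L = 0, b_noise = 0, seed = 1, ...) {
  g <- area_graph(sizes, mode = "classifier", hierarchy = "strict")
  mc_network(g, cond = cond, act = act, eta = eta, sigma_L = sigma_L,
             b_noise = b_noise, seed = seed, ...)
}

cosine <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

state_max_abs <- function(st) {
  max(abs(unlist(lapply(c(st$u_som, st$e_som, st$u_pred, st$u_err), abs),
                 use.names = FALSE)), 0)
}

# run the pure-R reference dynamics for n ticks (plasticity optional)
run_r_ticks <- function(net, input, target = NULL, n, plasticity = FALSE) {
  st <- mc_state(net)
  for (t in seq_len(n)) {
    r <- mc_tick(net, st, input, target, plasticity = plasticity)
    st <- r$state; net <- r$net
  }
  list(net = net, state = st)
}
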