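# 1D double-well toy shared by the WHAM tests: V(q) = k ((q-0.5)^2 - a^2)^2
# with minima at 0.5 +/- a and analytic barrier k a^4 (= 3 kT here).
dw_k <- 768
dw_a <- 0.25
dw_V <- function(q) dw_k * ((q - 0.5)^2 - dw_a^2)^2

# seeded Metropolis sampler of exp(-(V + bias)) on [0, 1]
mc_sample <- function(V_bias, n, q_start, prop_sd = 0.08, seed = 1) {
  set.seed(seed)
  q <- numeric(n)
  cur <- q_start
  e_cur <- V_bias(cur)
  jumps <- rnorm(n, sd = prop_sd)
  accepts <- runif(n)
  for (i in seq_len(n)) {
    cand <- cur + jumps[i]
    if (cand >= 0 && cand <= 1) {
      e_cand <- V_bias(cand)
      if (accepts[i] < exp(e_cur - e_cand)) {
        cur <- cand; e_cur <- e_cand
      }
    }
    q[i] <- cur
  }
  q
}
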