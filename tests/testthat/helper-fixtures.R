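# Shared fixtures: published parameter sets and small synthetic inputs.

wt_params <- function() load_params("interface_wt")
mutant_params <- function() load_params("interface_mutant")

# sequential two-step chain (no reorganization, no rebinding): closed-form
# oracle territory
chain_params <- function(k0 = 0.5, xb = 1.0) {
  sliding_rebinding_params(k0, xb, k_plus1 = 0, k_plus2 = 0, F_C1 = 0,
                           F_C2 = 100, n = 1, variant = "mutant")
}

# closed-form survival of the two-step chain P11 -(a)-> P10 -(b)-> P00
chain_survival <- function(t, a, b) {
  if (abs(b - a) < 1e-12) return(exp(-a * t) * (1 + a * t))
  exp(-a * t) + a / (b - a) * (exp(-a * t) - exp(-b * t))
}

# central finite difference of a scalar energy over bead coordinates
fd_forces <- function(pos, energy_fn, h = 1e-6) {
  g <- matrix(0, nrow(pos), 2)
  for (i in seq_len(nrow(pos))) for (d in 1:2) {
    up <- pos; up[i, d] <- up[i, d] + h
    dn <- pos; dn[i, d] <- dn[i, d] - h
    g[i, d] <- -(energy_fn(up) - energy_fn(dn)) / (2 * h)
  }
  g
}
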