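# Independent oracles used across the suite. These deliberately take the
# dumb, transparent route (fixed-point iteration, root polynomials, sliding
# windows, combinatorial sums) so they share no code path with the
# implementation they check.

# Brute-force three-species resin equilibrium: bait B on the resin binds
# prey D with Kd K1; prey I binds D (independent site) with Kd KL. Solves
# the coupled mass balances by damped fixed-point iteration and returns
# the supernatant depletions of D and I. All concentrations in one unit.
oracle_tethered_equilibrium <- function(B_tot, D_tot, I_tot, K1, KL,
                                        iters = 500) {
  B <- B_tot
  I <- I_tot
  D <- D_tot
  for (it in seq_len(iters)) {
    D <- D_tot / ((1 + B / K1) * (1 + I / KL))
    I <- I_tot / (1 + D * (1 + B / K1) / KL)
    BD <- B * D / K1
    BDI <- BD * I / KL
    B <- B_tot - BD - BDI
  }
  BD <- B * D / K1
  BDI <- BD * I / KL
  list(
    theta_direct = (BD + BDI) / D_tot,
    theta_indirect = BDI / I_tot
  )
}

# Closed-form cubic for the free receptor r in the two-ligand competition
# equilibrium: r(K1+r)(K2+r) + rL(K2+r) + rC(K1+r) - R(K1+r)(K2+r) = 0.
# Expanded to a monic cubic and solved with polyroot; the physical root
# lies in [0, R].
oracle_competitive_free_receptor <- function(R, L, C, K1, K2) {
  a3 <- 1
  a2 <- K1 + K2 + L + C - R
  a1 <- K1 * K2 + K2 * L + K1 * C - R * (K1 + K2)
  a0 <- -R * K1 * K2
  roots <- polyroot(c(a0, a1, a2, a3))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))])
  real <- real[real >= -1e-12 & real <= R * (1 + 1e-9)]
  if (length(real) == 0) stop("no physical root found")
  max(min(real), 0)
}

# Naive overlapping sliding-window scan for a fixed-position consensus
# ("x" = wildcard). Returns 1-based start positions.
oracle_scan_positions <- function(sequence, consensus) {
  sq <- strsplit(toupper(sequence), "")[[1]]
  pat <- strsplit(consensus, "")[[1]]
  len <- length(pat)
  starts <- integer(0)
  if (length(sq) < len) return(starts)
  for (i in seq_len(length(sq) - len + 1)) {
    win <- sq[i:(i + len - 1)]
    if (all(pat == "x" | toupper(pat) == win)) starts <- c(starts, i)
  }
  starts
}

# Exhaustive upper-tail hypergeometric probability by combinatorial
# enumeration of draw compositions (feasible for N <= ~25).
oracle_hyper_upper <- function(k, K, N, n) {
  total <- choose(N, n)
  js <- seq(max(k, 0), min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / total
}

# random amino-acid sequence for property tests
random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
    replace = TRUE), collapse = "")
}
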