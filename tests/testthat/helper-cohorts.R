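# Shared fixtures, all generated in code.

ten_v_ten <- function(prefixes = c("case", "ctrl"), n = c(10L, 10L)) {
  stats::setNames(c(rep("case", n[1]), rep("control", n[2])),
                  c(sprintf("%s%02d", prefixes[1], seq_len(n[1])),
                    sprintf("%s%02d", prefixes[2], seq_len(n[2]))))
}

# small planted cohort used across modules: 2 x 5mC and 2 x 5hmC regions
small_planted_cohort <- function(seed = 11, n_case = 10L, n_control = 10L,
                                 delta_5mc = 0.3, delta_5hmc = 0.15,
                                 coupling = 0, coverage = coverage_spec(30, 8)) {
  ref <- simulate_reference(2, 200, seed = seed)
  eff <- plant_effects(ref$map,
                       data.frame(mark = c("5mC", "5hmC"),
                                  delta = c(delta_5mc, delta_5hmc),
                                  coupling = coupling, n = c(2L, 2L)))
  spec <- truth_spec(ref$map, ten_v_ten(n = c(n_case, n_control)),
                     regions = eff, coverage = coverage, seed = seed)
  list(cohort = simulate_counts(spec), spec = spec, ref = ref, effects = eff)
}

# independent pair-counting AUC oracle (brute force over all case/control pairs)
auc_pair_oracle <- function(values, is_case) {
  x <- values[is_case]; y <- values[!is_case]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# independent exhaustive-permutation two-sided MWU p-value oracle,
# built on pair counting rather than ranks
mwu_perm_oracle <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  u_of <- function(idx) {
    a <- v[idx]; b <- v[-idx]
    s <- 0
    for (ai in a) for (bj in b) s <- s + (ai > bj) + 0.5 * (ai == bj)
    s
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  cmb <- utils::combn(n, n1)
  us <- apply(cmb, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force constrained likelihood search on a 0.001 lattice
mle_lattice_oracle <- function(c_bs, n_bs, c_ox, n_ox, step = 0.001) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(m = g, h = g)
  grid <- grid[grid$m + grid$h <= 1 + 1e-12, ]
  ll <- stats::dbinom(c_bs, n_bs, pmin(grid$m + grid$h, 1), log = TRUE) +
    stats::dbinom(c_ox, n_ox, grid$m, log = TRUE)
  grid[which.max(ll), ]
}
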