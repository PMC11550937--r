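# Independent oracles used across the suite. These deliberately share no code
# with the package: a fixed-step RK4 integrator for the co-culture model, the
# logistic closed form, a brute-force transcription of the weighted
# plate-count ratio, and a from-first-principles Dunn z for two groups.

# Fixed-step RK4 for dS,dI,dR,dP; returns states at `times` (subset of the
# internal fine grid).
oracle_rk4 <- function(p, times, dt = 0.005) {
  deriv <- function(y) {
    S <- max(y[1], 0); I <- max(y[2], 0); R <- max(y[3], 0); P <- max(y[4], 0)
    N <- S + I + R
    c(p$r * S * (1 - N / p$K) - p$delta * S * P - p$mu_res * S,
      p$delta * S * P - I / p$tau,
      p$r * R * (1 - N / p$K) + p$mu_res * S,
      (p$beta / p$tau) * I - p$delta * N * P - p$lam * P)
  }
  t_end <- max(times)
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  y <- c(p$S0, 0, 0, p$P0)
  grid_t <- 0
  out <- matrix(NA_real_, length(times), 4)
  colnames(out) <- c("S", "I", "R", "P")
  ti <- 1
  if (times[1] == 0) { out[1, ] <- y; ti <- 2 }
  for (s in seq_len(n_steps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    grid_t <- grid_t + dt
    while (ti <= length(times) && times[ti] <= grid_t + 1e-9) {
      out[ti, ] <- y
      ti <- ti + 1
    }
  }
  out
}

oracle_od <- function(p, times, dt = 0.005) {
  st <- oracle_rk4(p, times, dt)
  p$od_per_cell * (st[, "S"] + st[, "I"] + st[, "R"])
}

# Phage-free logistic closed form for S(t).
oracle_logistic <- function(S0, r, K, t) {
  K * S0 * exp(r * t) / (K + S0 * (exp(r * t) - 1))
}

# Trapezoid AUC (kept separate from the package's compute_auc).
oracle_trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

# Brute-force weighted plate-count estimate: direct transcription of the
# ratio (total countable counts over weighted plate numbers) then rescale by
# the least dilute countable level. Returns NA when nothing is countable.
oracle_weighted_estimate <- function(count, exponent, volume,
                                     cmin = 10, cmax = 300) {
  ok <- count >= cmin & count <= cmax
  if (!any(ok)) return(NA_real_)
  levs <- sort(unique(exponent[ok]), decreasing = TRUE)
  levs <- levs[seq(max(1, length(levs) - 1), length(levs))]  # two most dilute
  e1 <- levs[1]
  use <- ok & exponent %in% levs
  n1 <- sum(exponent[use] == e1)
  n2 <- sum(exponent[use] == e1 - 1)
  ratio <- sum(count[use]) / (n1 * 1 + n2 * 0.1)
  ratio / (10^e1 * volume)
}

# Dunn z for one pair from pooled mid-ranks, tie-corrected, computed longhand.
oracle_dunn_z <- function(x, y) {
  all_v <- c(x, y)
  rk <- rank(all_v)
  N <- length(all_v)
  ties <- table(rk)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(rk[seq_along(x)]) - mean(rk[length(x) + seq_along(y)])) /
    sqrt(sigma2 * (1 / length(x) + 1 / length(y)))
}

# Random valid co-culture parameter set for property tests.
random_params <- function() {
  phagekit::coculture_params(
    r = runif(1, 0.1, 1.5),
    K = 10^runif(1, 8, 10),
    delta = 10^runif(1, -11, -8),
    tau = runif(1, 0.2, 2),
    beta = runif(1, 5, 200),
    lam = runif(1, 0, 0.2),
    mu_res = sample(c(0, 10^runif(1, -8, -5)), 1),
    noise_sd = runif(1, 0, 0.02),
    S0 = 10^runif(1, 5, 7),
    P0 = sample(c(0, 10^runif(1, 5, 8)), 1)
  )
}
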