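# Canonical regular-spiking parameter set used across the suite
rs_params <- function(b = -2, a = 0.03, d = 100) {
  izhi_params(C = 100, k = 0.7, Vr = -60, Vt = -40, Vpeak = 35, Vmin = -50,
              a = a, b = b, d = d)
}

# Independent reference integrator: plain-R forward Euler for a single
# compartment under a step current. Deliberately separate from the package's
# compiled path; used as the high-resolution oracle.
euler_reference <- function(p, amp_pA, onset, duration, total, dt) {
  n <- round(total / dt)
  V <- p$Vr
  U <- 0
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    I <- if (t >= onset && t < onset + duration) amp_pA else 0
    Vn <- V + dt * (p$k * (V - p$Vr) * (V - p$Vt) - U + I) / p$C
    Un <- U + dt * p$a * (p$b * (V - p$Vr) - U)
    if (Vn >= p$Vpeak) {
      spikes <- c(spikes, i * dt)
      Vn <- p$Vmin
      Un <- Un + p$d
    }
    V <- Vn
    U <- Un
  }
  spikes
}

# Brute-force spike clustering by direct rule application (oracle for
# segment_bursts): split at ISIs exceeding ratio x both the local previous
# interval and the robust intra estimate, via explicit loops.
brute_clusters <- function(st, gap_ratio = 3) {
  isis <- diff(st)
  intra <- isis[isis <= mean(isis)]
  thr <- gap_ratio * median(intra)
  groups <- list(st[1])
  for (i in seq_along(isis)) {
    prev <- if (i == 1) (if (length(isis) > 1) isis[2] else isis[1])
            else isis[i - 1]
    if (isis[i] > thr && isis[i] > gap_ratio * prev) {
      groups[[length(groups) + 1]] <- st[i + 1]
    } else {
      g <- groups[[length(groups)]]
      groups[[length(groups)]] <- c(g, st[i + 1])
    }
  }
  groups
}

# Exhaustive-enumeration oracle for Barnard's test: naive loops over the
# full outcome space and the nuisance grid.
barnard_oracle <- function(tab, grid_step = 0.001) {
  n1 <- sum(tab[, 1])
  n2 <- sum(tab[, 2])
  wald <- function(x, y) {
    pp <- (x + y) / (n1 + n2)
    if (pp == 0 || pp == 1) return(0)
    (x / n1 - y / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  z_obs <- abs(wald(tab[1, 1], tab[1, 2]))
  best <- 0
  for (pv in seq(grid_step, 1 - grid_step, by = grid_step)) {
    tot <- 0
    for (x in 0:n1) for (y in 0:n2) {
      if (abs(wald(x, y)) >= z_obs - 1e-12)
        tot <- tot + dbinom(x, n1, pv) * dbinom(y, n2, pv)
    }
    if (tot > best) best <- tot
  }
  min(best, 1)
}

# Definitional Benjamini-Hochberg scan: largest k with p_(k) <= k q / m,
# reject all hypotheses with p at most that threshold.
bh_oracle <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k <- suppressWarnings(max(which(s <= seq_len(m) * q / m)))
  if (!is.finite(k)) return(rep(FALSE, m))
  p <= s[k]
}
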