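# Shared fixtures and independent oracles for the test suite.

default_temps <- function() zone_center_temps()

# --- track fixtures built in code ------------------------------------------

stationary_track <- function(x = 30, duration_s = 60, fps = 15,
                             id = "still") {
  n <- round(duration_s * fps)
  animal_track(data.frame(time_s = (seq_len(n) - 1) / fps,
                          x_cm = rep(x, n)), id, fps = fps)
}

linear_track <- function(from, to, duration_s = 60, fps = 15, id = "line") {
  n <- round(duration_s * fps)
  animal_track(data.frame(time_s = (seq_len(n) - 1) / fps,
                          x_cm = seq(from, to, length.out = n)),
               id, fps = fps)
}

# --- independent least-squares oracles --------------------------------------
# These recompute the Gaussian residual SS directly from the model formula;
# they share no code with the package's fitting path.

oracle_ss <- function(t_peak, sd, temps, y, mode = "free_3p") {
  g <- exp(-(temps - t_peak)^2 / (2 * sd^2))
  if (mode == "free_3p") {
    a <- sum(g * y) / sum(g * g)
    sum((y - a * g)^2)
  } else {
    u <- sort(unique(temps))
    gu <- exp(-(u - t_peak)^2 / (2 * sd^2))
    pred <- (100 * gu / sum(gu))[match(temps, u)]
    sum((y - pred)^2)
  }
}

# Exhaustive dense grid over the fitting box at a fixed step. Chunked by
# t_peak to bound memory. Returns the arg-min and its SS.
dense_grid_fit <- function(temps, y, step = 0.01, mode = "free_3p") {
  u <- sort(unique(temps))
  s1 <- as.numeric(tapply(y, match(temps, u), sum))
  m <- as.numeric(tabulate(match(temps, u), nbins = length(u)))
  sumy2 <- sum(y^2)
  tp_seq <- seq(4, 58, by = step)
  sd_seq <- seq(0.5, 40, by = step)
  inv2sd2 <- 1 / (2 * sd_seq^2)
  best <- list(ss = Inf)
  for (chunk in split(tp_seq, ceiling(seq_along(tp_seq) / 60))) {
    for (tp in chunk) {
      D2 <- outer(inv2sd2, (u - tp)^2) # n_sd x n_temp
      G <- exp(-D2)
      if (mode == "free_3p") {
        num <- as.numeric(G %*% s1)
        den <- as.numeric((G * G) %*% m)
        ss <- sumy2 - num^2 / den
      } else {
        P <- 100 * G / rowSums(G)
        ss <- sumy2 - 2 * as.numeric(P %*% s1) + as.numeric((P * P) %*% m)
      }
      j <- which.min(ss)
      if (ss[j] < best$ss)
        best <- list(ss = ss[j], t_peak = tp, sd = sd_seq[j])
    }
  }
  best
}

# Iteratively zoomed grid search; independent route to near-exact SS minima
# for the F-test equivalence check. `shared` fits two groups with a common
# t_peak.
zoom_grid_fit <- function(temps, y, mode = "free_3p", rounds = 6) {
  tp_rng <- c(4, 58)
  sd_rng <- c(0.5, 40)
  for (r in seq_len(rounds)) {
    tp_seq <- seq(tp_rng[1], tp_rng[2], length.out = 31)
    sd_seq <- seq(sd_rng[1], sd_rng[2], length.out = 31)
    ss <- outer(tp_seq, sd_seq,
                Vectorize(function(a, b) oracle_ss(a, b, temps, y, mode)))
    ij <- arrayInd(which.min(ss), dim(ss))
    tp0 <- tp_seq[ij[1]]
    sd0 <- sd_seq[ij[2]]
    htp <- diff(tp_rng) / 10
    hsd <- diff(sd_rng) / 10
    tp_rng <- c(max(4, tp0 - htp), min(58, tp0 + htp))
    sd_rng <- c(max(0.5, sd0 - hsd), min(40, sd0 + hsd))
  }
  list(t_peak = tp0, sd = sd0, ss = min(ss))
}

zoom_grid_fit_shared_tpeak <- function(temps_a, y_a, temps_b, y_b,
                                       mode = "free_3p", rounds = 6) {
  tp_rng <- c(4, 58)
  sda_rng <- sdb_rng <- c(0.5, 40)
  for (r in seq_len(rounds)) {
    tp_seq <- seq(tp_rng[1], tp_rng[2], length.out = 21)
    sda_seq <- seq(sda_rng[1], sda_rng[2], length.out = 21)
    sdb_seq <- seq(sdb_rng[1], sdb_rng[2], length.out = 21)
    best <- list(ss = Inf)
    for (tp in tp_seq) {
      ssa <- vapply(sda_seq, function(s) oracle_ss(tp, s, temps_a, y_a, mode), 0)
      ssb <- vapply(sdb_seq, function(s) oracle_ss(tp, s, temps_b, y_b, mode), 0)
      tot <- min(ssa) + min(ssb)
      if (tot < best$ss)
        best <- list(ss = tot, tp = tp, sda = sda_seq[which.min(ssa)],
                     sdb = sdb_seq[which.min(ssb)])
    }
    htp <- diff(tp_rng) / 10
    ha <- diff(sda_rng) / 10
    hb <- diff(sdb_rng) / 10
    tp_rng <- c(max(4, best$tp - htp), min(58, best$tp + htp))
    sda_rng <- c(max(0.5, best$sda - ha), min(40, best$sda + ha))
    sdb_rng <- c(max(0.5, best$sdb - hb), min(40, best$sdb + hb))
  }
  best
}

# Noisy pooled occupancy fixture: `n_animals` x 14 zones from a 3p Gaussian
# with iid normal zone noise.
noisy_points <- function(t_peak = 31, sd = 10, amplitude = 14,
                         n_animals = 2, noise_sd = 2, seed = 1) {
  set.seed(seed)
  temps <- rep(default_temps(), n_animals)
  g <- exp(-(temps - t_peak)^2 / (2 * sd^2))
  data.frame(temp_c = temps, percent = amplitude * g + rnorm(length(temps), 0, noise_sd))
}
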