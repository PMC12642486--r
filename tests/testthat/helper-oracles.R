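# Independent, deliberately naive reference implementations used to check
# the package's fast paths. These follow the written rules with explicit
# loops and never share code with the implementation.

# --- brute-force peak scan -------------------------------------------------
# local maxima of x: plateau resolved to its leftmost frame, boundary
# plateaus discarded, topographic prominence >= prom_min, greedy minimum
# separation (taller first, leftmost on ties)
oracle_find_peaks <- function(x, prom_min, min_sep) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i - 1] == x[i]) next                      # not the plateau start
    l <- i - 1                                      # differs by construction
    r <- NA
    for (j in (i + 1):n) if (x[j] != x[i]) { r <- j; break }
    if (is.na(r)) next                              # plateau runs to the end
    if (x[l] < x[i] && x[r] < x[i]) cand <- c(cand, i)
  }
  keep <- integer(0)
  for (i in cand) {
    # prominence: lowest point toward the nearest strictly higher sample
    # (or edge) on each side; height above the higher of the two
    lo_l <- 1
    for (j in (i - 1):1) if (x[j] > x[i]) { lo_l <- j + 1; break }
    hi_r <- n
    for (j in (i + 1):n) if (x[j] > x[i]) { hi_r <- j - 1; break }
    prom <- x[i] - max(min(x[lo_l:i]), min(x[i:hi_r]))
    if (prom >= prom_min) keep <- c(keep, i)
  }
  if (!length(keep)) return(integer(0))
  ord <- keep[order(-x[keep], keep)]
  out <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in out) if (abs(j - i) < min_sep) ok <- FALSE
    if (ok) out <- c(out, i)
  }
  sort(out)
}

# full detector oracle: peaks, valleys, alternation by explicit scan
oracle_detect <- function(x, fps, hr_max_hz, prom_frac) {
  prom_min <- prom_frac * (max(x) - min(x))
  min_sep <- fps / hr_max_hz
  peaks <- oracle_find_peaks(x, prom_min, min_sep)
  valleys <- oracle_find_peaks(-x, prom_min, min_sep)
  idx <- sort(c(peaks, valleys))
  typ <- ifelse(idx %in% peaks, "p", "v")
  repeat {
    dup <- NA
    for (j in seq_len(length(idx) - 1)) {
      if (typ[j] == typ[j + 1]) { dup <- j; break }
    }
    if (is.na(dup)) break
    a <- idx[dup]; b <- idx[dup + 1]
    better_b <- if (typ[dup] == "p") x[b] > x[a] else x[b] < x[a]
    drop <- if (better_b) dup else dup + 1
    idx <- idx[-drop]; typ <- typ[-drop]
  }
  list(peaks = idx[typ == "p"], valleys = idx[typ == "v"])
}

# random traces exercising plateaus and ties: rounded smoothed random walks
random_trace <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n))
  k <- rep(1 / 5, 5)
  x <- as.numeric(stats::filter(x, k, sides = 2))
  x[is.na(x)] <- x[!is.na(x)][1]
  round(x, 1)
}

# --- Welch t-test from the textbook formulas -------------------------------
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# --- Kaplan-Meier product-limit by hand ------------------------------------
# survival at each distinct event time for records (time, event 1/0)
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t_i <- times[i]
    at_risk <- sum(time >= t_i)
    died <- sum(time == t_i & event == 1)
    s <- s * (1 - died / at_risk)
    out[i] <- s
  }
  data.frame(time = times, surv = out)
}

# --- log-rank by hand (two groups, O-E with hypergeometric variance) -------
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- c(rep(1, length(ta)), rep(2, length(tb)))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t_i in times) {
    n <- sum(time >= t_i)
    n1 <- sum(time >= t_i & grp == 1)
    d <- sum(time == t_i & event == 1)
    d1 <- sum(time == t_i & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# small fast kinematics used across tests
test_kin <- function(..., seed = 1) {
  vessel_kinematics(duration_s = 4, jitter_cv = 0, seed = seed, ...)
}
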