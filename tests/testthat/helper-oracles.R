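# Independent brute-force oracles used across the suite. These stay naive
# (per-sample loops, O(n^2) sweeps) on purpose: they must not share code
# paths with the implementation they check.

# rolling extrema midpoint, centered window truncated at edges
oracle_threshold <- function(x, fs, window) {
  half <- floor(max(3L, 2L * floor(window * fs / 2) + 1L) / 2)
  vapply(seq_along(x), function(i) {
    w <- x[max(1L, i - half):min(length(x), i + half)]
    (max(w) + min(w)) / 2
  }, numeric(1))
}

# first-sample threshold-crossing scan, no refractory
oracle_upward_crossings <- function(x, thr, t0 = 0, fs = 100) {
  above <- x >= thr
  t0 + (which(above[-1] & !above[-length(above)])) / fs
}

# elementwise weighted-mean CoP
oracle_cop <- function(P, xs, ys) {
  n <- nrow(P)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    s <- 0; sx <- 0; sy <- 0
    for (j in seq_len(ncol(P))) {
      s <- s + P[i, j]
      sx <- sx + xs[j] * P[i, j]
      sy <- sy + ys[j] * P[i, j]
    }
    out[i, ] <- c(sx / s, sy / s)
  }
  out
}

# O(n^2) pairwise interval-intersection sweep
oracle_overlaps <- function(a, b) {
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a$ic_time[i], b$ic_time[j])
      e <- min(a$to_time[i], b$to_time[j])
      if (e > s) { starts <- c(starts, s); ends <- c(ends, e) }
    }
  }
  ord <- order(starts)
  data.frame(start = starts[ord], end = ends[ord],
             duration = (ends - starts)[ord])
}

# exhaustive IC/TO pairing: for each IC take the first TO after it that
# precedes the next IC
oracle_pairing <- function(ics, tos) {
  ic_out <- numeric(0); to_out <- numeric(0)
  for (k in seq_along(ics)) {
    nxt <- if (k < length(ics)) ics[k + 1] else Inf
    hit <- Inf
    for (t in tos) if (t > ics[k] && t < nxt && t < hit) hit <- t
    if (is.finite(hit)) {
      ic_out <- c(ic_out, ics[k]); to_out <- c(to_out, hit)
    }
  }
  data.frame(ic_time = ic_out, to_time = to_out)
}

# random disjoint stance train starting near `start`
random_stance_train <- function(n, start = 0) {
  ic <- numeric(n); to <- numeric(n)
  t <- start
  for (i in seq_len(n)) {
    t <- t + stats::runif(1, 0.1, 0.8)
    ic[i] <- t
    t <- t + stats::runif(1, 0.2, 0.9)
    to[i] <- t
  }
  data.frame(ic_time = ic, to_time = to)
}

# square wave: `high` kPa on [on, off) of each `period`, for n_cycles
square_wave <- function(on, off, period, n_cycles, fs = 100, high = 200,
                        tail = 0.2) {
  t <- seq(0, n_cycles * period + tail, by = 1 / fs)
  phase <- t %% period
  ifelse(phase >= on & phase < off & t < n_cycles * period, high, 0)
}

# hand-built CoP trajectory for velocity unit tests
make_cop <- function(cop_x, cop_y, valid = rep(TRUE, length(cop_x)),
                     fs = 100, foot_side = "left") {
  n <- length(cop_x)
  cop_x[!valid] <- NA_real_; cop_y[!valid] <- NA_real_
  structure(
    data.frame(time_s = (seq_len(n) - 1) / fs, cop_x = cop_x, cop_y = cop_y,
               valid = valid, vel_x = NA_real_, vel_y = NA_real_),
    class = c("cop_trajectory", "data.frame"),
    fs = fs, foot_side = foot_side, contact_floor = 10)
}
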