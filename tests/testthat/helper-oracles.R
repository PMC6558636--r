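# Independent brute-force oracles used by the property tests. These stay
# deliberately naive: enumeration over all possibilities, no shortcuts
# shared with the implementation they check.

# all permutations of a vector
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# brute-force minimum of sum(cost) + unlink_cost * (#unmatched rows +
# #unmatched cols) over all one-to-one matchings restricted to allowed
# (finite-cost) pairs; returns the minimal objective value
brute_force_link_cost <- function(cost, unlink_cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  best <- Inf
  recurse <- function(i, used_cols, acc) {
    if (acc >= best) return()
    if (i > n1) {
      total <- acc + unlink_cost * (n2 - sum(used_cols))
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1L, used_cols, acc + unlink_cost)  # row i unmatched
    for (j in seq_len(n2)) {
      if (!used_cols[j] && is.finite(cost[i, j])) {
        used_cols[j] <- TRUE
        recurse(i + 1L, used_cols, acc + cost[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n2), 0)
  best
}

# brute-force scan for maximal runs of consecutive frames with distance
# <= gate, length >= min_run, given two per-frame position tables
brute_force_runs <- function(frames, d, gate, min_run) {
  ok <- d <= gate
  runs <- list()
  start <- NA_integer_
  for (k in seq_along(ok)) {
    if (ok[k] && is.na(start)) start <- k
    if ((!ok[k] || k == length(ok)) && !is.na(start)) {
      end <- if (ok[k]) k else k - 1L
      if (end - start + 1L >= min_run)
        runs[[length(runs) + 1L]] <- c(frames[start], frames[end])
      start <- NA_integer_
    }
  }
  runs
}

# closed-form lens area of two overlapping unit-radius circles at center
# distance d, as a fraction of one circle's area
circle_lens_fraction <- function(d, r = 1) {
  (2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)) / (pi * r^2)
}

# tiny spot-table constructor for hand-built frames
mk_spots <- function(x, y, w = 0.3, frame = 0L, channel = "green",
                     amplitude = 1000) {
  n <- length(x)
  data.frame(channel = channel, frame = frame, x_um = x, y_um = y,
             wx_um = rep_len(w, n), wy_um = rep_len(w, n),
             orientation_rad = 0, amplitude = rep_len(amplitude, n),
             background = 0,
             area_half_max_um2 = pi * rep_len(w, n)^2,
             fit_quality = 1)
}
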