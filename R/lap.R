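#' Minimum-cost linear assignment (square cost matrix)
#'
#' Shortest-augmenting-path solver with dual potentials (the
#' Jonker-Volgenant scheme) for the square linear assignment problem.
#' Deterministic for a fixed cost matrix. Used by the frame-linking step;
#' no assignment solver for dense cost matrices is available among the
#' package's dependencies, so the primitive is implemented here and tested
#' against brute-force enumeration.
#'
#' @param cost Square numeric matrix of finite costs.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`;
#'   the assignment minimizes `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square", call. = FALSE)
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop("costs must be finite", call. = FALSE)
  INF <- Inf
  # arrays over columns 0..n; index 1 is the virtual column 0
  p <- integer(n + 1L)       # p[j+1] = row assigned to column j (0 = none)
  u <- numeric(n + 1L)       # row potentials (u[i+1] for row i)
  v <- numeric(n + 1L)       # column potentials
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- logical(n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])          # candidate columns (1-based ids)
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      if (any(upd)) {
        jj <- free_j[upd]
        minv[jj + 1L] <- cur[upd]
        way[jj + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j + 1L])]
      delta <- minv[j1 + 1L]
      usedi <- which(used)                 # indices into (n+1) arrays
      u[p[usedi] + 1L] <- u[p[usedi] + 1L] + delta
      v[usedi] <- v[usedi] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  a
}
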