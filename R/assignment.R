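# Minimum-cost one-to-one assignment (Hungarian algorithm, shortest
# augmenting path with potentials, O(n^3)). Rectangular matrices are padded
# with zero-cost dummy rows/columns so exactly min(nrow, ncol) real pairs
# are matched at minimum total cost.
#
# Returns an integer vector `match` of length nrow(cost): match[i] = column
# assigned to row i (NA for rows matched to a dummy column).
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || any(!is.finite(cost))) {
    abort("`cost` must be a finite numeric matrix")
  }
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost

  u <- numeric(n) # row potentials
  v <- numeric(n + 1) # column potentials, v[j + 1] for j in 0..n
  p <- integer(n + 1) # p[j + 1] = row matched to column j (0 = free)
  way <- integer(n + 1)

  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L]) # candidate columns 1..n
      cur <- a[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        jj <- free_j[upd]
        minv[jj] <- cur[upd]
        way[jj + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used) - 1L # columns 0..n currently in the tree
      rows_in_tree <- p[used_j + 1L]
      u[rows_in_tree] <- u[rows_in_tree] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }

  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1L]] <- j
  match <- match[seq_len(nr)]
  match[match > nc] <- NA_integer_
  match
}
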