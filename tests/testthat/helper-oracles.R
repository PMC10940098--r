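# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain loops, naive enumeration) and share
# no code with the package internals they check.

oracle_offsets <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

inb <- function(v, dims) all(v >= 1) && all(v <= dims)

# naive symmetric co-occurrence matrix for one offset
oracle_glcm <- function(q, G, off) {
  dims <- dim(q)
  M <- matrix(0, G, G)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- q[x, y, z]
    if (a == 0) next
    v <- c(x, y, z) + off
    if (!inb(v, dims)) next
    b <- q[v[1], v[2], v[3]]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# naive run-length matrix summed over the 13 directions
oracle_glrlm <- function(q, G) {
  dims <- dim(q)
  R <- matrix(0, G, max(dims))
  for (off in oracle_offsets()) {
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      a <- q[x, y, z]
      if (a == 0) next
      prev <- c(x, y, z) - off
      if (inb(prev, dims) && q[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(x, y, z) + off
      while (inb(cur, dims) && q[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + off
      }
      R[a, len] <- R[a, len] + 1
    }
  }
  R
}

# naive 26-connected equal-level zones: data.frame(level, size)
oracle_zones <- function(q) {
  dims <- dim(q)
  seen <- array(FALSE, dims)
  res <- list()
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (q[x, y, z] == 0 || seen[x, y, z]) next
    lev <- q[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(nbhd))) {
        w <- v + nbhd[r, ]
        if (inb(w, dims) && !seen[w[1], w[2], w[3]] && q[w[1], w[2], w[3]] == lev) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- c(queue, list(w))
        }
      }
    }
    res[[length(res) + 1]] <- c(lev, size)
  }
  m <- do.call(rbind, res)
  data.frame(level = m[, 1], size = m[, 2])
}

# naive dependence matrix (G x 27), dependence size includes the center
oracle_gldm <- function(q, G) {
  dims <- dim(q)
  D <- matrix(0, G, 27)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- q[x, y, z]
    if (a == 0) next
    dep <- 1
    for (r in seq_len(nrow(nbhd))) {
      w <- c(x, y, z) + nbhd[r, ]
      if (inb(w, dims) && q[w[1], w[2], w[3]] == a) dep <- dep + 1
    }
    D[a, dep] <- D[a, dep] + 1
  }
  D
}

# naive neighborhood gray-tone accumulators
oracle_ngtdm <- function(q, G) {
  dims <- dim(q)
  nvec <- numeric(G); svec <- numeric(G)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- q[x, y, z]
    if (a == 0) next
    vals <- c()
    for (r in seq_len(nrow(nbhd))) {
      w <- c(x, y, z) + nbhd[r, ]
      if (inb(w, dims) && q[w[1], w[2], w[3]] > 0)
        vals <- c(vals, q[w[1], w[2], w[3]])
    }
    if (length(vals)) {
      nvec[a] <- nvec[a] + 1
      svec[a] <- svec[a] + abs(a - mean(vals))
    }
  }
  list(n = nvec, s = svec)
}

# exhaustive nearest-foreground-voxel search (mm), small grids only
oracle_edt <- function(mask, spacing) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dims)
  if (nrow(fg) == 0) return(out)
  fg_mm <- sweep(fg, 2, spacing, "*")
  all_idx <- which(array(TRUE, dims), arr.ind = TRUE)
  all_mm <- sweep(all_idx, 2, spacing, "*")
  for (r in seq_len(nrow(all_idx))) {
    d2 <- colSums((t(fg_mm) - all_mm[r, ])^2)
    out[all_idx[r, 1], all_idx[r, 2], all_idx[r, 3]] <- sqrt(min(d2))
  }
  out
}

# hand product-limit estimator (no censoring adjustments beyond risk sets)
oracle_km <- function(time, event, t_eval) {
  s <- 1
  for (tt in sort(unique(time[event == 1]))) {
    if (tt > t_eval) break
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

# log-rank by per-event-time hypergeometric bookkeeping (2 groups)
oracle_logrank <- function(time, event, group) {
  g <- sort(unique(group))
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & group == g[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# all-pairs concordance audit
oracle_cindex <- function(lp, time, event) {
  num <- 0; den <- 0
  n <- length(lp)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (event[i] != 1) next
    usable <- time[j] > time[i] || (time[j] == time[i] && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (lp[i] > lp[j]) num <- num + 1
    else if (lp[i] == lp[j]) num <- num + 0.5
  }
  num / den
}

# brute-force Cox partial likelihood (Breslow) over a beta grid, 1 covariate
oracle_cox_grid <- function(x, time, event, grid = seq(-3, 3, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    s <- 0
    for (tt in unique(time[event == 1])) {
      d_idx <- which(time == tt & event == 1)
      risk <- which(time >= tt)
      s <- s + b * sum(x[d_idx]) - length(d_idx) * log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# Youden exhaustive scan (independent of the package rule implementation)
oracle_youden <- function(scores, labels) {
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, j = best_j)
}
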