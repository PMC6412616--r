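# Independent brute-force oracles. These deliberately share no code with
# the package: medians via stats::median over explicitly built windows,
# ranks written out longhand, the signed-rank null enumerated sign
# pattern by sign pattern.

# exhaustive per-window median with edge replication; window anchored at
# floor(side/2) like the package contract
bf_median_filter <- function(x, side) {
  lo <- side %/% 2
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    rs <- pmin(pmax((r - lo):(r - lo + side - 1), 1), nr)
    for (c in seq_len(nc)) {
      cs <- pmin(pmax((c - lo):(c - lo + side - 1), 1), nc)
      out[r, c] <- stats::median(x[rs, cs])
    }
  }
  out
}

# all ordered index pairs i < j
bf_qube_score <- function(v) {
  a <- 0
  b <- 0
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- max(a, v[j] - v[i])
      b <- max(b, v[i] - v[j])
    }
  }
  list(a = a, b = b, score = a + b)
}

# scalar even-odd crossing test with explicit boundary handling
bf_point_in_polygon <- function(pr, pc, v) {
  n <- nrow(v)
  eps <- 1e-9
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1 else i + 1, ]
    # on-segment?
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 > 0) {
      crossp <- (pr - a[1]) * ab[2] - (pc - a[2]) * ab[1]
      dotp <- (pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]
      if (abs(crossp) <= eps * sqrt(len2) && dotp >= -eps && dotp <= len2 + eps) {
        return(TRUE)
      }
    }
    if ((a[1] > pr) != (b[1] > pr)) {
      xint <- a[2] + (pr - a[1]) * (b[2] - a[2]) / (b[1] - a[1])
      if (pc < xint) inside <- !inside
    }
  }
  inside
}

bf_rasterize <- function(v, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in 0:(dims[1] - 1)) {
    for (c in 0:(dims[2] - 1)) {
      mask[r + 1, c + 1] <- bf_point_in_polygon(r, c, v)
    }
  }
  mask
}

# exhaustive integer-shift search maximizing NCC over the overlap,
# ties by smallest norm then row-major
bf_best_shift <- function(ref, frm, radius) {
  best <- -Inf
  best_d <- c(0L, 0L)
  found <- FALSE
  cand <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  cand <- cand[order(cand$dr^2 + cand$dc^2, cand$dr, cand$dc), ]
  nr <- nrow(ref)
  nc <- ncol(ref)
  for (k in seq_len(nrow(cand))) {
    dr <- cand$dr[k]
    dc <- cand$dc[k]
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    a <- as.vector(ref[r0:r1, c0:c1])
    b <- as.vector(frm[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    s <- stats::cor(a, b)
    if (s > best) {
      best <- s
      best_d <- c(dr, dc)
      found <- TRUE
    }
  }
  if (!found) c(0L, 0L) else best_d
}

# mid-ranks written out longhand
bf_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }
  r
}

bf_spearman_rho <- function(x, y) {
  rx <- bf_midranks(x)
  ry <- bf_midranks(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, divided by the tie factor
bf_kruskal_h <- function(groups) {
  x <- unlist(groups)
  r <- bf_midranks(x)
  n <- length(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 0L))
  rbar <- mean(r)
  h <- 0
  for (g in seq_along(groups)) {
    ni <- sum(idx == g)
    h <- h + ni * (mean(r[idx == g]) - rbar)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

bf_lin_ccc <- function(x, y) {
  n <- length(x)
  sxy <- mean(x * y) - mean(x) * mean(y)
  sxx <- mean(x^2) - mean(x)^2
  syy <- mean(y^2) - mean(y)^2
  2 * sxy / (sxx + syy + (mean(x) - mean(y))^2)
}

# exact two-sided signed-rank p by enumerating every sign pattern
bf_wilcoxon_exact <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- bf_midranks(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    vs[m + 1] <- sum(r[signs])
  }
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
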