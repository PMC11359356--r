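# Brute-force oracles, written as direct double loops / enumerations,
# independent of the package's vectorized and compiled implementations.

# random quantized ROI on an n x n grid with a random mask
random_qroi <- function(seed, n = 12, Ng = 6, p_mask = 0.8) {
  set.seed(seed)
  gray <- matrix(runif(n * n, 0, 255), n, n)
  mask <- matrix(runif(n * n) < p_mask, n, n)
  if (!any(mask)) mask[1, 1] <- TRUE
  quantize_roi(gray, mask, Ng)
}

oracle_glcm <- function(q, directions) {
  L <- q$levels; M <- q$mask; Ng <- q$Ng
  C <- matrix(0, Ng, Ng)
  for (d in directions) {
    for (i in seq_len(nrow(L))) {
      for (j in seq_len(ncol(L))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (!M[i, j]) next
        if (i2 < 1 || i2 > nrow(L) || j2 < 1 || j2 > ncol(L)) next
        if (!M[i2, j2]) next
        C[L[i, j], L[i2, j2]] <- C[L[i, j], L[i2, j2]] + 1
        C[L[i2, j2], L[i, j]] <- C[L[i2, j2], L[i, j]] + 1
      }
    }
  }
  p <- C / sum(C)
  asm <- 0; con <- 0; ent <- 0; hom <- 0; dis <- 0; ac <- 0; sa <- 0
  mu <- 0
  for (a in 1:Ng) for (b in 1:Ng) mu <- mu + a * p[a, b]
  v <- 0
  for (a in 1:Ng) for (b in 1:Ng) v <- v + (a - mu)^2 * p[a, b]
  corr <- 0
  for (a in 1:Ng) for (b in 1:Ng) {
    pa <- p[a, b]
    asm <- asm + pa^2
    con <- con + pa * (a - b)^2
    if (pa > 0) ent <- ent - pa * log2(pa)
    hom <- hom + pa / (1 + (a - b)^2)
    dis <- dis + pa * abs(a - b)
    ac <- ac + a * b * pa
    sa <- sa + (a + b) * pa
    if (v > 0) corr <- corr + (a - mu) * (b - mu) * pa / v
  }
  c(asm, con, ent, mu, v, corr, hom, dis, ac, sa)
}

# runs along one direction, scanned pixel by pixel
oracle_glrlm_matrix <- function(q, d) {
  L <- q$levels; M <- q$mask
  nr <- nrow(L); nc <- ncol(L)
  R <- matrix(0, q$Ng, max(nr, nc))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!M[i, j]) next
      pi_ <- i - d[1]; pj <- j - d[2]
      inside <- pi_ >= 1 && pi_ <= nr && pj >= 1 && pj <= nc
      if (inside && M[pi_, pj] && L[pi_, pj] == L[i, j]) next  # not a start
      len <- 1
      ci <- i + d[1]; cj <- j + d[2]
      while (ci >= 1 && ci <= nr && cj >= 1 && cj <= nc &&
             M[ci, cj] && L[ci, cj] == L[i, j]) {
        len <- len + 1; ci <- ci + d[1]; cj <- cj + d[2]
      }
      R[L[i, j], len] <- R[L[i, j], len] + 1
    }
  }
  R
}

oracle_glrlm_features <- function(q, directions) {
  Rs <- lapply(directions, function(d) oracle_glrlm_matrix(q, d))
  R <- Reduce(`+`, Rs) / length(Rs)
  np <- sum(q$mask)
  nr <- sum(R)
  out <- numeric(13)
  mui <- 0; mul <- 0
  for (a in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    mui <- mui + a * R[a, l] / nr
    mul <- mul + l * R[a, l] / nr
  }
  for (a in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    r <- R[a, l]
    out[1] <- out[1] + r / l^2
    out[2] <- out[2] + r * l^2
    out[6] <- out[6] + r / a^2
    out[7] <- out[7] + r * a^2
    out[8] <- out[8] + r / (a^2 * l^2)
    out[9] <- out[9] + r * a^2 / l^2
    out[10] <- out[10] + r * l^2 / a^2
    out[11] <- out[11] + r * a^2 * l^2
    out[12] <- out[12] + r / nr * (a - mui)^2
    out[13] <- out[13] + r / nr * (l - mul)^2
  }
  out[1] <- out[1] / nr; out[2] <- out[2] / nr
  out[3] <- sum(rowSums(R)^2) / nr
  out[4] <- sum(colSums(R)^2) / nr
  out[5] <- nr / np
  out[6] <- out[6] / nr; out[7] <- out[7] / nr
  out[8] <- out[8] / nr; out[9] <- out[9] / nr
  out[10] <- out[10] / nr; out[11] <- out[11] / nr
  out
}

# 8-connected zones by breadth-first search
oracle_glszm_zones <- function(q) {
  L <- q$levels; M <- q$mask
  nr <- nrow(L); nc <- ncol(L)
  seen <- matrix(FALSE, nr, nc)
  zones <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!M[i, j] || seen[i, j]) next
    lev <- L[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (seen[ni, nj] || !M[ni, nj] || L[ni, nj] != lev) next
        seen[ni, nj] <- TRUE
        queue[[length(queue) + 1]] <- c(ni, nj)
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_glszm_features <- function(q) {
  z <- oracle_glszm_zones(q)
  nz <- nrow(z); np <- sum(q$mask)
  i <- z[, 1]; s <- z[, 2]
  gln <- 0
  for (lev in unique(i)) gln <- gln + sum(i == lev)^2
  zsn <- 0
  for (sz in unique(s)) zsn <- zsn + sum(s == sz)^2
  c(mean(1 / s^2), mean(s^2), gln / nz, zsn / nz, nz / np,
    mean(1 / i^2), mean(i^2), mean(1 / (i^2 * s^2)), mean(i^2 / s^2),
    mean(s^2 / i^2), mean(i^2 * s^2),
    mean((i - mean(i))^2), mean((s - mean(s))^2))
}

oracle_ngtdm_features <- function(q) {
  L <- q$levels; M <- q$mask; Ng <- q$Ng
  nr <- nrow(L); nc <- ncol(L)
  s <- numeric(Ng); n <- numeric(Ng)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!M[i, j]) next
    tot <- 0; cnt <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > nr || nj < 1 || nj > nc || !M[ni, nj]) next
      tot <- tot + L[ni, nj]; cnt <- cnt + 1
    }
    if (cnt == 0) next
    s[L[i, j]] <- s[L[i, j]] + abs(L[i, j] - tot / cnt)
    n[L[i, j]] <- n[L[i, j]] + 1
  }
  N <- sum(n)
  p <- n / N
  act <- which(p > 0); ngp <- length(act)
  den <- sum(p * s)
  coar <- if (den > 1e-6) 1 / den else 1e6
  con <- 0; bden <- 0; comp <- 0; ts <- 0
  for (a in act) for (b in act) {
    con <- con + p[a] * p[b] * (a - b)^2
    bden <- bden + abs(a * p[a] - b * p[b])
    comp <- comp + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    ts <- ts + (p[a] + p[b]) * (a - b)^2
  }
  con <- if (ngp > 1) con / (ngp * (ngp - 1)) * sum(s) / N else 0
  bus <- if (bden > 0) den / bden else 0
  comp <- if (ngp > 1) comp / N else 0
  ts <- if (sum(s) > 0) ts / sum(s) else 0
  c(coar, con, bus, comp, ts)
}

# full enumeration of the Mann-Whitney null: all assignments of the pooled
# sample to group labels; two-sided p by distance of U from its mean.
# The observed U is the direct pair count; the enumerated U values use the
# rank-sum identity U = R1 - n1(n1+1)/2 (tie-free inputs).
oracle_mw_enumeration <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1); n <- length(pooled)
  u <- 0
  for (x in g1) for (y in g2) u <- u + (x > y) + 0.5 * (x == y)
  mu <- n1 * (n - n1) / 2
  rk <- rank(pooled)
  combs <- utils::combn(n, n1)
  us <- colSums(matrix(rk[combs], n1)) - n1 * (n1 + 1) / 2
  list(U = u, p = mean(abs(us - mu) >= abs(u - mu) - 1e-12))
}
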