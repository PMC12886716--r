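# Brute-force reference implementations used as independent oracles.
# Deliberately naive (explicit loops, no shared code with the package).

bf_huber <- function(a, b, phi = 1) {
  tot <- 0
  for (i in seq_along(a)) {
    d <- abs(a[i] - b[i])
    tot <- tot + if (d < phi) d^2 / (2 * phi) else d - phi / 2
  }
  tot / length(a)
}

bf_bce <- function(p, label) -(label * log(p) + (1 - label) * log(1 - p))

bf_tv <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  tot <- 0
  for (c in seq_len(dim(img)[3]))
    for (n in seq_len(dim(img)[1]))
      for (m in seq_len(dim(img)[2])) {
        if (n < dim(img)[1]) tot <- tot + abs(img[n + 1, m, c] - img[n, m, c])
        if (m < dim(img)[2]) tot <- tot + abs(img[n, m + 1, c] - img[n, m, c])
      }
  tot
}

bf_smth <- function(dy, dx) {
  tot <- 0
  for (comp in list(dy, dx))
    for (x in seq_len(nrow(comp)))
      for (y in seq_len(ncol(comp))) {
        if (x < nrow(comp)) tot <- tot + (comp[x + 1, y] - comp[x, y])^2
        if (y < ncol(comp)) tot <- tot + (comp[x, y + 1] - comp[x, y])^2
      }
  tot / length(dy)
}

bf_mse <- function(a, b) {
  tot <- 0
  for (i in seq_along(a)) tot <- tot + (a[i] - b[i])^2
  tot / length(a)
}

bf_psnr <- function(a, b) 10 * log10(max(b)^2 / bf_mse(a, b))

bf_d_iou <- function(m1, m2, f = 8, thr = 0.01) {
  H <- f * ceiling(nrow(m1) / f); W <- f * ceiling(ncol(m1) / f)
  pad <- function(m) { p <- matrix(0, H, W); p[seq_len(nrow(m)), seq_len(ncol(m))] <- m; p }
  m1 <- pad(m1 * 1); m2 <- pad(m2 * 1)
  num <- den <- 0
  for (bi in seq_len(H / f)) for (bj in seq_len(W / f)) {
    r <- (bi - 1) * f + seq_len(f); c <- (bj - 1) * f + seq_len(f)
    p1 <- mean(m1[r, c]) > thr
    p2 <- mean(m2[r, c]) > thr
    num <- num + p1 * p2
    den <- den + min(p1 + p2, 1)
  }
  if (den == 0) 1 else num / den
}

# windowed SSIM on a luminance matrix, explicit loops over valid positions
bf_ssim <- function(a, b, win = 11, sigma = 1.5, K = c(0.01, 0.03), L = 1) {
  lum <- function(x) {
    if (is.matrix(x)) return(x)
    0.2989 * x[, , 1] + 0.5870 * x[, , 2] + 0.1140 * x[, , 3]
  }
  a <- lum(a); b <- lum(b)
  r <- seq_len(win) - (win + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (K[1] * L)^2; C2 <- (K[2] * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - win + 1))
    for (j in seq_len(ncol(a) - win + 1)) {
      pa <- a[i + seq_len(win) - 1, j + seq_len(win) - 1]
      pb <- b[i + seq_len(win) - 1, j + seq_len(win) - 1]
      mua <- sum(w * pa); mub <- sum(w * pb)
      va <- sum(w * pa^2) - mua^2; vb <- sum(w * pb^2) - mub^2
      cab <- sum(w * pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  mean(vals)
}

# connected-component labeling by breadth-first search
bf_count_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cnt <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] > 0) next
    cnt <- cnt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cnt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- cnt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  cnt
}

# central-difference numeric gradient of a scalar function
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_img <- function(h, w, c = 3, seed = 1) {
  set.seed(seed)
  array(runif(h * w * c), c(h, w, c))
}
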