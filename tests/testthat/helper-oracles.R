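# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and direct formula evaluation only.

# exhaustive between-class-variance maximisation; lowest maximiser
oracle_otsu <- function(levels, counts) {
  p <- counts / sum(counts)
  best_t <- NA_integer_; best <- -Inf
  for (i in seq_along(levels)) {
    w0 <- sum(p[seq_len(i)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[seq_len(i)] * levels[seq_len(i)]) / w0
    mu1 <- sum(p[-seq_len(i)] * levels[-seq_len(i)]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best) { best <- s; best_t <- levels[i] }
  }
  best_t
}

# exhaustive Kapur entropy-sum maximisation; lowest maximiser
oracle_kapur <- function(levels, counts) {
  p <- counts / sum(counts)
  best_t <- NA_integer_; best <- -Inf
  for (i in seq_along(levels)) {
    pb <- p[seq_len(i)]; pf <- p[-seq_len(i)]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    qb <- pb[pb > 0] / Pb
    qf <- pf[pf > 0] / Pf
    H <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (H > best) { best <- H; best_t <- levels[i] }
  }
  best_t
}

# naive double-loop raw moment over a (u, v) pixel matrix
oracle_moment <- function(region, p, q) {
  s <- 0
  for (i in seq_len(nrow(region)))
    s <- s + region[i, 1]^p * region[i, 2]^q
  unname(s)
}

oracle_central_moment <- function(region, p, q) {
  xb <- oracle_moment(region, 1, 0) / nrow(region)
  yb <- oracle_moment(region, 0, 1) / nrow(region)
  s <- 0
  for (i in seq_len(nrow(region)))
    s <- s + (region[i, 1] - xb)^p * (region[i, 2] - yb)^q
  unname(s)
}

# flood-fill connected-component labelling (stack-based BFS), selectable
# connectivity, labels in raster-scan (row-major) order of first pixel
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nextlab <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nextlab
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; c2 <- cur[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nextlab
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  list(labels = lab, count = nextlab)
}

# direct loop implementation of one Crimmins iteration (dark then light
# pass, four directions, reflective out-of-frame neighbours)
oracle_crimmins <- function(m, iterations) {
  nr <- nrow(m); nc <- ncol(m)
  ref <- function(i, n) { if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i }
  get3 <- function(img, r, cc, dr, dc)
    c(img[ref(r - dr, nr), ref(cc - dc, nc)], img[r, cc],
      img[ref(r + dr, nr), ref(cc + dc, nc)])
  dirs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (it in seq_len(iterations)) {
    for (s in c(1, -1)) {
      for (d in dirs) {
        for (step in 1:4) {
          new <- m
          for (r in seq_len(nr)) for (cc in seq_len(nc)) {
            abc <- get3(m, r, cc, d[1], d[2])
            a <- s * (abc[1] - abc[2]); c3 <- s * (abc[3] - abc[2])
            hit <- switch(step,
                          a >= 2,
                          a > 0 && c3 >= 0,
                          c3 > 0 && a >= 0,
                          c3 >= 2)
            if (hit) new[r, cc] <- new[r, cc] + s
          }
          m <- new
        }
      }
    }
  }
  m
}

# rasterise a filled ellipse (centre cx, cy; semi-axes a, b; rotation theta)
# as a 0-based (u, v) pixel matrix
render_ellipse_region <- function(a, b, theta = 0, cx = 0, cy = 0) {
  w <- ceiling(max(a, b)) + 2
  us <- seq(floor(cx - w), ceiling(cx + w))
  vs <- seq(floor(cy - w), ceiling(cy + w))
  out <- matrix(NA_real_, 0, 2)
  ct <- cos(theta); st <- sin(theta)
  for (v in vs) {
    du <- us - cx; dv <- v - cy
    x <- du * ct + dv * st
    y <- -du * st + dv * ct
    keep <- (x / a)^2 + (y / b)^2 <= 1
    if (any(keep)) out <- rbind(out, cbind(us[keep], v))
  }
  colnames(out) <- c("u", "v")
  out
}

random_histogram <- function(n_levels = 64, max_count = 40) {
  counts <- sample.int(max_count + 1L, n_levels, replace = TRUE) - 1L
  while (sum(counts > 0) < 2L)
    counts <- sample.int(max_count + 1L, n_levels, replace = TRUE) - 1L
  counts
}

random_region <- function(n = 50, span = 20) {
  repeat {
    px <- unique(cbind(u = sample.int(span, n, replace = TRUE),
                       v = sample.int(span, n, replace = TRUE)))
    if (nrow(px) >= 2) return(px)
  }
}
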