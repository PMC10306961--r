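# fixtures and brute-force oracles, independent of the implementation paths

make_grid <- function(values, dim3 = NULL, spacing = c(1, 1, 1), ...) {
  if (!is.null(dim3)) values <- array(values, dim3)
  voxel_grid(values, spacing = spacing, ...)
}

random_grid <- function(shape, lo = 0, hi = 10, spacing = c(1, 1, 1)) {
  make_grid(runif(prod(shape), lo, hi), shape, spacing = spacing)
}

# --- first-order oracle: plain sort/moment arithmetic on the raw vector ----
oracle_first_order <- function(x) {
  n <- length(x)
  xs <- sort(x)
  md <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  list(mean = mu, median = md, min = xs[1], max = xs[n],
       range = xs[n] - xs[1],
       sd = if (n > 1) sqrt(sum((x - mu)^2) / (n - 1)) else 0,
       skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 - 3 else NA_real_,
       energy = sum(x^2),
       max_ad_md = max(abs(x - md)))
}

# --- GLCM oracle: exhaustive loop over voxel pairs for one offset ----------
oracle_glcm <- function(lev, off, L) {
  d <- dim(lev)
  m <- matrix(0, L, L)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
    if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] && zz >= 1 && zz <= d[3]) {
      a <- lev[x, y, z]; b <- lev[xx, yy, zz]
      m[a, b] <- m[a, b] + 1
    }
  }
  m <- m + t(m)
  if (sum(m) == 0) NULL else m / sum(m)
}

# --- GLRLM oracle: walk every lattice line voxel by voxel ------------------
oracle_glrlm <- function(lev, off, L) {
  d <- dim(lev)
  counts <- list()
  bump <- function(g, len) {
    key <- paste(g, len)
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  inside <- function(p) all(p >= 1) && all(p <= d)
  seen <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inside(p - off)) next           # not a line start
    # walk the whole line from its start
    run_g <- -1L; run_len <- 0L
    q <- p
    while (inside(q)) {
      g <- lev[q[1], q[2], q[3]]
      if (g == run_g) run_len <- run_len + 1L
      else {
        if (run_len > 0L) bump(run_g, run_len)
        run_g <- g; run_len <- 1L
      }
      q <- q + off
    }
    if (run_len > 0L) bump(run_g, run_len)
  }
  rmax <- max(vapply(names(counts), function(k)
    as.integer(strsplit(k, " ")[[1]][2]), integer(1)))
  m <- matrix(0, L, rmax)
  for (k in names(counts)) {
    gl <- as.integer(strsplit(k, " ")[[1]])
    m[gl[1], gl[2]] <- counts[[k]]
  }
  m
}

# brute-force hottest cubic window (all positions, direct means)
oracle_hottest <- function(vals, k) {
  d <- dim(vals)
  best <- -Inf
  for (x in seq_len(d[1] - k + 1)) for (y in seq_len(d[2] - k + 1))
    for (z in seq_len(d[3] - k + 1)) {
      m <- mean(vals[x:(x + k - 1), y:(y + k - 1), z:(z + k - 1)])
      if (m > best) best <- m
    }
  best
}
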