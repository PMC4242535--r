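# Independent brute-force oracles for the threshold criteria. These are
# deliberately written as naive loops over every candidate threshold,
# sharing no code with the package internals, so that agreement between the
# two routes is meaningful.

oracle_otsu <- function(counts) {
  g <- 0:255
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    left <- 1:(t + 1); right <- if (t < 255) (t + 2):256 else integer(0)
    n0 <- sum(counts[left]); n1 <- sum(counts[right])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(g[left] * counts[left]) / n0
    mu1 <- sum(g[right] * counts[right]) / n1
    w0 <- n0 / (n0 + n1); w1 <- 1 - w0
    obj <- w0 * w1 * (mu0 - mu1)^2
    if (obj > best) { best <- obj; bt <- t }
  }
  bt
}

oracle_isodata <- function(counts) {
  g <- 0:255
  nz <- which(counts > 0) - 1L
  for (t in min(nz):(max(nz) - 1L)) {
    left <- 1:(t + 1); right <- (t + 2):256
    n0 <- sum(counts[left]); n1 <- sum(counts[right])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(g[left] * counts[left]) / n0
    mu1 <- sum(g[right] * counts[right]) / n1
    if (t >= (mu0 + mu1) / 2) return(t)
  }
  NA_integer_
}

oracle_max_entropy <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    h0 <- 0
    for (i in 1:(t + 1)) if (p[i] > 0) h0 <- h0 - (p[i] / P0) * log(p[i] / P0)
    h1 <- 0
    for (i in (t + 2):256) if (p[i] > 0) h1 <- h1 - (p[i] / P1) * log(p[i] / P1)
    if (h0 + h1 > best) { best <- h0 + h1; bt <- t }
  }
  bt
}

oracle_min_error <- function(counts) {
  g <- 0:255
  best <- Inf; bt <- NA_integer_
  N <- sum(counts)
  for (t in 0:254) {
    left <- 1:(t + 1); right <- (t + 2):256
    n0 <- sum(counts[left]); n1 <- sum(counts[right])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(g[left] * counts[left]) / n0
    mu1 <- sum(g[right] * counts[right]) / n1
    v0 <- sum(counts[left] * (g[left] - mu0)^2) / n0
    v1 <- sum(counts[right] * (g[right] - mu1)^2) / n1
    if (v0 <= 1e-7 || v1 <= 1e-7) next
    w0 <- n0 / N; w1 <- n1 / N
    J <- 1 + 2 * (w0 * log(sqrt(v0)) + w1 * log(sqrt(v1))) -
      2 * (w0 * log(w0) + w1 * log(w1))
    if (J < best) { best <- J; bt <- t }
  }
  bt
}

# plateau-aware mode structure: condenses the sequence to runs by a scan,
# then compares each run against its differing neighbours.
oracle_mode_structure <- function(y) {
  n <- length(y)
  keep <- c(TRUE, y[-1] != y[-n])
  v <- y[keep]
  first <- which(keep)
  last <- c(first[-1] - 1L, n)
  k <- length(v)
  ismax <- logical(k); ismin <- logical(k)
  for (i in seq_len(k)) {
    okl <- i == 1 || v[i - 1] < v[i]
    okr <- i == k || v[i + 1] < v[i]
    ismax[i] <- okl && okr
    okl <- i == 1 || v[i - 1] > v[i]
    okr <- i == k || v[i + 1] > v[i]
    ismin[i] <- okl && okr
  }
  list(v = v, first = first, last = last, ismax = ismax, ismin = ismin)
}

# valley gray span between exactly two modes, or NULL
oracle_valley <- function(y, offset_to_gray = function(i) i - 1L) {
  st <- oracle_mode_structure(y)
  im <- which(st$ismax)
  if (length(im) != 2L) return(NULL)
  mid <- (im[1] + 1L):(im[2] - 1L)
  vm <- mid[st$ismin[mid]]
  if (length(vm) != 1L) return(NULL)
  c(st$first[vm], st$last[vm])
}

oracle_minimum <- function(counts, max_passes = 10000L) {
  y <- as.numeric(counts)
  passes <- 0L
  repeat {
    valley <- oracle_valley(y)
    if (!is.null(valley)) {
      return(list(t = floor((valley[1] - 1L + valley[2] - 1L) / 2), passes = passes))
    }
    if (passes >= max_passes) return(NULL)
    y <- (c(y[1], y[-256]) + y + c(y[-1], y[256])) / 3
    passes <- passes + 1L
  }
}

oracle_minimum_histogram <- function(counts) {
  for (w in 1:128) {
    nb <- ceiling(256 / w)
    b <- numeric(nb)
    for (i in 0:255) b[i %/% w + 1L] <- b[i %/% w + 1L] + counts[i + 1L]
    valley <- oracle_valley(b)
    if (!is.null(valley)) {
      lo <- (valley[1] - 1L) * w
      hi <- min(valley[2] * w - 1L, 255L)
      return(list(t = floor((lo + hi) / 2), width = w))
    }
  }
  NULL
}

# brute-force edge value: binarize, enumerate every 4-neighbour pair
oracle_edge_detection <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    veg <- values <= t
    ds <- c()
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (cc < nc && veg[r, cc] != veg[r, cc + 1]) {
        ds <- c(ds, abs(values[r, cc] - values[r, cc + 1]))
      }
      if (r < nr && veg[r, cc] != veg[r + 1, cc]) {
        ds <- c(ds, abs(values[r, cc] - values[r + 1, cc]))
      }
    }
    if (length(ds) == 0) next
    ev <- mean(ds)
    if (ev > best) { best <- ev; bt <- t }
  }
  bt
}

# seeded bimodal mixture histogram: two truncated normals with random
# means, spreads and mixing weight
rand_mixture_hist <- function(seed, n = 20000L) {
  set.seed(seed)
  mu1 <- runif(1, 30, 100); mu2 <- runif(1, 140, 230)
  s1 <- runif(1, 5, 25); s2 <- runif(1, 5, 30)
  w <- runif(1, 0.2, 0.8)
  x <- c(rnorm(round(n * w), mu1, s1), rnorm(n - round(n * w), mu2, s2))
  tabulate(pmin(pmax(round(x), 0), 255) + 1L, 256L)
}
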