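#' Binary vegetation/sky classification map
#'
#' Internal constructor for the result of [binarize()]: an integer matrix
#' with codes 1 = vegetation, 2 = sky, 3 = outside the analyzed area.
#'
#' @param cls Integer matrix of class codes.
#' @return A `binary_map`.
#' @keywords internal
new_binary_map <- function(cls) {
  storage.mode(cls) <- "integer"
  structure(cls, levels = c("vegetation", "sky", "outside"), class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  n <- tabulate(unclass(x), 3L)
  cat(sprintf(
    "<binary_map> %d x %d pixels: %d vegetation, %d sky, %d outside\n",
    ncol(x), nrow(x), n[1], n[2], n[3]
  ))
  invisible(x)
}

#' Binarize a gray image at a global threshold
#'
#' Applies the standard convention of canopy-photo processing: every pixel
#' with a gray value below or equal to the threshold is classified as
#' vegetation, every brighter pixel as sky. Pixels outside the mask are
#' classified `outside`.
#'
#' @param image A [gray_image()].
#' @param t Integer threshold in \[0, 255\].
#' @return A `binary_map`.
#' @export
binarize <- function(image, t) {
  stopifnot(inherits(image, "gray_image"))
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255) {
    stop("threshold must be a single gray value in [0, 255]")
  }
  cls <- ifelse(image$values <= t, 1L, 2L)
  cls[!image$mask] <- 3L
  new_binary_map(cls)
}

#' Gap fraction of a binarized photograph
#'
#' The proportion of analyzed (non-outside) pixels classified as sky,
#' computed over the whole map without any zenith-angle weighting. This is
#' the quantity sometimes called canopy openness or sky-view factor.
#'
#' @param binary A `binary_map`.
#' @return Proportion of sky pixels in \[0, 1\].
#' @export
gap_fraction <- function(binary) {
  stopifnot(inherits(binary, "binary_map"))
  cls <- unclass(binary)
  n_in <- sum(cls != 3L)
  if (n_in == 0L) stop("all pixels are outside the analyzed area")
  sum(cls == 2L) / n_in
}

# ---- threshold result container ------------------------------------------

new_threshold_result <- function(method, threshold, objective = NULL,
                                 iterations = 0L, converged = TRUE,
                                 note = NULL) {
  structure(
    list(
      method = method,
      threshold = as.integer(threshold),
      objective = objective,
      iterations = as.integer(iterations),
      converged = isTRUE(converged),
      note = note
    ),
    class = "canopy_threshold"
  )
}

#' @export
print.canopy_threshold <- function(x, ...) {
  cat(sprintf("<canopy_threshold> method = %s, t = %d%s\n",
              x$method, x$threshold,
              if (x$converged) "" else " (NOT converged)"))
  if (x$iterations > 0L) cat(sprintf("  iterations: %d\n", x$iterations))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Plot the objective trace of a threshold search
#'
#' @param x A `canopy_threshold` with a recorded objective trace.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.canopy_threshold <- function(x, ...) {
  if (is.null(x$objective)) stop("no objective trace recorded for method ", x$method)
  graphics::plot(x$objective$candidate_t, x$objective$objective, type = "l",
                 xlab = "candidate threshold", ylab = "objective",
                 main = x$method, ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

# per-threshold class statistics shared by the histogram criteria.
# index i corresponds to t = i - 1; class 0 = gray values <= t.
.hist_class_stats <- function(counts) {
  p <- counts / sum(counts)
  g <- 0:255
  w0 <- cumsum(p)
  w1 <- 1 - w0
  s1 <- cumsum(p * g)
  s2 <- cumsum(p * g^2)
  mu0 <- ifelse(w0 > 0, s1 / w0, NA_real_)
  mu1 <- ifelse(w1 > 0, (s1[256] - s1) / w1, NA_real_)
  var0 <- ifelse(w0 > 0, s2 / w0 - mu0^2, NA_real_)
  var1 <- ifelse(w1 > 0, (s2[256] - s2) / w1 - mu1^2, NA_real_)
  list(p = p, w0 = w0, w1 = w1, mu0 = mu0, mu1 = mu1,
       var0 = pmax(var0, 0), var1 = pmax(var1, 0))
}

.check_histogram_input <- function(hist) {
  hist <- as_gray_histogram(hist)
  if (sum(unclass(hist) > 0L) < 2L) {
    stop("histogram has fewer than two distinct nonzero gray values; no valid split exists")
  }
  as.numeric(hist)
}

.objective_frame <- function(obj, admissible) {
  data.frame(candidate_t = (0:255)[admissible], objective = obj[admissible])
}

# smallest t maximizing/minimizing an objective over admissible candidates
.arg_best <- function(obj, admissible, maximize = TRUE) {
  idx <- which(admissible)
  if (length(idx) == 0L) return(NA_integer_)
  vals <- obj[idx]
  best <- if (maximize) max(vals) else min(vals)
  idx[which(vals == best)[1L]] - 1L
}

# ---- the seven algorithms -------------------------------------------------

#' Otsu's threshold (maximum between-class variance)
#'
#' Exhaustively evaluates the between-class variance
#' \eqn{\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2} for every candidate
#' threshold with two nonempty classes (class 0 = gray values \eqn{\le t})
#' and returns the smallest maximizing threshold.
#'
#' @param hist A `gray_histogram` (or a 256-vector of counts).
#' @return A `canopy_threshold` with the objective trace.
#' @export
threshold_otsu <- function(hist) {
  counts <- .check_histogram_input(hist)
  st <- .hist_class_stats(counts)
  admissible <- st$w0 > 0 & st$w1 > 0
  obj <- st$w0 * st$w1 * (st$mu0 - st$mu1)^2
  t <- .arg_best(obj, admissible, maximize = TRUE)
  new_threshold_result("otsu", t, .objective_frame(obj, admissible))
}

#' IsoData (Ridler--Calvard) threshold
#'
#' Scans candidate thresholds upward from the smallest occupied gray value
#' and returns the first threshold at or above the midpoint of the two class
#' means, \eqn{t \ge (\mu_0(t)+\mu_1(t))/2} — the intersection-point form of
#' the Ridler--Calvard fixed point.
#'
#' @inheritParams threshold_otsu
#' @return A `canopy_threshold`; `iterations` is the number of candidates
#'   scanned. If no candidate satisfies the condition before the last
#'   occupied gray value, the last scanned candidate is returned with
#'   `converged = FALSE` and a warning.
#' @export
threshold_isodata <- function(hist) {
  counts <- .check_histogram_input(hist)
  st <- .hist_class_stats(counts)
  nz <- which(counts > 0) - 1L
  gmin <- min(nz); gmax <- max(nz)
  iterations <- 0L
  for (t in gmin:(gmax - 1L)) {
    iterations <- iterations + 1L
    mid <- (st$mu0[t + 1L] + st$mu1[t + 1L]) / 2
    if (t >= mid) {
      return(new_threshold_result("isodata", t, iterations = iterations))
    }
  }
  warning("IsoData scan reached the last occupied gray value without a fixed point; ",
          "returning the last candidate")
  new_threshold_result("isodata", gmax - 1L, iterations = iterations,
                       converged = FALSE,
                       note = "no fixed point before the last occupied gray value")
}

#' Maximum-entropy (Kapur--Sahoo--Wong) threshold
#'
#' Maximizes the sum of the Shannon entropies of the two class-conditional
#' gray-value distributions induced by the threshold. Zero-probability bins
#' contribute nothing; candidates leaving either class empty are excluded;
#' ties break to the smallest threshold.
#'
#' @inheritParams threshold_otsu
#' @return A `canopy_threshold` with the objective trace.
#' @export
threshold_max_entropy <- function(hist) {
  counts <- .check_histogram_input(hist)
  p <- counts / sum(counts)
  P0 <- cumsum(p)
  P1 <- 1 - P0
  plogp <- ifelse(p > 0, p * log(p), 0)
  A <- cumsum(plogp)
  Atot <- A[256]
  H0 <- ifelse(P0 > 0, log(P0) - A / P0, NA_real_)
  H1 <- ifelse(P1 > 0, log(P1) - (Atot - A) / P1, NA_real_)
  admissible <- P0 > 0 & P1 > 0
  obj <- H0 + H1
  t <- .arg_best(obj, admissible, maximize = TRUE)
  new_threshold_result("max_entropy", t, .objective_frame(obj, admissible))
}

#' Minimum-error (Kittler--Illingworth) threshold
#'
#' Models the two classes as Gaussians and minimizes the average
#' classification-error criterion
#' \eqn{J(t) = 1 + 2[\omega_0\ln\sigma_0 + \omega_1\ln\sigma_1]
#'      - 2[\omega_0\ln\omega_0 + \omega_1\ln\omega_1]}
#' by exhaustive scan (not the iterative variant, which depends on its
#' starting point). Candidates where either class has zero variance are
#' inadmissible.
#'
#' The criterion is known to be unstable on effectively unimodal histograms;
#' if the chosen threshold leaves one class with less than 1% of the pixels,
#' the result is flagged `converged = FALSE` with a warning.
#'
#' @inheritParams threshold_otsu
#' @return A `canopy_threshold` with the objective trace.
#' @export
threshold_min_error <- function(hist) {
  counts <- .check_histogram_input(hist)
  st <- .hist_class_stats(counts)
  # classes concentrated on one gray value have true variance 0; the
  # cumulative-moment computation can leave ~1e-9 of cancellation noise
  # there, so the admissibility cut sits well above it (any real two-value
  # class of an 8-bit histogram has variance >= 1/n)
  admissible <- st$w0 > 0 & st$w1 > 0 & st$var0 > 1e-7 & st$var1 > 1e-7
  if (!any(admissible)) {
    stop("minimum-error criterion has no admissible threshold ",
         "(a class with nonzero variance is required on both sides of every split)")
  }
  obj <- 1 + (st$w0 * log(st$var0) + st$w1 * log(st$var1)) -
    2 * (st$w0 * log(st$w0) + st$w1 * log(st$w1))
  t <- .arg_best(obj, admissible, maximize = FALSE)
  res <- new_threshold_result("min_error", t, .objective_frame(obj, admissible))
  wmin <- min(st$w0[t + 1L], st$w1[t + 1L])
  if (wmin < 0.01) {
    warning("minimum-error threshold leaves a class with weight ",
            format(wmin, digits = 3),
            "; the histogram is probably not a two-Gaussian mixture")
    res$converged <- FALSE
    res$note <- "degenerate split: minority class weight < 1%"
  }
  res
}

# run-length local extrema with plateau handling: a plateau of equal values
# counts as a single extremum, judged against its nearest differing
# neighbours. Returns, per run, value / first index / last index / type.
.runs_extrema <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  left <- c(NA, r$values[-k])
  right <- c(r$values[-1], NA)
  is_max <- (is.na(left) | left < r$values) & (is.na(right) | right < r$values)
  is_min <- (is.na(left) | left > r$values) & (is.na(right) | right > r$values)
  data.frame(value = r$values, first = first, last = last,
             is_max = is_max, is_min = is_min)
}

# the valley between exactly two modes: runs strictly between the two
# maximum runs that are local minima; returns NULL unless there is exactly
# one, else c(first_index, last_index) of the minimum plateau (1-based).
.unique_valley <- function(runs) {
  imax <- which(runs$is_max)
  if (length(imax) != 2L) return(NULL)
  between <- runs[(imax[1] + 1L):(imax[2] - 1L), , drop = FALSE]
  vmin <- between[between$is_min, , drop = FALSE]
  if (nrow(vmin) != 1L) return(NULL)
  c(vmin$first, vmin$last)
}

#' Minimum threshold (iterative histogram smoothing)
#'
#' Repeatedly smooths the histogram with a three-point moving average
#' (edge-replicated boundaries, floating-point accumulation) until exactly
#' two local maxima remain, then returns the gray value of the unique
#' minimum between the two modes. A plateau of equal counts is treated as a
#' single extremum; if the valley itself is a plateau, the floor of its
#' middle gray value is returned. Smoothing is capped at 10000 passes;
#' histograms that never become bimodal (e.g. unimodal input) raise an
#' error.
#'
#' @inheritParams threshold_otsu
#' @param max_passes Smoothing-pass cap before giving up.
#' @return A `canopy_threshold`; `iterations` is the number of smoothing
#'   passes applied.
#' @export
threshold_minimum <- function(hist, max_passes = 10000L) {
  counts <- .check_histogram_input(hist)
  y <- counts
  passes <- 0L
  repeat {
    runs <- .runs_extrema(y)
    valley <- .unique_valley(runs)
    if (!is.null(valley)) {
      t <- floor(((valley[1] - 1L) + (valley[2] - 1L)) / 2)
      return(new_threshold_result("minimum", t, iterations = passes))
    }
    if (passes >= max_passes) {
      stop("histogram did not become bimodal after ", max_passes,
           " smoothing passes (minimum method requires two modes)")
    }
    y <- (c(y[1], y[-256]) + y + c(y[-1], y[256])) / 3
    passes <- passes + 1L
  }
}

#' Minimum-histogram threshold (increasing bin widths)
#'
#' Rebins the histogram at increasing bin widths w = 1, 2, 3, ... with the
#' left border of the first bin fixed at gray value 0, and stops at the
#' first width at which the binned histogram shows exactly two local maxima
#' with a single local minimum between them. The threshold is the floor of
#' the middle gray value of that minimum bin. Plateaus count as a single
#' extremum. Widths above 128 cannot hold two modes plus a valley, so the
#' scan errors out there.
#'
#' @inheritParams threshold_otsu
#' @return A `canopy_threshold`; `iterations` is the qualifying bin width.
#' @export
threshold_minimum_histogram <- function(hist) {
  counts <- .check_histogram_input(hist)
  for (w in 1:128) {
    bin <- (0:255) %/% w
    binned <- as.numeric(tapply(counts, bin, sum))
    runs <- .runs_extrema(binned)
    valley <- .unique_valley(runs)
    if (!is.null(valley)) {
      lo <- (valley[1] - 1L) * w                      # left gray of first valley bin
      hi <- min(valley[2] * w - 1L, 255L)             # right gray of last valley bin
      t <- floor((lo + hi) / 2)
      return(new_threshold_result("minimum_histogram", t, iterations = w))
    }
  }
  stop("no bin width up to 128 produced two modes with a single minimum between them")
}

#' Edge-detection threshold (maximum boundary contrast)
#'
#' For every candidate threshold the image is conceptually binarized and the
#' Edge Value — the mean absolute gray-value difference over all
#' 4-neighbour pixel pairs (both inside the mask) whose members fall in
#' opposite classes — is computed. The threshold maximizing the Edge Value
#' is returned; candidates producing no class boundary are inadmissible and
#' ties break to the smallest threshold.
#'
#' A pair with gray values a < b straddles the class boundary exactly for
#' thresholds \eqn{a \le t < b}, so the whole trace is accumulated in one
#' pass over the pairs.
#'
#' @param image A [gray_image()].
#' @param stride Candidate-pixel subsampling step; pairs are formed between
#'   grid neighbours `stride` pixels apart. The default 1 evaluates the
#'   exact objective on every pixel pair.
#' @return A `canopy_threshold` with the objective trace.
#' @export
threshold_edge_detection <- function(image, stride = 1L) {
  stopifnot(inherits(image, "gray_image"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  v <- image$values
  m <- image$mask
  if (stride > 1L) {
    ri <- seq(1L, nrow(v), by = stride)
    ci <- seq(1L, ncol(v), by = stride)
    v <- v[ri, ci, drop = FALSE]
    m <- m[ri, ci, drop = FALSE]
  }
  nr <- nrow(v); nc <- ncol(v)
  a <- c(if (nc > 1L) v[, -nc][m[, -nc] & m[, -1L]],
         if (nr > 1L) v[-nr, ][m[-nr, ] & m[-1L, ]])
  b <- c(if (nc > 1L) v[, -1L][m[, -nc] & m[, -1L]],
         if (nr > 1L) v[-1L, ][m[-nr, ] & m[-1L, ]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- hi > lo
  if (!any(keep)) stop("image is constant inside the mask; no threshold separates two classes")
  lo <- lo[keep]; hi <- hi[keep]; d <- as.numeric(hi - lo)
  # pair contributes to all t in [lo, hi - 1]: difference-array accumulation
  add_at <- function(x, idx) {
    out <- numeric(257)
    s <- tapply(x, idx, sum)
    out[as.integer(names(s)) + 1L] <- s
    out
  }
  dsum <- cumsum((add_at(d, lo) - add_at(d, hi))[1:256])
  dcnt <- cumsum((add_at(rep(1, length(d)), lo) - add_at(rep(1, length(d)), hi))[1:256])
  admissible <- dcnt > 0.5
  obj <- ifelse(admissible, dsum / dcnt, NA_real_)
  t <- .arg_best(obj, admissible, maximize = TRUE)
  new_threshold_result("edge_detection", t, .objective_frame(obj, admissible))
}

#' Compute a global binarization threshold
#'
#' Front end dispatching to the seven implemented algorithms. Histogram-based
#' methods accept either a `gray_image` (its masked histogram is used) or a
#' `gray_histogram`; `edge_detection` requires the image itself.
#'
#' @param x A [gray_image()] or, for histogram-based methods, a
#'   `gray_histogram`.
#' @param method One of `"minimum"`, `"minimum_histogram"`,
#'   `"edge_detection"`, `"isodata"`, `"otsu"`, `"max_entropy"`,
#'   `"min_error"`.
#' @param ... Passed to the specific algorithm (e.g. `stride` for
#'   `edge_detection`).
#' @return A `canopy_threshold`.
#' @export
canopy_threshold <- function(x, method = c("minimum", "minimum_histogram",
                                           "edge_detection", "isodata", "otsu",
                                           "max_entropy", "min_error"), ...) {
  method <- match.arg(method)
  if (method == "edge_detection") {
    if (!inherits(x, "gray_image")) {
      stop("edge_detection operates on the image itself, not a histogram")
    }
    return(threshold_edge_detection(x, ...))
  }
  hist <- if (inherits(x, "gray_image")) gray_histogram(x) else as_gray_histogram(x)
  switch(method,
    minimum = threshold_minimum(hist, ...),
    minimum_histogram = threshold_minimum_histogram(hist),
    isodata = threshold_isodata(hist),
    otsu = threshold_otsu(hist),
    max_entropy = threshold_max_entropy(hist),
    min_error = threshold_min_error(hist)
  )
}

#' Names of the implemented threshold algorithms
#' @return Character vector of the seven method names.
#' @export
threshold_methods <- function() {
  c("minimum", "minimum_histogram", "edge_detection",
    "isodata", "otsu", "max_entropy", "min_error")
}
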