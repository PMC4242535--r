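#' Parameters of a synthetic hemispherical canopy scene
#'
#' Bundles the controls of the scene simulator. The defaults describe a
#' moderately closed, foliated canopy photographed on its blue color plane:
#' a strongly bimodal gray-value distribution (dark vegetation, bright and
#' approximately normal sky), a zenith-to-horizon brightness gradient, a
#' small share of mixed boundary pixels, and a choice between
#' histogram-exposure (the brightest scene element is placed exactly at
#' gray value 255, nothing clips) and auto-exposure (a brightness excess is
#' added before clamping, so sky saturates and piles up in a spike at 255).
#' Blooming around saturated pixels is rendered with a small default radius;
#' it only becomes visible when saturation occurs, i.e. under auto-exposure.
#'
#' @param width,height Scene size in pixels.
#' @param canopy_cover Target vegetation proportion in \[0, 1\].
#' @param structure_scale Smoothing length of the procedural canopy field in
#'   pixels; larger values give larger foliage clumps and gaps.
#' @param mixed_fraction_target Proportion of all pixels rendered as
#'   vegetation/sky mixtures along class boundaries.
#' @param mu_veg,sigma_veg Mean and sd of vegetation gray values.
#' @param mu_sky,sigma_sky Mean and sd of sky gray values (`mu_sky` must
#'   exceed `mu_veg`; blue-plane contrast).
#' @param zenith_gradient Peak-to-edge brightness difference in gray levels
#'   (zenith brighter).
#' @param exposure `"histogram"` or `"auto"`.
#' @param clip_excess Brightness offset (gray levels) added before clamping
#'   when `exposure = "auto"`.
#' @param blooming_radius Radius (pixels) within which saturated pixels
#'   brighten neighbouring vegetation; 0 disables blooming.
#' @param seed Integer seed driving the whole generate/render chain.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(width = 512L, height = 512L, canopy_cover = 0.7,
                         structure_scale = 8L, mixed_fraction_target = 0.03,
                         mu_veg = 40, sigma_veg = 15, mu_sky = 200,
                         sigma_sky = 20, zenith_gradient = 30,
                         exposure = c("histogram", "auto"), clip_excess = 60,
                         blooming_radius = 2L, seed = 1L) {
  exposure <- match.arg(exposure)
  if (canopy_cover < 0 || canopy_cover > 1) stop("canopy_cover must be in [0, 1]")
  if (mu_sky <= mu_veg) stop("mu_sky must exceed mu_veg (blue-plane contrast)")
  if (sigma_veg <= 0 || sigma_sky <= 0) stop("sigmas must be positive")
  if (mixed_fraction_target < 0 || mixed_fraction_target >= 1) {
    stop("mixed_fraction_target must be in [0, 1)")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         canopy_cover = canopy_cover,
         structure_scale = as.integer(structure_scale),
         mixed_fraction_target = mixed_fraction_target,
         mu_veg = mu_veg, sigma_veg = sigma_veg,
         mu_sky = mu_sky, sigma_sky = sigma_sky,
         zenith_gradient = zenith_gradient, exposure = exposure,
         clip_excess = clip_excess,
         blooming_radius = as.integer(blooming_radius),
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

# separable box blur with edge replication; applied three times it
# approximates a Gaussian of scale ~ k.
.smooth_field <- function(m, k) {
  if (k <= 1L) return(m)
  pad <- k %/% 2L
  win <- 2L * pad + 1L
  blur_cols <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1L, pad), , drop = FALSE], x,
                x[rep(n, pad), , drop = FALSE])
    cs <- rbind(0, apply(xp, 2L, cumsum))
    (cs[(1:n) + win, , drop = FALSE] - cs[1:n, , drop = FALSE]) / win
  }
  for (i in 1:3) {
    m <- blur_cols(m)
    m <- t(blur_cols(t(m)))
  }
  m
}

#' Generate the ground-truth class map of a synthetic scene
#'
#' Thresholds a seeded, smoothed random field at the quantile that yields
#' the requested canopy cover, then converts pixels adjacent to the
#' vegetation/sky boundary into mixed pixels with a vegetation fraction
#' alpha drawn uniformly on (0, 1), up to the requested share of all
#' pixels. Deterministic under the seed.
#'
#' @param params A [scene_params()].
#' @return An object of class `scene_truth`: list with `class` (integer
#'   matrix, 1 = vegetation, 2 = sky, 3 = mixed) and `alpha` (numeric
#'   matrix; vegetation fraction, 1 for vegetation, 0 for sky).
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  if ((p$canopy_cover == 0 || p$canopy_cover == 1) && p$mixed_fraction_target > 0) {
    stop("a single-class scene has no boundary; set mixed_fraction_target = 0")
  }
  set.seed(p$seed)
  z <- matrix(stats::rnorm(p$height * p$width), p$height, p$width)
  z <- .smooth_field(z, p$structure_scale)
  veg <- z <= stats::quantile(z, p$canopy_cover)
  if (p$canopy_cover == 0) veg[] <- FALSE
  if (p$canopy_cover == 1) veg[] <- TRUE
  cls <- ifelse(veg, 1L, 2L)
  alpha <- ifelse(veg, 1, 0)
  if (p$mixed_fraction_target > 0) {
    h <- nrow(cls); w <- ncol(cls)
    nb_differs <- matrix(FALSE, h, w)
    nb_differs[-h, ] <- nb_differs[-h, ] | (cls[-h, ] != cls[-1L, ])
    nb_differs[-1L, ] <- nb_differs[-1L, ] | (cls[-1L, ] != cls[-h, ])
    nb_differs[, -w] <- nb_differs[, -w] | (cls[, -w] != cls[, -1L])
    nb_differs[, -1L] <- nb_differs[, -1L] | (cls[, -1L] != cls[, -w])
    boundary <- which(nb_differs)
    want <- round(p$mixed_fraction_target * h * w)
    if (length(boundary) > want) {
      boundary <- sample(boundary, want)
    }
    cls[boundary] <- 3L
    alpha[boundary] <- stats::runif(length(boundary))
  }
  structure(list(class = cls, alpha = alpha), class = "scene_truth")
}

#' Render a synthetic scene into a gray image
#'
#' Each pixel's value is the alpha-mixture of a vegetation draw
#' `N(mu_veg, sigma_veg)` and a sky draw `N(mu_sky, sigma_sky)`, plus a
#' radial zenith gradient (brightest at the image center). Under
#' histogram-exposure the result is rescaled so the brightest pixel sits
#' exactly at 255 with no clipped mass; under auto-exposure `clip_excess`
#' is added first and the result clamped, so saturated pixels pile up in a
#' spike at gray value 255.
#'
#' @param truth A [generate_truth()] result.
#' @param params The matching [scene_params()].
#' @return A [gray_image()].
#' @export
render_scene <- function(truth, params) {
  stopifnot(inherits(truth, "scene_truth"), inherits(params, "scene_params"))
  p <- params
  h <- nrow(truth$class); w <- ncol(truth$class)
  set.seed(p$seed + 1000003L)
  V <- matrix(stats::rnorm(h * w, p$mu_veg, p$sigma_veg), h, w)
  S <- matrix(stats::rnorm(h * w, p$mu_sky, p$sigma_sky), h, w)
  val <- truth$alpha * V + (1 - truth$alpha) * S
  if (p$zenith_gradient != 0) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    px <- matrix(rep(0:(w - 1L), each = h), h, w)
    py <- matrix(rep(0:(h - 1L), times = w), h, w)
    r <- sqrt((px - cx)^2 + (py - cy)^2) / (min(w, h) / 2)
    val <- val + p$zenith_gradient * (1 - pmin(r, 1))
  }
  val <- pmax(val, 0)
  if (p$exposure == "histogram") {
    val <- val * (255 / max(val))
  } else {
    val <- pmin(val + p$clip_excess, 255)
  }
  gray_image(matrix(as.integer(round(pmin(pmax(val, 0), 255))), h, w))
}

#' Add blooming around saturated pixels
#'
#' Emulates the blooming artifact of overexposed sensors: vegetation and
#' mixed pixels within `radius` of a saturated (gray 255) pixel are raised
#' toward 255 with a weight that decays with Euclidean distance. Ground
#' truth is never changed — blooming corrupts gray values, not classes,
#' which is exactly why bloomed vegetation is hard to classify.
#'
#' @param image The rendered [gray_image()].
#' @param truth The matching [generate_truth()] result.
#' @param radius Blooming radius in pixels; 0 returns the image unchanged.
#' @return The image with bloomed gray values.
#' @export
apply_blooming <- function(image, truth, radius) {
  stopifnot(inherits(image, "gray_image"), inherits(truth, "scene_truth"))
  radius <- as.integer(radius)
  if (radius <= 0L) return(image)
  sat <- image$values == 255L
  if (!any(sat)) return(image)
  h <- nrow(sat); w <- ncol(sat)
  dist <- matrix(Inf, h, w)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      d <- sqrt(dy^2 + dx^2)
      if (d > radius || (dx == 0L && dy == 0L)) next
      if (max(1L, 1L - dy) > min(h, h - dy)) next
      if (max(1L, 1L - dx) > min(w, w - dx)) next
      src_r <- max(1L, 1L - dy):min(h, h - dy)
      src_c <- max(1L, 1L - dx):min(w, w - dx)
      shifted <- matrix(FALSE, h, w)
      shifted[src_r + dy, src_c + dx] <- sat[src_r, src_c]
      dist[shifted & dist > d] <- d
    }
  }
  affected <- is.finite(dist) & truth$class != 2L & !sat
  wgt <- pmax(0, 1 - dist[affected] / (radius + 1))
  v <- image$values
  v[affected] <- as.integer(round(v[affected] + (255L - v[affected]) * 0.8 * wgt))
  image$values <- v
  image
}

#' Simulate a complete synthetic scene
#'
#' Chains truth generation, rendering and blooming under a single seed.
#'
#' @param params A [scene_params()].
#' @return An object of class `synthetic_scene`: list with `truth`,
#'   `image` and `params`.
#' @export
simulate_scene <- function(params = scene_params()) {
  truth <- generate_truth(params)
  img <- render_scene(truth, params)
  img <- apply_blooming(img, truth, params$blooming_radius)
  structure(list(truth = truth, image = img, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cm <- census_metrics(x$truth, binarize(x$image, 255L))
  cat(sprintf(
    "<synthetic_scene> %d x %d, cover %.2f, exposure %s, census gap fraction %.4f\n",
    x$params$width, x$params$height, x$params$canopy_cover,
    x$params$exposure, cm$gf
  ))
  invisible(x)
}

# resolve mixed pixels into binary truth labels
.truth_binary <- function(truth, alpha_rule = c("half", "exclude")) {
  alpha_rule <- match.arg(alpha_rule)
  lab <- ifelse(truth$alpha >= 0.5, 1L, 2L)   # 1 veg, 2 sky
  keep <- matrix(TRUE, nrow(lab), ncol(lab))
  if (alpha_rule == "exclude") keep <- truth$class != 3L
  list(label = lab, keep = keep)
}

#' Census accuracy of a binarization against ground truth
#'
#' Computes full-population (census) percentage correct, Cohen's kappa and
#' the true gap fraction by comparing a binary map against the scene truth
#' over every analyzed pixel — the oracle a human operator approximates via
#' sampling. Mixed pixels are assigned to vegetation when their vegetation
#' fraction is at least 0.5 (`alpha_rule = "half"`) or dropped from the
#' census (`alpha_rule = "exclude"`).
#'
#' @param truth A [generate_truth()] result.
#' @param binary A `binary_map` of identical dimensions.
#' @param alpha_rule `"half"` or `"exclude"`.
#' @return `list(pc, kappa, gf)`: census percentage correct, census kappa,
#'   and the census gap fraction (true sky proportion).
#' @export
census_metrics <- function(truth, binary, alpha_rule = c("half", "exclude")) {
  stopifnot(inherits(truth, "scene_truth"), inherits(binary, "binary_map"))
  if (!identical(dim(truth$class), dim(unclass(binary)))) {
    stop("truth and binary map dimensions differ")
  }
  tb <- .truth_binary(truth, alpha_rule)
  cls <- unclass(binary)
  keep <- tb$keep & cls != 3L
  if (!any(keep)) stop("no pixels left in the census")
  ref <- tb$label[keep]
  alg <- cls[keep]
  n <- length(ref)
  po <- mean(ref == alg)
  pr_v <- mean(ref == 1L); pa_v <- mean(alg == 1L)
  pe <- pr_v * pa_v + (1 - pr_v) * (1 - pa_v)
  kap <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  list(pc = po, kappa = kap, gf = mean(ref == 2L))
}

#' Label a reference sample from scene ground truth
#'
#' Plays the role of the human operator on synthetic scenes: fills the
#' sample's labels from the per-pixel truth, assigning mixed pixels to
#' vegetation when their vegetation fraction is at least 0.5.
#'
#' @param sample A [stratified_sample()] result drawn from the scene image.
#' @param truth The scene's [generate_truth()] result.
#' @return The sample with labels filled.
#' @export
label_from_truth <- function(sample, truth) {
  stopifnot(inherits(sample, "reference_sample"), inherits(truth, "scene_truth"))
  a <- truth$alpha[cbind(sample$records$y + 1L, sample$records$x + 1L)]
  sample$records$label <- ifelse(a >= 0.5, "vegetation", "sky")
  sample
}

#' Write a synthetic scene to disk
#'
#' Saves the rendered image (PNG), the truth map (PNG with the vegetation
#' fraction quantized to 8 bits) and a JSON sidecar with every generation
#' parameter, so a scene can be archived and regenerated.
#'
#' @param scene A [simulate_scene()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(scene$image$values / 255, file.path(dir, "image.png"))
  png::writePNG(scene$truth$alpha, file.path(dir, "truth_alpha.png"))
  jsonlite::write_json(unclass(scene$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
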