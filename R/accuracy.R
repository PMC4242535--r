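#' Draw a stratified random sample of reference pixels
#'
#' Implements the reference design used for assessing binarization accuracy:
#' the gray-value range is divided into contiguous strata (default 16 strata
#' of 16 gray values each) and a simple random sample without replacement is
#' drawn from the mask-true pixels of every stratum (default 24 per stratum,
#' i.e. 384 pixels in total when all strata are populated). Stratification
#' guarantees that reference pixels cover the whole intensity range, in
#' particular the sparse mid-gray region around the class boundary.
#'
#' @param image A [gray_image()].
#' @param strata_width Stratum width in gray values; must divide 256.
#' @param per_stratum Target sample size per stratum. Strata holding fewer
#'   eligible pixels contribute all of them, with a warning.
#' @param seed Integer RNG seed; the draw is reproducible under it.
#' @return An object of class `reference_sample`: a list with
#'   \describe{
#'     \item{records}{`data.frame(x, y, gray, stratum, label)`, 0-based
#'       pixel coordinates, `label` initialized `NA` (to be filled by an
#'       operator or [label_from_truth()]).}
#'     \item{strata}{`data.frame(stratum, lo, hi, N_h, n_h)` with population
#'       and sample sizes per stratum.}
#'     \item{strata_width, per_stratum, seed, n, N}{design parameters and
#'       totals.}
#'   }
#' @export
stratified_sample <- function(image, strata_width = 16L, per_stratum = 24L,
                              seed = 1L) {
  stopifnot(inherits(image, "gray_image"))
  strata_width <- as.integer(strata_width)
  if (strata_width < 1L || 256L %% strata_width != 0L) {
    stop("strata_width must divide 256")
  }
  if (per_stratum < 1L) stop("per_stratum must be >= 1")
  nh_strata <- 256L %/% strata_width
  h <- nrow(image$values); w <- ncol(image$values)
  idx <- which(image$mask)
  gray <- image$values[idx]
  stratum <- gray %/% strata_width + 1L
  N_h <- tabulate(stratum, nh_strata)
  set.seed(seed)
  rec <- vector("list", nh_strata)
  underfilled <- integer(0)
  for (s in seq_len(nh_strata)) {
    pool <- idx[stratum == s]
    if (length(pool) == 0L) next
    take <- min(per_stratum, length(pool))
    if (take < per_stratum) underfilled <- c(underfilled, s)
    pick <- if (length(pool) == 1L) pool else sample(pool, take)
    rec[[s]] <- data.frame(
      x = (pick - 1L) %/% h,          # 0-based column
      y = (pick - 1L) %% h,           # 0-based row
      gray = image$values[pick],
      stratum = s,
      label = NA_character_
    )
  }
  if (length(underfilled) > 0L) {
    warning("strata with fewer than ", per_stratum, " eligible pixels: ",
            paste(underfilled, collapse = ", "),
            " (all their pixels were taken)")
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  strata <- data.frame(
    stratum = seq_len(nh_strata),
    lo = (seq_len(nh_strata) - 1L) * strata_width,
    hi = seq_len(nh_strata) * strata_width - 1L,
    N_h = N_h,
    n_h = as.integer(tabulate(records$stratum, nh_strata))
  )
  structure(
    list(records = records, strata = strata, strata_width = strata_width,
         per_stratum = as.integer(per_stratum), seed = as.integer(seed),
         n = nrow(records), N = length(idx),
         underfilled = underfilled),
    class = "reference_sample"
  )
}

#' @export
print.reference_sample <- function(x, ...) {
  cat(sprintf(
    "<reference_sample> %d records in %d populated strata (width %d), %d labeled\n",
    x$n, sum(x$strata$n_h > 0L), x$strata_width, sum(!is.na(x$records$label))
  ))
  invisible(x)
}

#' Export a labeling sheet and magnified context chips
#'
#' Writes the sample as a CSV sheet (`label` column empty, to be filled with
#' `vegetation` or `sky`) plus one magnified PNG chip per record showing the
#' surrounding pixels with the reference pixel marked in red, so an operator
#' can judge each pixel in context (position in the hemisphere, blooming,
#' reflection at vegetation). Chips at the image border are padded with
#' mid-gray and flagged in the sheet.
#'
#' @param sample A [stratified_sample()] result.
#' @param image The [gray_image()] the sample was drawn from.
#' @param dir Output directory (created if missing).
#' @param chip_radius Half-width of the context window in pixels.
#' @param zoom Integer magnification factor for the chips.
#' @return Invisibly, the sheet path.
#' @export
export_label_sheet <- function(sample, image, dir, chip_radius = 10L, zoom = 8L) {
  stopifnot(inherits(sample, "reference_sample"), inherits(image, "gray_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chip_dir <- file.path(dir, "chips")
  dir.create(chip_dir, showWarnings = FALSE)
  rec <- sample$records
  h <- nrow(image$values); w <- ncol(image$values)
  r <- as.integer(chip_radius)
  padded <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    cx <- rec$x[i] + 1L; cy <- rec$y[i] + 1L
    rows <- (cy - r):(cy + r); cols <- (cx - r):(cx + r)
    chip <- matrix(0.5, 2L * r + 1L, 2L * r + 1L)
    ok_r <- rows >= 1L & rows <= h; ok_c <- cols >= 1L & cols <= w
    padded[i] <- !all(ok_r) || !all(ok_c)
    chip[ok_r, ok_c] <- image$values[rows[ok_r], cols[ok_c]] / 255
    big <- kronecker(chip, matrix(1, zoom, zoom))
    rgb <- array(big, c(dim(big), 3L))
    ctr <- (r * zoom + 1L):((r + 1L) * zoom)      # the reference pixel block
    rgb[ctr, ctr, 1L] <- pmin(1, rgb[ctr, ctr, 1L] + 0.5)
    rgb[ctr, ctr, 2:3] <- rgb[ctr, ctr, 2:3] * 0.5
    png::writePNG(rgb, file.path(chip_dir, sprintf("chip_%04d.png", i)))
  }
  sheet <- data.frame(rec[c("x", "y", "gray", "stratum")],
                      label = "", padded = padded,
                      chip = sprintf("chips/chip_%04d.png", seq_len(nrow(rec))))
  path <- file.path(dir, "label_sheet.csv")
  utils::write.csv(sheet, path, row.names = FALSE)
  invisible(path)
}

#' Load operator labels back into a reference sample
#'
#' Reads a filled labeling sheet and attaches the labels to the sample.
#' Rows are keyed by pixel coordinates, so their order is free; every row
#' must carry the label `vegetation` or `sky`.
#'
#' @param sample The [stratified_sample()] the sheet was exported from.
#' @param sheet Path to the filled CSV sheet, or an equivalent data frame
#'   with columns `x`, `y`, `label`.
#' @return The sample with `records$label` filled.
#' @export
load_labels <- function(sample, sheet) {
  stopifnot(inherits(sample, "reference_sample"))
  tab <- if (is.character(sheet)) {
    utils::read.csv(sheet, stringsAsFactors = FALSE)
  } else {
    as.data.frame(sheet)
  }
  need <- c("x", "y", "label")
  if (!all(need %in% names(tab))) {
    stop("label sheet must have columns ", paste(need, collapse = ", "))
  }
  key <- paste(tab$x, tab$y)
  if (anyDuplicated(key)) stop("duplicate coordinates in label sheet")
  lab <- trimws(as.character(tab$label))
  bad <- which(!(lab %in% c("vegetation", "sky")))
  if (length(bad) > 0L) {
    stop("unlabeled or unknown label in sheet row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected 'vegetation' or 'sky', got '", lab[bad[1L]], "')")
  }
  skey <- paste(sample$records$x, sample$records$y)
  pos <- match(skey, key)
  if (anyNA(pos)) stop("label sheet does not cover every sampled pixel")
  sample$records$label <- lab[pos]
  sample
}

#' Per-stratum confusion matrices with image marginal proportions
#'
#' Crosses the operator labels of a reference sample (rows) with the
#' algorithm classification (columns) within each stratum, and computes the
#' image marginal proportions `W_V`, `W_S` — the fractions of the stratum's
#' entire pixel population (not the sample) that the algorithm classified as
#' vegetation and sky. The marginals are what makes the sample-based
#' accuracy estimators design-unbiased.
#'
#' @param sample A labeled [stratified_sample()] result.
#' @param binary The `binary_map` under evaluation (derived from `image`).
#' @param image The [gray_image()] both refer to.
#' @return A data frame of class `stratum_confusion`, one row per stratum:
#'   `stratum, lo, hi, N_h, n_h, n_VV, n_VS, n_SV, n_SS, W_V, W_S`
#'   (first confusion subscript = operator/reference label, second =
#'   algorithm label).
#' @export
confusion_by_stratum <- function(sample, binary, image) {
  stopifnot(inherits(sample, "reference_sample"),
            inherits(binary, "binary_map"),
            inherits(image, "gray_image"))
  if (!identical(dim(binary), dim(image$values))) {
    stop("binary map and image dimensions differ")
  }
  rec <- sample$records
  if (anyNA(rec$label)) stop("sample is not fully labeled")
  cls <- unclass(binary)
  alg <- cls[cbind(rec$y + 1L, rec$x + 1L)]
  if (any(alg == 3L)) stop("sampled pixel falls outside the binarized area")
  ref_veg <- rec$label == "vegetation"
  alg_veg <- alg == 1L
  ns <- nrow(sample$strata)
  tab <- function(cond) {
    as.integer(tabulate(rec$stratum[cond], ns))
  }
  out <- sample$strata
  out$n_VV <- tab(ref_veg & alg_veg)
  out$n_VS <- tab(ref_veg & !alg_veg)
  out$n_SV <- tab(!ref_veg & alg_veg)
  out$n_SS <- tab(!ref_veg & !alg_veg)
  # marginals over the full stratum population
  in_mask <- image$mask
  stratum_all <- image$values[in_mask] %/% sample$strata_width + 1L
  veg_all <- cls[in_mask] == 1L
  nveg <- tabulate(stratum_all[veg_all], ns)
  out$W_V <- ifelse(out$N_h > 0L, nveg / out$N_h, 0)
  out$W_S <- ifelse(out$N_h > 0L, 1 - out$W_V, 0)
  class(out) <- c("stratum_confusion", "data.frame")
  out
}

# bias-corrected cell proportions for one stratum; 0/0 cells (empty
# algorithm class with zero marginal) contribute 0 by convention.
.corrected_cells <- function(n_VV, n_VS, n_SV, n_SS, W_V, W_S) {
  ncV <- n_VV + n_SV   # algorithm-vegetation column total
  ncS <- n_VS + n_SS
  rat <- function(num, den) ifelse(den > 0L, num / den, 0)
  list(
    p_VV = W_V * rat(n_VV, ncV), p_SV = W_V * rat(n_SV, ncV),
    p_VS = W_S * rat(n_VS, ncS), p_SS = W_S * rat(n_SS, ncS),
    ncV = ncV, ncS = ncS
  )
}

#' Bias-corrected percentage correct per stratum
#'
#' Estimates, for each stratum, the probability that a randomly selected
#' pixel of the stratum is classified in agreement with the operator. The
#' raw within-column agreement rates are corrected for sampling bias with
#' the image marginal proportions:
#' \eqn{PC_h = W_V\,n_{VV}/n_{\cdot V} + W_S\,n_{SS}/n_{\cdot S}}, with a
#' 0/0 column contributing 0. The variance is the stratified binomial form
#' \eqn{\sum_k W_k^2\, q_k(1-q_k)/\max(n_{\cdot k}-1, 1)} with
#' \eqn{q_k = n_{kk}/n_{\cdot k}}.
#'
#' @param conf A [confusion_by_stratum()] table (or one row of it).
#' @return `data.frame(stratum, PC, var)`; `PC` in \[0, 1\].
#' @export
percentage_correct_stratum <- function(conf) {
  cc <- .corrected_cells(conf$n_VV, conf$n_VS, conf$n_SV, conf$n_SS,
                         conf$W_V, conf$W_S)
  pc <- cc$p_VV + cc$p_SS
  vterm <- function(W, n_kk, nc) {
    q <- ifelse(nc > 0L, n_kk / nc, 0)
    ifelse(nc > 0L, W^2 * q * (1 - q) / pmax(nc - 1L, 1L), 0)
  }
  v <- vterm(conf$W_V, conf$n_VV, cc$ncV) + vterm(conf$W_S, conf$n_SS, cc$ncS)
  data.frame(stratum = conf$stratum, PC = pc, var = v)
}

#' Stratum-size-weighted overall estimate with a normal 95% CI
#'
#' Combines per-stratum estimates by their stratum population shares
#' \eqn{N_h/N}: the overall estimate is \eqn{\sum_h (N_h/N)\,\theta_h} and
#' its variance \eqn{\sum_h (N_h/N)^2\,\mathrm{var}(\theta_h)}.
#'
#' @param est Per-stratum estimates.
#' @param var Per-stratum variances.
#' @param weights Stratum weights `N_h / N`; must sum to 1 (strata with an
#'   empty population carry weight 0).
#' @param conf_level Confidence level for the symmetric normal interval.
#' @return `list(estimate, var, se, ci)` with `ci` a length-2 vector.
#' @export
weighted_overall <- function(est, var, weights, conf_level = 0.95) {
  if (abs(sum(weights) - 1) > 1e-8) stop("stratum weights must sum to 1")
  if (length(est) != length(weights) || length(var) != length(weights)) {
    stop("estimates, variances and weights must have equal length")
  }
  e <- sum(weights * est)
  v <- sum(weights^2 * var)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = e, var = v, se = sqrt(v), ci = e + c(-1, 1) * z * sqrt(v))
}

#' Overall bias-corrected percentage correct
#'
#' @param per_strata Output of [percentage_correct_stratum()].
#' @param weights Stratum weights `N_h / N`.
#' @param conf_level Confidence level.
#' @return `list(estimate, var, se, ci)`.
#' @export
percentage_correct_overall <- function(per_strata, weights, conf_level = 0.95) {
  weighted_overall(per_strata$PC, per_strata$var, weights, conf_level)
}

#' Bias-corrected kappa per stratum
#'
#' Chance-corrected agreement between the algorithm classification and the
#' operator reference, computed from the bias-corrected cell proportions
#' \eqn{\hat p_{jk} = W_k\, n_{jk} / n_{\cdot k}}:
#' \eqn{\kappa_h = (p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o = \hat p_{VV} + \hat p_{SS}} and chance agreement
#' \eqn{p_e} from the corrected row and column marginals. \eqn{p_e = 1}
#' occurs exactly when a single-class stratum agrees perfectly with the
#' reference; the chance correction is then undefined and kappa is reported
#' as 1 (perfect agreement) with `degenerate = TRUE`. A single-class
#' stratum with some disagreement instead yields \eqn{p_o = p_e < 1} and so
#' \eqn{\kappa_h = 0} naturally — a constant classifier earns no
#' chance-corrected credit. The variance is the standard delta-method
#' (Fleiss--Cohen--Everitt) large-sample form evaluated on the corrected
#' proportions and divided by the stratum sample size.
#'
#' @inheritParams percentage_correct_stratum
#' @return `data.frame(stratum, kappa, var, degenerate)`.
#' @export
kappa_stratum <- function(conf) {
  cc <- .corrected_cells(conf$n_VV, conf$n_VS, conf$n_SV, conf$n_SS,
                         conf$W_V, conf$W_S)
  # rows = reference, columns = algorithm; column marginals are W_V, W_S
  p_Vdot <- cc$p_VV + cc$p_VS
  p_Sdot <- cc$p_SV + cc$p_SS
  p_dotV <- cc$p_VV + cc$p_SV
  p_dotS <- cc$p_VS + cc$p_SS
  po <- cc$p_VV + cc$p_SS
  pe <- p_Vdot * p_dotV + p_Sdot * p_dotS
  degenerate <- abs(1 - pe) < 1e-12
  kap <- ifelse(degenerate, 1, (po - pe) / (1 - pe))
  # delta-method variance on the corrected 2x2 proportions
  th1 <- po
  th2 <- pe
  th3 <- cc$p_VV * (p_Vdot + p_dotV) + cc$p_SS * (p_Sdot + p_dotS)
  th4 <- cc$p_VV * (p_Vdot + p_dotV)^2 + cc$p_VS * (p_Sdot + p_dotV)^2 +
    cc$p_SV * (p_Vdot + p_dotS)^2 + cc$p_SS * (p_Sdot + p_dotS)^2
  n_h <- pmax(conf$n_h, 1L)
  v <- ifelse(
    degenerate, 0,
    (th1 * (1 - th1) / (1 - th2)^2 +
       2 * (1 - th1) * (2 * th1 * th2 - th3) / (1 - th2)^3 +
       (1 - th1)^2 * (th4 - 4 * th2^2) / (1 - th2)^4) / n_h
  )
  data.frame(stratum = conf$stratum, kappa = kap, var = pmax(v, 0),
             degenerate = degenerate)
}

#' Overall bias-corrected kappa
#'
#' @param per_strata Output of [kappa_stratum()].
#' @param weights Stratum weights `N_h / N`.
#' @param conf_level Confidence level.
#' @return `list(estimate, var, se, ci)`.
#' @export
kappa_overall <- function(per_strata, weights, conf_level = 0.95) {
  weighted_overall(per_strata$kappa, per_strata$var, weights, conf_level)
}

#' Gap fraction estimated from the reference labels
#'
#' The design-unbiased stratified estimator of the sky proportion:
#' \eqn{GF_{ref} = \sum_h (N_h/N)\,(s_h/n_h)} with \eqn{s_h} the number of
#' sky-labeled reference pixels in stratum h. Comparing it with the
#' picture-based gap fraction separates classification errors that cancel
#' from those that bias the gap fraction.
#'
#' @param sample A fully labeled [stratified_sample()] result.
#' @return The estimated sky proportion in \[0, 1\].
#' @export
gap_fraction_reference <- function(sample) {
  stopifnot(inherits(sample, "reference_sample"))
  rec <- sample$records
  if (anyNA(rec$label)) stop("sample is not fully labeled")
  ns <- nrow(sample$strata)
  s_h <- tabulate(rec$stratum[rec$label == "sky"], ns)
  n_h <- sample$strata$n_h
  N_h <- sample$strata$N_h
  keep <- n_h > 0L
  sum((N_h[keep] / sample$N) * (s_h[keep] / n_h[keep]))
}

#' Gap-fraction misestimation ratio
#'
#' The picture-based gap fraction divided by the reference-based one; 1.0
#' indicates an unbiased classification, values above 1 an overestimated
#' gap fraction.
#'
#' @param gf_pic Gap fraction from the binarized picture.
#' @param gf_ref Gap fraction from the reference labels (> 0).
#' @return The ratio `gf_pic / gf_ref`.
#' @export
misestimation <- function(gf_pic, gf_ref) {
  if (gf_ref <= 0) stop("reference gap fraction is 0; misestimation undefined")
  gf_pic / gf_ref
}

#' Full accuracy assessment of a binarization
#'
#' Runs the complete evaluation protocol for one binarized photograph:
#' per-stratum confusion matrices with image marginal proportions,
#' bias-corrected percentage correct and kappa with delta-method variances,
#' stratum-size-weighted overall estimates with normal confidence
#' intervals, picture- and reference-based gap fraction, and the
#' misestimation ratio.
#'
#' @param image The analyzed [gray_image()].
#' @param binary The `binary_map` produced by a threshold algorithm.
#' @param sample A fully labeled [stratified_sample()] result.
#' @param conf_level Confidence level for the intervals.
#' @param method Optional method label carried into the report.
#' @return An object of class `binarization_accuracy`: list with elements
#'   `strata` (per-stratum table), `pc`, `kappa` (each
#'   `list(estimate, var, se, ci)`), `gf_pic`, `gf_ref`, `misestimation`,
#'   `method`, `conf_level`.
#' @export
binarization_accuracy <- function(image, binary, sample, conf_level = 0.95,
                                  method = NULL) {
  conf <- confusion_by_stratum(sample, binary, image)
  pcs <- percentage_correct_stratum(conf)
  kps <- kappa_stratum(conf)
  wts <- conf$N_h / sum(conf$N_h)
  pc <- percentage_correct_overall(pcs, wts, conf_level)
  kp <- kappa_overall(kps, wts, conf_level)
  gfp <- gap_fraction(binary)
  gfr <- gap_fraction_reference(sample)
  strata <- cbind(conf,
                  PC = pcs$PC, PC_var = pcs$var,
                  kappa = kps$kappa, kappa_var = kps$var,
                  kappa_degenerate = kps$degenerate)
  structure(
    list(strata = strata, pc = pc, kappa = kp,
         gf_pic = gfp, gf_ref = gfr,
         misestimation = if (gfr > 0) gfp / gfr else NA_real_,
         method = method, conf_level = conf_level),
    class = "binarization_accuracy"
  )
}

#' @export
print.binarization_accuracy <- function(x, ...) {
  cat("<binarization_accuracy>",
      if (!is.null(x$method)) paste0("method = ", x$method) else "", "\n")
  cat(sprintf("  percentage correct: %.1f%%  (%d%% CI %.1f%% .. %.1f%%)\n",
              100 * x$pc$estimate, round(100 * x$conf_level),
              100 * x$pc$ci[1], 100 * x$pc$ci[2]))
  cat(sprintf("  kappa:              %.3f  (%d%% CI %.3f .. %.3f)\n",
              x$kappa$estimate, round(100 * x$conf_level),
              x$kappa$ci[1], x$kappa$ci[2]))
  cat(sprintf("  gap fraction:       picture %.4f, reference %.4f, ratio %.3f\n",
              x$gf_pic, x$gf_ref, x$misestimation))
  if (any(x$strata$kappa_degenerate)) {
    cat("  note: single-class strata in perfect agreement (kappa degenerate, 1):",
        paste(x$strata$stratum[x$strata$kappa_degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.binarization_accuracy <- function(object, ...) {
  cat("Per-stratum accuracy\n")
  tab <- object$strata[object$strata$n_h > 0L,
                       c("stratum", "lo", "hi", "N_h", "n_h",
                         "n_VV", "n_VS", "n_SV", "n_SS", "W_V",
                         "PC", "kappa")]
  print(tab, row.names = FALSE, digits = 4)
  cat("\nOverall\n")
  print.binarization_accuracy(object)
  invisible(object)
}

#' Export an accuracy report as CSV and JSON
#'
#' Writes the per-stratum table (plus one overall row per metric) as CSV and
#' a compact JSON summary
#' `{pc, pc_ci, kappa, kappa_ci, gf_pic, gf_ref, misestimation}`.
#'
#' @param report A [binarization_accuracy()] result.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the JSON summary as a list.
#' @export
write_accuracy_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "binarization_accuracy"))
  if (!is.null(csv_path)) {
    tab <- report$strata
    overall <- data.frame(
      metric = c("pc", "pc_ci_lo", "pc_ci_hi",
                 "kappa", "kappa_ci_lo", "kappa_ci_hi",
                 "gf_pic", "gf_ref", "misestimation"),
      value = c(report$pc$estimate, report$pc$ci,
                report$kappa$estimate, report$kappa$ci,
                report$gf_pic, report$gf_ref, report$misestimation)
    )
    utils::write.csv(tab, csv_path, row.names = FALSE)
    utils::write.csv(overall, sub("\\.csv$", "_overall.csv", csv_path),
                     row.names = FALSE)
  }
  js <- list(
    method = report$method,
    pc = report$pc$estimate, pc_ci = report$pc$ci,
    kappa = report$kappa$estimate, kappa_ci = report$kappa$ci,
    gf_pic = report$gf_pic, gf_ref = report$gf_ref,
    misestimation = report$misestimation
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(js)
}
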