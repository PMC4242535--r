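test_that("the default stratified design yields 384 records in 16 strata", {
  img <- rand_image(21, 96L, 96L)   # uniform gray values populate all strata
  s <- stratified_sample(img, seed = 7L)
  expect_identical(s$n, 384L)
  expect_identical(nrow(s$strata), 16L)
  expect_true(all(s$strata$n_h == 24L))
  # every record's gray value lies inside its stratum, no duplicate pixels
  expect_true(all(s$records$gray >= s$strata$lo[s$records$stratum] &
                    s$records$gray <= s$strata$hi[s$records$stratum]))
  expect_false(anyDuplicated(s$records[c("x", "y")]) > 0)
  # reproducible under seed
  s2 <- stratified_sample(img, seed = 7L)
  expect_identical(s$records, s2$records)
  expect_false(identical(s$records, stratified_sample(img, seed = 8L)$records))
})

test_that("under-populated strata are exhausted with a warning", {
  vals <- matrix(10L, 30L, 30L)
  vals[1:5] <- 250L   # only 5 pixels in the top stratum
  img <- gray_image(vals)
  expect_warning(s <- stratified_sample(img, seed = 1L), "fewer than")
  expect_identical(s$strata$n_h[16], 5L)
  expect_identical(s$strata$n_h[1], 24L)
})

test_that("label sheets round-trip and reject bad labels", {
  img <- rand_image(5, 30L, 30L)
  s <- stratified_sample(img, strata_width = 64L, per_stratum = 4L, seed = 2L)
  dir <- withr::local_tempdir()
  sheet <- export_label_sheet(s, img, dir, chip_radius = 3L, zoom = 2L)
  tab <- utils::read.csv(sheet)
  expect_identical(nrow(tab), s$n)
  expect_true(all(file.exists(file.path(dir, tab$chip))))
  # chips for pixels near the border are flagged as padded
  near_edge <- tab$x < 3 | tab$y < 3 | tab$x > 26 | tab$y > 26
  expect_identical(tab$padded, near_edge)
  # re-import of an untouched (unlabeled) sheet fails
  expect_error(load_labels(s, sheet), "unlabeled|unknown")
  # an unknown token fails naming the row
  tab$label <- "vegetation"
  tab$label[3] <- "cloud"
  expect_error(load_labels(s, tab), "row")
  # permuted rows are accepted (keyed by coordinates)
  tab$label <- ifelse(tab$gray > 127, "sky", "vegetation")
  perm <- tab[sample(nrow(tab)), ]
  loaded <- load_labels(s, perm)
  expect_identical(loaded$records$label,
                   ifelse(s$records$gray > 127, "sky", "vegetation"))
  # duplicates rejected
  expect_error(load_labels(s, rbind(tab, tab[1, ])), "duplicate")
})

test_that("confusion cells match a brute-force recount and W is population-based", {
  sc <- small_scene(3L)
  s <- label_from_truth(stratified_sample(sc$image, seed = 9L), sc$truth)
  bin <- binarize(sc$image, 110L)
  conf <- confusion_by_stratum(s, bin, sc$image)
  # brute-force recount over the records
  cls <- unclass(bin)
  for (hh in which(conf$n_h > 0)) {
    rec <- s$records[s$records$stratum == hh, ]
    alg_veg <- cls[cbind(rec$y + 1L, rec$x + 1L)] == 1L
    ref_veg <- rec$label == "vegetation"
    expect_identical(conf$n_VV[hh], sum(ref_veg & alg_veg))
    expect_identical(conf$n_VS[hh], sum(ref_veg & !alg_veg))
    expect_identical(conf$n_SV[hh], sum(!ref_veg & alg_veg))
    expect_identical(conf$n_SS[hh], sum(!ref_veg & !alg_veg))
    # W from the full stratum population
    in_h <- sc$image$values %/% 16L + 1L == hh
    expect_equal(conf$W_V[hh], mean(cls[in_h] == 1L))
  }
  expect_true(all(conf$n_VV + conf$n_VS + conf$n_SV + conf$n_SS == conf$n_h))
  expect_equal(conf$W_V + conf$W_S, rep(1, 16))
  # a threshold on a stratum boundary makes every stratum single-class
  conf127 <- confusion_by_stratum(s, binarize(sc$image, 127L), sc$image)
  expect_true(all(conf127$W_V %in% c(0, 1)))
})

test_that("percentage correct reproduces the hand-worked stratum", {
  conf <- data.frame(stratum = 1L, N_h = 1000L, n_h = 24L,
                     n_VV = 20L, n_SV = 1L, n_VS = 1L, n_SS = 2L,
                     W_V = 0.9, W_S = 0.1)
  pc <- percentage_correct_stratum(conf)
  expect_equal(pc$PC, 0.9 * 20 / 21 + 0.1 * 2 / 3, tolerance = 1e-12)
  expect_equal(pc$PC, 0.92381, tolerance = 1e-4)
  # perfect diagonal
  perf <- data.frame(stratum = 1L, N_h = 500L, n_h = 24L,
                     n_VV = 20L, n_SV = 0L, n_VS = 0L, n_SS = 4L,
                     W_V = 20 / 24, W_S = 4 / 24)
  expect_equal(percentage_correct_stratum(perf)$PC, 1)
  # an absent algorithm class (W = 0 with empty column) contributes 0
  onecol <- data.frame(stratum = 1L, N_h = 500L, n_h = 24L,
                       n_VV = 22L, n_SV = 2L, n_VS = 0L, n_SS = 0L,
                       W_V = 1, W_S = 0)
  expect_equal(percentage_correct_stratum(onecol)$PC, 22 / 24)
})

test_that("overall PC is the stratum-size-weighted mean with aggregated variance", {
  per <- data.frame(stratum = 1:2, PC = c(1, 0.8), var = c(0, 0))
  ov <- percentage_correct_overall(per, weights = c(0.75, 0.25))
  expect_equal(ov$estimate, 0.95)
  expect_equal(diff(ov$ci), 0)
  per2 <- data.frame(stratum = 1:2, PC = c(0.9, 0.7), var = c(0.01, 0.04))
  ov2 <- percentage_correct_overall(per2, weights = c(0.5, 0.5))
  expect_equal(ov2$var, 0.25 * 0.01 + 0.25 * 0.04)
  expect_equal(ov2$ci[2] - ov2$estimate, 1.959964 * sqrt(ov2$var), tolerance = 1e-6)
  expect_error(percentage_correct_overall(per, weights = c(0.5, 0.3)), "sum to 1")
})

test_that("a census sample reproduces census accuracy exactly", {
  sc <- small_scene(8L, width = 64L, height = 64L)
  bin <- binarize(sc$image, canopy_threshold(sc$image, "otsu")$threshold)
  suppressWarnings(
    s <- label_from_truth(stratified_sample(sc$image, per_stratum = 10^6L, seed = 1L),
                          sc$truth)
  )
  expect_identical(s$n, s$N)   # every pixel sampled
  rep <- binarization_accuracy(sc$image, bin, s)
  cm <- census_metrics(sc$truth, bin, "half")
  expect_equal(rep$pc$estimate, cm$pc, tolerance = 1e-12)
  expect_equal(rep$gf_ref, cm$gf, tolerance = 1e-12)
})

test_that("kappa reproduces the hand-worked stratum and its conventions", {
  conf <- data.frame(stratum = 1L, N_h = 1000L, n_h = 24L,
                     n_VV = 20L, n_SV = 1L, n_VS = 1L, n_SS = 2L,
                     W_V = 0.9, W_S = 0.1)
  k <- kappa_stratum(conf)
  expect_equal(k$kappa, 0.5939, tolerance = 1e-4)
  expect_false(k$degenerate)
  expect_gt(k$var, 0)
  # perfect diagonal with both classes present
  perf <- data.frame(stratum = 1L, N_h = 500L, n_h = 24L,
                     n_VV = 20L, n_SV = 0L, n_VS = 0L, n_SS = 4L,
                     W_V = 20 / 24, W_S = 4 / 24)
  expect_equal(kappa_stratum(perf)$kappa, 1)
  # exact chance agreement: cells [[9,1],[9,1]] with W matching column shares
  chance <- data.frame(stratum = 1L, N_h = 200L, n_h = 20L,
                       n_VV = 9L, n_VS = 1L, n_SV = 9L, n_SS = 1L,
                       W_V = 0.9, W_S = 0.1)
  expect_equal(kappa_stratum(chance)$kappa, 0)
  # perfect agreement in a single-class stratum: chance correction
  # undefined, reported as perfect with a degeneracy flag
  single <- data.frame(stratum = 1L, N_h = 300L, n_h = 24L,
                       n_VV = 24L, n_SV = 0L, n_VS = 0L, n_SS = 0L,
                       W_V = 1, W_S = 0)
  ks <- kappa_stratum(single)
  expect_true(ks$degenerate)
  expect_equal(ks$kappa, 1)
  # single-class stratum with disagreement earns no chance-corrected credit
  lone <- data.frame(stratum = 1L, N_h = 300L, n_h = 24L,
                     n_VV = 20L, n_SV = 4L, n_VS = 0L, n_SS = 0L,
                     W_V = 1, W_S = 0)
  expect_equal(kappa_stratum(lone)$kappa, 0)
})

test_that("overall kappa aggregates like PC and keeps identities", {
  per <- data.frame(stratum = 1:2, kappa = c(0.8, 0.4), var = c(0, 0))
  expect_equal(kappa_overall(per, c(0.5, 0.5))$estimate, 0.6)
  expect_equal(kappa_overall(per[1, ], 1)$estimate, 0.8)
  expect_true(kappa_overall(per, c(0.5, 0.5))$estimate <= 1)
})

test_that("reference gap fraction is the weighted sky share of the sample", {
  img <- rand_image(13, 40L, 40L)
  s <- stratified_sample(img, seed = 3L)
  s$records$label <- "sky"
  expect_equal(gap_fraction_reference(s), 1)
  # hand-worked two-stratum case via a constructed sample
  vals <- matrix(c(rep(10L, 1200), rep(200L, 400)), 40, 40)
  img2 <- gray_image(vals)
  suppressWarnings(s2 <- stratified_sample(img2, strata_width = 128L,
                                           per_stratum = 24L, seed = 4L))
  s2$records$label <- ifelse(s2$records$stratum == 1L, "vegetation", "sky")
  # weights 0.75 / 0.25, sky shares 0 / 1 -> GF_ref = 0.25
  expect_equal(gap_fraction_reference(s2), 0.25)
  s2$records$label[s2$records$stratum == 2L] <-
    rep(c("sky", "vegetation"), 12)   # sky share 0.5 in the bright stratum
  expect_equal(gap_fraction_reference(s2), 0.125)
})

test_that("misestimation is the picture-to-reference ratio", {
  expect_equal(misestimation(0.2, 0.2), 1)
  expect_equal(misestimation(0.2, 0.1), 2)
  expect_error(misestimation(0.2, 0), "undefined")
})

test_that("accuracy statistics are invariant to record order", {
  sc <- small_scene(6L)
  s <- suppressWarnings(
    label_from_truth(stratified_sample(sc$image, seed = 2L), sc$truth))
  bin <- binarize(sc$image, 100L)
  r1 <- binarization_accuracy(sc$image, bin, s)
  set.seed(1)
  s2 <- s
  s2$records <- s2$records[sample(nrow(s2$records)), ]
  r2 <- binarization_accuracy(sc$image, bin, s2)
  expect_equal(r1$pc$estimate, r2$pc$estimate)
  expect_equal(r1$kappa$estimate, r2$kappa$estimate)
  expect_equal(r1$gf_ref, r2$gf_ref)
})

test_that("report writing produces the CSV/JSON interface", {
  sc <- small_scene(9L, width = 64L, height = 64L)
  s <- suppressWarnings(
    label_from_truth(stratified_sample(sc$image, seed = 5L), sc$truth))
  bin <- binarize(sc$image, canopy_threshold(sc$image, "otsu")$threshold)
  rep <- binarization_accuracy(sc$image, bin, s, method = "otsu")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  out <- write_accuracy_report(rep, csv, js)
  expect_identical(nrow(utils::read.csv(csv)), 16L)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$pc, rep$pc$estimate, tolerance = 1e-9)
  expect_named(out, c("method", "pc", "pc_ci", "kappa", "kappa_ci",
                      "gf_pic", "gf_ref", "misestimation"))
})
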