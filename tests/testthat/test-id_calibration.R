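test_that("percentile binning groups 5/10x9 percent of spacers", {
  set.seed(1)
  fam <- data.frame(spacer_bp = sample(1:100000, 1000),
                    inverted = rep(c(TRUE, FALSE), 500))
  g <- bin_spacer_percentiles(fam)
  expect_equal(g$percentile, c(2.5, seq(10, 90, 10)))
  expect_equal(g$n_inverted + g$n_direct, c(50, rep(100, 9)))
  expect_true(all(diff(g$median_spacer) > 0))
  expect_true(all(g$spacer_lo <= g$median_spacer &
                  g$median_spacer <= g$spacer_hi))
  expect_error(bin_spacer_percentiles(fam[1:999, ]), "pool")
})

test_that("group I:D is the inverted/direct count ratio", {
  # 2000 pairs: the 10th-percentile group is pairs 101..300 by spacer
  # rank; give it 98 inverted / 102 direct
  inv <- rep(FALSE, 2000)
  inv[101:198] <- TRUE
  fam <- data.frame(spacer_bp = 1:2000, inverted = inv)
  g <- bin_spacer_percentiles(fam)
  expect_equal(g$n_inverted[2L], 98L)
  expect_equal(g$id_ratio[2L], 98 / 102)
  # a 49/51 split evaluates to 0.96078...
  expect_equal(49 / 51, 0.9607843, tolerance = 1e-7)
  all_dir <- data.frame(spacer_bp = 1:1000, inverted = FALSE)
  gd <- bin_spacer_percentiles(all_dir)
  expect_true(all(gd$id_ratio == 0))
  expect_true(all(gd$n_inverted == 0))
})

test_that("pooling sums counts instead of averaging ratios", {
  groups <- data.frame(pair_type = 1L, apsn = c(1L, 2L), percentile = 2.5,
                       spacer_lo = 0, spacer_hi = 10, median_spacer = 5,
                       n_inverted = c(10L, 30L), n_direct = c(10L, 10L),
                       id_ratio = c(1, 3))
  pooled <- pool_percentiles_across_apsns(groups)
  expect_equal(pooled$pooled$pooled_id, 2.0)      # 40/20, not mean(1, 3)
  expect_equal(pooled$pooled$n_inverted, 40L)
  one <- pool_percentiles_across_apsns(groups[1L, ])
  expect_equal(one$pooled$pooled_id, 1.0)          # single APSN: identity
  expect_equal(nrow(one$series), 1L)
})

test_that("percentile curve fitting recovers noiseless polynomials", {
  spacer <- round(10^seq(1.5, 5, length.out = 40))
  x <- log10(spacer + 1)
  y <- 0.8 + 0.05 * x - 0.01 * x^2
  ser <- data.frame(median_spacer = spacer, id_ratio = y)
  fit <- fit_percentile_curve(ser)
  expect_lt(sqrt(mean((eval_percentile_fit(fit, spacer) - y)^2)), 1e-6)
  # constant series at 1.0 -> fitted function is 1.0 everywhere observed
  serc <- data.frame(median_spacer = spacer, id_ratio = 1)
  fitc <- fit_percentile_curve(serc)
  expect_equal(eval_percentile_fit(fitc, c(40, 500, 90000)),
               rep(1, 3), tolerance = 1e-9)
})

test_that("segmented fitting isolates a sharp regime change", {
  set.seed(4)
  spacer <- round(10^seq(2, 5, length.out = 60))
  y_true <- c(rep(0.8, 12), rep(1.0, 48))
  ser <- data.frame(median_spacer = spacer,
                    id_ratio = y_true + rnorm(60, 0, 0.005),
                    n_inverted = 5000L, n_direct = 5000L)
  fit <- fit_percentile_curve(ser)
  yy <- eval_percentile_fit(fit, spacer)
  expect_lt(max(abs(yy[1:10] - 0.8)), 0.02)
  expect_lt(max(abs(yy[20:60] - 1.0)), 0.02)
})

test_that("anchor extraction evaluates each APSN at its own medians", {
  groups <- expand.grid(percentile = c(2.5, seq(10, 90, 10)),
                        apsn = 1:3, pair_type = 1L)
  groups$median_spacer <- 100 * seq_len(nrow(groups))
  groups$spacer_lo <- 0; groups$spacer_hi <- 1e6
  groups$n_inverted <- 500L; groups$n_direct <- 500L
  groups$id_ratio <- 1
  fits <- lapply(c(2.5, seq(10, 90, 10)), function(pc) {
    ser <- groups[groups$percentile == pc, ]
    fit_percentile_curve(data.frame(median_spacer = ser$median_spacer,
                                    id_ratio = 1))
  })
  names(fits) <- sprintf("t1_p%s", format(c(2.5, seq(10, 90, 10))))
  anchors <- extract_apsn_curves(fits, groups)
  expect_equal(anchors$id_fitted, rep(1, 30), tolerance = 1e-9)
  # 10 anchors per (type, apsn)
  expect_equal(unname(table(anchors$apsn)), rep(10L, 3),
               ignore_attr = TRUE)
})

test_that("the significance filter sets apsn_max from the last sub-cutoff anchor", {
  s <- fake_surface(values = 1.0, types = 1L, apsns = 1:40)
  s$anchors$id_fitted[s$anchors$apsn <= 30 & s$anchors$percentile == 2.5] <- 0.97
  s2 <- apply_significance_filter(s)
  expect_equal(s2$apsn_max, 30L)
  s3 <- apply_significance_filter(s, cutoff = 1.1)
  expect_equal(s3$apsn_max, 40L)       # everything retained
  s4 <- fake_surface(values = 1.0, types = 1L, apsns = 1:40)
  expect_equal(apply_significance_filter(s4)$apsn_max, 0L)
})

test_that("calibration on a symmetric landscape centres anchors near unity", {
  el <- simulate_landscape(landscape_spec(6e7, seed = 21))
  surf <- fit_id_surface(el, apsn_cal_max = 12, min_pairs = 800)
  a <- surf$anchors
  expect_true(all(a$percentile %in% c(2.5, seq(10, 90, 10))))
  # unthinned symmetric genome: anchors are statistically consistent with 1
  n <- a$n_inverted + a$n_direct
  expect_gt(mean(id_in_ci(1.0, n, a$id_fitted)), 0.90)
  # pooled per-percentile counts are consistent with I:D = 1
  pooled <- surf$pooled
  se <- 2 / sqrt(pooled$n_inverted + pooled$n_direct)
  expect_true(all(abs(pooled$pooled_id - 1) < 4 * se))
})

test_that("surface serialization round-trips exactly", {
  el <- simulate_landscape(landscape_spec(1.5e7, seed = 22))
  surf <- suppressMessages(fit_id_surface(el, apsn_cal_max = 8,
                                          min_pairs = 300))
  f <- withr::local_tempfile(fileext = ".json")
  write_id_surface(surf, f)
  back <- read_id_surface(f)
  expect_identical(back$anchors$id_fitted, surf$anchors$id_fitted)
  expect_identical(back$anchors$median_spacer, surf$anchors$median_spacer)
  expect_identical(back$apsn_max, surf$apsn_max)
  expect_identical(back$type0$anchor, surf$type0$anchor)
  pairs <- enumerate_alu_pairs(el, apsn_max = 8)
  expect_identical(predict(surf, pairs), predict(back, pairs))
  # clamp idempotence through serialization
  f2 <- withr::local_tempfile(fileext = ".json")
  write_id_surface(back, f2)
  expect_identical(predict(read_id_surface(f2), pairs),
                   predict(surf, pairs))
})
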