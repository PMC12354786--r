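test_that("a triangle wave splits into its cycles", {
  lam <- triangle_path(c(1.2, 1.3, 1.4))
  n <- length(lam)
  raw <- tensile_curve(seq_len(n) - 1, lam, rep(1, n), pmax(lam - 1, 0) * 10)
  cyc <- split_cycles(raw)
  expect_equal(sort(unique(cyc$cycle)), 1:3)
  for (ci in 1:3) {
    seg <- cyc[cyc$cycle == ci, ]
    expect_setequal(unique(seg$phase), c("loading", "unloading"))
    # loading precedes unloading within the cycle
    expect_true(max(seg$time_s[seg$phase == "loading"]) <
                  min(seg$time_s[seg$phase == "unloading"]))
  }
})

test_that("generator segment labels are recovered from the unlabeled trace", {
  g <- generate_cyclic(generator_profile(noise_sd_force = 0,
                                         noise_sd_stretch = 0),
                       peak_list = c(1.1, 1.2, 1.3, 1.4))
  raw <- tensile_curve(g$curve$time_s, g$curve$lambda_ax,
                       g$curve$lambda_tr, g$curve$force_per_width)
  cyc <- split_cycles(raw)
  expect_equal(cyc$cycle, g$curve$cycle)
  expect_equal(cyc$phase, g$curve$phase)
})

test_that("a monotone ramp is not cyclic", {
  lam <- seq(1, 1.4, length.out = 60)
  raw <- tensile_curve(seq_along(lam), lam, rep(1, 60), (lam - 1) * 12)
  expect_error(split_cycles(raw), class = "wallmech_not_cyclic")
})

test_that("recovery is 100% for an elastic cycle and 50% for a half-recovered one", {
  # elastic: unloads exactly back to (1, 0)
  lam <- c(seq(1, 1.3, length.out = 30), seq(1.3, 1, length.out = 30)[-1])
  f <- (lam - 1) * 40
  cyc <- tensile_curve(seq_along(lam), lam, rep(1, length(lam)), f,
                       cycle = rep(1L, length(lam)),
                       phase = rep(c("loading", "unloading"), c(30, 29)))
  rec <- recovery_analysis(cyc)
  expect_equal(rec$recovery_percent, 100, tolerance = 1e-6)
  expect_equal(rec$residual_stretch, 1, tolerance = 1e-8)

  # plastic: zero force crossing at stretch 1.15 after a peak of 1.3
  lam2 <- c(seq(1, 1.3, length.out = 30), seq(1.3, 1.1, length.out = 30)[-1])
  f2 <- c((seq(1, 1.3, length.out = 30) - 1) * 40,
          (seq(1.3, 1.1, length.out = 30)[-1] - 1.15) * 80)
  cyc2 <- tensile_curve(seq_along(lam2), lam2, rep(1, length(lam2)), f2,
                        cycle = rep(1L, length(lam2)),
                        phase = rep(c("loading", "unloading"), c(30, 29)))
  rec2 <- recovery_analysis(cyc2)
  expect_equal(rec2$residual_stretch, 1.15, tolerance = 1e-3)
  expect_equal(rec2$recovery_percent, 50, tolerance = 0.5)
})

test_that("unloading that retraces loading always ends at full recovery", {
  set.seed(5)
  for (i in 1:5) {
    peak <- runif(1, 1.1, 1.5)
    up <- seq(1, peak, length.out = 40)
    f_up <- cumsum(c(0, runif(39, 0.1, 1)))   # arbitrary increasing force
    lam <- c(up, rev(up)[-1])
    f <- c(f_up, rev(f_up)[-1])
    ltr <- 1 - 0.5 * (lam - 1)
    cyc <- tensile_curve(seq_along(lam), lam, ltr, f,
                         cycle = rep(1L, length(lam)),
                         phase = rep(c("loading", "unloading"), c(40, 39)))
    rec <- recovery_analysis(cyc)
    expect_equal(rec$recovery_percent, 100, tolerance = 0.1)
    expect_equal(rec$recovery_percent_tr, 100, tolerance = 0.1)
  }
})

test_that("an unloading branch that never reaches zero force is flagged", {
  lam <- c(seq(1, 1.3, length.out = 20), seq(1.3, 1.2, length.out = 20)[-1])
  f <- c((seq(1, 1.3, length.out = 20) - 1) * 40,
         rev(seq(6, 11.9, length.out = 19)))
  cyc <- tensile_curve(seq_along(lam), lam, rep(1, length(lam)), f,
                       cycle = rep(1L, length(lam)),
                       phase = rep(c("loading", "unloading"), c(20, 19)))
  expect_warning(rec <- recovery_analysis(cyc), "zero force")
  expect_true(rec$zero_not_reached)
  expect_equal(rec$residual_stretch, 1.2, tolerance = 1e-6)
})

test_that("residual stretch is tabulated against peak force in force order", {
  g <- generate_cyclic(generator_profile(noise_sd_force = 0,
                                         noise_sd_stretch = 0),
                       peak_list = c(1.1, 1.25, 1.4))
  rec <- recovery_analysis(g$curve)
  tab <- residual_vs_force(rec)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$peak_force_per_width) > 0))
  expect_true(all(diff(tab$residual_stretch) >= 0))
})
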