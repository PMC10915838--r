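test_that("thermodynamic constants are sane", {
  expect_equal(log10(kbt_over_h(298.15)), 12.793, tolerance = 1e-3 / 12.793)
  expect_equal(R_KCAL, 0.0019872)
})

test_that("LFESR fits recover planted lines exactly without noise", {
  xs <- seq(-5, 15, length.out = 10)
  profiles <- lapply(seq_along(xs), function(i) {
    x <- xs[i]
    energy_profile(paste0("p", i), "C2",
                   c("1" = 0.8 * x + 2.0, "TS2" = 0.5 * x + 10,
                     "2" = x, "TS3" = 0.3 * x + 7),
                   dgr = 0.1 * x - 11)
  })
  fit <- fit_lfesr(profiles)
  tab <- fit$table
  row1 <- tab[tab$state == "1", ]
  expect_equal(row1$slope, 0.8, tolerance = 1e-10)
  expect_equal(row1$intercept, 2.0, tolerance = 1e-10)
  expect_equal(row1$r2, 1, tolerance = 1e-10)

  # the descriptor state regressed on itself is the identity
  row2 <- tab[tab$state == "2", ]
  expect_equal(row2$slope, 1, tolerance = 1e-12)
  expect_equal(row2$intercept, 0, tolerance = 1e-10)

  expect_error(fit_lfesr(profiles[1:2]), "3")
})

test_that("fitted slope confidence intervals achieve nominal coverage", {
  # planted slope 0.6, noise sd 0.5, n = 40 per replicate; with 300
  # replicates, a correct 95% CI passes the 92% floor with ~99% probability
  # while a mis-propagated interval (coverage <= 85%) essentially never does
  slope <- 0.6
  covered <- 0
  set.seed(20)
  for (rep in 1:300) {
    x <- stats::runif(40, -10, 20)
    profiles <- lapply(seq_along(x), function(i) {
      energy_profile(paste0("p", i), "C2",
                     c("1" = 1, "TS2" = slope * x[i] + 8 + stats::rnorm(1, 0, 0.5),
                       "2" = x[i], "TS3" = 5),
                     dgr = -11)
    })
    tab <- fit_lfesr(profiles)$table
    r <- tab[tab$state == "TS2", ]
    se_slope <- r$sigma / sqrt(r$sxx)
    half <- stats::qt(0.975, r$n - 2) * se_slope
    covered <- covered + (abs(r$slope - slope) <= half)
  }
  expect_gte(covered, 276)
})

test_that("energy-span TOF matches closed forms and the pair-scan oracle", {
  rt <- R_KCAL * 298.15
  log10_kbth <- log10(kbt_over_h(298.15))

  # lone TS at +10, exergonic cycle: the span is 10
  p1 <- energy_profile("a", "C2", c(TS2 = 10), dgr = -5)
  expect_equal(attr(tof_energy_span(p1), "log10_tof"),
               log10_kbth - 10 / (rt * log(10)), tolerance = 1e-10)
  expect_equal(attr(tof_energy_span(p1), "delta_e"), 10)

  # intermediate at -3 preceding a TS at +8: the span is 11
  p2 <- energy_profile("b", "C2", c("1" = -3, TS2 = 8), dgr = -5)
  expect_equal(attr(tof_energy_span(p2), "delta_e"), 11)
  expect_equal(attr(tof_energy_span(p2), "log10_tof"),
               log10_kbth - 11 / (rt * log(10)), tolerance = 1e-10)

  expect_error(energy_profile("c", "C2", c(TS2 = NaN), dgr = -5), "non-finite")
  expect_error(tof_energy_span(energy_profile("d", "C2", c("1" = 2), dgr = -5)),
               "no transition state")

  # exhaustive max over all (TS, intermediate incl. reference) pairs,
  # with dG_r added when the TS precedes the intermediate
  set.seed(21)
  for (i in 1:1000) {
    st <- c("1" = stats::rnorm(1, 0, 6), "TS1" = stats::rnorm(1, 8, 6),
            "1B" = stats::rnorm(1, 0, 6), "TS2" = stats::rnorm(1, 8, 6),
            "2" = stats::rnorm(1, 0, 6), "TS3" = stats::rnorm(1, 8, 6))
    dgr <- stats::rnorm(1, -10, 4)
    p <- energy_profile("r", "C3", st, dgr)
    inter <- c(ref = 0, st[c("1", "1B", "2")])
    ipos <- c(0, 1, 3, 5)
    tss <- st[c("TS1", "TS2", "TS3")]
    tpos <- c(2, 4, 6)
    spans <- c()
    for (ti in 1:3) for (ij in 1:4) {
      spans <- c(spans, tss[ti] - inter[ij] + if (tpos[ti] < ipos[ij]) dgr else 0)
    }
    expect_equal(attr(tof_energy_span(p), "delta_e"), max(spans))
  }
})

test_that("degree of TOF control weights are normalized sensitivities", {
  # a single kinetically relevant TS takes all the control
  p1 <- energy_profile("a", "C2", c(TS2 = 10), dgr = -5)
  expect_equal(unname(degree_of_tof_control(p1)), 1, tolerance = 1e-6)

  # two TSs constructed with equal dominant spans share control equally
  p2 <- energy_profile("b", "C2", c("1" = -2, TS2 = 8, "2" = -4, TS3 = 6),
                       dgr = -50)
  w <- degree_of_tof_control(p2)
  expect_equal(unname(w["TS2"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(w["TS3"]), 0.5, tolerance = 1e-3)

  # weights always sum to 1
  set.seed(22)
  for (i in 1:50) {
    st <- c("1" = stats::rnorm(1, 0, 4), "TS2" = stats::rnorm(1, 9, 4),
            "2" = stats::rnorm(1, 0, 4), "TS3" = stats::rnorm(1, 9, 4))
    p <- energy_profile("r", "C2", st, dgr = stats::rnorm(1, -12, 2))
    expect_equal(sum(degree_of_tof_control(p)), 1, tolerance = 1e-6)
  }
})

test_that("TOF responds monotonically to single-state changes", {
  set.seed(23)
  for (i in 1:25) {
    st <- c("1" = stats::rnorm(1, 0, 4), "TS2" = stats::rnorm(1, 9, 4),
            "2" = stats::rnorm(1, 0, 4), "TS3" = stats::rnorm(1, 9, 4))
    p <- energy_profile("r", "C2", st, dgr = -12)
    tof0 <- as.numeric(tof_energy_span(p, method = "sum"))
    up <- p; up$states["TS2"] <- up$states["TS2"] + 0.5
    expect_lt(as.numeric(tof_energy_span(up, method = "sum")), tof0)
    dn <- p; dn$states["2"] <- dn$states["2"] - 0.5
    expect_lt(as.numeric(tof_energy_span(dn, method = "sum")), tof0)
  }
})

test_that("volcano curves reproduce the planted two-regime crossing", {
  ls <- small_landscape()
  profiles <- emit_profiles(ls, 30, seed = 3, sigma = 0)
  fit <- fit_lfesr(profiles)
  v <- build_volcano(fit, grid = seq(-25, 25, by = 0.1))

  # peak at the analytic line intersection of the planted relations
  expect_equal(v$peak_x, ls$peak_x, tolerance = 0.1)
  expect_equal(v$peak_log10_tof, ls$peak_log10_tof, tolerance = 1e-3)

  # the noise-free curve equals the pointwise closed-form span expression
  rt <- R_KCAL * 298.15
  lines <- ls$lfesr$C2
  closed <- vapply(v$curve$x, function(x) {
    st <- c("1" = lines[["1"]][1] * x + lines[["1"]][2],
            "TS2" = lines[["TS2"]][1] * x + lines[["TS2"]][2],
            "2" = x,
            "TS3" = lines[["TS3"]][1] * x + lines[["TS3"]][2])
    dgr <- lines$dgr[1] * x + lines$dgr[2]
    inter <- c(0, st["1"], st["2"]); ipos <- c(0, 1, 3)
    tss <- st[c("TS2", "TS3")]; tpos <- c(2, 4)
    spans <- c()
    for (ti in 1:2) for (ij in 1:3) {
      spans <- c(spans, tss[ti] - inter[ij] + if (tpos[ti] < ipos[ij]) dgr else 0)
    }
    log10(kbt_over_h(298.15)) - max(spans) / (rt * log(10))
  }, numeric(1))
  expect_equal(v$curve$log10_tof, closed, tolerance = 1e-8)

  # bands bracket the central curve
  expect_true(all(v$curve$lo <= v$curve$log10_tof + 1e-9))
  expect_true(all(v$curve$hi >= v$curve$log10_tof - 1e-9))

  expect_error(build_volcano(fit, grid = seq(-200, 200, 10)), "sensible range")
})

test_that("degenerate flat scaling relations give a flat volcano", {
  profiles <- lapply(1:6, function(i) {
    # state "2" must track the descriptor; all other states are flat
    energy_profile(paste0("p", i), "C2",
                   c("1" = 30, "TS2" = 12, "2" = i, "TS3" = 11), dgr = -10)
  })
  fit <- fit_lfesr(profiles)
  tab <- fit$table
  tab$slope[tab$state %in% c("1", "TS2", "TS3", "dgr")] <- 0
  tab$slope[tab$state == "2"] <- 0  # decouple the descriptor too
  fit$table <- tab
  v <- build_volcano(fit, grid = seq(-5, 5, 0.5))
  expect_lt(diff(range(v$curve$log10_tof)), 1e-8)
})

test_that("gaussian activity merit peaks at the target and decays", {
  expect_equal(gaussian_activity(-9, -9, 3), 1)
  expect_equal(gaussian_activity(-6, -9, 3), exp(-0.5), tolerance = 1e-12)
  expect_equal(gaussian_activity(-12, -9, 3), exp(-0.5), tolerance = 1e-12)
  xs <- seq(-9, 10, by = 0.5)
  f <- gaussian_activity(xs, -9, 3)
  expect_true(all(diff(f) < 0))
  expect_error(gaussian_activity(0, -9, 0), "width")
})

test_that("profiles round-trip through CSV", {
  ls <- small_landscape()
  profiles <- emit_profiles(ls, 10, seed = 4, mechanism = "C3")
  td <- withr::local_tempdir()
  path <- file.path(td, "profiles.csv")
  write_profiles(profiles, path)
  back <- read_profiles(path)
  expect_equal(length(back), 10)
  for (i in 1:10) {
    expect_equal(back[[i]]$states, profiles[[i]]$states, tolerance = 1e-12)
    expect_equal(back[[i]]$dgr, profiles[[i]]$dgr, tolerance = 1e-12)
    expect_identical(back[[i]]$mechanism, "C3")
  }
})
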