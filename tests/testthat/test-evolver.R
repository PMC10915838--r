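test_that("the hierarchical scalarizer enforces threshold, hierarchy, tiers", {
  spec <- scalarizer_spec()

  # hard 2.0 kcal/mol floor on median selectivity
  M <- rbind(A = c(2.1, 0.5, 0.3, 0.1), B = c(1.6, 0.5, 0.3, 0.1))
  m <- chimera_scalarize(M, spec)
  expect_gt(m[1], m[2])

  # equal on objectives 1-3 and above all thresholds: objective 4 decides
  M <- rbind(c(2.5, 0.8, 0.2, 0.10), c(2.5, 0.8, 0.2, 0.05))
  m <- chimera_scalarize(M, spec)
  expect_gt(m[2], m[1])

  # non-finite rows fall to the worst tier
  M <- rbind(c(2.5, 0.8, 0.2, 0.1), c(NA, 0.9, 0.1, 0.1), c(0.5, 0.1, 0.9, 0.9))
  m <- chimera_scalarize(M, spec)
  expect_equal(which.min(m), 2)

  # identical rows receive identical merit regardless of position
  M <- rbind(c(2.2, 0.7, 0.3, 0.2), c(1.0, 0.2, 0.5, 0.4), c(2.2, 0.7, 0.3, 0.2))
  m <- chimera_scalarize(M, spec)
  expect_equal(m[1], m[3])
})

test_that("the tolerance-to-zero limit is strict lexicographic ordering", {
  tight <- scalarizer_spec(degradation = 1e-9, spread_tolerance = 1e-9)
  set.seed(40)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    M <- cbind(stats::runif(n, 0, 4), stats::runif(n), stats::runif(n),
               stats::runif(n))
    merit <- chimera_scalarize(M, tight)
    expect_identical(rank(-merit, ties.method = "first"),
                     lexicographic_rank(M))
  }
})

test_that("the scalarizer is invariant to row order and affine rescaling", {
  spec <- scalarizer_spec()
  set.seed(41)
  M <- cbind(stats::runif(12, 0, 4), stats::runif(12), stats::runif(12),
             stats::runif(12))
  m <- chimera_scalarize(M, spec)
  perm <- sample.int(12)
  expect_equal(chimera_scalarize(M[perm, ], spec), m[perm],
               ignore_attr = TRUE)

  # positive affine rescaling of a relative objective preserves the ordering
  M2 <- M
  M2[, 2] <- 3.7 * M[, 2] + 1.2
  expect_identical(order(-chimera_scalarize(M2, spec)), order(-m))
  # ... and rescaling the thresholded objective together with its threshold
  M3 <- M
  M3[, 1] <- 2.5 * M[, 1] + 1.0
  spec3 <- scalarizer_spec(ddg_threshold = 2.5 * spec$ddg_threshold + 1.0)
  expect_identical(order(-chimera_scalarize(M3, spec3)), order(-m))
})

test_that("pareto_front matches the quadratic dominance scan", {
  pts <- rbind(c(1, 3), c(2, 2), c(3, 1), c(1, 1))
  expect_equal(pareto_front(pts), c(1, 2, 3))
  expect_equal(pareto_front(rbind(c(5, 5))), 1)

  set.seed(42)
  for (rep in 1:500) {
    n <- sample(3:40, 1)
    P <- matrix(stats::rnorm(2 * n), ncol = 2)
    if (rep %% 5 == 0) P <- round(P)  # exercise ties and duplicates
    expect_identical(pareto_front(P), pareto_oracle(P))
  }

  # orientation: minimizing the second objective flips dominance
  P <- rbind(c(2, 1), c(1, 2))
  expect_equal(pareto_front(P, maximize = c(TRUE, FALSE)), 1)
  expect_equal(pareto_front(P, maximize = c(TRUE, TRUE)), c(1, 2))
})

test_that("candidate evaluation summarizes panel predictions correctly", {
  ls <- small_landscape()
  models <- landscape_models(ls)
  set.seed(43)
  cand <- sample_candidate(ls$library)

  # single-reaction panel: median equals the prediction, zero spread
  p1 <- substrate_panel(ls$sub_a[1], ls$sub_b[1])
  fv <- evaluate_candidate(cand, p1, models)
  expect_equal(unname(fv$objectives["median_ddg"]),
               truth_ddg(ls, cand, ls$sub_a[1], ls$sub_b[1]))
  expect_equal(unname(fv$objectives["sd_ddg"]), 0)

  # a panel of identical reactions behaves like the single-reaction case
  pk <- data.frame(sub_a = rep(ls$sub_a[1], 5), sub_b = rep(ls$sub_b[1], 5))
  fvk <- evaluate_candidate(cand, pk, models)
  expect_equal(fvk$objectives[c("median_ddg", "median_f")],
               fv$objectives[c("median_ddg", "median_f")])
  expect_equal(unname(fvk$objectives["sd_ddg"]), 0)

  # medians and spreads match an independent recomputation
  set.seed(44)
  for (i in 1:100) {
    vals_ddg <- stats::runif(9, 0, 3)
    vals_desc <- stats::rnorm(9, 5, 4)
    fake <- list(selectivity = function(cand, panel) vals_ddg,
                 descriptor = function(cand, panel) vals_desc)
    panel <- substrate_panel(ls$sub_a[rep(1:3, 3)], ls$sub_b[rep(1:3, each = 3)])
    fv <- evaluate_candidate(cand, panel, fake)
    srt <- sort(vals_ddg)
    expect_equal(unname(fv$objectives["median_ddg"]), srt[5], tolerance = 1e-12)
    f <- exp(-(vals_desc + 9)^2 / 18)
    expect_equal(unname(fv$objectives["median_f"]), sort(f)[5], tolerance = 1e-12)
    expect_equal(unname(fv$objectives["sd_f"]),
                 sqrt(sum((f - mean(f))^2) / 8), tolerance = 1e-12)
  }
})

test_that("fitness is memoized: one model call per unique chromosome", {
  ls <- small_landscape()
  panel <- landscape_panel(ls, 8, seed = 45)
  calls <- new.env(); calls$n <- 0L
  counting <- list(
    selectivity = function(cand, p) {
      calls$n <- calls$n + 1L
      truth_ddg(ls, cand, p$sub_a, p$sub_b)
    },
    descriptor = function(cand, p) truth_descriptor(ls, cand, p$sub_a, p$sub_b)
  )
  run <- evolve(ls$library, panel, counting,
                config = ga_config(generations = 15, seed = 46))
  expect_identical(calls$n, run$model_calls)
  expect_identical(calls$n, nrow(run$evaluated))
  # the run revisits chromosomes (elitism alone guarantees it) without calls
  total_slots <- 15 * 10
  expect_lt(run$model_calls, total_slots)
})

test_that("zero mutation with full selection and elitism is a fixed point", {
  ls <- small_landscape()
  panel <- landscape_panel(ls, 5, seed = 47)
  models <- landscape_models(ls)
  cfg <- ga_config(population_size = 6, generations = 8, mutation_rate = 0,
                   selection_rate = 1, elitism = 6, seed = 48)
  run <- evolve(ls$library, panel, models, cfg)
  key0 <- sort(vapply(run$generations[[1]]$population,
                      function(c) c$template_id, character(1)))
  smiles_gen <- function(g) sort(vapply(run$generations[[g]]$population,
    function(c) paste(c$template_id, paste(c$assignment, collapse = ",")),
    character(1)))
  for (g in 2:8) expect_identical(smiles_gen(g), smiles_gen(1))
})

test_that("with elitism the incumbent's merit never decreases", {
  ls <- small_landscape()
  panel <- landscape_panel(ls, 8, seed = 49)
  models <- landscape_models(ls)
  spec <- scalarizer_spec()
  for (seed in 1:5) {
    run <- evolve(ls$library, panel, models,
                  config = ga_config(generations = 20, seed = seed), spec = spec)
    tr <- run$trajectory
    # pairwise scalarization of consecutive incumbents: later never loses
    for (g in 2:nrow(tr)) {
      m <- chimera_scalarize(rbind(
        as.numeric(tr[g, c("median_ddg", "median_f", "sd_ddg", "sd_f")]),
        as.numeric(tr[g - 1, c("median_ddg", "median_f", "sd_ddg", "sd_f")])
      ), spec)
      expect_gte(m[1], m[2])
    }
  }
})

test_that("assembly failures demote a candidate instead of crashing the run", {
  ls <- small_landscape()
  panel <- landscape_panel(ls, 5, seed = 50)
  failing <- list(
    selectivity = function(cand, p) {
      if (grepl("Br", cand$smiles)) stop("synthetic featurization failure")
      truth_ddg(ls, cand, p$sub_a, p$sub_b)
    },
    descriptor = function(cand, p) truth_descriptor(ls, cand, p$sub_a, p$sub_b)
  )
  run <- evolve(ls$library, panel, failing,
                config = ga_config(generations = 10, seed = 51))
  expect_s3_class(run, "ga_run")
  expect_false(grepl("Br", run$best$candidate$smiles))
})
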