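# Genetic optimization of catalyst candidates with generality fitness:
# per-candidate predictions over a substrate panel, hierarchical (Chimera-style)
# scalarization of four objectives, truncation selection, uniform crossover,
# per-gene mutation, and Pareto-front extraction.

#' Scalarizer specification for generality fitness
#'
#' Four objectives, in fixed hierarchy: (1) median predicted ddG-dagger across
#' the panel, required to exceed an absolute threshold; (2) median Gaussian
#' activity merit, maximized with a fractional degradation allowance;
#' (3) spread (sd) of ddG-dagger, minimized with a fractional compromise;
#' (4) spread of the activity merit, minimized likewise.
#'
#' @param ddg_threshold absolute floor on median ddG-dagger (kcal/mol).
#' @param activity_target volcano-peak descriptor value (kcal/mol).
#' @param activity_width Gaussian merit width sigma (kcal/mol).
#' @param degradation fractional degradation allowed on objective 2.
#' @param spread_tolerance fractional compromise on objectives 3 and 4.
#' @return object of class `scalarizer_spec`.
#' @export
scalarizer_spec <- function(ddg_threshold = 2.0, activity_target = -9.0,
                            activity_width = 3.0, degradation = 0.10,
                            spread_tolerance = 0.25) {
  stopifnot(degradation > 0, degradation < 1,
            spread_tolerance > 0, spread_tolerance < 1,
            activity_width > 0)
  structure(list(ddg_threshold = ddg_threshold,
                 activity_target = activity_target,
                 activity_width = activity_width,
                 degradation = degradation,
                 spread_tolerance = spread_tolerance),
            class = "scalarizer_spec")
}

#' GA configuration
#'
#' Defaults follow the study conditions: populations of 10 randomized
#' individuals, 10% mutation, 25% truncation selection, 50 generations, one
#' elite, toluene as solvent, benzoic acid as co-catalyst for selectivity
#' calls and acetic acid for descriptor calls (none for CPA-only runs).
#'
#' @param population_size individuals per generation (>= 2).
#' @param generations number of generations.
#' @param mutation_rate per-gene mutation probability in (0, 1).
#' @param selection_rate fraction of the population kept as parents, in (0, 1).
#' @param elitism number of top candidates copied unchanged (>= 1 recommended).
#' @param seed RNG seed for the run.
#' @param solvent fixed solvent context.
#' @param cocatalyst_selectivity,cocatalyst_descriptor fixed co-catalyst SMILES
#'   for the two surrogate calls; use `NA` for no co-catalyst.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, generations = 50L,
                      mutation_rate = 0.10, selection_rate = 0.25,
                      elitism = 1L, seed = 1L,
                      solvent = "toluene",
                      cocatalyst_selectivity = "OC(=O)c1ccccc1",
                      cocatalyst_descriptor = "CC(=O)O") {
  stopifnot(population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate < 1,
            selection_rate > 0, selection_rate <= 1,
            elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 selection_rate = selection_rate,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed),
                 solvent = solvent,
                 cocatalyst_selectivity = cocatalyst_selectivity,
                 cocatalyst_descriptor = cocatalyst_descriptor),
            class = "ga_config")
}

# Internal: dispatch a predictor. `model` is either a surrogate_ensemble or a
# function(candidate, panel) -> numeric vector of per-reaction predictions.
.predict_panel <- function(model, candidate, panel, cocatalyst, solvent) {
  if (is.function(model)) {
    return(list(mean = model(candidate, panel), std = rep(0, nrow(panel))))
  }
  df <- data.frame(sub_a = panel$sub_a, sub_b = panel$sub_b,
                   catalyst = candidate$smiles,
                   cocatalyst = if (is.na(cocatalyst)) NA_character_ else cocatalyst,
                   solvent = solvent, stringsAsFactors = FALSE)
  pr <- predict(model, df)
  list(mean = pr$mean, std = pr$std)
}

#' Evaluate one candidate's generality fitness vector
#'
#' Predicts ddG-dagger and the activity descriptor for every panel reaction in
#' the fixed solvent/co-catalyst context, converts descriptors to the Gaussian
#' activity merit, and summarizes medians and spreads.
#'
#' @param candidate a `catalyst_candidate`.
#' @param panel a `substrate_panel`.
#' @param models list with elements `selectivity` and `descriptor`, each a
#'   `surrogate_ensemble` or a `function(candidate, panel)` returning
#'   per-reaction values (ground-truth benchmarking).
#' @param spec a [scalarizer_spec()].
#' @param config a [ga_config()] providing the fixed reaction context.
#' @return object of class `fitness_vector` with per-reaction predictions and
#'   the objective summary `c(median_ddg, median_f, sd_ddg, sd_f)`.
#' @export
evaluate_candidate <- function(candidate, panel, models,
                               spec = scalarizer_spec(), config = ga_config()) {
  sel <- .predict_panel(models$selectivity, candidate, panel,
                        config$cocatalyst_selectivity, config$solvent)
  des <- .predict_panel(models$descriptor, candidate, panel,
                        config$cocatalyst_descriptor, config$solvent)
  f <- gaussian_activity(des$mean, spec$activity_target, spec$activity_width)
  objectives <- c(
    median_ddg = stats::median(sel$mean),
    median_f = stats::median(f),
    sd_ddg = stats::sd(sel$mean),
    sd_f = stats::sd(f)
  )
  # single-reaction panels have no spread
  if (nrow(panel) == 1L) objectives[c("sd_ddg", "sd_f")] <- 0
  structure(
    list(candidate = candidate,
         ddg = sel$mean, ddg_std = sel$std,
         descriptor = des$mean, descriptor_std = des$std,
         f = f, objectives = objectives),
    class = "fitness_vector"
  )
}

#' Hierarchical achievement scalarization of generality objectives
#'
#' Region-carving scalarizer over a batch of candidates. Objective columns are
#' `median_ddg` (maximize, absolute threshold), `median_f` (maximize,
#' fractional degradation), `sd_ddg` and `sd_f` (minimize, fractional
#' compromise). The threshold of each relative objective is
#' `best - fraction * range`, computed over the candidates satisfying all
#' previous objectives. Candidates are tiered by how many leading objectives
#' they satisfy and ranked within a tier by the first unsatisfied (or the
#' last) objective, yielding a total order; larger merit is better. As the
#' tolerances shrink to zero the ordering becomes strictly lexicographic.
#'
#' @param objectives numeric matrix, candidates x 4, columns
#'   (median_ddg, median_f, sd_ddg, sd_f). Non-finite rows drop to the worst
#'   tier.
#' @param spec a [scalarizer_spec()].
#' @return numeric merit vector; attributes `tier` (satisfied-prefix length)
#'   and `thresholds`.
#' @export
chimera_scalarize <- function(objectives, spec = scalarizer_spec()) {
  M <- as.matrix(objectives)
  if (ncol(M) != 4) stop("objective matrix must have 4 columns")
  n <- nrow(M)
  if (n < 1) stop("need at least one candidate")
  # orient every objective to larger-is-better
  S <- cbind(M[, 1], M[, 2], -M[, 3], -M[, 4])
  finite <- apply(S, 1, function(r) all(is.finite(r)))
  fracs <- c(NA, spec$degradation, spec$spread_tolerance, spec$spread_tolerance)
  thresholds <- numeric(4)
  thresholds[1] <- spec$ddg_threshold
  eps <- 1e-12
  sat <- matrix(FALSE, n, 4)
  region <- finite
  for (k in 1:4) {
    pool <- if (any(region)) region else finite
    if (k == 1) {
      tk <- thresholds[1]
    } else {
      if (!any(pool)) { thresholds[k] <- NA; next }
      best <- max(S[pool, k]); worst <- min(S[pool, k])
      tk <- best - fracs[k] * (best - worst)
      thresholds[k] <- tk
    }
    sat[finite, k] <- S[finite, k] >= tk - eps
    region <- region & sat[, k]
  }
  # tier = length of satisfied prefix; deciding score = first unsatisfied
  # objective (or the last, when all four are satisfied)
  tier <- integer(n)
  decide <- numeric(n)
  for (i in seq_len(n)) {
    if (!finite[i]) { tier[i] <- -1L; decide[i] <- -Inf; next }
    m <- 0L
    while (m < 4L && sat[i, m + 1L]) m <- m + 1L
    tier[i] <- m
    decide[i] <- S[i, min(m + 1L, 4L)]
  }
  merit <- numeric(n)
  for (m in sort(unique(tier))) {
    idx <- tier == m
    d <- decide[idx]
    fin <- is.finite(d)
    scaled <- rep(0, sum(idx))
    if (any(fin)) {
      rng <- range(d[fin])
      span <- rng[2] - rng[1]
      scaled[fin] <- if (span < eps) 0.5 else (d[fin] - rng[1]) / span
    }
    merit[idx] <- m + 0.999 * scaled
  }
  attr(merit, "tier") <- tier
  attr(merit, "thresholds") <- thresholds
  merit
}

# Stable pairwise comparator: TRUE when `a` is strictly better than `b` under
# the two-row scalarization (a transitive lexicographic-with-tolerance order).
.beats <- function(a, b, spec) {
  m <- chimera_scalarize(rbind(a, b), spec)
  m[1] > m[2]
}

#' Pareto front of a two-objective candidate set
#'
#' @param points numeric matrix/data.frame, candidates x 2.
#' @param maximize logical length-2; `FALSE` entries are minimized.
#' @return sorted integer indices of all non-dominated points (a point is
#'   dominated if another is at least as good in both objectives and strictly
#'   better in one).
#' @export
pareto_front <- function(points, maximize = c(TRUE, TRUE)) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2, all(is.finite(P)))
  for (j in 1:2) if (!maximize[j]) P[, j] <- -P[, j]
  n <- nrow(P)
  ord <- order(-P[, 1], -P[, 2])
  front <- logical(n)
  best2 <- -Inf  # max obj2 among points with strictly larger obj1
  i <- 1L
  while (i <= n) {
    # handle ties on objective 1 as one group: within it, only the group's
    # obj2 maximum survives; against earlier groups, dominance needs obj2 >=
    j <- i
    while (j < n && P[ord[j + 1L], 1] == P[ord[i], 1]) j <- j + 1L
    grp <- ord[i:j]
    grp_max2 <- max(P[grp, 2])
    front[grp] <- (P[grp, 2] > best2) & (P[grp, 2] == grp_max2)
    best2 <- max(best2, grp_max2)
    i <- j + 1L
  }
  sort(which(front))
}

# --- genetic operators ------------------------------------------------------

.random_assignment <- function(template, library) {
  asg <- character(length(template$slots))
  names(asg) <- names(template$slots)
  for (g in .slot_groups(template)) {
    pool <- library$by_category[[template$slots[[g[1]]]]]
    asg[g] <- pool[sample.int(length(pool), 1L)]
  }
  asg
}

.enforce_symmetry <- function(asg, template) {
  for (g in template$symmetric_groups) asg[g] <- asg[[g[1]]]
  asg
}

.crossover <- function(p1, p2, library) {
  tpl <- library$templates[[p1$template_id]]
  asg <- p1$assignment
  for (slot in names(tpl$slots)) {
    if (stats::runif(1) < 0.5) {
      # inherit from parent 2 where the slot name exists and is compatible
      g2 <- if (slot %in% names(p2$assignment)) p2$assignment[[slot]] else NULL
      if (!is.null(g2) && !is.na(g2) &&
          library$fragments[[g2]]$category == tpl$slots[[slot]]) {
        asg[slot] <- g2
      }
    }
  }
  .enforce_symmetry(asg, tpl)
}

.mutate <- function(template_id, asg, library, rate) {
  # template gene
  if (stats::runif(1) < rate && length(library$templates) > 1L) {
    new_tid <- sample(setdiff(names(library$templates), template_id), 1L)
    new_tpl <- library$templates[[new_tid]]
    new_asg <- .random_assignment(new_tpl, library)
    # keep genes whose slot name and category carry over
    for (slot in intersect(names(new_tpl$slots), names(asg))) {
      fid <- asg[[slot]]
      if (library$fragments[[fid]]$category == new_tpl$slots[[slot]]) {
        new_asg[slot] <- fid
      }
    }
    template_id <- new_tid
    asg <- .enforce_symmetry(new_asg, new_tpl)
  }
  tpl <- library$templates[[template_id]]
  for (g in .slot_groups(tpl)) {
    if (stats::runif(1) < rate) {
      pool <- library$by_category[[tpl$slots[[g[1]]]]]
      asg[g] <- pool[sample.int(length(pool), 1L)]
    }
  }
  list(template_id = template_id, assignment = .enforce_symmetry(asg, tpl))
}

.candidate_key <- function(template_id, asg) {
  paste0(template_id, "|", paste(names(asg), asg, sep = "=", collapse = ";"))
}

#' Run a generality-oriented genetic optimization
#'
#' Each generation: evaluate all unseen candidates (fitness is memoized by
#' chromosome, so duplicates cost nothing), rank the population with
#' [chimera_scalarize()], carry over the elite, keep the top
#' `selection_rate` fraction as parents, breed offspring by uniform per-slot
#' crossover of random parent pairs, and mutate each gene (template and slots)
#' with probability `mutation_rate`. Candidates that fail to assemble receive
#' the worst merit instead of aborting the run. The incumbent best is tracked
#' with a stable pairwise comparator so that, with elitism, it never worsens.
#'
#' @param library a `catalyst_library`.
#' @param panel a `substrate_panel`.
#' @param models list with `selectivity` and `descriptor` predictors (see
#'   [evaluate_candidate()]).
#' @param config a [ga_config()].
#' @param spec a [scalarizer_spec()].
#' @return object of class `ga_run`: `trajectory` (one row per generation),
#'   `generations` (per-generation populations and merits), `best` (incumbent
#'   candidate), `best_overall` (argmax of a joint re-scalarization of every
#'   candidate evaluated during the run), `evaluated` (their objectives), and
#'   `model_calls` (surrogate invocation count, for the memoization audit).
#' @export
evolve <- function(library, panel, models, config = ga_config(),
                   spec = scalarizer_spec()) {
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  calls <- 0L

  eval_chrom <- function(template_id, asg) {
    key <- .candidate_key(template_id, asg)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fv <- tryCatch({
      cand <- assemble(library$templates[[template_id]], as.list(asg), library)
      calls <<- calls + 1L
      evaluate_candidate(cand, panel, models, spec, config)
    }, error = function(e) {
      structure(list(candidate = list(template_id = template_id,
                                      assignment = asg, smiles = NA_character_),
                     objectives = c(median_ddg = NA_real_, median_f = NA_real_,
                                    sd_ddg = NA_real_, sd_f = NA_real_),
                     error = conditionMessage(e)),
                class = "fitness_vector")
    })
    cache[[key]] <- fv
    fv
  }

  # initial population: randomized individuals
  pop <- lapply(seq_len(config$population_size), function(i) {
    cand <- sample_candidate(library)
    list(template_id = cand$template_id, assignment = cand$assignment)
  })

  incumbent <- NULL
  trajectory <- vector("list", config$generations)
  generations <- vector("list", config$generations)

  for (gen in seq_len(config$generations)) {
    fvs <- lapply(pop, function(ch) eval_chrom(ch$template_id, ch$assignment))
    if (all(vapply(fvs, function(f) any(!is.finite(f$objectives)), logical(1)))) {
      stop("GA extinction at generation ", gen,
           ": no candidate in the population assembles/evaluates")
    }
    obj <- do.call(rbind, lapply(fvs, `[[`, "objectives"))
    merit <- chimera_scalarize(obj, spec)
    ord <- order(-merit)  # ties keep lowest index first (stable)
    gen_best <- fvs[[ord[1]]]
    changed <- is.null(incumbent) ||
      .candidate_key(gen_best$candidate$template_id, gen_best$candidate$assignment) !=
        .candidate_key(incumbent$candidate$template_id, incumbent$candidate$assignment)
    if (is.null(incumbent) ||
        .beats(gen_best$objectives, incumbent$objectives, spec)) {
      incumbent <- gen_best
    } else {
      changed <- FALSE
    }
    generations[[gen]] <- list(population = pop, objectives = obj, merit = merit,
                               best_index = ord[1])
    trajectory[[gen]] <- data.frame(
      generation = gen,
      best_smiles = incumbent$candidate$smiles,
      best_template = incumbent$candidate$template_id,
      median_ddg = incumbent$objectives[["median_ddg"]],
      median_f = incumbent$objectives[["median_f"]],
      sd_ddg = incumbent$objectives[["sd_ddg"]],
      sd_f = incumbent$objectives[["sd_f"]],
      merit = merit[ord[1]],
      best_changed = changed,
      model_calls = calls,
      stringsAsFactors = FALSE
    )
    if (gen == config$generations) break

    # next generation: elite + incumbent guard, then offspring from parents
    n_parents <- max(2L, ceiling(config$selection_rate * config$population_size))
    parents <- pop[ord[seq_len(min(n_parents, length(pop)))]]
    nxt <- list()
    if (config$elitism > 0L) {
      elite_n <- min(config$elitism, length(pop))
      nxt <- pop[ord[seq_len(elite_n)]]
      # elitism guarantee: the incumbent stays in the population
      keys <- vapply(nxt, function(c) .candidate_key(c$template_id, c$assignment),
                     character(1))
      inc_key <- .candidate_key(incumbent$candidate$template_id,
                                incumbent$candidate$assignment)
      if (!inc_key %in% keys) {
        nxt[[1]] <- list(template_id = incumbent$candidate$template_id,
                         assignment = incumbent$candidate$assignment)
      }
    }
    nxt_keys <- vapply(nxt, function(c) .candidate_key(c$template_id, c$assignment),
                       character(1))
    while (length(nxt) < config$population_size) {
      pi <- sample.int(length(parents), 2L, replace = length(parents) < 2L)
      p1 <- parents[[pi[1]]]; p2 <- parents[[pi[2]]]
      child_asg <- .crossover(p1, p2, library)
      child <- .mutate(p1$template_id, child_asg, library, config$mutation_rate)
      # keep populations duplicate-free where possible: a clone of a member
      # already present is re-mutated (it would only share memoized fitness);
      # a child the run has already scored gets a few extra attempts too, a
      # soft novelty bias that keeps the small population exploring
      tries <- 0L
      while (config$mutation_rate > 0) {
        key <- .candidate_key(child$template_id, child$assignment)
        in_pop <- key %in% nxt_keys
        seen <- !is.null(cache[[key]])
        if ((!in_pop && !seen) || (tries >= 20L) || (!in_pop && tries >= 5L)) break
        child <- .mutate(child$template_id, child$assignment, library,
                         max(config$mutation_rate, 0.5))
        tries <- tries + 1L
      }
      nxt[[length(nxt) + 1L]] <- child
      nxt_keys <- c(nxt_keys, .candidate_key(child$template_id, child$assignment))
    }
    pop <- nxt
  }

  trajectory <- do.call(rbind, trajectory)

  # joint re-scalarization of everything the run evaluated
  keys <- ls(cache)
  fvs <- lapply(keys, function(k) cache[[k]])
  ok <- vapply(fvs, function(f) all(is.finite(f$objectives)), logical(1))
  eval_df <- data.frame(
    key = keys,
    smiles = vapply(fvs, function(f) f$candidate$smiles %||% NA_character_, character(1)),
    template_id = vapply(fvs, function(f) f$candidate$template_id, character(1)),
    do.call(rbind, lapply(fvs, function(f) as.data.frame(t(f$objectives)))),
    stringsAsFactors = FALSE
  )
  joint <- rep(-Inf, length(fvs))
  if (any(ok)) {
    joint[ok] <- chimera_scalarize(
      do.call(rbind, lapply(fvs[ok], `[[`, "objectives")), spec)
  }
  eval_df$merit <- joint
  best_overall <- fvs[[which.max(joint)]]

  structure(
    list(trajectory = trajectory, generations = generations,
         best = incumbent, best_overall = best_overall,
         evaluated = eval_df, model_calls = calls, config = config,
         spec = spec),
    class = "ga_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ga_run <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat("ga_run:", n, "generations,", x$model_calls, "model calls,",
      nrow(x$evaluated), "unique candidates\n")
  cat("  best:", x$best$candidate$smiles, "\n")
  cat("  objectives:",
      paste(names(x$best$objectives), signif(x$best$objectives, 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
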