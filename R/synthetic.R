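# Synthetic benchmark generator: fragment libraries built from real small
# molecules, additive ground-truth landscapes for selectivity and the activity
# descriptor, reaction tables with Gaussian noise, energy profiles obeying
# planted linear scaling relations, and a brute-force optimum oracle.
#
# The SMILES are genuine substituted indoles/tryptamines, carbonyl compounds
# and catalyst-like scaffolds so that fingerprints are chemically meaningful,
# but the planted fragment/substrate effects attach to fragment identity, not
# to chemistry: this is a statistical stand-in for a curated reaction
# database, not a model of real Pictet-Spengler energetics.

.SUBSTITUENTS <- c("F", "Cl", "Br", "C", "CC", "CCC", "C(C)C", "C(C)(C)C",
                   "OC", "OCC", "O", "C(F)(F)F", "[N+](=O)[O-]", "C#N",
                   "C=C", "OC(C)=O", "C(=O)OC", "N", "N(C)C", "SC",
                   "c2ccccc2", "Cc2ccccc2", "OCc2ccccc2", "c2ccc(F)cc2",
                   "c2ccc(C)cc2")

.SUBA_SCAFFOLDS <- c(
  "NCCc1c[nH]c2cc({X})cc({Y})c12",
  "NCCc1c[nH]c2cc({X})ccc12",
  "NCCc1c[nH]c2ccc({X})cc12",
  "C(=O)({X})NCCc1c[nH]c2ccc({Y})cc12",
  "C({X})NCCc1c[nH]c2cc({Y})ccc12"
)

.SUBB_SCAFFOLDS <- c(
  "O=Cc1ccc({X})cc1{Y}",
  "O=C{X}",
  "O=CC({X}){Y}",
  "O=C(C){X}",
  "O=C(C(=O)OC){X}",
  "O=C(C(N)=O){X}",
  "O=C({X})C(=O){Y}"
)

.expand_scaffold <- function(scaffold, pool) {
  toks <- .placeholders(scaffold)
  if (length(toks) == 0L) return(scaffold)
  grid <- expand.grid(rep(list(pool), length(toks)), stringsAsFactors = FALSE)
  apply(grid, 1, function(row) {
    smi <- scaffold
    for (i in seq_along(toks)) smi <- sub(paste0("{", toks[i], "}"), row[i], smi, fixed = TRUE)
    smi
  })
}

#' Generate pools of synthetic substrate SMILES
#'
#' Decorates tryptamine-derivative scaffolds (SubA) and carbonyl scaffolds
#' (SubB) with common substituents, canonicalizes, deduplicates, and returns
#' the first `n_a`/`n_b` unique molecules in a fixed deterministic order.
#'
#' @param n_a number of SubA (tryptamine derivatives).
#' @param n_b number of SubB (carbonyl compounds).
#' @return list with character vectors `sub_a` and `sub_b`.
#' @export
synthetic_substrates <- function(n_a = 20L, n_b = 20L) {
  gen <- function(scaffolds, n) {
    out <- character(0)
    for (sc in scaffolds) {
      cand <- .expand_scaffold(sc, .SUBSTITUENTS)
      can <- canonical_smiles(cand)
      out <- unique(c(out, can[!is.na(can)]))
      if (length(out) >= n) break
    }
    if (length(out) < n) {
      stop("substrate scaffolds can only produce ", length(out),
           " unique molecules; asked for ", n)
    }
    out[seq_len(n)]
  }
  list(sub_a = gen(.SUBA_SCAFFOLDS, n_a), sub_b = gen(.SUBB_SCAFFOLDS, n_b))
}

# Benchmark catalyst library: an N-aryl urea (2 slots), and a dual
# hydrogen-bond donor with two symmetric N-aryl arms plus one ring slot.
# Category sizes 6/10/12 give a 6*10 + 12*10 = 180-candidate space.
.benchmark_templates <- function() {
  list(
    catalyst_template(
      "urea", "urea",
      "O=C(Nc1ccc({R2a})cc1)N{R1a}",
      c(R1a = "R1", R2a = "R2")
    ),
    catalyst_template(
      "bisarylurea", "dual-HBD urea",
      "O=C(Nc1ccc({R3a})cc1{R2c})Nc1ccc({R3b})cc1",
      c(R3a = "R3", R3b = "R3", R2c = "R2"),
      symmetric_groups = list(c("R3a", "R3b"))
    )
  )
}

.benchmark_fragments <- function(sizes = c(R1 = 6L, R2 = 10L, R3 = 12L)) {
  pools <- list(
    R1 = c("C", "CC", "C(C)C", "C(C)(C)C", "c2ccccc2", "Cc2ccccc2",
           "C2CCCCC2", "c2ccc(C)cc2"),
    R2 = c("F", "Cl", "Br", "C", "CC", "OC", "C(F)(F)F", "[N+](=O)[O-]",
           "C#N", "O", "CCC", "OCC"),
    R3 = c("F", "Cl", "C", "CC", "OC", "C(F)(F)F", "c2ccccc2", "C(C)C",
           "C(C)(C)C", "Br", "C#N", "OCC", "[N+](=O)[O-]", "CCC")
  )
  frags <- list()
  for (cat in names(sizes)) {
    pool <- pools[[cat]]
    if (sizes[[cat]] > length(pool)) {
      stop("category ", cat, " pool has only ", length(pool), " fragments")
    }
    for (i in seq_len(sizes[[cat]])) {
      frags[[length(frags) + 1L]] <-
        catalyst_fragment(sprintf("%s_%02d", tolower(cat), i), pool[i], cat)
    }
  }
  frags
}

# Planted linear scaling relations (slope, intercept per state, kcal/mol).
# The C2 lines cross so that the TOF volcano peaks at a descriptor value of
# -9.0 kcal/mol; the C3 pathway sits slightly below it everywhere.
.PLANTED_LFESR <- list(
  C2 = list("1" = c(0.15, 3.0), "TS2" = c(0.35, 13.65),
            "2" = c(1.0, 0.0), "TS3" = c(0.50, 6.0),
            dgr = c(0.05, -12.0)),
  C3 = list("1" = c(0.15, 3.0), "TS1" = c(0.36, 14.0), "1B" = c(0.50, 3.0),
            "TS2" = c(0.35, 13.65), "2" = c(1.0, 0.0), "TS3" = c(0.50, 6.0),
            dgr = c(0.05, -12.0))
)

.planted_profile <- function(landscape, x, mechanism = "C2",
                             reaction_id = sprintf("x=%.3f", x)) {
  lines <- landscape$lfesr[[mechanism]]
  st <- setdiff(names(lines), "dgr")
  e <- stats::setNames(
    vapply(st, function(s) lines[[s]][1] * x + lines[[s]][2], numeric(1)), st)
  energy_profile(reaction_id, mechanism, e,
                 dgr = lines$dgr[1] * x + lines$dgr[2])
}

#' Construct a synthetic ground-truth landscape
#'
#' Builds a catalyst library and substrate pools, then plants additive
#' ground-truth functions for both surrogate targets: ddG-dagger is a template
#' base plus per-gene fragment effects plus substrate effects (plus optional
#' sparse fragment-substrate interactions), truncated at 0; the descriptor is
#' centered on the weak-binding side of the volcano (default +7 kcal/mol) with
#' fragment effects anti-correlated with the selectivity effects through
#' `tradeoff`, reproducing the activity/selectivity tension. Linear scaling
#' relations for the energy profiles are planted so the volcano peak falls at
#' -9.0 kcal/mol.
#'
#' @param seed RNG seed; the whole landscape is reproducible from it.
#' @param category_sizes named sizes of the fragment categories.
#' @param n_sub_a,n_sub_b substrate pool sizes.
#' @param noise_ddg,noise_descriptor Gaussian noise sd (kcal/mol) applied by
#'   [emit_reaction_table()].
#' @param noise_state per-state noise sd (kcal/mol) used by [emit_profiles()].
#' @param interaction_density fraction of (fragment, substrate) pairs carrying
#'   an interaction term.
#' @param tradeoff strength of the selectivity/activity anti-correlation.
#' @param descriptor_center mean of the descriptor distribution (kcal/mol).
#' @return object of class `synthetic_landscape`.
#' @export
make_landscape <- function(seed = 1L,
                           category_sizes = c(R1 = 6L, R2 = 10L, R3 = 12L),
                           n_sub_a = 20L, n_sub_b = 20L,
                           noise_ddg = 0.3, noise_descriptor = 1.0,
                           noise_state = 0.5,
                           interaction_density = 0.0, tradeoff = 0.5,
                           descriptor_center = 7.0) {
  if (any(category_sizes < 1) || n_sub_a < 1 || n_sub_b < 1) {
    stop("degenerate landscape sizes")
  }
  set.seed(seed)
  library <- catalyst_library(.benchmark_templates(), .benchmark_fragments(category_sizes))
  subs <- synthetic_substrates(n_sub_a, n_sub_b)

  fids <- names(library$fragments)
  tids <- names(library$templates)
  fcat <- vapply(library$fragments, `[[`, character(1), "category")
  # effects are centered (per fragment category and per pool) so the
  # population means sit exactly at the configured levels
  center_by <- function(x, g) x - stats::ave(x, g)
  frag_ddg <- stats::setNames(
    center_by(stats::rnorm(length(fids), 0, 0.45), fcat), fids)
  frag_desc <- stats::setNames(
    center_by(tradeoff * 2.0 * frag_ddg + stats::rnorm(length(fids), 0, 0.8),
              fcat), fids)
  base_ddg <- stats::setNames(stats::rnorm(length(tids), 1.1, 0.25), tids)
  base_desc <- stats::setNames(
    scale(stats::rnorm(length(tids), 0, 1.0), scale = FALSE)[, 1], tids)
  sub_a_ddg <- stats::setNames(
    center_by(stats::rnorm(n_sub_a, 0, 0.35), 1), subs$sub_a)
  sub_b_ddg <- stats::setNames(
    center_by(stats::rnorm(n_sub_b, 0, 0.35), 1), subs$sub_b)
  sub_a_desc <- stats::setNames(
    center_by(stats::rnorm(n_sub_a, 0, 1.2), 1), subs$sub_a)
  sub_b_desc <- stats::setNames(
    center_by(stats::rnorm(n_sub_b, 0, 1.2), 1), subs$sub_b)

  interactions <- list(ddg = list(), desc = list())
  if (interaction_density > 0) {
    all_subs <- c(subs$sub_a, subs$sub_b)
    for (f in fids) {
      hit <- stats::runif(length(all_subs)) < interaction_density
      for (s in all_subs[hit]) {
        interactions$ddg[[paste(f, s, sep = "|")]] <- stats::rnorm(1, 0, 0.3)
        interactions$desc[[paste(f, s, sep = "|")]] <- stats::rnorm(1, 0, 0.5)
      }
    }
  }

  ls <- structure(
    list(seed = as.integer(seed), library = library,
         sub_a = subs$sub_a, sub_b = subs$sub_b,
         frag_ddg = frag_ddg, frag_desc = frag_desc,
         base_ddg = base_ddg, base_desc = base_desc,
         sub_a_ddg = sub_a_ddg, sub_b_ddg = sub_b_ddg,
         sub_a_desc = sub_a_desc, sub_b_desc = sub_b_desc,
         interactions = interactions,
         noise_ddg = noise_ddg, noise_descriptor = noise_descriptor,
         noise_state = noise_state,
         descriptor_center = descriptor_center, tradeoff = tradeoff,
         lfesr = .PLANTED_LFESR),
    class = "synthetic_landscape"
  )

  # locate the planted volcano peak from the noise-free lines
  grid <- seq(-25, 25, by = 0.25)
  lt <- vapply(grid, function(x)
    attr(tof_energy_span(.planted_profile(ls, x, "C2")), "log10_tof"), numeric(1))
  i <- which.max(lt)
  opt <- stats::optimize(
    function(x) attr(tof_energy_span(.planted_profile(ls, x, "C2")), "log10_tof"),
    c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]), maximum = TRUE)
  ls$peak_x <- opt$maximum
  ls$peak_log10_tof <- opt$objective
  ls
}

# per-gene fragment sum: symmetric slot groups contribute once
.gene_fragments <- function(landscape, candidate) {
  tpl <- landscape$library$templates[[candidate$template_id]]
  vapply(.slot_groups(tpl), function(g) candidate$assignment[[g[1]]], character(1))
}

.interaction_sum <- function(landscape, which, frags, sub_a, sub_b) {
  tbl <- landscape$interactions[[which]]
  if (!length(tbl)) return(0)
  s <- 0
  for (f in frags) {
    for (sub in c(sub_a, sub_b)) {
      v <- tbl[[paste(f, sub, sep = "|")]]
      if (!is.null(v)) s <- s + v
    }
  }
  s
}

#' Ground-truth selectivity of a candidate/substrate combination
#'
#' @param landscape a `synthetic_landscape`.
#' @param candidate a `catalyst_candidate` (or list with `template_id`,
#'   `assignment`).
#' @param sub_a,sub_b substrate SMILES from the landscape pools (vectorized,
#'   recycled to equal length).
#' @return ddG-dagger truth values (kcal/mol, truncated at 0).
#' @export
truth_ddg <- function(landscape, candidate, sub_a, sub_b) {
  frags <- .gene_fragments(landscape, candidate)
  base <- landscape$base_ddg[[candidate$template_id]] +
    sum(landscape$frag_ddg[frags])
  n <- max(length(sub_a), length(sub_b))
  sub_a <- rep_len(sub_a, n); sub_b <- rep_len(sub_b, n)
  v <- vapply(seq_len(n), function(i) {
    base + landscape$sub_a_ddg[[sub_a[i]]] + landscape$sub_b_ddg[[sub_b[i]]] +
      .interaction_sum(landscape, "ddg", frags, sub_a[i], sub_b[i])
  }, numeric(1))
  pmax(v, 0)
}

#' Ground-truth activity descriptor of a candidate/substrate combination
#'
#' @inheritParams truth_ddg
#' @return descriptor truth values (kcal/mol).
#' @export
truth_descriptor <- function(landscape, candidate, sub_a, sub_b) {
  frags <- .gene_fragments(landscape, candidate)
  base <- landscape$descriptor_center +
    landscape$base_desc[[candidate$template_id]] +
    sum(landscape$frag_desc[frags])
  n <- max(length(sub_a), length(sub_b))
  sub_a <- rep_len(sub_a, n); sub_b <- rep_len(sub_b, n)
  vapply(seq_len(n), function(i) {
    base + landscape$sub_a_desc[[sub_a[i]]] + landscape$sub_b_desc[[sub_b[i]]] +
      .interaction_sum(landscape, "desc", frags, sub_a[i], sub_b[i])
  }, numeric(1))
}

#' Ground-truth predictors in the form the GA consumes
#'
#' @param landscape a `synthetic_landscape`.
#' @return list with `selectivity` and `descriptor` functions
#'   `(candidate, panel) -> numeric`, usable as the `models` argument of
#'   [evolve()] and [evaluate_candidate()].
#' @export
landscape_models <- function(landscape) {
  list(
    selectivity = function(candidate, panel)
      truth_ddg(landscape, candidate, panel$sub_a, panel$sub_b),
    descriptor = function(candidate, panel)
      truth_descriptor(landscape, candidate, panel$sub_a, panel$sub_b)
  )
}

#' Random substrate panel from a landscape's pools
#'
#' @param landscape a `synthetic_landscape`.
#' @param k panel size.
#' @param seed RNG seed.
#' @return a [substrate_panel()].
#' @export
landscape_panel <- function(landscape, k = 15L, seed = 1L) {
  n <- length(landscape$sub_a) * length(landscape$sub_b)
  if (k > n) stop("k exceeds the ", n, " available substrate pairs")
  set.seed(seed)
  idx <- sample.int(n, k)
  ai <- (idx - 1L) %% length(landscape$sub_a) + 1L
  bi <- (idx - 1L) %/% length(landscape$sub_a) + 1L
  substrate_panel(landscape$sub_a[ai], landscape$sub_b[bi], name = "synthetic")
}

#' Emit a noisy synthetic reaction table
#'
#' Samples candidate/substrate combinations from the landscape, sets
#' `ddg_kcal` to truth plus Gaussian noise (truncated at 0) and
#' `descriptor_kcal` to truth plus its own noise, and completes er/ee.
#'
#' @param landscape a `synthetic_landscape`.
#' @param n number of reactions.
#' @param seed RNG seed.
#' @param cocatalyst,solvent fixed reaction context written into the table.
#' @return a `reaction_table` with attribute `truth` holding the noise-free
#'   values.
#' @export
emit_reaction_table <- function(landscape, n, seed = 1L,
                                cocatalyst = "OC(=O)c1ccccc1",
                                solvent = "toluene") {
  stopifnot(n >= 1)
  set.seed(seed)
  cands <- sample_candidate(landscape$library, n)
  if (n == 1L) cands <- list(cands)
  sub_a <- sample(landscape$sub_a, n, replace = TRUE)
  sub_b <- sample(landscape$sub_b, n, replace = TRUE)
  t_ddg <- vapply(seq_len(n), function(i)
    truth_ddg(landscape, cands[[i]], sub_a[i], sub_b[i]), numeric(1))
  t_desc <- vapply(seq_len(n), function(i)
    truth_descriptor(landscape, cands[[i]], sub_a[i], sub_b[i]), numeric(1))
  ddg <- pmax(t_ddg + stats::rnorm(n, 0, landscape$noise_ddg), 0)
  desc <- t_desc + stats::rnorm(n, 0, landscape$noise_descriptor)
  df <- data.frame(
    sub_a = sub_a, sub_b = sub_b,
    catalyst = vapply(cands, `[[`, character(1), "smiles"),
    cocatalyst = cocatalyst, solvent = solvent,
    temperature_K = 298.15,
    er = NA_real_, ee = NA_real_, ddg_kcal = ddg, descriptor_kcal = desc,
    source = "synthetic", stringsAsFactors = FALSE
  )
  out <- reaction_table(df, check_smiles = FALSE)
  attr(out, "truth") <- data.frame(ddg = t_ddg, descriptor = t_desc)
  out
}

#' Emit synthetic energy profiles obeying the planted scaling relations
#'
#' Descriptor values are drawn around the landscape's descriptor center; each
#' state energy is its planted line plus Gaussian noise, except state "2",
#' which is set exactly to the descriptor (it defines the x-axis).
#'
#' @param landscape a `synthetic_landscape`.
#' @param n number of profiles.
#' @param seed RNG seed.
#' @param mechanism "C2" or "C3".
#' @param sigma per-state noise sd; defaults to the landscape's `noise_state`.
#' @param x_sd spread of the sampled descriptor values.
#' @return list of `energy_profile` objects.
#' @export
emit_profiles <- function(landscape, n, seed = 1L, mechanism = c("C2", "C3"),
                          sigma = landscape$noise_state, x_sd = 6.0) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  xs <- stats::rnorm(n, landscape$descriptor_center, x_sd)
  lines <- landscape$lfesr[[mechanism]]
  st <- setdiff(names(lines), "dgr")
  lapply(seq_len(n), function(i) {
    x <- xs[i]
    e <- vapply(st, function(s) {
      if (s == .DESCRIPTOR_STATE) return(x)
      lines[[s]][1] * x + lines[[s]][2] + stats::rnorm(1, 0, sigma)
    }, numeric(1))
    energy_profile(sprintf("synthetic_%03d", i), mechanism,
                   stats::setNames(e, st),
                   dgr = lines$dgr[1] * x + lines$dgr[2] + stats::rnorm(1, 0, sigma))
  })
}

#' Exhaustive ground-truth optimum of a landscape
#'
#' Enumerates every candidate, computes the ground-truth objective vector over
#' the panel, applies the same hierarchical scalarizer the GA uses (one joint
#' batch), and returns the argmax (lowest index on ties).
#'
#' @param landscape a `synthetic_landscape`.
#' @param panel a [substrate_panel()].
#' @param spec a [scalarizer_spec()].
#' @param max_size enumeration guard.
#' @return list with `candidate`, `objectives`, `merit`, `index`, and the full
#'   `objective_matrix`.
#' @export
brute_force_optimum <- function(landscape, panel, spec = scalarizer_spec(),
                                max_size = 1e5) {
  cands <- enumerate_all(landscape$library, max_size = max_size)
  models <- landscape_models(landscape)
  obj <- do.call(rbind, lapply(cands, function(cd) {
    fv <- evaluate_candidate(cd, panel, models, spec)
    fv$objectives
  }))
  merit <- chimera_scalarize(obj, spec)
  best <- which.max(merit)  # first maximum = lowest index tie-break
  list(candidate = cands[[best]], objectives = obj[best, ], merit = merit[best],
       index = best, objective_matrix = obj)
}

#' Write a benchmark bundle to disk
#'
#' Emits `fragments.csv`, `templates.csv`, `reactions.csv`, `profiles.csv`,
#' and `truth.json` (landscape parameters and planted peak) into a directory.
#'
#' @param landscape a `synthetic_landscape`.
#' @param dir output directory.
#' @param n_reactions,n_profiles table sizes.
#' @param seed RNG seed for the emitted tables.
#' @return invisibly, `dir`.
#' @export
write_benchmark <- function(landscape, dir, n_reactions = 500L,
                            n_profiles = 44L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_library(landscape$library,
                file.path(dir, "templates.csv"), file.path(dir, "fragments.csv"))
  write_reaction_table(emit_reaction_table(landscape, n_reactions, seed = seed),
                       file.path(dir, "reactions.csv"))
  write_profiles(emit_profiles(landscape, n_profiles, seed = seed),
                 file.path(dir, "profiles.csv"))
  jsonlite::write_json(
    list(seed = landscape$seed, peak_x = landscape$peak_x,
         peak_log10_tof = landscape$peak_log10_tof,
         descriptor_center = landscape$descriptor_center,
         noise = list(ddg = landscape$noise_ddg,
                      descriptor = landscape$noise_descriptor,
                      state = landscape$noise_state),
         tradeoff = landscape$tradeoff),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
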