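# Energy profiles, linear free-energy scaling relationships (LFESRs), the
# energy-span model of turnover frequency, and TOF volcano curves.
#
# A profile holds the relative Gibbs free energies (kcal/mol, separated
# reactants at 0) of the cycle states along the reaction coordinate, plus the
# cycle's reaction free energy dG_r. Two mechanisms of the Pictet-Spengler
# cyclization are supported: concerted attack at C2 of the indole
# (1 -> TS2 -> 2 -> TS3) and stepwise attack at C3 through the
# aza-spiroindolenine (1 -> TS1 -> 1B -> TS2 -> 2 -> TS3). State "2" (the
# protonated tetrahydro-beta-carboline) is the volcano descriptor.

.MECHANISM_STATES <- list(
  C2 = c("1", "TS2", "2", "TS3"),
  C3 = c("1", "TS1", "1B", "TS2", "2", "TS3")
)

.DESCRIPTOR_STATE <- "2"

#' Physical constant: kB*T/h in s^-1
#' @param temperature kelvin.
#' @return attempt frequency kB*T/h.
#' @export
kbt_over_h <- function(temperature = 298.15) {
  1.380649e-23 * temperature / 6.62607015e-34
}

#' Create an energy profile for one reaction
#'
#' @param reaction_id identifier string.
#' @param mechanism "C2" or "C3".
#' @param states named numeric vector of relative Gibbs energies (kcal/mol);
#'   names must come from the mechanism's state vocabulary (a subset is
#'   allowed, e.g. for truncated cycles). Labels starting with "TS" are
#'   transition states.
#' @param dgr reaction free energy of the cycle (kcal/mol).
#' @return object of class `energy_profile`; its `descriptor` field is the
#'   energy of state "2" (`NA` when absent).
#' @export
energy_profile <- function(reaction_id, mechanism = c("C2", "C3"), states, dgr) {
  mechanism <- match.arg(mechanism)
  want <- .MECHANISM_STATES[[mechanism]]
  extra <- setdiff(names(states), want)
  if (length(extra) || length(states) == 0L) {
    stop("profile '", reaction_id, "': mechanism ", mechanism,
         " allows states {", paste(want, collapse = ", "), "}")
  }
  if (anyDuplicated(names(states))) {
    stop("profile '", reaction_id, "': duplicate state labels")
  }
  states <- states[intersect(want, names(states))]  # reaction-coordinate order
  if (any(!is.finite(states)) || !is.finite(dgr)) {
    stop("profile '", reaction_id, "': non-finite energies")
  }
  desc <- if (.DESCRIPTOR_STATE %in% names(states)) {
    unname(states[.DESCRIPTOR_STATE])
  } else NA_real_
  structure(
    list(reaction_id = reaction_id, mechanism = mechanism,
         states = states, dgr = dgr, descriptor = desc),
    class = "energy_profile"
  )
}

.is_ts <- function(labels) startsWith(labels, "TS")

# Effective span matrix of a profile: rows = transition states, columns =
# intermediates (including the 0-energy reference that opens the cycle).
# E[i, j] = T_i - I_j, plus dG_r when TS i precedes intermediate j along the
# cycle (the TS is then crossed in the next turnover).
.span_matrix <- function(profile) {
  labels <- names(profile$states)
  energies <- c(0, unname(profile$states))
  pos <- c(0, seq_along(labels))
  names(energies) <- names(pos) <- c("ref", labels)
  ts <- c(FALSE, .is_ts(labels))
  Ti <- energies[ts]; Pi <- pos[ts]
  Ij <- energies[!ts]; Pj <- pos[!ts]
  E <- outer(Ti, Ij, "-") + profile$dgr * outer(Pi, Pj, "<")
  dimnames(E) <- list(names(Ti), names(Ij))
  E
}

#' Turnover frequency from the energy-span model
#'
#' With `method = "span"` (default), the energy span dE is the largest
#' effective gap between a transition state and a preceding intermediate
#' (adding dG_r when the TS precedes the intermediate in the cycle) and
#' TOF = (kB*T/h) exp(-dE / RT). With `method = "sum"`, the smooth summed
#' expression TOF = (kB*T/h) (1 - exp(dG_r/RT)) / sum_ij exp(E_ij/RT) is used,
#' which the span form approximates when one pair dominates.
#'
#' @param profile an `energy_profile` with at least one TS.
#' @param temperature kelvin.
#' @param method "span" or "sum".
#' @return TOF in s^-1, with attributes `delta_e`, `log10_tof`, and (for
#'   "span") `tdts`/`tdi`, the TOF-determining TS and intermediate.
#' @export
tof_energy_span <- function(profile, temperature = 298.15,
                            method = c("span", "sum")) {
  method <- match.arg(method)
  if (!any(.is_ts(names(profile$states)))) {
    stop("profile '", profile$reaction_id, "' has no transition state")
  }
  rt <- R_KCAL * temperature
  E <- .span_matrix(profile)
  if (method == "span") {
    delta_e <- max(E)
    ij <- which(E == delta_e, arr.ind = TRUE)[1, ]
    tof <- kbt_over_h(temperature) * exp(-delta_e / rt)
    attr(tof, "delta_e") <- delta_e
    attr(tof, "tdts") <- rownames(E)[ij[1]]
    attr(tof, "tdi") <- colnames(E)[ij[2]]
  } else {
    if (profile$dgr >= 0) {
      stop("summed energy-span expression requires an exergonic cycle (dgr < 0)")
    }
    # factor out the max exponent for numerical stability
    m <- max(E)
    denom <- sum(exp((E - m) / rt))
    tof <- kbt_over_h(temperature) * (1 - exp(profile$dgr / rt)) *
      exp(-m / rt) / denom
    attr(tof, "delta_e") <- m + rt * log(denom) - rt * log1p(-exp(profile$dgr / rt))
  }
  attr(tof, "log10_tof") <- log10(as.vector(tof))
  tof
}

#' Degree of TOF control of each transition state
#'
#' Sensitivity of the turnover frequency to each TS energy,
#' X_i = d ln TOF / d(-T_i/RT), evaluated by central differences on the summed
#' energy-span expression. The weights are non-negative and sum to 1.
#'
#' @param profile an `energy_profile`.
#' @param temperature kelvin.
#' @param h finite-difference step (kcal/mol).
#' @return named numeric vector of per-TS weights.
#' @export
degree_of_tof_control <- function(profile, temperature = 298.15, h = 1e-4) {
  rt <- R_KCAL * temperature
  ts_labels <- names(profile$states)[.is_ts(names(profile$states))]
  ln_tof <- function(states) {
    p <- profile
    p$states <- states
    log(as.numeric(tof_energy_span(p, temperature, method = "sum")))
  }
  w <- vapply(ts_labels, function(lab) {
    up <- profile$states; up[lab] <- up[lab] + h
    dn <- profile$states; dn[lab] <- dn[lab] - h
    # d lnTOF / d(-T/RT) = -RT * d lnTOF / dT
    -rt * (ln_tof(up) - ln_tof(dn)) / (2 * h)
  }, numeric(1))
  pmax(w, 0)
}

#' Fit linear free-energy scaling relationships
#'
#' Ordinary least-squares regression of each cycle state's energy (and of the
#' reaction free energy) against the descriptor, the energy of state "2",
#' across a set of profiles sharing one mechanism. The descriptor state's own
#' fit is the identity by construction.
#'
#' @param profiles list of `energy_profile` objects, all with the same
#'   mechanism and >= 3 profiles.
#' @return object of class `lfesr_fit`: a data.frame with one row per state
#'   (plus "dgr") holding slope, intercept, r2, residual standard error
#'   `sigma`, `n`, and the regressor statistics needed for prediction bands.
#' @export
fit_lfesr <- function(profiles) {
  stopifnot(length(profiles) >= 3)
  mech <- unique(vapply(profiles, `[[`, character(1), "mechanism"))
  if (length(mech) != 1) stop("profiles mix mechanisms: ", paste(mech, collapse = ", "))
  x <- vapply(profiles, `[[`, numeric(1), "descriptor")
  states <- .MECHANISM_STATES[[mech]]
  rows <- lapply(c(states, "dgr"), function(st) {
    y <- if (st == "dgr") vapply(profiles, `[[`, numeric(1), "dgr")
         else vapply(profiles, function(p) unname(p$states[st]), numeric(1))
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      return(data.frame(state = st, slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, sigma = NA_real_, n = sum(ok),
                        x_mean = NA_real_, sxx = NA_real_, fittable = FALSE))
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    co <- stats::coef(fit)
    # the descriptor state regressed on itself is an exact fit by design;
    # summary.lm warns about it
    sm <- suppressWarnings(summary(fit))
    data.frame(state = st, slope = unname(co[2]), intercept = unname(co[1]),
               r2 = sm$r.squared, sigma = sm$sigma, n = sum(ok),
               x_mean = mean(x[ok]), sxx = sum((x[ok] - mean(x[ok]))^2),
               fittable = TRUE)
  })
  out <- do.call(rbind, rows)
  structure(list(table = out, mechanism = mech), class = "lfesr_fit")
}

# Reconstruct a (noise-free) profile from an LFESR fit at descriptor value x.
profile_from_fit <- function(fit, x, reaction_id = sprintf("x=%.3f", x)) {
  tab <- fit$table
  states <- .MECHANISM_STATES[[fit$mechanism]]
  e <- stats::setNames(tab$slope[match(states, tab$state)] * x +
                         tab$intercept[match(states, tab$state)], states)
  dgr_row <- match("dgr", tab$state)
  energy_profile(reaction_id, fit$mechanism, e,
                 dgr = tab$slope[dgr_row] * x + tab$intercept[dgr_row])
}

#' Build a TOF volcano curve from fitted scaling relationships
#'
#' At each descriptor grid value the cycle profile is reconstructed from the
#' LFESR lines and the energy-span TOF evaluated. 95% bands propagate each
#' state's regression prediction interval conservatively: the lower band
#' raises every TS and lowers every intermediate by its interval half-width,
#' the upper band does the reverse.
#'
#' @param fit an `lfesr_fit` covering all mechanism states.
#' @param grid descriptor grid (kcal/mol); values must stay within +/-100.
#' @param temperature kelvin.
#' @param level confidence level for the bands.
#' @return object of class `volcano_model` with the curve data.frame
#'   (`x`, `log10_tof`, `lo`, `hi`), `peak_x`, `peak_log10_tof`, mechanism and
#'   thermodynamic constants.
#' @export
build_volcano <- function(fit, grid = seq(-25, 25, by = 0.1),
                          temperature = 298.15, level = 0.95) {
  if (any(abs(grid) > 100)) stop("descriptor grid outside a sensible range (|x| > 100)")
  tab <- fit$table
  if (any(!tab$fittable)) {
    stop("LFESR fit has unfittable state(s): ",
         paste(tab$state[!tab$fittable], collapse = ", "))
  }
  states <- .MECHANISM_STATES[[fit$mechanism]]
  ts <- .is_ts(states)
  curve_at <- function(x, shift = 0) {
    # shift > 0: adversarial (TS up, intermediates down, dgr up) -> lower band
    pred_se <- tab$sigma * sqrt(1 + 1 / tab$n + (x - tab$x_mean)^2 / tab$sxx)
    tq <- stats::qt(1 - (1 - level) / 2, df = tab$n - 2)
    delta <- shift * tq * pred_se
    idx <- match(states, tab$state)
    e <- tab$slope[idx] * x + tab$intercept[idx] +
      ifelse(ts, delta[idx], -delta[idx])
    names(e) <- states
    dgi <- match("dgr", tab$state)
    dgr <- tab$slope[dgi] * x + tab$intercept[dgi] + abs(shift) * 0  # dgr not shifted
    p <- energy_profile("grid", fit$mechanism, e, dgr)
    attr(tof_energy_span(p, temperature), "log10_tof")
  }
  log_tof <- vapply(grid, curve_at, numeric(1))
  lo <- vapply(grid, curve_at, numeric(1), shift = 1)
  hi <- vapply(grid, curve_at, numeric(1), shift = -1)
  i <- which.max(log_tof)
  lower <- grid[max(1L, i - 1L)]
  upper <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(x) curve_at(x), c(lower, upper), maximum = TRUE)
  structure(
    list(curve = data.frame(x = grid, log10_tof = log_tof, lo = lo, hi = hi),
         peak_x = opt$maximum, peak_log10_tof = opt$objective,
         mechanism = fit$mechanism,
         thermo = list(temperature = temperature, R = R_KCAL,
                       kbt_h = kbt_over_h(temperature))),
    class = "volcano_model"
  )
}

#' Evaluate a volcano curve at arbitrary descriptor values
#'
#' Linear interpolation on the stored grid (constant extrapolation outside).
#'
#' @param volcano a `volcano_model` or a list of them; with several, the
#'   operative value is the pointwise maximum over mechanisms.
#' @param x descriptor values (kcal/mol).
#' @return log10 TOF values.
#' @export
log_tof_at <- function(volcano, x) {
  if (inherits(volcano, "volcano_model")) volcano <- list(volcano)
  vals <- vapply(volcano, function(v) {
    stats::approx(v$curve$x, v$curve$log10_tof, xout = x, rule = 2)$y
  }, numeric(length(x)))
  if (length(x) == 1L) max(vals) else apply(matrix(vals, nrow = length(x)), 1, max)
}

#' Gaussian activity merit
#'
#' Unit-peak Gaussian of the activity descriptor around the volcano peak:
#' f = exp(-(x - target)^2 / (2 width^2)), so f(target) = 1 and f decays
#' strictly with |x - target|.
#'
#' @param x descriptor value(s), kcal/mol.
#' @param target peak location (default -9.0 kcal/mol).
#' @param width Gaussian width sigma in kcal/mol (> 0).
#' @return merit value(s) in (0, 1].
#' @export
gaussian_activity <- function(x, target = -9.0, width = 3.0) {
  if (width <= 0) stop("width must be > 0")
  exp(-(x - target)^2 / (2 * width^2))
}

#' Read energy profiles from CSV
#'
#' Wide format: columns `reaction_id`, `mechanism`, one column per state label
#' (`s1`, `TS1`, `s1B`, `TS2`, `s2`, `TS3`; intermediate columns are prefixed
#' with "s" to keep CSV headers syntactic), and `dgr_kcal`.
#'
#' @param path CSV path.
#' @return list of `energy_profile` objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    mech <- df$mechanism[i]
    want <- .MECHANISM_STATES[[mech]]
    cols <- ifelse(.is_ts(want), want, paste0("s", want))
    present <- cols %in% names(df)
    vals <- suppressWarnings(as.numeric(df[i, cols[present]]))
    keep <- is.finite(vals)
    energy_profile(df$reaction_id[i], mech,
                   stats::setNames(vals[keep], want[present][keep]),
                   dgr = df$dgr_kcal[i])
  })
}

#' Write energy profiles to CSV
#' @param profiles list of `energy_profile` objects (one mechanism per file).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  mech <- unique(vapply(profiles, `[[`, character(1), "mechanism"))
  if (length(mech) != 1) stop("write one mechanism per file")
  want <- .MECHANISM_STATES[[mech]]
  cols <- ifelse(.is_ts(want), want, paste0("s", want))
  rows <- lapply(profiles, function(p) {
    v <- as.list(stats::setNames(rep(NA_real_, length(want)), cols))
    for (st in names(p$states)) {
      v[[cols[match(st, want)]]] <- unname(p$states[st])
    }
    cbind(data.frame(reaction_id = p$reaction_id, mechanism = p$mechanism,
                     stringsAsFactors = FALSE),
          as.data.frame(v), data.frame(dgr_kcal = p$dgr))
  })
  df <- do.call(rbind, rows)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 17, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a volcano curve to CSV
#' @param volcano a `volcano_model`.
#' @param path output CSV (columns x, log10_tof, lo95, hi95).
#' @return invisibly, `path`.
#' @export
write_volcano <- function(volcano, path) {
  df <- volcano$curve
  names(df) <- c("x", "log10_tof", "lo95", "hi95")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
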