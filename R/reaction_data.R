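# Reaction records and selectivity unit conversions.
#
# A reaction table is a plain data.frame, one row per Pictet-Spengler
# condensation, with columns sub_a, sub_b, catalyst, cocatalyst, solvent,
# temperature_K, er, ee, ddg_kcal, descriptor_kcal, source (and optionally
# cinchona, a logical mechanism flag). The three selectivity encodings are
# mutually consistent bijections:
#   er  = (1 + ee) / (1 - ee)          (ee as a fraction in [0, 1))
#   ddg = R T ln(er)                   (kcal/mol, stored as a magnitude >= 0)
#   ee% = 100 tanh(ddg / (2 R T))

#' Gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 0.0019872

.DEFAULT_T <- 298.15

#' Free-energy difference of activation from an enantiomeric ratio
#'
#' @param er enantiomeric ratio(s), major:minor, >= 1.
#' @param temperature kelvin.
#' @return ddG-dagger in kcal/mol (non-negative magnitude).
#' @export
ddg_from_er <- function(er, temperature = .DEFAULT_T) {
  stopifnot(all(temperature > 0))
  if (any(er < 1)) {
    stop("er must be >= 1 (major:minor); invert ratios below 1 before calling")
  }
  R_KCAL * temperature * log(er)
}

#' Enantiomeric ratio from a free-energy difference of activation
#'
#' @param ddg ddG-dagger in kcal/mol, >= 0.
#' @param temperature kelvin.
#' @return enantiomeric ratio >= 1.
#' @export
er_from_ddg <- function(ddg, temperature = .DEFAULT_T) {
  stopifnot(all(temperature > 0))
  if (any(ddg < 0)) stop("ddg must be a non-negative magnitude")
  exp(ddg / (R_KCAL * temperature))
}

#' Percent enantiomeric excess from a free-energy difference of activation
#'
#' @param ddg ddG-dagger in kcal/mol, >= 0.
#' @param temperature kelvin.
#' @return ee in percent, in [0, 100).
#' @export
ee_from_ddg <- function(ddg, temperature = .DEFAULT_T) {
  stopifnot(all(temperature > 0))
  if (any(ddg < 0)) stop("ddg must be a non-negative magnitude")
  100 * tanh(ddg / (2 * R_KCAL * temperature))
}

#' Free-energy difference of activation from a fractional ee
#'
#' @param ee enantiomeric excess as a fraction in [0, 1).
#' @param temperature kelvin.
#' @return ddG-dagger in kcal/mol.
#' @export
ddg_from_ee <- function(ee, temperature = .DEFAULT_T) {
  if (any(ee < 0 | ee >= 1)) stop("ee must be a fraction in [0, 1)")
  ddg_from_er((1 + ee) / (1 - ee), temperature)
}

#' Fractional ee from an enantiomeric ratio
#' @param er enantiomeric ratio >= 1.
#' @return ee as a fraction in [0, 1).
#' @export
ee_from_er <- function(er) {
  if (any(er < 1)) stop("er must be >= 1")
  (er - 1) / (er + 1)
}

.REACTION_COLS <- c("sub_a", "sub_b", "catalyst", "cocatalyst", "solvent",
                    "temperature_K", "er", "ee", "ddg_kcal", "descriptor_kcal",
                    "source")

#' Build a reaction table
#'
#' Completes the missing selectivity encodings from whichever of `er`, `ee`
#' (fraction), `ddg_kcal` are present, validates mutual consistency of those
#' supplied, and checks that substrate/catalyst SMILES parse.
#'
#' @param df data.frame with at least `sub_a`, `sub_b` and one selectivity
#'   column; other reaction columns are filled with defaults (toluene,
#'   298.15 K, no co-catalyst).
#' @param tol consistency tolerance: absolute on ee and ddg, relative on er.
#' @param check_smiles validate SMILES columns (disable for huge synthetic
#'   crosses where the generator guarantees validity).
#' @return data.frame of class `reaction_table`.
#' @export
reaction_table <- function(df, tol = 1e-6, check_smiles = TRUE) {
  stopifnot(is.data.frame(df), all(c("sub_a", "sub_b") %in% names(df)))
  n <- nrow(df)
  defaults <- list(catalyst = NA_character_, cocatalyst = NA_character_,
                   solvent = "toluene", temperature_K = .DEFAULT_T,
                   er = NA_real_, ee = NA_real_, ddg_kcal = NA_real_,
                   descriptor_kcal = NA_real_, source = "unknown")
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- rep(defaults[[col]], n)
  }
  if (!"cinchona" %in% names(df)) df$cinchona <- rep(FALSE, n)
  if (any(!is.finite(df$temperature_K)) || any(df$temperature_K <= 0)) {
    stop("temperature_K must be finite and > 0")
  }
  for (i in seq_len(n)) {
    tK <- df$temperature_K[i]
    er <- df$er[i]; ee <- df$ee[i]; ddg <- df$ddg_kcal[i]
    if (all(is.na(c(er, ee, ddg)))) {
      stop("row ", i, ": at least one of er, ee, ddg_kcal must be present")
    }
    # derive the canonical ddg from the first encoding present
    ddg0 <- if (!is.na(ddg)) ddg else if (!is.na(er)) ddg_from_er(er, tK)
            else ddg_from_ee(ee, tK)
    er0 <- er_from_ddg(ddg0, tK)
    ee0 <- ee_from_er(er0)
    if (!is.na(er) && abs(er - er0) > tol * max(1, er0)) {
      stop("row ", i, ": er = ", er, " inconsistent with other fields (implies er = ",
           signif(er0, 8), ")")
    }
    if (!is.na(ee) && abs(ee - ee0) > tol) {
      stop("row ", i, ": ee = ", ee, " inconsistent with other fields (implies ee = ",
           signif(ee0, 8), ")")
    }
    if (!is.na(ddg) && abs(ddg - ddg0) > tol) {
      stop("row ", i, ": ddg_kcal inconsistent with other fields")
    }
    df$ddg_kcal[i] <- ddg0; df$er[i] <- er0; df$ee[i] <- ee0
  }
  if (check_smiles) {
    for (col in c("sub_a", "sub_b", "catalyst", "cocatalyst")) {
      vals <- df[[col]]
      idx <- which(!is.na(vals) & nzchar(vals))
      if (length(idx)) {
        bad <- idx[!is_valid_smiles(vals[idx])]
        if (length(bad)) {
          stop("row ", bad[1], ": column '", col, "' has unparseable SMILES: ",
               vals[bad[1]])
        }
      }
    }
  }
  df <- df[, c(.REACTION_COLS, "cinchona")]
  class(df) <- c("reaction_table", "data.frame")
  df
}

#' Read a reaction table from CSV
#'
#' @param path CSV file with the reaction columns; missing selectivity
#'   encodings are completed, contradictions beyond `tol` are row errors.
#' @param tol consistency tolerance (see [reaction_table()]).
#' @return a `reaction_table`.
#' @export
read_reaction_table <- function(path, tol = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sub_a", "sub_b", "catalyst", "cocatalyst", "solvent", "source")) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  reaction_table(df, tol = tol)
}

#' Write a reaction table to CSV
#'
#' Numeric columns are written at full precision so that write-then-read is
#' the identity on canonical tables.
#'
#' @param records a `reaction_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_reaction_table <- function(records, path) {
  out <- as.data.frame(records)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- format(out[[col]], digits = 17, trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Count unique transformations (distinct substrate pairs)
#'
#' Two records describe the same transformation when their (SubA, SubB) pairs
#' are identical after SMILES canonicalization, i.e. they lead to the same
#' tetrahydro-beta-carboline product.
#'
#' @param records a `reaction_table` or data.frame with `sub_a`, `sub_b`.
#' @return integer count of distinct canonical pairs.
#' @export
unique_transformations <- function(records) {
  a <- records$sub_a; b <- records$sub_b
  # canonicalize each distinct SMILES once; tables are big, molecules few
  ua <- unique(a); ub <- unique(b)
  ca <- stats::setNames(canonical_smiles(ua), ua)
  cb <- stats::setNames(canonical_smiles(ub), ub)
  if (anyNA(ca)) stop("unparseable sub_a SMILES: ", ua[is.na(ca)][1])
  if (anyNA(cb)) stop("unparseable sub_b SMILES: ", ub[is.na(cb)][1])
  length(unique(paste(ca[a], cb[b], sep = ">>")))
}

#' Define a substrate panel
#'
#' @param sub_a,sub_b equal-length SMILES vectors of substrate pairs.
#' @param name panel label.
#' @param map_index optional indices of the pairs in the map they were
#'   selected from.
#' @return data.frame of class `substrate_panel`.
#' @export
substrate_panel <- function(sub_a, sub_b, name = "panel", map_index = NA_integer_) {
  stopifnot(length(sub_a) == length(sub_b), length(sub_a) > 0)
  key <- paste(sub_a, sub_b, sep = ">>")
  if (anyDuplicated(key)) stop("substrate panel pairs must be unique")
  out <- data.frame(sub_a = sub_a, sub_b = sub_b, map_index = map_index,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("substrate_panel", "data.frame")
  out
}
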