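# Low-level SMILES handling backed by Open Babel (ChemmineOB). All results are
# memoized in a package-local environment: the GA and the featurizer hit the
# same few hundred molecules thousands of times.

.chem_cache <- new.env(parent = emptyenv())

.cache_get <- function(store, key) {
  env <- .chem_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .chem_cache[[store]] <- env
  }
  env[[key]]
}

.cache_set <- function(store, key, value) {
  env <- .chem_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .chem_cache[[store]] <- env
  }
  env[[key]] <- value
  value
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical form. Invalid SMILES yield `NA`
#' rather than an error so that callers can attach row/component context to
#' their own error messages.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    hit <- .cache_get("canon", s)
    if (!is.null(hit)) return(hit)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) ""
    )
    out <- sub("[ \t\r\n].*$", "", out) # strip title field and newline
    if (!nzchar(out)) out <- NA_character_
    .cache_set("canon", s, out)
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Hashed structural fingerprint of a molecule
#'
#' 1024-bit Open Babel FP2 fingerprint (hashed linear fragments up to seven
#' bonds), optionally OR-folded down to a smaller power-of-two width. A pure,
#' memoized function of the SMILES string.
#'
#' @param smiles single SMILES string.
#' @param n_bits fingerprint width; must divide 1024.
#' @return integer vector of 0/1 of length `n_bits`.
#' @export
smiles_fingerprint <- function(smiles, n_bits = 1024L) {
  n_bits <- as.integer(n_bits)
  if (n_bits <= 0L || 1024L %% n_bits != 0L) {
    stop("n_bits must be a positive divisor of 1024, got ", n_bits)
  }
  key <- paste0(smiles, "|", n_bits)
  hit <- .cache_get("fp", key)
  if (!is.null(hit)) return(hit)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("cannot fingerprint unparseable SMILES: ", smiles)
  raw <- suppressWarnings(
    ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", can, identity), "FP2")
  )
  raw <- as.integer(raw != 0)
  if (n_bits < 1024L) {
    folds <- matrix(raw, nrow = n_bits)
    raw <- as.integer(rowSums(folds) > 0)
  }
  .cache_set("fp", key, raw)
}

#' Count SMARTS pattern matches in a molecule
#'
#' @param smiles single SMILES string.
#' @param smarts SMARTS pattern.
#' @return integer match count (0 if the molecule does not parse).
#' @keywords internal
smarts_count <- function(smiles, smarts) {
  key <- paste0(smiles, "|", smarts)
  hit <- .cache_get("smarts", key)
  if (!is.null(hit)) return(hit)
  n <- tryCatch({
    res <- suppressWarnings(
      ChemmineOB::smartsSearch_OB(
        ChemmineOB::forEachMol("SMILES", smiles, identity), smarts
      )
    )
    as.integer(res[[1]])
  }, error = function(e) 0L)
  .cache_set("smarts", key, n)
}

# Common laboratory solvents -> representative SMILES. Unknown names that are
# themselves valid SMILES are used as-is; anything else maps to an all-zero
# fingerprint block (the stated absent-component policy).
.solvent_table <- c(
  toluene          = "Cc1ccccc1",
  benzene          = "c1ccccc1",
  dcm              = "ClCCl",
  dichloromethane  = "ClCCl",
  chloroform       = "ClC(Cl)Cl",
  ether            = "CCOCC",
  "diethyl ether"  = "CCOCC",
  mtbe             = "COC(C)(C)C",
  thf              = "C1CCOC1",
  dioxane          = "C1COCCO1",
  "1,4-dioxane"    = "C1COCCO1",
  acetonitrile     = "CC#N",
  mecn             = "CC#N",
  methanol         = "CO",
  ethanol          = "CCO",
  water            = "O",
  dmf              = "CN(C)C=O",
  dmso             = "CS(C)=O",
  "ethyl acetate"  = "CCOC(C)=O",
  hexane           = "CCCCCC",
  cyclohexane      = "C1CCCCC1"
)

#' Map a solvent name to a representative SMILES
#'
#' @param solvent character vector of solvent names or SMILES.
#' @return character vector of SMILES, `NA` where no representation exists.
#' @export
solvent_smiles <- function(solvent) {
  vapply(as.character(solvent), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    hit <- .solvent_table[[tolower(trimws(s))]]
    if (!is.null(hit)) return(hit)
    can <- canonical_smiles(s)
    if (!is.na(can)) return(s)
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
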