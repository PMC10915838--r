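# Reaction featurization, 2D chemical-space maps, and diverse subset
# selection by farthest point sampling.

#' Fingerprint configuration for reaction featurization
#'
#' Each reaction component contributes one fixed-width fingerprint block; the
#' blocks are concatenated in `components` order. Absent components (e.g. no
#' co-catalyst) contribute an all-zero block. `radius` is retained as model
#' metadata describing the intended circular-neighborhood size; the installed
#' fingerprint backend (Open Babel FP2) enumerates linear fragments up to
#' seven bonds and does not consume it.
#'
#' @param n_bits bits per component block (divisor of 1024).
#' @param radius neighborhood radius metadata (default 2).
#' @param components ordered component names; each must be a reaction-table
#'   column among catalyst, cocatalyst, sub_a, sub_b, solvent.
#' @return object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(n_bits = 1024L, radius = 2L,
                               components = c("catalyst", "cocatalyst",
                                              "sub_a", "sub_b", "solvent")) {
  stopifnot(n_bits > 0, 1024L %% as.integer(n_bits) == 0L)
  allowed <- c("catalyst", "cocatalyst", "sub_a", "sub_b", "solvent")
  if (!all(components %in% allowed)) {
    stop("unknown component(s): ", paste(setdiff(components, allowed), collapse = ", "))
  }
  structure(list(n_bits = as.integer(n_bits), radius = as.integer(radius),
                 components = components),
            class = "fingerprint_config")
}

.component_smiles <- function(records, component) {
  vals <- as.character(records[[component]])
  if (component == "solvent") vals <- solvent_smiles(vals)
  vals
}

#' Featurize reactions as concatenated fingerprint blocks
#'
#' @param records a `reaction_table` or data.frame carrying the component
#'   columns named in `config`.
#' @param config a [fingerprint_config()].
#' @return a sparse 0/1 matrix (`dgCMatrix`), one row per reaction, with
#'   `n_bits * length(components)` columns.
#' @export
featurize_reactions <- function(records, config = fingerprint_config()) {
  n <- nrow(records)
  nb <- config$n_bits
  blocks <- lapply(seq_along(config$components), function(ci) {
    comp <- config$components[ci]
    if (!comp %in% names(records)) {
      stop("featurization error: records lack component column '", comp, "'")
    }
    smi <- .component_smiles(records, comp)
    ii <- integer(0); jj <- integer(0)
    for (r in seq_len(n)) {
      s <- smi[r]
      if (is.na(s) || !nzchar(s)) next  # absent component -> zero block
      fp <- tryCatch(smiles_fingerprint(s, nb), error = function(e) {
        stop("featurization error in component '", comp, "' (row ", r, "): ",
             conditionMessage(e), call. = FALSE)
      })
      on <- which(fp != 0L)
      ii <- c(ii, rep.int(r, length(on)))
      jj <- c(jj, on + (ci - 1L) * nb)
    }
    list(i = ii, j = jj)
  })
  Matrix::sparseMatrix(
    i = unlist(lapply(blocks, `[[`, "i")),
    j = unlist(lapply(blocks, `[[`, "j")),
    x = 1,
    dims = c(n, nb * length(config$components))
  )
}

#' Embed reaction fingerprints into a 2D map
#'
#' Exact, deterministic PCA down to `pca_dims` components followed by t-SNE to
#' two dimensions (single-threaded, seeded). The PCA coordinates are kept so
#' the deterministic stage can be inspected independently of the stochastic
#' embedding.
#'
#' @param x fingerprint matrix (rows = reactions) or a `reaction_table` to
#'   featurize with `config`.
#' @param pca_dims number of principal components retained (capped at the data
#'   rank).
#' @param perplexity t-SNE perplexity; requires `3 * perplexity < n - 1`.
#' @param seed RNG seed; identical seed and input give identical coordinates.
#' @param config fingerprint configuration used when `x` is a table.
#' @return object of class `embedding_map` with `coords` (n x 2), `pca_coords`,
#'   and the parameters.
#' @export
embed_map <- function(x, pca_dims = 100L, perplexity = 30, seed = 1L,
                      config = fingerprint_config()) {
  if (is.data.frame(x)) x <- featurize_reactions(x, config)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("embedding needs at least 3 reactions, got ", n)
  if (3 * perplexity >= n - 1) {
    stop("perplexity ", perplexity, " too large for ", n,
         " samples (needs 3*perplexity < n - 1)")
  }
  k <- min(as.integer(pca_dims), n - 1L, ncol(x))
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  pc <- pca$x
  set.seed(seed)
  ts <- Rtsne::Rtsne(pc, dims = 2, perplexity = perplexity, pca = FALSE,
                     check_duplicates = FALSE, num_threads = 1, verbose = FALSE)
  structure(
    list(coords = ts$Y, pca_coords = pc,
         pca_dims = k, perplexity = perplexity, seed = seed),
    class = "embedding_map"
  )
}

#' Farthest point sampling
#'
#' Greedy maximin selection on a coordinate matrix. The first point is the one
#' farthest from the centroid; each subsequent point maximizes its minimum
#' Euclidean distance to the already-selected set. All ties break to the
#' lowest index, so the selection is fully deterministic.
#'
#' @param coords numeric matrix (or vector), one row per point.
#' @param k number of points to select, `1 <= k <= nrow(coords)`.
#' @return integer vector of `k` selected row indices, in selection order.
#' @export
farthest_point_sample <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k > n) stop("k must be between 1 and ", n, ", got ", k)
  centroid <- colMeans(coords)
  d0 <- sqrt(rowSums((coords - rep(centroid, each = n))^2))
  sel <- integer(k)
  sel[1] <- which.max(d0)  # which.max takes the first (lowest-index) maximum
  mind <- sqrt(rowSums((coords - rep(coords[sel[1], ], each = n))^2))
  if (k > 1) {
    for (i in 2:k) {
      mind[sel[seq_len(i - 1L)]] <- -Inf
      sel[i] <- which.max(mind)
      di <- sqrt(rowSums((coords - rep(coords[sel[i], ], each = n))^2))
      mind <- pmin(mind, di)
    }
  }
  sel
}

#' Farthest point sampling on a precomputed distance matrix
#'
#' Same greedy maximin scheme as [farthest_point_sample()], for metrics
#' without coordinates (e.g. Jaccard distances between fingerprints). The
#' first point is the one with the largest mean distance to all others; ties
#' break to the lowest index.
#'
#' @param dmat symmetric n x n distance matrix.
#' @param k number of points to select.
#' @return integer vector of `k` selected indices, in selection order.
#' @export
farthest_point_sample_dist <- function(dmat, k) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (k < 1 || k > n) stop("k must be between 1 and ", n, ", got ", k)
  sel <- integer(k)
  sel[1] <- which.max(rowMeans(dmat))
  mind <- dmat[, sel[1]]
  if (k > 1) {
    for (i in 2:k) {
      mind[sel[seq_len(i - 1L)]] <- -Inf
      sel[i] <- which.max(mind)
      mind <- pmin(mind, dmat[, sel[i]])
    }
  }
  sel
}

#' Select a diverse substrate panel
#'
#' Deduplicates substrate pairs, featurizes them on the SubA+SubB fingerprint
#' blocks only, and picks `k` pairs by farthest point sampling — by default on
#' the 2D PCA/t-SNE map, optionally directly in fingerprint space with
#' Jaccard distances (`space = "fingerprint"`).
#'
#' @param records a `reaction_table` or data.frame with `sub_a`, `sub_b`.
#' @param k panel size (default 50).
#' @param config fingerprint configuration; only its `n_bits` matters here.
#' @param pca_dims,perplexity,seed passed to [embed_map()] (map space only).
#' @param space "map" (default) or "fingerprint".
#' @param name panel label.
#' @return a [substrate_panel()]; in map space the selected coordinates are in
#'   `attr(, "coords")` and the full map in `attr(, "map")`.
#' @export
select_panel <- function(records, k = 50L, config = fingerprint_config(),
                         pca_dims = 100L, perplexity = 30, seed = 1L,
                         space = c("map", "fingerprint"), name = "GPS") {
  space <- match.arg(space)
  key <- paste(records$sub_a, records$sub_b, sep = ">>")
  keep <- !duplicated(key)
  pairs <- data.frame(sub_a = records$sub_a[keep], sub_b = records$sub_b[keep],
                      stringsAsFactors = FALSE)
  if (k > nrow(pairs)) {
    stop("k = ", k, " exceeds the ", nrow(pairs), " unique substrate pairs")
  }
  cfg <- fingerprint_config(n_bits = config$n_bits, radius = config$radius,
                            components = c("sub_a", "sub_b"))
  X <- featurize_reactions(pairs, cfg)
  if (space == "fingerprint") {
    Xd <- as.matrix(X)
    inter <- Xd %*% t(Xd)
    ones <- rowSums(Xd)
    union <- outer(ones, ones, "+") - inter
    jaccard <- 1 - inter / pmax(union, 1)
    idx <- farthest_point_sample_dist(jaccard, k)
    panel <- substrate_panel(pairs$sub_a[idx], pairs$sub_b[idx], name = name,
                             map_index = idx)
    return(panel)
  }
  map <- embed_map(X, pca_dims = pca_dims, perplexity = perplexity, seed = seed)
  idx <- farthest_point_sample(map$coords, k)
  panel <- substrate_panel(pairs$sub_a[idx], pairs$sub_b[idx], name = name,
                           map_index = idx)
  attr(panel, "coords") <- map$coords[idx, , drop = FALSE]
  attr(panel, "map") <- map
  panel
}

#' Write a 2D map to CSV
#' @param map an `embedding_map`.
#' @param path output CSV (columns id, x, y).
#' @param ids optional reaction identifiers.
#' @return invisibly, `path`.
#' @export
write_map <- function(map, path, ids = seq_len(nrow(map$coords))) {
  utils::write.csv(
    data.frame(id = ids, x = map$coords[, 1], y = map$coords[, 2]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a substrate panel to CSV
#' @param panel a `substrate_panel`.
#' @param path output CSV (columns sub_a, sub_b, map_index).
#' @return invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read a substrate panel from CSV
#' @param path CSV with columns sub_a, sub_b (map_index optional).
#' @param name panel label.
#' @return a `substrate_panel`.
#' @export
read_panel <- function(path, name = "panel") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  substrate_panel(df$sub_a, df$sub_b, name = name,
                  map_index = if ("map_index" %in% names(df)) df$map_index else NA_integer_)
}
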