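# Shared fixtures, built in code.

# 12-candidate single-template space (R1 x R2 = 3 x 4)
toy_library <- function() {
  catalyst_library(
    list(catalyst_template("t1", "toy", "c1cc({R2a})cc({R1a})c1",
                           c(R1a = "R1", R2a = "R2"))),
    list(catalyst_fragment("f_f", "F", "R1"),
         catalyst_fragment("f_cl", "Cl", "R1"),
         catalyst_fragment("f_br", "Br", "R1"),
         catalyst_fragment("g_me", "C", "R2"),
         catalyst_fragment("g_et", "CC", "R2"),
         catalyst_fragment("g_ome", "OC", "R2"),
         catalyst_fragment("g_cf3", "C(F)(F)F", "R2"))
  )
}

# adds a template with one symmetric R3 pair (5 fragments -> 5 assignments)
toy_library_symmetric <- function() {
  lib <- toy_library()
  sym <- catalyst_template("t2", "toy-sym", "O=C(N{R3a})N{R3b}",
                           c(R3a = "R3", R3b = "R3"),
                           symmetric_groups = list(c("R3a", "R3b")))
  r3 <- lapply(c("C", "CC", "CCC", "C(C)C", "c2ccccc2"), function(s)
    catalyst_fragment(paste0("h_", gsub("[^A-Za-z]", "", s), nchar(s)), s, "R3"))
  catalyst_library(c(lib$templates, list(sym)), c(lib$fragments, r3))
}

# mean silhouette coefficient for 2D points with integer labels
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# brute-force farthest-point-sampling trace for the per-step oracle
fps_oracle <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  dmat <- as.matrix(stats::dist(coords))
  centroid <- colMeans(coords)
  d0 <- sqrt(rowSums((coords - rep(centroid, each = n))^2))
  sel <- unname(which.max(d0))
  while (length(sel) < k) {
    mind <- apply(dmat[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    sel <- c(sel, unname(which.max(mind)))
  }
  as.integer(sel)
}

# O(n^2) dominance scan for the Pareto oracle (maximize both)
pareto_oracle <- function(P) {
  n <- nrow(P)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ])
    }, logical(1)))
  }, logical(1))
  sort(which(keep))
}

# strict lexicographic merit oracle for the tolerance->0 limit of the
# scalarizer: candidates meeting the absolute first threshold rank first,
# ordered by (median_f desc, sd_ddg asc, sd_f asc); the rest follow, ordered
# by median_ddg desc
lexicographic_rank <- function(M, ddg_threshold = 2.0) {
  ok <- M[, 1] >= ddg_threshold
  key <- order(-ok, -M[, 2] * ok, M[, 3] * ok, M[, 4] * ok, -M[, 1] * !ok)
  rank_out <- integer(nrow(M))
  rank_out[key] <- seq_len(nrow(M))
  rank_out
}

# tiny landscape for fast GA tests
small_landscape <- function(seed = 7, ...) {
  make_landscape(seed = seed, n_sub_a = 8, n_sub_b = 8, ...)
}
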