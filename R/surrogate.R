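# Fingerprint-based tree-ensemble surrogate models of selectivity
# (ddG-dagger) and of the activity descriptor, trained with repeated random
# 90/10 splits; predictions average the split members and report the member
# spread as the uncertainty.

.CARBOXYLIC_ACID_SMARTS <- "[CX3](=O)[OX2H1]"
.ACETIC_ACID <- "CC(=O)O"

# Descriptor-model convention: carboxylic-acid co-catalysts are represented by
# acetic acid; benzoyl bromide and "none" keep their identity.
.simplify_cocatalyst <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    if (smarts_count(s, .CARBOXYLIC_ACID_SMARTS) > 0) .ACETIC_ACID else s
  }, character(1), USE.NAMES = FALSE)
}

.target_column <- c(selectivity = "ddg_kcal", descriptor = "descriptor_kcal")

.default_xgb_params <- function(booster) {
  base <- list(objective = "reg:squarederror", nthread = 1)
  if (booster == "rf") {
    c(base, list(eta = 1, max_depth = 8, subsample = 0.8,
                 colsample_bynode = 0.8, num_parallel_tree = 100))
  } else {
    c(base, list(eta = 0.3, max_depth = 6, subsample = 1))
  }
}

#' Train a surrogate ensemble
#'
#' Trains `n_splits` tree-ensemble regressors on independent random
#' train/test splits of the featurized reaction table. For
#' `target = "selectivity"` the representation concatenates catalyst,
#' co-catalyst, SubA, SubB and solvent fingerprints and the response is
#' `ddg_kcal`; for `target = "descriptor"` the solvent block is dropped,
#' carboxylic-acid co-catalysts are modelled as acetic acid, rows flagged
#' `cinchona` are excluded (different mechanism), and the response is
#' `descriptor_kcal`.
#'
#' @param records a `reaction_table`.
#' @param target "selectivity" or "descriptor".
#' @param config a [fingerprint_config()]; its component list is adapted to
#'   the target.
#' @param n_splits number of train/test splits (default 100).
#' @param train_fraction fraction of rows in each training split.
#' @param seed RNG seed; fixes the splits and the boosters.
#' @param booster "gbtree" (gradient-boosted trees, default) or "rf"
#'   (random-forest mode).
#' @param nrounds boosting rounds per member.
#' @param params extra xgboost parameters overriding the defaults.
#' @return object of class `surrogate_ensemble` with the fitted members,
#'   per-row averaged out-of-fold predictions (`oof`), and a `cv` report
#'   (MAE, MSE).
#' @export
train_surrogate <- function(records, target = c("selectivity", "descriptor"),
                            config = fingerprint_config(), n_splits = 100L,
                            train_fraction = 0.9, seed = 1L,
                            booster = c("gbtree", "rf"), nrounds = 100L,
                            params = list()) {
  target <- match.arg(target)
  booster <- match.arg(booster)
  df <- as.data.frame(records)
  if (target == "descriptor") {
    if ("cinchona" %in% names(df)) df <- df[!isTRUE_v(df$cinchona), , drop = FALSE]
    df$cocatalyst <- .simplify_cocatalyst(df$cocatalyst)
    components <- setdiff(config$components, "solvent")
  } else {
    components <- config$components
  }
  ycol <- .target_column[[target]]
  if (!ycol %in% names(df)) stop("records lack target column '", ycol, "'")
  y <- df[[ycol]]
  keep <- is.finite(y)
  if (any(!keep)) {
    df <- df[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(df)
  if (n < 20) stop("need at least 20 records with a finite target, got ", n)
  cfg <- fingerprint_config(config$n_bits, config$radius, components)
  X <- featurize_reactions(df, cfg)

  xgb_params <- utils::modifyList(.default_xgb_params(booster), params)
  n_train <- max(1L, floor(train_fraction * n))
  set.seed(seed)
  members <- vector("list", n_splits)
  oof_sum <- numeric(n)
  oof_cnt <- integer(n)
  for (s in seq_len(n_splits)) {
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    booster_fit <- xgboost::xgb.train(
      params = c(xgb_params, list(seed = sample.int(.Machine$integer.max, 1L))),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
    members[[s]] <- list(model = booster_fit, train = tr, test = te)
    if (length(te)) {
      pr <- predict(booster_fit, X[te, , drop = FALSE])
      oof_sum[te] <- oof_sum[te] + pr
      oof_cnt[te] <- oof_cnt[te] + 1L
    }
  }
  oof <- ifelse(oof_cnt > 0, oof_sum / oof_cnt, NA_real_)
  seen <- oof_cnt > 0
  cv <- list(mae = mean(abs(oof[seen] - y[seen])),
             mse = mean((oof[seen] - y[seen])^2),
             n_oof = sum(seen))
  structure(
    list(members = members, target = target, config = cfg, booster = booster,
         n_splits = as.integer(n_splits), train_fraction = train_fraction,
         seed = as.integer(seed), nrounds = as.integer(nrounds),
         params = xgb_params, y = y, oof = oof, cv = cv),
    class = "surrogate_ensemble"
  )
}

# vectorized isTRUE for optional logical columns read from CSV
isTRUE_v <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == "true")

#' Predict with a surrogate ensemble
#'
#' @param object a `surrogate_ensemble`.
#' @param newdata a data.frame with the component columns (co-catalyst
#'   simplification is applied automatically for descriptor models).
#' @param ... unused.
#' @return data.frame with `mean` and `std` (population standard deviation
#'   across members); the per-member prediction matrix is attached as
#'   `attr(, "members")`.
#' @export
predict.surrogate_ensemble <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  if (object$target == "descriptor") {
    df$cocatalyst <- .simplify_cocatalyst(df$cocatalyst)
  }
  X <- featurize_reactions(df, object$config)
  pm <- vapply(object$members, function(m) predict(m$model, X),
               numeric(nrow(X)))
  pm <- matrix(pm, nrow = nrow(X))
  mean_ <- rowMeans(pm)
  std_ <- sqrt(rowMeans((pm - mean_)^2))
  out <- data.frame(mean = mean_, std = std_)
  attr(out, "members") <- pm
  out
}

#' Evaluate a surrogate on held-out records
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param records held-out `reaction_table` rows with the target column set.
#' @return list with `mae`, `mse`, `n`, and the mean predictions.
#' @export
evaluate_surrogate <- function(ensemble, records) {
  df <- as.data.frame(records)
  if (nrow(df) == 0) stop("empty held-out set")
  y <- df[[.target_column[[ensemble$target]]]]
  if (any(!is.finite(y))) stop("held-out rows must all carry the target")
  pr <- predict(ensemble, df)
  list(mae = mean(abs(pr$mean - y)), mse = mean((pr$mean - y)^2),
       n = nrow(df), predictions = pr$mean)
}

#' Save / load a surrogate ensemble
#'
#' The archive is a directory holding the configuration as JSON and each
#' member's booster in xgboost's binary format. Reloaded models reproduce
#' predictions exactly on the same platform.
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param dir archive directory (created if needed).
#' @return `save_surrogate` returns `dir` invisibly; `load_surrogate` returns
#'   the restored `surrogate_ensemble`.
#' @export
save_surrogate <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- ensemble[c("target", "booster", "n_splits", "train_fraction",
                     "seed", "nrounds", "params", "y", "oof", "cv")]
  meta$config <- unclass(ensemble$config)
  meta$train_idx <- lapply(ensemble$members, `[[`, "train")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in seq_along(ensemble$members)) {
    xgboost::xgb.save(ensemble$members[[s]]$model,
                      file.path(dir, sprintf("member_%04d.ubj", s)))
  }
  invisible(dir)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- as.integer(meta$n_splits)
  # equal-length index vectors come back as a matrix (one row per member)
  train_idx <- if (is.matrix(meta$train_idx)) {
    lapply(seq_len(nrow(meta$train_idx)), function(i) meta$train_idx[i, ])
  } else {
    meta$train_idx
  }
  members <- lapply(seq_len(n), function(s) {
    list(model = xgboost::xgb.load(file.path(dir, sprintf("member_%04d.ubj", s))),
         train = train_idx[[s]],
         test = NULL)
  })
  structure(
    list(members = members, target = meta$target,
         config = fingerprint_config(meta$config$n_bits, meta$config$radius,
                                     meta$config$components),
         booster = meta$booster, n_splits = as.integer(meta$n_splits),
         train_fraction = meta$train_fraction, seed = as.integer(meta$seed),
         nrounds = as.integer(meta$nrounds), params = as.list(meta$params),
         y = meta$y, oof = meta$oof, cv = as.list(meta$cv)),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("surrogate_ensemble [", x$target, "] ", x$n_splits, " x ",
      round(100 * x$train_fraction), "/", round(100 * (1 - x$train_fraction)),
      " splits, booster=", x$booster, "\n", sep = "")
  cat(sprintf("  out-of-fold MAE = %.4f, MSE = %.4f (n = %d)\n",
              x$cv$mae, x$cv$mse, x$cv$n_oof))
  invisible(x)
}
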