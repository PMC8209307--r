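# Node-class-specific diameter regression: squared Pearson correlation,
# OLS through the origin with uncentered adjusted R^2, stepwise pair
# selection with an improvement constant, the 3/2-power branch-point
# check, and the diameter autocorrelation decay fit.

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Pearson's coefficient of determination, in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined statistic: zero variance")
  stats::cor(x, y)^2
}

#' Ordinary least squares through the origin
#'
#' Fits `y = X b` with no intercept and reports the uncentered coefficient
#' of determination `R2 = 1 - SSR / sum(y^2)` and its adjusted form
#' `1 - (1 - R2) * n / (n - p)`, the standard convention for regression
#' through the origin.  Adjusted R^2 may be negative and is not clipped.
#'
#' @param X numeric matrix (n x p, p >= 1) with named columns, or a vector.
#' @param y numeric response vector, length n > p.
#' @return List with `coefficients` (named), `adj_r2`, `r2`, `n`, `p`,
#'   `fitted`, `residuals`.
#' @export
ols_no_intercept <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n <= p) stop("need more observations than features")
  qx <- qr(X)
  if (qx$rank < p) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design matrix; offending column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  ssr <- sum(res^2)
  tss <- sum(y^2)
  if (tss == 0) stop("undefined statistic: response is identically zero")
  r2 <- 1 - ssr / tss
  adj <- 1 - (1 - r2) * n / (n - p)
  list(coefficients = stats::coef(fit), adj_r2 = adj, r2 = r2,
       n = n, p = p, fitted = fit$fitted.values, residuals = res)
}

#' Stepwise feature selection by adjusted R^2 with an improvement constant
#'
#' Selects the feature set used to predict node diameter for one node
#' class, by the three-step procedure: (1) rank candidate features by
#' single-feature adjusted R^2 (OLS through the origin); (2) taking
#' features in descending order, pair each with every other candidate;
#' (3) a pair becomes the winner if and only if its adjusted R^2 exceeds
#' both of its single-feature R^2 by at least `improvement` and exceeds
#' the best qualifying pair found so far.  If no pair qualifies, the best
#' single feature wins.  At most two features are ever selected.
#'
#' @param table per-node feature table ([feature_table()]).
#' @param node_class one of `"initial"`, `"branching_child"`,
#'   `"continuing"`.
#' @param tree_label `"apical"`, `"basal"` or `"generic"`; rows with other
#'   labels are ignored.  `NULL` pools all labels.
#' @param improvement minimum adjusted-R^2 gain a pair must show over each
#'   of its singles (default 0.001; results in practice are insensitive
#'   between 0.001 and 0.02).
#' @param candidates candidate feature columns (default PD, IB, TD, PS,
#'   LP, TL).
#' @return List: `features` (winning set), `adj_r2`, `singles` (named
#'   vector of single-feature adjusted R^2, descending), `pairs`
#'   (data.frame of qualifying candidate pairs in the order considered).
#' @export
select_features <- function(table, node_class, tree_label = NULL,
                            improvement = 0.001,
                            candidates = FEATURE_NAMES) {
  rows <- table$node_class == node_class
  if (!is.null(tree_label)) rows <- rows & table$tree_label == tree_label
  tbl <- table[rows, , drop = FALSE]
  if (nrow(tbl) < 3)
    stop("empty-model error: no (or too few) rows for class ", node_class,
         if (!is.null(tree_label)) paste0(" / ", tree_label))
  y <- tbl$D
  usable <- candidates[vapply(candidates, function(f)
    stats::var(tbl[[f]]) > 0 || any(tbl[[f]] != 0), logical(1))]
  singles <- vapply(usable, function(f)
    ols_no_intercept(tbl[[f]], y)$adj_r2, numeric(1))
  singles <- sort(singles, decreasing = TRUE)
  best <- list(features = names(singles)[1], adj_r2 = singles[[1]])
  pair_log <- list()
  feats <- names(singles)
  for (i in seq_along(feats)) {
    for (j in seq_along(feats)) {
      if (j <= i) next
      f1 <- feats[i]; f2 <- feats[j]
      X <- cbind(tbl[[f1]], tbl[[f2]])
      colnames(X) <- c(f1, f2)
      a <- tryCatch(ols_no_intercept(X, y)$adj_r2,
                    error = function(e) -Inf)
      qualifies <- a >= singles[[f1]] + improvement &&
        a >= singles[[f2]] + improvement
      if (qualifies) {
        pair_log[[length(pair_log) + 1L]] <-
          data.frame(f1 = f1, f2 = f2, adj_r2 = a)
        if (a > best$adj_r2) best <- list(features = c(f1, f2), adj_r2 = a)
      }
    }
  }
  list(features = best$features, adj_r2 = best$adj_r2, singles = singles,
       pairs = if (length(pair_log)) do.call(rbind, pair_log) else NULL)
}

#' Construct a single diameter model
#'
#' @param node_class,tree_label class and tree the model applies to.
#' @param features character vector (length 1 or 2) of feature names.
#' @param coefficients numeric, one per feature (um per feature unit).
#' @param adj_r2 training adjusted R^2 (may be NA for hand-entered models).
#' @param n_train training node count (NA if unknown).
#' @param note optional free-text caveat, carried through serialization.
#' @return Object of class `diameter_model`.
#' @export
diameter_model <- function(node_class, tree_label, features, coefficients,
                           adj_r2 = NA_real_, n_train = NA_integer_,
                           note = NULL) {
  stopifnot(length(features) %in% 1:2,
            length(coefficients) == length(features))
  structure(list(node_class = node_class, tree_label = tree_label,
                 features = features,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                features),
                 adj_r2 = adj_r2, n_train = n_train, note = note),
            class = "diameter_model")
}

#' Evaluate a diameter model on a feature vector
#'
#' @param model a `diameter_model`.
#' @param features named numeric vector (or 1-row data.frame) holding at
#'   least the model's features.
#' @return Predicted diameter in micrometres (no intercept, pure linear
#'   combination).
#' @export
evaluate_model <- function(model, features) {
  if (is.data.frame(features)) features <- unlist(features[1, ])
  miss <- setdiff(model$features, names(features))
  if (length(miss)) stop("feature(s) missing for model evaluation: ",
                         paste(miss, collapse = ", "))
  sum(model$coefficients * as.numeric(features[model$features]))
}

#' @export
print.diameter_model <- function(x, ...) {
  eq <- paste(sprintf("%.6g x %s", x$coefficients, x$features),
              collapse = " + ")
  cat(sprintf("<diameter_model> %s / %s: D = %s (adj R2 = %s, n = %s)\n",
              x$tree_label, x$node_class, eq, format(x$adj_r2),
              format(x$n_train)))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Fit a complete model set on training morphologies
#'
#' For each (tree label x node class) present in the training data, runs
#' [select_features()] followed by [ols_no_intercept()] on the pooled
#' training nodes.  Classes with too few nodes fall back to a
#' single-feature PD model when possible, with a warning, or are skipped.
#'
#' @param train list of `morphology` objects (the training split).
#' @param cell_type label recorded in the model set.
#' @param improvement passed to [select_features()].
#' @param seed integer recorded in the provenance (use the same seed that
#'   produced the train/test split).
#' @param candidates candidate features, default all six.
#' @return Object of class `model_set`: models keyed by
#'   `"<tree_label>/<node_class>"`, plus `cell_type` and `provenance`.
#' @export
fit_model_set <- function(train, cell_type = "unspecified",
                          improvement = 0.001, seed = NA_integer_,
                          candidates = FEATURE_NAMES) {
  if (inherits(train, "morphology")) train <- list(train)
  if (length(train) < 1) stop("need at least one training morphology")
  tbl <- feature_table(train)
  models <- list()
  for (lab in unique(tbl$tree_label)) {
    for (cls in levels(tbl$node_class)) {
      sub <- tbl[tbl$tree_label == lab & tbl$node_class == cls, ,
                 drop = FALSE]
      if (nrow(sub) == 0) next
      if (nrow(sub) < 4) {
        if (nrow(sub) >= 2 && stats::var(sub$PD) >= 0) {
          warning("class ", cls, "/", lab, " has only ", nrow(sub),
                  " nodes; falling back to a PD-only model")
          co <- sum(sub$PD * sub$D) / sum(sub$PD^2)
          models[[paste(lab, cls, sep = "/")]] <-
            diameter_model(cls, lab, "PD", co, NA_real_, nrow(sub))
        } else {
          warning("class ", cls, "/", lab, " skipped: too few nodes")
        }
        next
      }
      sel <- select_features(tbl, cls, lab, improvement, candidates)
      X <- as.matrix(sub[sel$features])
      fit <- ols_no_intercept(X, sub$D)
      models[[paste(lab, cls, sep = "/")]] <-
        diameter_model(cls, lab, sel$features, fit$coefficients,
                       fit$adj_r2, fit$n)
    }
  }
  morph_ids <- vapply(train, function(m) {
    nm <- m$metadata$name
    if (is.null(nm)) nm <- m$metadata$source
    if (is.null(nm)) nm <- "unnamed"
    nm
  }, character(1))
  structure(list(cell_type = cell_type, models = models,
                 provenance = list(train = morph_ids, seed = seed,
                                   improvement = improvement)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("<model_set> cell type:", x$cell_type, "-", length(x$models),
      "models\n")
  for (m in x$models) print(m)
  invisible(x)
}

#' Split an archive into training and testing morphologies
#'
#' @param ms list of morphologies.
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed; recorded so the split is reproducible.
#' @return List with `train`, `test`, and `seed`.
#' @export
split_archive <- function(ms, fraction = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required for the split")
  n <- length(ms)
  set.seed(seed)
  n_train <- max(1L, round(fraction * n))
  idx <- sample.int(n, n_train)
  list(train = ms[idx], test = ms[-idx], seed = seed)
}

#' Compare predicted against original diameters
#'
#' Squared Pearson correlation between original and predicted node
#' diameters, computed separately per dendritic tree (one apical and/or
#' one basal/generic tree per morphology) so that large and small trees
#' weigh equally when averaged across morphologies.
#'
#' @param orig,pred morphologies with identical topology, differing only
#'   in radii.
#' @return data.frame with `tree_label`, `n_nodes`, `r2`, plus an attribute
#'   `pooled_r2` over all dendritic nodes.
#' @export
evaluate_prediction <- function(orig, pred) {
  if (nrow(orig$nodes) != nrow(pred$nodes) ||
      any(orig$nodes$id != pred$nodes$id) ||
      any(orig$nodes$parent != pred$nodes$parent))
    stop("structural error: topology mismatch between morphologies")
  dend <- dendritic_mask(orig)
  lab <- tree_label_of(orig$nodes$type[dend])
  d0 <- 2 * orig$nodes$radius[dend]
  d1 <- 2 * pred$nodes$radius[dend]
  labs <- unique(lab)
  r2 <- vapply(labs, function(L) {
    i <- lab == L
    if (sum(i) < 3 || stats::var(d0[i]) == 0 || stats::var(d1[i]) == 0)
      return(NA_real_)
    pearson_r2(d0[i], d1[i])
  }, numeric(1))
  out <- data.frame(tree_label = labs,
                    n_nodes = as.integer(table(lab)[labs]),
                    r2 = r2)
  attr(out, "pooled_r2") <-
    if (stats::var(d0) > 0 && stats::var(d1) > 0) pearson_r2(d0, d1)
    else NA_real_
  out
}

#' Mean per-tree prediction R^2 across morphologies
#'
#' @param origs,preds parallel lists of original and predicted
#'   morphologies.
#' @return Named numeric vector: mean R^2 per tree label, averaged across
#'   morphologies (the per-morphology-then-average convention).
#' @export
mean_prediction_r2 <- function(origs, preds) {
  per <- Map(evaluate_prediction, origs, preds)
  all_rows <- do.call(rbind, per)
  tapply(all_rows$r2, all_rows$tree_label,
         function(v) mean(v, na.rm = TRUE))
}

#' Branch-point 3/2-power (Rall) check
#'
#' For every dendritic branch point, correlates the branch node's diameter
#' raised to the 3/2 power with the sum of its children's diameters raised
#' to the 3/2 power.  Also reports the individual-child variant (child D
#' vs parent D^1.5), which predicts single diameters rather than their
#' sum and performs worse.
#'
#' @param ms morphology or list of morphologies.
#' @return List: `sum_rule_r2`, `child_rule_r2`, `n_branch_points`, and the
#'   assembled vectors (`parent_pow`, `child_sum_pow`).
#' @export
rall_check <- function(ms) {
  if (inherits(ms, "morphology")) ms <- list(ms)
  pp <- numeric(0); cs <- numeric(0)
  cd <- numeric(0); pd_pow <- numeric(0)
  for (m in ms) {
    nd <- m$nodes
    pidx <- parent_index(m)
    dend <- dendritic_mask(m)
    kids <- children_index(pidx, nrow(nd))
    nchild <- lengths(kids)
    bp <- which(dend & nchild >= 2)
    for (b in bp) {
      ch <- kids[[b]]
      ch <- ch[dend[ch]]
      if (length(ch) < 2) next
      pp <- c(pp, (2 * nd$radius[b])^1.5)
      cs <- c(cs, sum((2 * nd$radius[ch])^1.5))
      cd <- c(cd, 2 * nd$radius[ch])
      pd_pow <- c(pd_pow, rep((2 * nd$radius[b])^1.5, length(ch)))
    }
  }
  if (!length(pp))
    return(list(sum_rule_r2 = NA_real_, child_rule_r2 = NA_real_,
                n_branch_points = 0L, parent_pow = pp, child_sum_pow = cs))
  list(sum_rule_r2 = if (length(pp) >= 3 && stats::var(pp) > 0 &&
                           stats::var(cs) > 0) pearson_r2(pp, cs)
       else NA_real_,
       child_rule_r2 = if (length(cd) >= 3 && stats::var(cd) > 0 &&
                             stats::var(pd_pow) > 0)
         pearson_r2(pd_pow, cd) else NA_real_,
       n_branch_points = length(pp),
       parent_pow = pp, child_sum_pow = cs)
}

#' Fraction of nodes whose diameter equals the parent diameter
#'
#' @param table feature table.
#' @param node_class class to evaluate (default `"continuing"`).
#' @param tol equality tolerance in micrometres; the default 1e-4
#'   corresponds to equality at standard 4-decimal SWC file precision.
#' @return Fraction in \[0, 1\].
#' @export
pd_equality_fraction <- function(table, node_class = "continuing",
                                 tol = 1e-4) {
  rows <- table[table$node_class == node_class, , drop = FALSE]
  if (!nrow(rows)) return(NA_real_)
  mean(abs(rows$D - rows$PD) <= tol)
}

#' Diameter autocorrelation along dendritic paths and its decay fit
#'
#' For each morphology, the correlation between the diameters of dendritic
#' nodes separated by k parent links is computed for k = 1..`max_lag`
#' (lag in node counts, not micrometres).  The per-morphology
#' autocorrelation is averaged across the archive to reduce noise and the
#' average is fit to a double exponential decay
#' `A1 exp(-k/lambda1) + A2 exp(-k/lambda2)` with non-negative amplitudes,
#' by nonlinear least squares initialized from a log-linear
#' single-exponential fit.  The smaller space constant is returned first.
#'
#' @param archive morphology or list of morphologies.
#' @param max_lag maximum node separation (default 20); shrunk with a
#'   warning when all paths are shorter.
#' @return Object of class `autocorr_fit`: `lags`, `acf` (averaged),
#'   `A1`, `A2`, `lambda1`, `lambda2` (lambda1 <= lambda2), `per_morph`
#'   matrix.
#' @export
diameter_autocorrelation <- function(archive, max_lag = 20) {
  if (inherits(archive, "morphology")) archive <- list(archive)
  per <- lapply(archive, function(m) {
    nd <- m$nodes
    pidx <- parent_index(m)
    dmask <- dendritic_mask(m)
    d <- 2 * nd$radius
    anc <- pidx  # k-step ancestor per row, advanced in place
    out <- rep(NA_real_, max_lag)
    for (k in seq_len(max_lag)) {
      idx <- which(dmask & !is.na(anc) & dmask[replace(anc, is.na(anc), 1)])
      if (length(idx) >= 3) {
        a <- d[idx]; b <- d[anc[idx]]
        if (stats::var(a) > 0 && stats::var(b) > 0)
          out[k] <- stats::cor(a, b)
      }
      anc <- pidx[anc]
    }
    out
  })
  acfm <- do.call(rbind, per)
  avg <- colMeans(acfm, na.rm = TRUE)
  usable <- which(is.finite(avg))
  if (!length(usable))
    stop("undefined: no usable lags (constant diameters?)")
  if (max(usable) < max_lag)
    warning("lag range shrunk to ", max(usable),
            ": all paths shorter than max_lag")
  lags <- usable
  y <- avg[usable]
  # log-linear initialization for a single exponential
  pos <- y > 0
  lam0 <- if (sum(pos) >= 2)
    -1 / stats::coef(stats::lm(log(y[pos]) ~ lags[pos]))[[2]]
  else max_lag / 2
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- max_lag / 2
  df <- data.frame(k = lags, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-k / l1) + A2 * exp(-k / l2), data = df,
      start = list(A1 = y[1] * 0.6, A2 = y[1] * 0.4,
                   l1 = lam0 * 0.5, l2 = lam0 * 2),
      lower = c(0, 0, 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- c(A1 = y[1], A2 = 0, l1 = lam0, l2 = lam0)
  } else {
    co <- stats::coef(fit)
  }
  if (co[["l1"]] > co[["l2"]]) {
    co <- c(A1 = co[["A2"]], A2 = co[["A1"]],
            l1 = co[["l2"]], l2 = co[["l1"]])
  }
  structure(list(lags = lags, acf = y,
                 A1 = co[["A1"]], A2 = co[["A2"]],
                 lambda1 = co[["l1"]], lambda2 = co[["l2"]],
                 per_morph = acfm),
            class = "autocorr_fit")
}

#' @export
print.autocorr_fit <- function(x, ...) {
  cat(sprintf(
    "<autocorr_fit> lags 1..%d: %.3g exp(-k/%.3g) + %.3g exp(-k/%.3g)\n",
    max(x$lags), x$A1, x$lambda1, x$A2, x$lambda2))
  invisible(x)
}
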