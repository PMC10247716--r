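#' Missing-value filter for metabolite matrices
#'
#' Untargeted LC-MS matrices encode missing peaks as zero intensity. Features
#' whose zero-intensity proportion is strictly greater than
#' `max_missing_frac` are removed (the conventional "missing in more than
#' 60% of samples" rule); a feature exactly at the boundary is kept.
#'
#' @param table An intensity [feature_table()].
#' @param max_missing_frac Maximum tolerated zero fraction (default 0.6).
#' @return The filtered `feature_table`, with attribute `n_dropped`.
#' @export
missingness_filter <- function(table, max_missing_frac = 0.6) {
  stopifnot(inherits(table, "feature_table"))
  zero_frac <- rowMeans(table$values == 0)
  keep <- zero_frac <= max_missing_frac
  if (!any(keep)) warning("missingness filter removed every feature")
  out <- feature_table(table$values[keep, , drop = FALSE], table$group, table$kind)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Center and scale a samples x features matrix
#'
#' SIMCA-style column preprocessing ahead of (O)PLS: mean centering plus
#' unit-variance scaling (divide by SD), Pareto scaling (divide by sqrt(SD))
#' or centering only. Zero-variance columns are centered only and flagged.
#'
#' @param x Numeric matrix, samples in rows.
#' @param method `"unit_variance"`, `"pareto"` or `"none"`.
#' @return List with `x` (processed matrix), `center`, `scale` (divisors)
#'   and `zero_variance` (logical per column).
#' @export
scale_features <- function(x, method = c("unit_variance", "pareto", "none")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nrow(x) >= 2)
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zv <- sds == 0
  div <- switch(method,
    unit_variance = sds,
    pareto = sqrt(sds),
    none = rep(1, ncol(x))
  )
  div[zv | div == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, div, "/")
  list(x = xs, center = ctr, scale = div, zero_variance = zv, method = method)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis with a
#' single predictive component and `n_ortho` orthogonal (class-uncorrelated)
#' components, by the NIPALS-based O-PLS algorithm: the predictive weight
#' w is proportional to X'y; each orthogonal weight is the part of the
#' current loading orthogonal to w (w_o = p - (w'p / w'w) w), and X is
#' deflated by its orthogonal component t_o p_o' before the predictive
#' component t = X w is finally extracted.
#'
#' Predictive performance is summarised by R2Y (in-sample) and Q2
#' (cross-validated): Q2 = 1 - PRESS / SS over `cv_folds` seeded rounds,
#' each holding out max(1, round(N / cv_folds)) randomly chosen samples
#' ("1/k of the samples excluded per round"), refitting (including the
#' preprocessing) on the remainder and predicting the held-out class value.
#'
#' @param x Numeric matrix, samples x features (raw, unscaled).
#' @param y Numeric class encoding, typically +/-1; must have variance.
#' @param n_ortho Number of orthogonal components (default 1; 0 gives plain
#'   single-component PLS1).
#' @param scaling Column preprocessing, see [scale_features()].
#' @param cv_folds Number of cross-validation rounds (default 7).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `opls_model`: scaling state, predictive
#'   `w`/`p`/`t`/`q`, orthogonal `W_o`/`P_o`/`T_o`, `r2x`, `r2y`, `q2`,
#'   `n_ortho`, `cv_folds`.
#' @export
opls_fit <- function(x, y, n_ortho = 1, scaling = c("unit_variance", "pareto", "none"),
                     cv_folds = 7, seed = 1) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (stats::var(y) == 0) stop("`y` has zero variance")
  if (n_ortho >= qr(scale(x, scale = FALSE))$rank) {
    stop("n_ortho must be smaller than the rank of centered X")
  }

  core <- opls_core(x, y, n_ortho, scaling)

  # cross-validated Q2: seeded random hold-out rounds, preprocessing refit
  n <- nrow(x)
  holdout <- max(1L, as.integer(round(n / cv_folds)))
  set.seed(as.integer(seed))
  press <- 0
  sstot <- 0
  for (f in seq_len(cv_folds)) {
    test_idx <- sample.int(n, holdout)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (stats::var(y[train_idx]) == 0) next
    fold <- tryCatch(
      opls_core(x[train_idx, , drop = FALSE], y[train_idx], n_ortho, scaling),
      error = function(e) NULL
    )
    if (is.null(fold)) next
    yhat <- mean(y[train_idx]) + opls_predict_core(fold, x[test_idx, , drop = FALSE])
    press <- press + sum((y[test_idx] - yhat)^2)
    sstot <- sstot + sum((y[test_idx] - mean(y[train_idx]))^2)
  }
  core$q2 <- if (sstot > 0) 1 - press / sstot else NA_real_
  core$cv_folds <- cv_folds
  core$seed <- as.integer(seed)
  class(core) <- "opls_model"
  core
}

# Internal: deterministic O-PLS decomposition on one data set.
opls_core <- function(x, y, n_ortho, scaling) {
  sc <- scale_features(x, scaling)
  xs <- sc$x
  yc <- y - mean(y)
  ssx <- sum(xs^2)
  ssy <- sum(yc^2)

  w <- drop(crossprod(xs, yc))
  w <- w / sqrt(sum(w^2))

  W_o <- P_o <- matrix(0, ncol(x), 0)
  T_o <- matrix(0, nrow(x), 0)
  xd <- xs
  for (a in seq_len(n_ortho)) {
    t_pred <- drop(xd %*% w)
    p <- drop(crossprod(xd, t_pred)) / sum(t_pred^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(xd %*% w_o)
    p_o <- drop(crossprod(xd, t_o)) / sum(t_o^2)
    xd <- xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }

  t_pred <- drop(xd %*% w)
  p_pred <- drop(crossprod(xd, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  yhat <- t_pred * q
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  r2x_pred <- sum(t_pred^2) * sum(p_pred^2) / ssx
  r2x_ortho <- if (ncol(T_o) > 0) {
    sum(vapply(seq_len(ncol(T_o)),
               function(a) sum(T_o[, a]^2) * sum(P_o[, a]^2), numeric(1))) / ssx
  } else 0

  list(
    scaling = sc[c("center", "scale", "method", "zero_variance")],
    w = w, p = p_pred, t = t_pred, q = q,
    W_o = W_o, P_o = P_o, T_o = T_o,
    n_ortho = ncol(T_o),
    r2x = r2x_pred + r2x_ortho, r2y = r2y, q2 = NA_real_,
    feature_ids = colnames(x)
  )
}

# Internal: predict the class value for new samples (remove orthogonal
# variation first, then project on the predictive component).
opls_predict_core <- function(model, x_new) {
  xs <- sweep(sweep(x_new, 2, model$scaling$center, "-"), 2, model$scaling$scale, "/")
  if (ncol(model$T_o) > 0) {
    for (a in seq_len(ncol(model$T_o))) {
      t_o <- drop(xs %*% model$W_o[, a])
      xs <- xs - tcrossprod(t_o, model$P_o[, a])
    }
  }
  drop(xs %*% model$w) * model$q
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s); R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
    x$n_ortho, x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' Variable importance in the projection (VIP)
#'
#' VIP_j = sqrt(J * sum_a(w_aj^2 SSY_a) / sum_a SSY_a) over the predictive
#' component(s); with the single predictive component used here this reduces
#' to sqrt(J) * |w_j|. Squares sum to the number of features.
#'
#' @param model A fitted [opls_fit()] model.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("`model` must be a fitted opls_model")
  v <- sqrt(length(model$w)) * abs(model$w)
  names(v) <- model$feature_ids
  v
}

#' Hotelling's T-squared control limit for score plots
#'
#' The alpha-level control ellipse radius on the model's score space:
#' T2_crit = A (N^2 - 1) / (N (N - A)) * F_(1-alpha)(A, N - A) with A total
#' score columns and N samples, plus each sample's T2 = sum_a t_a^2 /
#' var(t_a).
#'
#' @param model A fitted [opls_fit()] model.
#' @param alpha Significance level (default 0.05 for a 95% ellipse).
#' @return List with `t2_crit` and per-sample `t2`.
#' @export
hotelling_t2_limit <- function(model, alpha = 0.05) {
  if (!inherits(model, "opls_model")) stop("`model` must be a fitted opls_model")
  scores <- cbind(model$t, model$T_o)
  n <- nrow(scores)
  a <- ncol(scores)
  if (n <= a) stop("need more samples than score columns")
  t2_crit <- a * (n^2 - 1) / (n * (n - a)) * stats::qf(1 - alpha, a, n - a)
  t2 <- rowSums(sweep(scores^2, 2, apply(scores, 2, stats::var), "/"))
  list(t2_crit = t2_crit, t2 = t2)
}

#' Screen metabolites: OPLS-DA VIP plus per-feature t-tests
#'
#' The standard untargeted-metabolomics differential screen: filter features
#' by missingness, log10(x + 1) transform, fit OPLS-DA on the scaled matrix,
#' compute VIP, and run a per-feature two-tailed Student t-test on the
#' transformed intensities. Selection (see [select_differential()]) requires
#' VIP strictly > `vip_threshold` and p strictly < `alpha`.
#'
#' @param table An intensity [feature_table()] with a 2-level group.
#' @param alpha t-test significance level (default 0.05).
#' @param vip_threshold VIP cutoff (default 1).
#' @param max_missing_frac Missingness filter level (default 0.6).
#' @param n_ortho,scaling,cv_folds Passed to [opls_fit()].
#' @param log_transform Transform intensities as log10(x + 1) before
#'   modeling (default TRUE).
#' @param seed Integer seed for the cross-validation folds.
#' @return List with `vips` (data.frame: feature_id, vip, t_p, direction,
#'   selected), `model` (the `opls_model`), `t2` (Hotelling limit), and
#'   `n_filtered` (features removed by the missingness filter).
#' @export
screen_metabolites <- function(table, alpha = 0.05, vip_threshold = 1,
                               max_missing_frac = 0.6, n_ortho = 1,
                               scaling = "unit_variance", cv_folds = 7,
                               log_transform = TRUE, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  g <- table$group
  if (nlevels(g) != 2L) stop("exactly 2 groups required")

  filtered <- missingness_filter(table, max_missing_frac)
  vals <- filtered$values
  if (log_transform) vals <- log10(vals + 1)

  x <- t(vals)  # samples x features
  y <- ifelse(g == levels(g)[2L], 1, -1)
  model <- opls_fit(x, y, n_ortho = n_ortho, scaling = scaling,
                    cv_folds = cv_folds, seed = seed)
  vips <- vip(model)

  idx0 <- which(g == levels(g)[1L])
  idx1 <- which(g == levels(g)[2L])
  t_p <- apply(vals, 1, function(v) {
    ttest_two_sample(v[idx1], v[idx0], variant = "student")$p_value
  })

  # direction from raw (unscaled, filtered) group means; ties count as "up"
  raw0 <- rowMeans(filtered$values[, idx0, drop = FALSE])
  raw1 <- rowMeans(filtered$values[, idx1, drop = FALSE])
  direction <- ifelse(raw1 >= raw0, "up", "down")

  vips_df <- data.frame(
    feature_id = filtered$feature_ids,
    vip = unname(vips),
    t_p = unname(t_p),
    direction = unname(direction),
    stringsAsFactors = FALSE
  )
  vips_df$selected <- vips_df$vip > vip_threshold & vips_df$t_p < alpha

  list(
    vips = vips_df,
    model = model,
    t2 = hotelling_t2_limit(model),
    n_filtered = attr(filtered, "n_dropped")
  )
}

#' Select differential metabolites from a VIP table
#'
#' Applies the strict double cutoff VIP > `vip_threshold` AND p <
#' `alpha`; values exactly on either boundary are excluded.
#'
#' @param vips Data.frame with columns `feature_id`, `vip`, `t_p` and
#'   optionally `direction` (as produced by [screen_metabolites()]).
#' @param vip_threshold,alpha Strict cutoffs (defaults 1 and 0.05).
#' @return Data.frame of the selected rows (feature_id, vip, t_p,
#'   direction).
#' @export
select_differential <- function(vips, vip_threshold = 1, alpha = 0.05) {
  stopifnot(all(c("feature_id", "vip", "t_p") %in% names(vips)))
  keep <- vips$vip > vip_threshold & vips$t_p < alpha
  vips[keep, , drop = FALSE]
}

#' Pathway over-representation analysis
#'
#' Per-pathway hypergeometric test of the selected metabolites against a
#' background, via [hypergeometric_enrichment()]. Pathway members outside
#' the background are ignored.
#'
#' @param selected Character vector of selected metabolite ids.
#' @param annotation Named list: pathway id -> character vector of member
#'   metabolite ids.
#' @param background Character vector: the metabolite universe tested.
#' @return Data.frame (pathway, n_pathway, overlap, p) sorted by p.
#' @export
pathway_enrichment <- function(selected, annotation, background) {
  if (length(annotation) == 0L) {
    return(data.frame(pathway = character(), n_pathway = integer(),
                      overlap = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  selected <- intersect(selected, background)
  rows <- lapply(names(annotation), function(pw) {
    members <- intersect(annotation[[pw]], background)
    res <- hypergeometric_enrichment(selected, members, background)
    data.frame(pathway = pw, n_pathway = length(members),
               overlap = res$statistic, p = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$pathway), , drop = FALSE]
}
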