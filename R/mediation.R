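#' @title Causal mediation engine
#' @description The core computation: for a candidate triad (exposure X,
#'   mediator M, outcome Y) with the treatment indicator Z as adjustment
#'   covariate, fit the three Gaussian GLMs
#'   \deqn{Y = b0 + b1 X + g1 Z + e1}
#'   \deqn{M = b0 + b2 X + g2 Z + e2}
#'   \deqn{Y = b0 + b3 M + b4 X + g3 Z + e3}
#'   and report the average causal mediation effect ACME = b2 * b3, the
#'   average direct effect ADE = b4, and the total effect b1. For linear
#'   models fitted by OLS on the same samples and covariates the exact
#'   decomposition b1 = b2 * b3 + b4 holds, so ACME + ADE = total.
#'   Uncertainty comes from quasi-Bayesian Monte Carlo: coefficient draws
#'   from their asymptotic sampling distributions propagated through the
#'   product.
#' @name mediation_engine
NULL

#' Bundle one mediation triad
#'
#' @param x,m,y Numeric vectors: exposure, mediator, outcome.
#' @param z Binary 0/1 treatment indicator (the adjustment covariate).
#' @param x_id,m_id,y_id Labels.
#' @param direction Label for the causal direction screened, e.g.
#'   `"hormone->metabolite->genus"`.
#' @return An object of class `mediation_triad`.
#' @export
mediation_triad <- function(x, m, y, z, x_id = "x", m_id = "m", y_id = "y",
                            direction = "x->m->y") {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, length(z) == n, n >= 6)
  if (!all(z %in% c(0, 1))) stop("`z` must be a binary 0/1 indicator")
  stopifnot(all(is.finite(x)), all(is.finite(m)), all(is.finite(y)))
  structure(
    list(x = x, m = m, y = y, z = z,
         x_id = x_id, m_id = m_id, y_id = y_id, direction = direction),
    class = "mediation_triad"
  )
}

#' Fit the three OLS regressions of a mediation triad
#'
#' Fits Y ~ X + Z (total-effect model), M ~ X + Z (mediator model) and
#' Y ~ M + X + Z (outcome model) by OLS, with classical coefficient
#' covariance. If any model is rank deficient (e.g. X collinear with Z) the
#' fit is returned with `ok = FALSE` and a reason, so the triad can be
#' skipped rather than aborting a screen.
#'
#' @param triad A [mediation_triad()].
#' @return An object of class `triad_fit`: coefficient estimates `beta1`,
#'   `beta2`, `beta3`, `beta4`, their SEs and two-tailed p-values, the
#'   covariance block of (beta3, beta4), residual variances, `n`, and `ok`.
#' @export
fit_triad <- function(triad) {
  stopifnot(inherits(triad, "mediation_triad"))
  df <- data.frame(x = triad$x, m = triad$m, y = triad$y, z = triad$z)
  n <- nrow(df)
  if (n < 5) stop("need n >= p + 2 observations for the outcome model")

  fit1 <- stats::lm(y ~ x + z, data = df)
  fit2 <- stats::lm(m ~ x + z, data = df)
  fit3 <- stats::lm(y ~ m + x + z, data = df)

  bad <- vapply(list(fit1, fit2, fit3), function(f) anyNA(stats::coef(f)), logical(1))
  if (any(bad)) {
    return(structure(
      list(ok = FALSE,
           reason = "rank-deficient design (collinear exposure/mediator/treatment)",
           triad = triad[c("x_id", "m_id", "y_id", "direction")], n = n),
      class = "triad_fit"
    ))
  }

  s1 <- summary(fit1)$coefficients
  s2 <- summary(fit2)$coefficients
  s3 <- summary(fit3)$coefficients

  structure(
    list(
      ok = TRUE,
      beta1 = s1["x", "Estimate"], beta1_se = s1["x", "Std. Error"],
      beta1_p = s1["x", "Pr(>|t|)"],
      beta2 = s2["x", "Estimate"], beta2_se = s2["x", "Std. Error"],
      beta2_p = s2["x", "Pr(>|t|)"],
      beta3 = s3["m", "Estimate"], beta3_se = s3["m", "Std. Error"],
      beta3_p = s3["m", "Pr(>|t|)"],
      beta4 = s3["x", "Estimate"], beta4_se = s3["x", "Std. Error"],
      beta4_p = s3["x", "Pr(>|t|)"],
      vcov34 = stats::vcov(fit3)[c("m", "x"), c("m", "x")],
      sigma2 = c(e1 = summary(fit1)$sigma^2, e2 = summary(fit2)$sigma^2,
                 e3 = summary(fit3)$sigma^2),
      n = n,
      triad = triad[c("x_id", "m_id", "y_id", "direction")]
    ),
    class = "triad_fit"
  )
}

#' @export
print.triad_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<triad_fit> skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<triad_fit %s: %s -> %s -> %s> b1 = %.3g (p = %.3g), b2 = %.3g (p = %.3g), b3 = %.3g (p = %.3g), b4 = %.3g (p = %.3g)\n",
    x$triad$direction, x$triad$x_id, x$triad$m_id, x$triad$y_id,
    x$beta1, x$beta1_p, x$beta2, x$beta2_p, x$beta3, x$beta3_p, x$beta4, x$beta4_p))
  invisible(x)
}

#' Apply the four mediation assumptions to a fitted triad
#'
#' The Baron-Kenny-style screening gate: (1) X significantly predicts Y
#' (p(b1) < alpha), (2) X significantly predicts M (p(b2) < alpha), (3) M
#' significantly predicts Y adjusting for X (p(b3) < alpha), (4) the X-Y
#' relationship is weakened when M is controlled (strictly |b4| < |b1|).
#'
#' @param fit A successful [fit_triad()] result.
#' @param alpha Significance level for gates 1-3 (default 0.05).
#' @return Named logical vector `c(xy, xm, my, weakened)` plus attribute
#'   `all_pass`.
#' @export
assumption_gate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "triad_fit"))
  if (!fit$ok) stop("cannot gate a skipped triad fit: ", fit$reason)
  flags <- c(
    xy = fit$beta1_p < alpha,
    xm = fit$beta2_p < alpha,
    my = fit$beta3_p < alpha,
    weakened = abs(fit$beta4) < abs(fit$beta1)
  )
  attr(flags, "all_pass") <- all(flags)
  flags
}

#' Estimate ACME, ADE and total effect with quasi-Bayesian intervals
#'
#' Point estimates are ACME = b2 * b3, ADE = b4, total = b1 (so ACME + ADE
#' = total exactly). Uncertainty: draw b2 from N(b2_hat, se^2) and (b3, b4)
#' jointly from their estimated bivariate normal (the two models' coefficient
#' blocks are independent), form the draw distributions of ACME, ADE and
#' total, and report 2.5/97.5 percentile intervals and two-sided
#' sign-crossing p-values, floored at 2 / n_sims.
#'
#' @param fit A successful [fit_triad()] result.
#' @param n_sims Number of Monte Carlo draws (>= 100; default 1000).
#' @param seed Integer seed.
#' @return An object of class `mediation_result`: point estimates, CIs,
#'   p-values, `prop_mediated` (ACME / total, NA when total is 0), gate
#'   flags, `n_sims`, `seed` and the triad labels.
#' @export
estimate_effects <- function(fit, n_sims = 1000, seed = 1) {
  stopifnot(inherits(fit, "triad_fit"))
  if (!fit$ok) stop("cannot estimate effects for a skipped triad fit: ", fit$reason)
  if (n_sims < 100) stop("n_sims must be at least 100 for stable percentiles")

  set.seed(as.integer(seed))
  b2_draws <- stats::rnorm(n_sims, fit$beta2, fit$beta2_se)
  b34_draws <- MASS::mvrnorm(n_sims, mu = c(fit$beta3, fit$beta4),
                             Sigma = fit$vcov34)
  acme_draws <- b2_draws * b34_draws[, 1]
  ade_draws <- b34_draws[, 2]
  total_draws <- acme_draws + ade_draws

  pvl <- function(draws) {
    max(2 * min(mean(draws <= 0), mean(draws >= 0)), 2 / n_sims)
  }
  ci <- function(draws) unname(stats::quantile(draws, c(0.025, 0.975)))

  acme <- fit$beta2 * fit$beta3
  total <- fit$beta1
  structure(
    list(
      triad = fit$triad,
      acme = acme, ade = fit$beta4, total = total,
      prop_mediated = if (abs(total) > 0) acme / total else NA_real_,
      acme_ci = ci(acme_draws), ade_ci = ci(ade_draws), total_ci = ci(total_draws),
      acme_p = pvl(acme_draws), ade_p = pvl(ade_draws), total_p = pvl(total_draws),
      gate = assumption_gate(fit),
      n_sims = n_sims, seed = as.integer(seed), n = fit$n
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result %s: %s -> %s -> %s>\n  ACME = %.3g [%.3g, %.3g] p = %.3g; ADE = %.3g p = %.3g; total = %.3g p = %.3g\n",
    x$triad$direction, x$triad$x_id, x$triad$m_id, x$triad$y_id,
    x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p, x$ade, x$ade_p, x$total, x$total_p))
  invisible(x)
}

# Internal: deterministic per-triad seed below 2^31, from the master seed
# and the triad labels, so results are order-independent.
triad_seed <- function(seed, direction, x_id, m_id, y_id) {
  key <- paste(direction, x_id, m_id, y_id, sep = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 1048573
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Screen candidate mediation triples in both causal directions
#'
#' Enumerates (exposure, mediator, outcome) combinations from the upstream
#' differential candidates — hormone -> metabolite -> genus and genus ->
#' metabolite -> hormone — fits each triad with the treatment indicator as
#' adjustment covariate, applies the assumption gate, and estimates
#' ACME/ADE/total for the gate-passing triads. A triad is `reported` when it
#' passes the gate and its ACME p-value is below `alpha` (set
#' `require_gate = FALSE` to report on ACME significance alone).
#'
#' Feature transforms (recorded in the output): genus abundances enter as
#' log10(relative abundance + 1e-6), metabolites as log10(intensity + 1),
#' hormones raw.
#'
#' @param hormones,genera,metabolites [feature_table()]s sharing samples in
#'   identical order; `genera` should hold (rarefied) counts.
#' @param candidates List with character vectors `hormones`, `genera`,
#'   `metabolites`: the features passing the upstream screens.
#' @param direction `"both"`, `"hormone->metabolite->genus"` or
#'   `"genus->metabolite->hormone"`.
#' @param alpha ACME significance level (default 0.05).
#' @param n_sims Quasi-Bayesian draws per triad (default 1000).
#' @param seed Master seed; per-triad seeds are derived from it and the
#'   triad labels.
#' @param require_gate Require all four assumptions for reporting
#'   (default TRUE).
#' @return Data.frame, one row per evaluated candidate triad, ordered by
#'   (direction, x_id, m_id, y_id): effects, CIs, p-values, gate flags,
#'   `gated`, `reported`, `seed`. Attribute `n_skipped` counts rank-deficient
#'   fits.
#' @export
screen_triples <- function(hormones, genera, metabolites, candidates,
                           direction = "both", alpha = 0.05, n_sims = 1000,
                           seed = 1, require_gate = TRUE) {
  stopifnot(inherits(hormones, "feature_table"), inherits(genera, "feature_table"),
            inherits(metabolites, "feature_table"))
  if (!identical(hormones$sample_ids, genera$sample_ids) ||
      !identical(hormones$sample_ids, metabolites$sample_ids)) {
    stop("hormone, genus and metabolite tables must share identical sample order")
  }
  z <- group_indicator(hormones)

  # transforms for regression
  rel <- sweep(genera$values, 2, colSums(genera$values), "/")
  genus_t <- log10(rel + 1e-6)
  met_t <- log10(metabolites$values + 1)
  horm_t <- hormones$values

  cand_h <- intersect(candidates$hormones, hormones$feature_ids)
  cand_g <- intersect(candidates$genera, genera$feature_ids)
  cand_m <- intersect(candidates$metabolites, metabolites$feature_ids)

  dirs <- if (direction == "both") {
    c("hormone->metabolite->genus", "genus->metabolite->hormone")
  } else direction

  combos <- list()
  for (d in dirs) {
    if (length(cand_h) == 0L || length(cand_g) == 0L || length(cand_m) == 0L) next
    grid <- expand.grid(
      x_id = if (d == "hormone->metabolite->genus") cand_h else cand_g,
      m_id = cand_m,
      y_id = if (d == "hormone->metabolite->genus") cand_g else cand_h,
      stringsAsFactors = FALSE
    )
    grid$direction <- d
    combos[[d]] <- grid
  }
  if (length(combos) == 0L || sum(vapply(combos, nrow, integer(1))) == 0L) {
    message("no candidate triples to screen")
    return(empty_mediation_frame())
  }
  grid <- do.call(rbind, combos)
  grid <- grid[order(grid$direction, grid$x_id, grid$m_id, grid$y_id), , drop = FALSE]

  n_skipped <- 0L
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$direction[i]
    x <- if (d == "hormone->metabolite->genus") horm_t[grid$x_id[i], ] else genus_t[grid$x_id[i], ]
    y <- if (d == "hormone->metabolite->genus") genus_t[grid$y_id[i], ] else horm_t[grid$y_id[i], ]
    m <- met_t[grid$m_id[i], ]
    triad <- mediation_triad(x, m, y, z, grid$x_id[i], grid$m_id[i], grid$y_id[i], d)
    fit <- fit_triad(triad)
    if (!fit$ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    gate <- assumption_gate(fit, alpha)
    gated <- attr(gate, "all_pass")
    ts <- triad_seed(seed, d, grid$x_id[i], grid$m_id[i], grid$y_id[i])
    if (gated || !require_gate) {
      eff <- estimate_effects(fit, n_sims = n_sims, seed = ts)
      rows[[i]] <- data.frame(
        direction = d, x_id = grid$x_id[i], m_id = grid$m_id[i], y_id = grid$y_id[i],
        acme = eff$acme, ade = eff$ade, total = eff$total,
        prop_mediated = eff$prop_mediated,
        acme_lo = eff$acme_ci[1], acme_hi = eff$acme_ci[2],
        ade_lo = eff$ade_ci[1], ade_hi = eff$ade_ci[2],
        total_lo = eff$total_ci[1], total_hi = eff$total_ci[2],
        acme_p = eff$acme_p, ade_p = eff$ade_p, total_p = eff$total_p,
        gate_xy = gate[["xy"]], gate_xm = gate[["xm"]], gate_my = gate[["my"]],
        gate_weakened = gate[["weakened"]], gated = gated,
        reported = (gated || !require_gate) && eff$acme_p < alpha,
        seed = ts, stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- data.frame(
        direction = d, x_id = grid$x_id[i], m_id = grid$m_id[i], y_id = grid$y_id[i],
        acme = fit$beta2 * fit$beta3, ade = fit$beta4, total = fit$beta1,
        prop_mediated = NA_real_,
        acme_lo = NA_real_, acme_hi = NA_real_, ade_lo = NA_real_, ade_hi = NA_real_,
        total_lo = NA_real_, total_hi = NA_real_,
        acme_p = NA_real_, ade_p = NA_real_, total_p = NA_real_,
        gate_xy = gate[["xy"]], gate_xm = gate[["xm"]], gate_my = gate[["my"]],
        gate_weakened = gate[["weakened"]], gated = FALSE, reported = FALSE,
        seed = ts, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_mediation_frame()
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_mediation_frame <- function() {
  data.frame(
    direction = character(), x_id = character(), m_id = character(),
    y_id = character(), acme = numeric(), ade = numeric(), total = numeric(),
    prop_mediated = numeric(), acme_lo = numeric(), acme_hi = numeric(),
    ade_lo = numeric(), ade_hi = numeric(), total_lo = numeric(),
    total_hi = numeric(), acme_p = numeric(), ade_p = numeric(),
    total_p = numeric(), gate_xy = logical(), gate_xm = logical(),
    gate_my = logical(), gate_weakened = logical(), gated = logical(),
    reported = logical(), seed = integer(), stringsAsFactors = FALSE
  )
}

#' Export reported mediation triads as a signed edge list
#'
#' Network-plot-ready edges for the reported triads: X -> M edges signed by
#' b2 (via the ACME and outcome path), M -> Y edges signed by b3, with the
#' ACME as edge weight. Signs follow the convention that a negative
#' coefficient is an inhibitory (blue) edge and a positive one an promoting
#' (red) edge.
#'
#' @param mediation Data.frame from [screen_triples()].
#' @param path Optional JSON output path.
#' @return (Invisibly) a list of edge records.
#' @export
mediation_edge_list <- function(mediation, path = NULL) {
  rep_rows <- mediation[mediation$reported, , drop = FALSE]
  edges <- lapply(seq_len(nrow(rep_rows)), function(i) {
    r <- rep_rows[i, ]
    list(
      direction = r$direction, x = r$x_id, m = r$m_id, y = r$y_id,
      acme = r$acme, acme_p = r$acme_p,
      sign = if (r$acme >= 0) "positive" else "negative"
    )
  })
  if (!is.null(path)) {
    jsonlite::write_json(edges, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(edges)
}
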