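#' Configuration for a synthetic two-group multi-omics study
#'
#' Defines the study conditions the generator emulates: a two-group
#' (control vs hypoxia) design with a hormone panel, a compositional genus
#' count table, and zero-inflated log-normal fecal/serum metabolite
#' matrices, plus planted ground truth: group-shifted differential features
#' and exposure -> mediator -> outcome triads with known standardized path
#' coefficients.
#'
#' Defaults follow the emulated study design where it states them (6
#' samples per group, 9 hormones with CRH/ACTH/CORT raised and TRH/tT4
#' lowered under hypoxia, 13 differential genera) and desk-scale feature
#' counts elsewhere (60 genera, 300 fecal and 150 serum metabolites;
#' `full_scale = TRUE` switches to the emulated study scale of 254/2945/1457). Library sizes are
#' log-normal around 30,000 reads. Metabolite zero-inflation is a
#' two-component masking mechanism: most features have a low zero rate and
#' a `high_missing_frac` share a high one, so the 60% missingness filter is
#' exercised.
#'
#' @param n_per_group Samples per group (default 6).
#' @param n_genera,n_fecal_mets,n_serum_mets,n_hormones Feature counts.
#' @param n_diff_genera Planted differential genera (default 13).
#' @param n_diff_fecal,n_diff_serum Planted differential metabolites
#'   (defaults 30 and 15).
#' @param n_diff_hormones Hormones with planted group shifts (default 5:
#'   CRH, ACTH, CORT up; TRH, tT4 down).
#' @param hormone_shift Group shift of differential hormones in
#'   within-group SD units (default 3).
#' @param genus_lfc Log2 fold change of differential genera (default 2).
#' @param met_lfc Log2 fold change of differential metabolites (default 2).
#' @param library_size_mean,library_size_cv Genus library-size log-normal
#'   mean and coefficient of variation (defaults 30000 and 0.2).
#' @param zero_inflation_rate Baseline per-feature zero-masking rate
#'   (default 0.15).
#' @param high_missing_frac Share of metabolites with a high (0.75) zero
#'   rate (default 0.1).
#' @param met_log_sd Within-group SD of metabolite log10 intensity
#'   (default 0.3).
#' @param triads List of planted triads; each a list with `direction`
#'   (`"hormone->metabolite->genus"` or `"genus->metabolite->hormone"`),
#'   `compartment` (`"fecal"` or `"serum"`), standardized coefficients `a`
#'   (X -> M), `b` (M -> Y), `c_prime` (direct X -> Y), `x_shift` (group
#'   shift of X in SD units, so the triad features are detectable by the
#'   upstream screens) and `z_effect` (direct treatment effect on Y).
#' @param full_scale Use full-study feature counts (default FALSE).
#' @param seed Master seed; all child seeds derive from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 6,
                             n_genera = 60, n_fecal_mets = 300,
                             n_serum_mets = 150, n_hormones = 9,
                             n_diff_genera = 13, n_diff_fecal = 30,
                             n_diff_serum = 15, n_diff_hormones = 5,
                             hormone_shift = 3, genus_lfc = 2, met_lfc = 2,
                             library_size_mean = 30000, library_size_cv = 0.2,
                             zero_inflation_rate = 0.15, high_missing_frac = 0.1,
                             met_log_sd = 0.3,
                             triads = list(), full_scale = FALSE, seed = 1) {
  if (full_scale) {
    n_genera <- 254; n_fecal_mets <- 2945; n_serum_mets <- 1457
  }
  stopifnot(n_per_group >= 3, n_genera > n_diff_genera,
            n_fecal_mets > n_diff_fecal, n_serum_mets > n_diff_serum,
            n_hormones >= n_diff_hormones)
  structure(
    list(
      n_per_group = n_per_group, n_genera = n_genera,
      n_fecal_mets = n_fecal_mets, n_serum_mets = n_serum_mets,
      n_hormones = n_hormones, n_diff_genera = n_diff_genera,
      n_diff_fecal = n_diff_fecal, n_diff_serum = n_diff_serum,
      n_diff_hormones = n_diff_hormones, hormone_shift = hormone_shift,
      genus_lfc = genus_lfc, met_lfc = met_lfc,
      library_size_mean = library_size_mean, library_size_cv = library_size_cv,
      zero_inflation_rate = zero_inflation_rate,
      high_missing_frac = high_missing_frac, met_log_sd = met_log_sd,
      triads = triads, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

hormone_names <- function(n) {
  base <- c("CRH", "ACTH", "CORT", "TRH", "tT4", "TSH", "fT4", "tT3", "fT3")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("H", seq_len(n - length(base))))
}

#' Generate a synthetic multi-omics study with planted ground truth
#'
#' Produces hormone, genus, fecal- and serum-metabolite [feature_table()]s
#' over a shared sample set, plus a `truth` record of every planted effect.
#'
#' Mechanisms: genus counts are multinomial draws over a Dirichlet-perturbed
#' log-normal base composition, with hypoxia-group log2 fold shifts on the
#' differential genera and log-normal library sizes; metabolite intensities
#' are log-normal with group shifts on differential features and independent
#' zero masking; hormones are Gaussian with group mean shifts in SD units
#' (the first three differential hormones shift up, the rest down, mirroring
#' an HPA-activation / HPT-suppression pattern). Planted triads then
#' regenerate the named mediator and outcome features from the structural
#' equations M = a X + e, Y = b M + c' X + d Z + e' on standardized scales,
#' mapped back to the observed scales (intensity for metabolites, counts for
#' genera, raw level for hormones); genus columns are rescaled afterwards so
#' every column still sums to its drawn library size.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_study` list: `hormones`, `genera`, `fecal`, `serum`
#'   (feature tables), `metadata` (data.frame), and `truth` (differential
#'   ids per table plus planted triad records).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n <- 2 * cf$n_per_group
  sample_ids <- sprintf("S%02d", seq_len(n))
  group <- factor(rep(c("control", "hypoxia"), each = cf$n_per_group),
                  levels = c("control", "hypoxia"))
  zvec <- as.integer(group == "hypoxia")

  # --- hormones (child seed 1) ---------------------------------------------
  set.seed(cf$seed + 101L)
  hnames <- hormone_names(cf$n_hormones)
  diff_h <- hnames[seq_len(cf$n_diff_hormones)]
  h_sign <- ifelse(seq_len(cf$n_diff_hormones) <= 3, 1, -1)  # up, up, up, down, down
  hmu <- stats::runif(cf$n_hormones, 50, 200)
  hsd <- hmu * 0.1
  H <- matrix(stats::rnorm(cf$n_hormones * n, hmu, hsd),
              nrow = cf$n_hormones, dimnames = list(hnames, sample_ids))
  for (i in seq_len(cf$n_diff_hormones)) {
    H[i, zvec == 1] <- H[i, zvec == 1] + h_sign[i] * cf$hormone_shift * hsd[i]
  }

  # --- genus counts (child seed 2) -----------------------------------------
  set.seed(cf$seed + 202L)
  gnames <- sprintf("genus_%03d", seq_len(cf$n_genera))
  diff_g <- gnames[seq_len(cf$n_diff_genera)]
  g_sign <- rep(c(1, -1), length.out = cf$n_diff_genera)  # enriched in hypoxia / control
  base_comp <- exp(stats::rnorm(cf$n_genera, 0, 1.5))
  base_comp <- base_comp / sum(base_comp)
  libs <- round(stats::rlnorm(n, log(cf$library_size_mean) -
                                0.5 * log(1 + cf$library_size_cv^2),
                              sqrt(log(1 + cf$library_size_cv^2))))
  G <- matrix(0, cf$n_genera, n, dimnames = list(gnames, sample_ids))
  conc <- 200  # Dirichlet concentration: sample-to-sample compositional noise
  for (j in seq_len(n)) {
    comp <- base_comp
    if (zvec[j] == 1) {
      comp[seq_len(cf$n_diff_genera)] <-
        comp[seq_len(cf$n_diff_genera)] * 2^(g_sign * cf$genus_lfc)
    }
    gam <- stats::rgamma(cf$n_genera, shape = comp * conc)
    probs <- gam / sum(gam)
    G[, j] <- stats::rmultinom(1, libs[j], probs)
  }

  # --- metabolites (child seeds 3, 4) --------------------------------------
  gen_mets <- function(n_feat, n_diff, prefix, child_seed) {
    set.seed(cf$seed + child_seed)
    ids <- sprintf("%s_met_%04d", prefix, seq_len(n_feat))
    mu <- stats::runif(n_feat, 4, 7)  # log10 intensity location
    lfc_sign <- rep(c(1, -1), length.out = n_diff)
    M <- matrix(stats::rnorm(n_feat * n, rep(mu, n), cf$met_log_sd),
                nrow = n_feat, dimnames = list(ids, sample_ids))
    for (i in seq_len(n_diff)) {
      M[i, zvec == 1] <- M[i, zvec == 1] + lfc_sign[i] * cf$met_lfc * log10(2)
    }
    vals <- 10^M
    zero_rate <- rep(cf$zero_inflation_rate, n_feat)
    n_high <- round(cf$high_missing_frac * n_feat)
    if (n_high > 0) zero_rate[seq(n_feat - n_high + 1, n_feat)] <- 0.75
    mask <- matrix(stats::runif(n_feat * n) < rep(zero_rate, n), nrow = n_feat)
    vals[mask] <- 0
    list(values = vals, diff_ids = ids[seq_len(n_diff)],
         lfc = lfc_sign * cf$met_lfc, mu = mu)
  }
  fec <- gen_mets(cf$n_fecal_mets, cf$n_diff_fecal, "fecal", 303L)
  ser <- gen_mets(cf$n_serum_mets, cf$n_diff_serum, "serum", 404L)

  # --- planted mediation triads (child seed 5) -----------------------------
  truth_triads <- list()
  if (length(cf$triads) > 0) {
    set.seed(cf$seed + 505L)
    used <- character()
    for (k in seq_along(cf$triads)) {
      tr <- cf$triads[[k]]
      stopifnot(tr$direction %in% c("hormone->metabolite->genus",
                                    "genus->metabolite->hormone"),
                tr$compartment %in% c("fecal", "serum"))
      a <- tr$a; b <- tr$b
      c_prime <- if (is.null(tr$c_prime)) 0 else tr$c_prime
      d <- if (is.null(tr$z_effect)) 0 else tr$z_effect
      x_shift <- if (is.null(tr$x_shift)) 3 else tr$x_shift

      # pick fresh (non-differential, unused) features for X, M, Y
      pick <- function(pool) {
        free <- setdiff(pool, used)
        if (length(free) == 0L) stop("no free features left to plant triad ", k)
        free[1L]
      }
      # metabolite pool: neither differential nor in the high-missingness tail
      comp_ids <- if (tr$compartment == "fecal") rownames(fec$values) else rownames(ser$values)
      n_diff_comp <- if (tr$compartment == "fecal") cf$n_diff_fecal else cf$n_diff_serum
      n_high <- round(cf$high_missing_frac * length(comp_ids))
      met_pool <- comp_ids[setdiff(
        seq_along(comp_ids)[-seq_len(n_diff_comp)],
        if (n_high > 0) seq(length(comp_ids) - n_high + 1, length(comp_ids)) else integer()
      )]
      horm_pool <- hnames[-seq_len(cf$n_diff_hormones)]
      genus_pool <- gnames[-seq_len(cf$n_diff_genera)]
      m_id <- pick(met_pool)
      if (tr$direction == "hormone->metabolite->genus") {
        x_id <- pick(horm_pool); y_id <- pick(genus_pool)
      } else {
        x_id <- pick(genus_pool); y_id <- pick(horm_pool)
      }
      used <- c(used, x_id, m_id, y_id)

      # structural equations on the latent (standardized-noise) scale; the
      # group shift is carried by X so the triad features are screenable
      zc <- zvec - 0.5
      x_star <- x_shift * zc + stats::rnorm(n)
      m_star <- a * x_star + stats::rnorm(n)
      y_star <- b * m_star + c_prime * x_star + d * zc + stats::rnorm(n)

      # theoretical latent SDs, used to keep the genus mapping bounded
      var_x <- 1 + x_shift^2 / 4
      sd_y <- sqrt((a * b + c_prime)^2 * var_x + b^2 + 1 +
                     d^2 / 4 + 2 * (a * b + c_prime) * d * x_shift / 4)
      # affine latent -> observed maps (on the regression-transform scale),
      # recorded in the truth so recovery tests can invert them
      genus_map <- function(sd_lat) list(center = -1.8, scale = 0.25 / sd_lat)
      if (tr$direction == "hormone->metabolite->genus") {
        i <- match(x_id, hnames)
        x_map <- list(center = hmu[i], scale = hsd[i])
        H[i, ] <- x_map$center + x_map$scale * x_star
        i <- match(y_id, gnames)
        y_map <- genus_map(sd_y)
        G[i, ] <- pmax(0, round(10^(y_map$center + y_map$scale * y_star) * libs))
      } else {
        i <- match(x_id, gnames)
        x_map <- genus_map(sqrt(var_x))
        G[i, ] <- pmax(0, round(10^(x_map$center + x_map$scale * x_star) * libs))
        i <- match(y_id, hnames)
        y_map <- list(center = hmu[i], scale = hsd[i])
        H[i, ] <- y_map$center + y_map$scale * y_star
      }
      # mediator metabolite: log10 intensity = mu + met_log_sd * M*
      if (tr$compartment == "fecal") {
        i <- match(m_id, rownames(fec$values))
        m_map <- list(center = fec$mu[i], scale = cf$met_log_sd)
        fec$values[i, ] <- 10^(m_map$center + m_map$scale * m_star)
      } else {
        i <- match(m_id, rownames(ser$values))
        m_map <- list(center = ser$mu[i], scale = cf$met_log_sd)
        ser$values[i, ] <- 10^(m_map$center + m_map$scale * m_star)
      }

      truth_triads[[k]] <- list(
        direction = tr$direction, compartment = tr$compartment,
        x_id = x_id, m_id = m_id, y_id = y_id,
        a = a, b = b, c_prime = c_prime, z_effect = d, x_shift = x_shift,
        x_map = x_map, m_map = m_map, y_map = y_map
      )
    }
    # restore exact library sizes: rescale the non-planted genus rows
    planted_g <- unique(unlist(lapply(truth_triads, function(t) {
      intersect(c(t$x_id, t$y_id), gnames)
    })))
    if (length(planted_g) > 0) {
      other <- setdiff(gnames, planted_g)
      for (j in seq_len(n)) {
        planted_sum <- sum(G[planted_g, j])
        if (planted_sum >= libs[j]) stop("planted genus abundance exceeds library size")
        target <- libs[j] - planted_sum
        cur <- sum(G[other, j])
        G[other, j] <- floor(G[other, j] * target / cur)
        shortfall <- target - sum(G[other, j])
        top <- other[order(G[other, j], decreasing = TRUE)[1L]]
        G[top, j] <- G[top, j] + shortfall
      }
    }
  }

  metadata <- data.frame(sample_id = sample_ids, group = as.character(group),
                         stringsAsFactors = FALSE)
  structure(
    list(
      hormones = feature_table(H, group, "hormone"),
      genera = feature_table(G, group, "counts"),
      fecal = feature_table(fec$values, group, "intensity"),
      serum = feature_table(ser$values, group, "intensity"),
      metadata = metadata,
      truth = list(
        hormones = diff_h, genera = diff_g,
        fecal = fec$diff_ids, serum = ser$diff_ids,
        triads = truth_triads
      ),
      config = cf
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d samples/group; %d genera, %d fecal + %d serum metabolites, %d hormones; %d planted triad(s)\n",
    x$config$n_per_group, nrow(x$genera$values), nrow(x$fecal$values),
    nrow(x$serum$values), nrow(x$hormones$values), length(x$truth$triads)))
  invisible(x)
}

#' Confusion counts of pipeline output against planted truth
#'
#' Compares reported differential feature sets (and, optionally, reported
#' mediation triads) with the study's planted ground truth.
#'
#' @param study A [generate_study()] result.
#' @param reported List with any of `hormones`, `genera`, `fecal`, `serum`
#'   (character id vectors) and `triads` (data.frame with `direction`,
#'   `x_id`, `m_id`, `y_id` of reported triads).
#' @return Data.frame with one row per screen: tp, fp, fn, sensitivity, fdr.
#' @export
truth_confusion <- function(study, reported) {
  stopifnot(inherits(study, "synthetic_study"))
  one <- function(name, truth_ids, rep_ids) {
    tp <- length(intersect(rep_ids, truth_ids))
    fp <- length(setdiff(rep_ids, truth_ids))
    fn <- length(setdiff(truth_ids, rep_ids))
    data.frame(
      screen = name, tp = tp, fp = fp, fn = fn,
      sensitivity = if (length(truth_ids) > 0) tp / length(truth_ids) else NA_real_,
      fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (nm in c("hormones", "genera", "fecal", "serum")) {
    if (!is.null(reported[[nm]])) {
      out[[nm]] <- one(nm, study$truth[[nm]], reported[[nm]])
    }
  }
  if (!is.null(reported$triads)) {
    truth_keys <- vapply(study$truth$triads, function(t) {
      paste(t$direction, t$x_id, t$m_id, t$y_id, sep = "|")
    }, character(1))
    rep_keys <- with(reported$triads, paste(direction, x_id, m_id, y_id, sep = "|"))
    out$triads <- one("triads", truth_keys, rep_keys)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
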