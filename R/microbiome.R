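#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads, the standard evening-out step before diversity analysis. Depth is
#' typically the minimum observed sample total.
#'
#' @param table A counts [feature_table()].
#' @param depth Target depth; every sample total must be >= `depth`.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return A counts `feature_table` whose columns each sum to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "feature_table"), table$kind == "counts")
  totals <- colSums(table$values)
  short <- totals < depth
  if (any(short)) {
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(table$sample_ids[short], collapse = ", "))
  }
  set.seed(as.integer(seed))
  # vegan::rrarefy works on samples-in-rows matrices; its "smallest count"
  # advisory (no singletons present) is irrelevant for subsampling itself
  rare <- withCallingHandlers(
    t(vegan::rrarefy(t(table$values), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  storage.mode(rare) <- "double"
  feature_table(rare, table$group, "counts")
}

#' Per-sample alpha diversity
#'
#' Computes, per sample: Shannon entropy (log base 2 by default, the QIIME-1
#' convention), observed richness, Simpson's diversity 1 - sum(p_i^2), and
#' the Chao1 richness estimator S + F1^2 / (2 F2) with the bias-corrected
#' form S + F1 (F1 - 1) / (2 (F2 + 1)) when there are no doubletons
#' (F1, F2 = singleton and doubleton counts).
#'
#' @param table A counts [feature_table()]; all-zero samples are an error.
#' @param shannon_base Logarithm base for Shannon entropy (default 2, bits).
#' @return A data.frame with columns `sample_id`, `group`, `shannon`,
#'   `chao1`, `observed`, `simpson`.
#' @export
alpha_diversity <- function(table, shannon_base = 2) {
  stopifnot(inherits(table, "feature_table"), table$kind == "counts")
  totals <- colSums(table$values)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(table$sample_ids[totals == 0], collapse = ", "))
  }
  res <- lapply(seq_along(table$sample_ids), function(j) {
    counts <- table$values[, j]
    p <- counts[counts > 0] / sum(counts)
    s <- length(p)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    chao1 <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
    data.frame(
      sample_id = table$sample_ids[j],
      group = as.character(table$group[j]),
      shannon = -sum(p * log(p, base = shannon_base)),
      chao1 = chao1,
      observed = s,
      simpson = 1 - sum(p^2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Cumulative-sum scaling (CSS) normalization
#'
#' Divides each sample by the cumulative sum of its counts up to a quantile
#' of its nonzero count distribution, then multiplies by a common scale. This
#' damps the influence of a few dominant taxa on library-size normalization.
#'
#' @param table A counts [feature_table()].
#' @param quantile Quantile of the per-sample nonzero counts (default 0.5;
#'   fixed rather than adaptively chosen for determinism at small n).
#' @param scale Common output scale (default 1000).
#' @return An intensity `feature_table` of normalized abundances.
#' @export
css_normalize <- function(table, quantile = 0.5, scale = 1000) {
  stopifnot(inherits(table, "feature_table"), table$kind == "counts",
            quantile > 0, quantile < 1)
  norm <- table$values
  for (j in seq_len(ncol(norm))) {
    counts <- table$values[, j]
    nz <- counts[counts > 0]
    if (length(nz) == 0L) stop("all-zero sample: ", table$sample_ids[j])
    q <- stats::quantile(nz, probs = quantile, names = FALSE)
    s_j <- sum(counts[counts <= q])
    if (s_j == 0) stop("zero CSS scaling factor for sample: ", table$sample_ids[j])
    norm[, j] <- counts / s_j * scale
  }
  feature_table(norm, table$group, "intensity")
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik) over samples, in
#' [0, 1]. Bray-Curtis is not a metric (the triangle inequality can fail);
#' a pair of all-zero samples has undefined dissimilarity and is set to 0
#' with a warning.
#'
#' @param table A [feature_table()] with non-negative values.
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$values < 0)) stop("Bray-Curtis requires non-negative values")
  d <- as.matrix(vegan::vegdist(t(table$values), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical scaling of a dissimilarity matrix: Gower double-centering
#' followed by eigendecomposition. Axes are ordered by eigenvalue; negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped and proportions explained are computed over the
#' positive eigenvalues.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @return An object of class `ordination_result`: `coordinates`
#'   (samples x axes), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, pos[pos <= ncol(fit$points)], drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig[pos],
      proportion_explained = eig[pos] / sum(eig[pos])
    ),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d axes; first axes explain %s\n",
              nrow(x$coordinates), length(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 2)),
                    collapse = ", ")))
  invisible(x)
}

#' LEfSe-style LDA effect-size screen for differential genera
#'
#' Identifies differentially abundant features between two groups by the
#' LEfSe recipe: per-sample total-sum scaling to one million, a
#' Kruskal-Wallis test per feature, then an effect size from bootstrapped
#' two-class linear discriminant analysis. Within each bootstrap round a
#' fraction of each group is subsampled, an LDA direction
#' w = S^-1 (mu1 - mu0) is computed with the pooled covariance shrunk
#' halfway toward its diagonal (necessary at n = 6/group, where the pooled
#' covariance is singular) and normalized to unit length, and the
#' per-feature effect is (|w_j (mu1_j - mu0_j)| + |mu1_j - mu0_j|) / 2 in
#' per-million units. The LDA score is log10(1 + mean effect over rounds).
#'
#' A feature passes iff its Kruskal-Wallis p < `alpha` AND its LDA score
#' exceeds `lda_threshold`.
#'
#' @param table A two-group [feature_table()] with >= 3 samples per group.
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param lda_threshold log10 effect-size threshold (default 3).
#' @param n_boot Bootstrap rounds (default 30).
#' @param boot_fraction Fraction of each group subsampled per round
#'   (default 2/3).
#' @param seed Integer seed for the bootstrap.
#' @return A data.frame with columns `feature_id`, `kw_p`, `lda_score`,
#'   `enriched_group`, `passed`.
#' @export
lda_effect_screen <- function(table, alpha = 0.05, lda_threshold = 3.0,
                              n_boot = 30, boot_fraction = 2 / 3, seed) {
  stopifnot(inherits(table, "feature_table"))
  g <- table$group
  if (nlevels(g) != 2L) stop("exactly 2 groups required")
  if (any(tabulate(g) < 3L)) stop("at least 3 samples per group required")

  # total-sum scaling to one million per sample
  tss <- sweep(table$values, 2, colSums(table$values), "/") * 1e6

  idx0 <- which(g == levels(g)[1L])
  idx1 <- which(g == levels(g)[2L])

  kw_p <- apply(tss, 1, function(v) {
    kruskal_wallis(list(v[idx0], v[idx1]))$p_value
  })

  n_sub0 <- max(2L, as.integer(round(boot_fraction * length(idx0))))
  n_sub1 <- max(2L, as.integer(round(boot_fraction * length(idx1))))

  set.seed(as.integer(seed))
  nfeat <- nrow(tss)
  effect_sum <- numeric(nfeat)
  for (b in seq_len(n_boot)) {
    s0 <- sample(idx0, n_sub0)
    s1 <- sample(idx1, n_sub1)
    m0 <- rowMeans(tss[, s0, drop = FALSE])
    m1 <- rowMeans(tss[, s1, drop = FALSE])
    x0 <- t(tss[, s0, drop = FALSE]) - rep(m0, each = n_sub0)
    x1 <- t(tss[, s1, drop = FALSE]) - rep(m1, each = n_sub1)
    sp <- (crossprod(x0) + crossprod(x1)) / (n_sub0 + n_sub1 - 2)
    # shrink halfway toward the diagonal; small ridge keeps it invertible
    sreg <- 0.5 * sp + 0.5 * diag(diag(sp), nfeat)
    diag(sreg) <- diag(sreg) + 1e-8 * max(diag(sreg), 1)
    w <- solve(sreg, m1 - m0)
    w <- w / sqrt(sum(w^2))
    effect_sum <- effect_sum + (abs(w * (m1 - m0)) + abs(m1 - m0)) / 2
  }
  lda_score <- log10(1 + effect_sum / n_boot)

  mean0 <- rowMeans(tss[, idx0, drop = FALSE])
  mean1 <- rowMeans(tss[, idx1, drop = FALSE])
  enriched <- ifelse(mean1 >= mean0, levels(g)[2L], levels(g)[1L])

  data.frame(
    feature_id = table$feature_ids,
    kw_p = unname(kw_p),
    lda_score = unname(lda_score),
    enriched_group = unname(enriched),
    passed = unname(kw_p < alpha & lda_score > lda_threshold),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
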