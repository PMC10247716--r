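test_that("rarefaction preserves depth, identity and hypergeometric expectation", {
  m <- matrix(c(9000, 1000, 0,
                3000, 2000, 500), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  tab <- make_table(m, group = c("control", "hypoxia"))

  r <- rarefy(tab, 1000, seed = 1)
  expect_equal(unname(colSums(r$values)), c(1000, 1000))
  # absent features stay absent
  expect_equal(r$values["g3", "s1"], 0)
  # a sample already at depth is unchanged
  m2 <- matrix(c(600, 400), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  tab2 <- feature_table(m2, "control", "counts")
  expect_equal(rarefy(tab2, 1000, seed = 9)$values, m2)
  # undersized sample errors with its name (s2 totals 5500)
  expect_error(rarefy(tab, 6000, seed = 1), "s2")

  # reproducibility
  expect_equal(rarefy(tab, 1000, seed = 5)$values, rarefy(tab, 1000, seed = 5)$values)

  # mean rarefied count follows the hypergeometric expectation 900
  one <- feature_table(matrix(c(9000, 1000), 2, dimnames = list(c("a", "b"), "s1")),
                       "control", "counts")
  draws <- vapply(1:500, function(i) rarefy(one, 1000, seed = i)$values["a", 1],
                  numeric(1))
  # SE of one draw: hypergeometric sd ~ sqrt(1000*.9*.1*(10000-1000)/9999)
  se_mean <- sqrt(1000 * 0.9 * 0.1 * 9000 / 9999) / sqrt(500)
  expect_lt(abs(mean(draws) - 900), 3 * se_mean)
})

test_that("alpha diversity matches closed forms and brute-force evaluation", {
  tab <- make_table(cbind(s1 = c(4, 4, 4, 4), s2 = c(8, 0, 0, 0), s3 = c(1, 1, 2, 5)),
                    group = c("control", "control", "hypoxia"))
  a <- alpha_diversity(tab)
  expect_equal(a$shannon[1], 2.0)
  expect_equal(a$simpson[1], 0.75)
  expect_equal(a$observed[1], 4)
  expect_equal(a$chao1[1], 4)          # no singletons
  expect_equal(a$shannon[2], 0)
  expect_equal(a$simpson[2], 0)
  expect_equal(a$chao1[3], 4 + 2^2 / (2 * 1))  # F1 = 2, F2 = 1

  expect_error(alpha_diversity(make_table(cbind(s1 = c(0, 0)))), "all-zero")

  # exhaustive small-instance oracle: every count vector of length <= 5 with
  # total <= 12, checked against direct formula evaluation (vegan supplies
  # the entropy/Simpson reference)
  vecs <- list()
  for (len in 1:5) {
    grid <- as.matrix(expand.grid(rep(list(0:12), len)))
    grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 12, , drop = FALSE]
    vecs <- c(vecs, lapply(seq_len(nrow(grid)), function(i) grid[i, ]))
  }
  mat <- vapply(vecs, function(v) c(v, rep(0, 5 - length(v))), numeric(5))
  dimnames(mat) <- list(paste0("f", 1:5), paste0("v", seq_len(ncol(mat))))
  res <- alpha_diversity(make_table(mat, group = rep("g1", ncol(mat))))
  ref_shannon <- vegan::diversity(t(mat), index = "shannon", base = 2)
  ref_simpson <- vegan::diversity(t(mat), index = "simpson")
  expect_equal(res$shannon, unname(ref_shannon), tolerance = 1e-10)
  expect_equal(res$simpson, unname(ref_simpson), tolerance = 1e-10)
  ref_chao <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]; s <- sum(v > 0); f1 <- sum(v == 1); f2 <- sum(v == 2)
    if (f2 > 0) s + f1 * f1 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
  }, numeric(1))
  expect_equal(res$chao1, ref_chao, tolerance = 1e-10)
  expect_true(all(res$observed <= res$chao1))
})

test_that("CSS normalization matches a hand-computed oracle and is scale invariant", {
  # sample s1: nonzero counts (2, 10, 40); median 10; s = 2 + 10 = 12
  # sample s2: nonzero counts (5, 5, 30); median 5; s = 5 + 5 = 10
  m <- cbind(s1 = c(2, 10, 40, 0), s2 = c(5, 5, 30, 0))
  rownames(m) <- paste0("g", 1:4)
  tab <- make_table(m, group = c("control", "hypoxia"))
  out <- css_normalize(tab, quantile = 0.5, scale = 1000)
  expect_equal(unname(out$values[, "s1"]), c(2, 10, 40, 0) / 12 * 1000)
  expect_equal(unname(out$values[, "s2"]), c(5, 5, 30, 0) / 10 * 1000)

  # identical samples normalize identically
  twin <- make_table(cbind(s1 = c(3, 6, 9), s2 = c(3, 6, 9)),
                     group = c("control", "hypoxia"))
  norm_twin <- css_normalize(twin)
  expect_equal(norm_twin$values[, 1], norm_twin$values[, 2])

  # multiplying one sample by k leaves its normalized column unchanged
  m_scaled <- m
  m_scaled[, "s2"] <- 7 * m[, "s2"]
  scaled <- make_table(m_scaled, group = c("control", "hypoxia"))
  expect_equal(css_normalize(scaled)$values[, "s2"], out$values[, "s2"])
})

test_that("Bray-Curtis follows the direct formula and stays in [0, 1]", {
  tab <- make_table(cbind(s1 = c(2, 1), s2 = c(1, 3), s3 = c(2, 1), s4 = c(0, 5)),
                    group = c("control", "control", "hypoxia", "hypoxia"))
  d <- bray_curtis(tab)
  expect_equal(d["s1", "s2"], 3 / 7, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))

  # disjoint supports
  dis <- make_table(cbind(s1 = c(4, 0), s2 = c(0, 9)), group = c("control", "hypoxia"))
  expect_equal(bray_curtis(dis)["s1", "s2"], 1)
})

test_that("PCoA recovers geometry from distances", {
  # two samples at d = 0.6: coordinates +/- 0.3 on one axis
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d2)
  expect_equal(unname(sort(abs(ord$coordinates[, 1]))), c(0.3, 0.3),
               tolerance = 1e-10)

  # three equidistant samples: first two eigenvalues equal
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa(d3)
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-10)

  # Euclidean distances from known 2-D points are reconstructed exactly
  set.seed(2)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  ordr <- pcoa(d)
  rec <- as.matrix(dist(ordr$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_true(all(diff(ordr$eigenvalues) <= 1e-10))
  expect_lte(sum(ordr$proportion_explained), 1 + 1e-12)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("LDA effect screen flags a planted genus and ignores flat features", {
  set.seed(10)
  n <- 12
  group <- rep(c("control", "hypoxia"), each = 6)
  # 30 null log-normal genera + one strongly shifted one
  base <- matrix(rlnorm(30 * n, meanlog = 5, sdlog = 0.3), nrow = 30)
  planted <- ifelse(group == "hypoxia", 2e5, 2e3) * rnorm(n, 1, 0.05)
  m <- rbind(base, planted = planted)
  rownames(m) <- c(paste0("g", 1:30), "planted")
  colnames(m) <- paste0("s", 1:n)
  tab <- feature_table(m, group, "intensity")

  res <- lda_effect_screen(tab, seed = 99)
  planted_row <- res[res$feature_id == "planted", ]
  expect_true(planted_row$passed)
  expect_gt(planted_row$lda_score, 3)
  expect_equal(planted_row$enriched_group, "hypoxia")

  # a feature constant on the screen's relative-abundance scale never passes
  # (columns with equal totals keep it constant through total-sum scaling)
  filler <- runif(n, 100, 900)
  m_const <- rbind(flat = rep(500, n), f2 = filler, f3 = 10000 - 500 - filler)
  colnames(m_const) <- paste0("s", 1:n)
  tab_const <- feature_table(m_const, group, "intensity")
  res_const <- lda_effect_screen(tab_const, seed = 99)
  flat_row <- res_const[res_const$feature_id == "flat", ]
  expect_false(flat_row$passed)
  expect_equal(flat_row$kw_p, 1)

  # invariant under sample relabeling (same seed, permuted columns)
  perm <- sample(n)
  tab_perm <- feature_table(m[, perm], group[perm], "intensity")
  res_perm <- lda_effect_screen(tab_perm, seed = 99)
  expect_equal(res_perm$kw_p, res$kw_p)
  expect_equal(res_perm$passed, res$passed)
})

test_that("LDA effect screen false-positive rate is near nominal on null features", {
  set.seed(123)
  n <- 12
  group <- rep(c("control", "hypoxia"), each = 6)
  m <- matrix(rlnorm(200 * n, meanlog = rep(runif(200, 3, 8), n), sdlog = 0.4),
              nrow = 200, dimnames = list(paste0("g", 1:200), paste0("s", 1:n)))
  tab <- feature_table(m, group, "intensity")
  res <- lda_effect_screen(tab, seed = 77)
  expect_lte(mean(res$passed), 0.05 + 0.03)
})
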