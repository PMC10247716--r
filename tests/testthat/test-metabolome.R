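test_that("missingness filter drops features strictly above the 60% zero rule", {
  n <- 12
  # 10 features with hand-enumerated zero patterns: feature i has i zeros
  # in 12 samples for i = 0..9; 60% of 12 = 7.2, so 0..7 zeros survive
  m <- t(vapply(0:9, function(z) c(rep(0, z), rep(100, n - z)), numeric(n)))
  dimnames(m) <- list(paste0("met", 0:9), paste0("s", 1:n))
  tab <- make_table(m, kind = "intensity")
  out <- missingness_filter(tab)
  expect_equal(out$feature_ids, paste0("met", 0:7))
  expect_equal(attr(out, "n_dropped"), 2)

  # boundary cases: 7/12 = 58.3% kept, 8/12 = 66.7% dropped
  expect_true("met7" %in% out$feature_ids)
  expect_false("met8" %in% out$feature_ids)
  # a zero-tolerance filter on features that all contain zeros removes everything
  all_zeroed <- subset_features(tab, paste0("met", 1:9))
  expect_warning(missingness_filter(all_zeroed, max_missing_frac = 0), "every feature")
})

test_that("feature scaling matches its formulas, including Pareto and zero variance", {
  x <- cbind(a = c(1, 2, 3, 6), b = c(5, 5, 5, 5), c = c(0, 10, 20, 30))
  uv <- scale_features(x, "unit_variance")
  expect_equal(unname(apply(uv$x, 2, sd)[c("a", "c")]), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(uv$x[, "b"]), rep(0, 4))  # constant column centered only
  expect_true(uv$zero_variance[["b"]])

  par <- scale_features(x, "pareto")
  expect_equal(unname(par$x[, "a"]), (x[, "a"] - 3) / sqrt(sd(x[, "a"])),
               tolerance = 1e-12)
  none <- scale_features(x, "none")
  expect_equal(unname(none$x[, "a"]), x[, "a"] - 3)
})

test_that("OPLS-DA fits the noiseless case and keeps scores orthogonal", {
  set.seed(21)
  n <- 12
  y <- rep(c(-1, 1), each = 6)
  # noiseless limit: y exactly linear in feature 1, all other features flat
  x0 <- cbind(y, matrix(5, n, 7))
  colnames(x0) <- paste0("f", 1:8)
  fit0 <- opls_fit(x0, y, n_ortho = 0, seed = 3)
  expect_equal(fit0$r2y, 1, tolerance = 1e-10)
  expect_equal(unname(abs(fit0$w[1])), 1, tolerance = 1e-10)

  # realistic fit: predictive scores orthogonal to orthogonal score columns
  x <- cbind(y + rnorm(n, sd = 0.3), matrix(rnorm(n * 7), n, 7))
  colnames(x) <- paste0("f", 1:8)
  fit <- opls_fit(x, y, n_ortho = 2, seed = 3)
  expect_lt(max(abs(crossprod(fit$t, fit$T_o))), 1e-8)
  expect_equal(fit$n_ortho, 2)

  # determinism
  fit2 <- opls_fit(x, y, n_ortho = 2, seed = 3)
  expect_identical(fit$q2, fit2$q2)
  expect_identical(fit$w, fit2$w)

  expect_error(opls_fit(x, rep(1, n)), "variance")
  expect_error(opls_fit(x, y, n_ortho = 50), "rank")
})

test_that("n_ortho = 0 reproduces single-component NIPALS PLS1", {
  set.seed(31)
  x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- c(-1, -1, -1, 1, 1, 1)
  fit <- opls_fit(x, y, n_ortho = 0, seed = 1)
  sc <- scale_features(x, "unit_variance")
  ref <- nipals_pls1(sc$x, y - mean(y))
  expect_lt(max(abs(abs(fit$w) - abs(ref$w))), 1e-8)
  expect_lt(max(abs(fit$t * fit$q - ref$t * ref$q)), 1e-8)
})

test_that("VIP squares sum to the feature count and follow the weights", {
  set.seed(41)
  for (i in 1:5) {
    x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(-1, 1), each = 3)
    fit <- opls_fit(x, y, n_ortho = 1, seed = i)
    v <- vip(fit)
    expect_equal(sum(v^2), 8, tolerance = 1e-8)
    expect_true(all(v >= 0))
  }
  # equal |w| across features gives VIP = 1 everywhere; zero weight gives 0
  fit <- list(w = c(0.5, -0.5, 0.5, -0.5), feature_ids = letters[1:4])
  class(fit) <- "opls_model"
  expect_equal(unname(vip(fit)), rep(1, 4))
  fit$w <- c(1, 0, 0, 0)
  expect_equal(unname(vip(fit))[2], 0)
})

test_that("Hotelling T2 control limit matches the F closed form", {
  set.seed(51)
  x <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(-1, 1), each = 6)
  fit <- opls_fit(x, y, n_ortho = 1, seed = 2)  # A = 2 score columns, N = 12
  h <- hotelling_t2_limit(fit, alpha = 0.05)
  expect_equal(h$t2_crit, 2 * 143 / 120 * qf(0.95, 2, 10), tolerance = 1e-10)
  expect_equal(h$t2_crit, 9.78, tolerance = 1e-2)
  expect_true(all(h$t2 >= 0))
  # alpha -> 1 sends the limit to 0
  expect_lt(hotelling_t2_limit(fit, alpha = 0.9999)$t2_crit, 1e-2)
})

test_that("Q2 under permuted labels is non-positive in median (overfit guard)", {
  set.seed(61)
  n <- 12
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  q2s <- vapply(1:50, function(i) {
    y <- sample(rep(c(-1, 1), each = 6))
    opls_fit(x, y, n_ortho = 1, seed = i)$q2
  }, numeric(1))
  expect_lte(median(q2s), 0)
})

test_that("differential selection applies strict VIP and p cutoffs", {
  vips <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    vip = c(1.0, 1.5, 2.0, 0.8),
    t_p = c(0.01, 0.04, 0.05, 0.001),
    direction = c("up", "down", "up", "down"),
    stringsAsFactors = FALSE
  )
  sel <- select_differential(vips)
  expect_equal(sel$feature_id, "b")  # boundary VIP = 1 and p = 0.05 excluded
})

test_that("metabolite screen recovers strongly shifted features", {
  set.seed(71)
  n <- 12
  group <- rep(c("control", "hypoxia"), each = 6)
  nfeat <- 100
  mu <- runif(nfeat, 4, 6)
  m <- matrix(10^rnorm(nfeat * n, rep(mu, n), 0.25), nrow = nfeat)
  # plant 5 ten-fold shifted metabolites (1 in log10, 4 sd: >= 3 SD shift)
  for (i in 1:5) m[i, group == "hypoxia"] <- m[i, group == "hypoxia"] * 10
  dimnames(m) <- list(paste0("met", 1:nfeat), paste0("s", 1:n))
  tab <- feature_table(m, group, "intensity")

  scr <- screen_metabolites(tab, seed = 8)
  sel <- select_differential(scr$vips)
  expect_true(all(paste0("met", 1:5) %in% sel$feature_id))
  expect_true(all(sel$direction[match(paste0("met", 1:5), sel$feature_id)] == "up"))
  # selection rate among the 95 null features stays near nominal
  null_sel <- setdiff(sel$feature_id, paste0("met", 1:5))
  expect_lte(length(null_sel) / 95, 0.05 + 2 * sqrt(0.05 * 0.95 / 95))
})

test_that("pathway enrichment delegates to the hypergeometric test", {
  bg <- paste0("m", 1:10)
  ann <- list(pw_hit = c("m1", "m2", "m3"), pw_miss = c("m9", "m10"),
              pw_dup = c("m1", "m2", "m3"))
  sel <- c("m1", "m2", "m3", "m4")
  res <- pathway_enrichment(sel, ann, bg)
  expect_equal(nrow(res), 3)
  expect_true(all(diff(res$p) >= 0))  # sorted by p
  # identical membership gives identical p
  expect_equal(res$p[res$pathway == "pw_hit"], res$p[res$pathway == "pw_dup"])
  # disjoint pathway: p = 1
  expect_equal(res$p[res$pathway == "pw_miss"], 1)
  # brute-force check of the top pathway on the 10-id background
  combos <- combn(10, 4)
  overlaps <- apply(combos, 2, function(idx) sum(bg[idx] %in% ann$pw_hit))
  expect_equal(res$p[res$pathway == "pw_hit"], mean(overlaps >= 3), tolerance = 1e-12)

  expect_equal(nrow(pathway_enrichment(sel, list(), bg)), 0)
})
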