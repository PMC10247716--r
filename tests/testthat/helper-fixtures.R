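# Small in-code fixtures shared across test files.

# A feature table from a plain matrix; groups split front/back half.
make_table <- function(values, kind = "counts", group = NULL) {
  if (is.null(group)) {
    group <- rep(c("control", "hypoxia"), each = ceiling(ncol(values) / 2))[
      seq_len(ncol(values))]
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  feature_table(values, group, kind)
}

# Independent normal-equations OLS oracle: coefficients, SEs, p-values.
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- beta / se
  list(beta = unname(drop(beta)), se = unname(se),
       p = unname(drop(2 * stats::pt(abs(tval), df, lower.tail = FALSE))))
}

# Independent single-component PLS1 NIPALS oracle on a preprocessed matrix.
nipals_pls1 <- function(xs, yc) {
  w <- drop(crossprod(xs, yc))
  w <- w / sqrt(sum(w^2))
  t_score <- drop(xs %*% w)
  q <- sum(yc * t_score) / sum(t_score^2)
  list(w = w, t = t_score, q = q)
}
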