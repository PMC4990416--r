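two_group_q <- function(vals_a, vals_b, gene = "g1") {
  q <- matrix(c(vals_a, vals_b), 1,
              dimnames = list(gene, paste0("s", seq_len(length(vals_a) +
                                                          length(vals_b)))))
  list(q = q, groups = setNames(rep(c("a", "b"),
                                    c(length(vals_a), length(vals_b))),
                                colnames(q)))
}

test_that("cell means and pooled variance come out in closed form", {
  d <- two_group_q(c(0, 0, 0), c(1, 1, 1))
  fit <- fit_group_model(d$q, d$groups)
  expect_equal(unname(fit$means["g1", ]), c(0, 1))
  expect_equal(unname(fit$sigma2["g1"]), 0)
  expect_equal(unname(fit$df["g1"]), 4L)
})

test_that("balanced two-group contrasts equal the pooled-t oracle", {
  set.seed(60)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(6, 1)
    d <- two_group_q(a, b)
    fit <- fit_group_model(d$q, d$groups)
    ct <- pairwise_contrasts(fit)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(ct$p_raw, tt$p.value, tolerance = 1e-9)
    expect_equal(ct$delta_log2, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-9)
    expect_equal(ct$df, 10)
  }
})

test_that("the closed-form fit matches gls with per-gene variances", {
  skip_if_not_installed("nlme")
  set.seed(61)
  q <- rbind(g1 = rnorm(12, sd = 0.3), g2 = rnorm(12, sd = 1.2))
  colnames(q) <- paste0("s", 1:12)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), colnames(q))
  fit <- fit_group_model(q, groups)
  long <- data.frame(y = as.numeric(t(q)),
                     gene = rep(rownames(q), each = 12),
                     grp = rep(groups, 2))
  gfit <- nlme::gls(y ~ 0 + gene:grp, data = long,
                    weights = nlme::varIdent(form = ~ 1 | gene))
  cf <- coef(gfit)
  for (g in rownames(q)) for (lv in c("a", "b", "c"))
    expect_equal(unname(fit$means[g, lv]),
                 unname(cf[paste0("gene", g, ":grp", lv)]),
                 tolerance = 1e-6)
})

test_that("location shifts change means but no test statistic", {
  set.seed(62)
  q <- rbind(g1 = rnorm(12), g2 = rnorm(12))
  colnames(q) <- paste0("s", 1:12)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), colnames(q))
  f0 <- fit_group_model(q, groups)
  q2 <- q; q2["g1", ] <- q2["g1", ] + 7
  f1 <- fit_group_model(q2, groups)
  c0 <- pairwise_contrasts(f0); c1 <- pairwise_contrasts(f1)
  expect_equal(f1$sigma2, f0$sigma2, tolerance = 1e-12)
  expect_equal(c1$delta_log2, c0$delta_log2, tolerance = 1e-12)
  expect_equal(c1$p_raw, c0$p_raw, tolerance = 1e-12)
})

test_that("Bonferroni adjustment and significance tiers are as defined", {
  set.seed(63)
  q <- rbind(g1 = rnorm(16), g2 = rnorm(16), g3 = rnorm(16))
  colnames(q) <- paste0("s", 1:16)
  groups <- setNames(rep(c("a", "b", "c", "d"), each = 4), colnames(q))
  ct <- pairwise_contrasts(fit_group_model(q, groups))
  m <- attr(ct, "family_size")
  expect_equal(m, 3 * 6)
  expect_equal(ct$p_bonferroni, pmin(1, m * ct$p_raw))
  expect_true(all(ct$stars[ct$p_bonferroni >= 0.05] == ""))
  # an exactly null contrast gives p = 1
  d <- two_group_q(c(1, 2, 3), c(3, 2, 1))
  cd <- pairwise_contrasts(fit_group_model(d$q, d$groups))
  expect_equal(cd$p_raw, 1)
  expect_equal(cd$p_bonferroni, 1)
})

test_that("family-wise error under a simulated null stays below 0.05", {
  set.seed(64)
  nrep <- 200
  fw <- 0
  groups <- setNames(rep(c("a", "b", "c", "d"), each = 4),
                     paste0("s", 1:16))
  for (rep in seq_len(nrep)) {
    q <- matrix(rnorm(6 * 16, sd = rep(seq(0.2, 1.2, length.out = 6), 16)),
                6, 16, dimnames = list(paste0("g", 1:6), names(groups)))
    ct <- pairwise_contrasts(fit_group_model(q, groups))
    if (any(ct$p_bonferroni < 0.05)) fw <- fw + 1
  }
  # binomial 95% upper band around 0.05 with 200 reps
  expect_lte(fw / nrep, 0.05 + 1.96 * sqrt(0.05 * 0.95 / nrep))
})

test_that("relative expression reports folds with exponentiated CIs", {
  set.seed(65)
  q <- rbind(g1 = c(rnorm(4, 0, 0.1), rnorm(4, 1, 0.1), rnorm(4, 1.807, 0.1)))
  colnames(q) <- paste0("s", 1:12)
  groups <- setNames(rep(c("base", "mid", "high"), each = 4), colnames(q))
  fit <- fit_group_model(q, groups)
  rel <- relative_expression(fit, "base")
  base_row <- rel[rel$group == "base", ]
  expect_equal(base_row$fold, 1)
  expect_equal(base_row$fold_ci_lo, 1)
  high <- rel[rel$group == "high", ]
  expect_equal(high$fold, 2^high$delta_log2)
  # a 1.807 log2 difference is about 3.5-fold
  expect_equal(high$fold, 3.5, tolerance = 0.15)
  expect_equal(2^1.807, 3.5, tolerance = 0.01)
  mid <- rel[rel$group == "mid", ]
  expect_equal(mid$fold, 2, tolerance = 0.15)
  expect_error(relative_expression(fit, "nope"),
               class = "refsel_validation_error")
})

test_that("singleton-only genes are rejected, single cells allowed", {
  q <- matrix(1:3, 1, dimnames = list("g1", paste0("s", 1:3)))
  groups <- setNames(c("a", "b", "c"), colnames(q))
  expect_error(fit_group_model(q, groups), class = "refsel_validation_error")
  q2 <- matrix(c(1, 2, 3), 1, dimnames = list("g1", paste0("s", 1:3)))
  g2 <- setNames(c("a", "a", "b"), colnames(q2))
  fit <- fit_group_model(q2, g2)
  expect_equal(unname(fit$df["g1"]), 1L)
})
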