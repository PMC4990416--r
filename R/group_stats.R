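# Gene-specific-variance group model, pairwise contrasts with Bonferroni
# correction, and fold-change estimates with confidence intervals.
#
# The model has a mean per gene x group cell and one residual variance
# per gene, constant across groups (the structure selected for both
# experimental designs). It is fitted in closed form: cell means, and a
# per-gene variance pooled across that gene's groups with
# df_i = sum_g (n_g - 1). All computation is on the log2 scale; log
# differences are converted to ratios only at reporting time.

#' Fit the gene-specific-variance group model
#'
#' @param normq a [logq_matrix()] of (normalized) log2 quantities.
#' @param groups sample annotation (see [normfinder()]); `NULL` puts all
#'   samples in one group.
#' @return object of class `group_model`: list with `means` (genes x
#'   groups cell means), `sigma2` (per-gene pooled residual variance),
#'   `df` (per-gene residual degrees of freedom, `sum_g (n_g - 1)`),
#'   `n_g` (group sizes), `groups`.
#' @export
fit_group_model <- function(normq, groups = NULL) {
  q <- as.matrix(normq)
  g <- resolve_groups(q, groups)
  n_g <- table(g)
  G <- nlevels(g)
  means <- matrix(NA_real_, nrow(q), G,
                  dimnames = list(rownames(q), levels(g)))
  sigma2 <- setNames(numeric(nrow(q)), rownames(q))
  df <- setNames(integer(nrow(q)), rownames(q))
  for (i in seq_len(nrow(q))) {
    ss <- 0; dfi <- 0L
    for (gi in seq_len(G)) {
      v <- q[i, g == levels(g)[gi]]
      v <- v[!is.na(v)]
      if (length(v) == 0)
        rs_stop(sprintf("gene '%s' has no observations in group '%s'",
                        rownames(q)[i], levels(g)[gi]),
                "refsel_validation_error")
      means[i, gi] <- mean(v)
      ss <- ss + sum((v - mean(v))^2)
      dfi <- dfi + length(v) - 1L
    }
    if (dfi < 1)
      rs_stop(sprintf("gene '%s' has no residual degrees of freedom (all cells singleton)",
                      rownames(q)[i]), "refsel_validation_error")
    sigma2[i] <- ss / dfi
    df[i] <- dfi
  }
  structure(list(means = means, sigma2 = sigma2, df = df, n_g = n_g,
                 groups = g),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("group_model: %d genes x %d groups (n = %s)\n",
              nrow(x$means), ncol(x$means),
              paste(as.numeric(x$n_g), collapse = ", ")))
  invisible(x)
}

#' Significance tier symbols at adjusted 0.05 / 0.01 / 0.001
#' @noRd
stars_of <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise group contrasts with Bonferroni correction
#'
#' For each gene and group pair, the estimate is the difference of cell
#' means; its standard error uses the gene's pooled variance,
#' `se = sigma_i * sqrt(1/n_g + 1/n_g')`, tested two-sided against
#' Student's t on the gene's residual df. The Bonferroni family is every
#' test in the invocation (`m = genes x pairs`): adjusted p is
#' `min(1, m * p_raw)`. Fold changes and their confidence intervals are
#' obtained by exponentiating the log2 estimate and its CI bounds only
#' after all calculations are complete.
#'
#' @param fit a [fit_group_model()] result.
#' @param pairs `"all"` or a list of length-2 character vectors of group
#'   names.
#' @param conf_level confidence level for the fold CI (default 0.95).
#' @return data frame with one row per gene x pair: `gene`, `group_a`,
#'   `group_b`, `delta_log2` (a minus b), `se`, `df`, `t`, `p_raw`,
#'   `p_bonferroni`, `stars`, `fold`, `fold_ci_lo`, `fold_ci_hi`;
#'   attribute `family_size` = m.
#' @export
pairwise_contrasts <- function(fit, pairs = "all", conf_level = 0.95) {
  stopifnot(inherits(fit, "group_model"))
  lev <- colnames(fit$means)
  if (identical(pairs, "all")) {
    pairs <- combn(lev, 2, simplify = FALSE)
  } else {
    for (p in pairs)
      if (!all(p %in% lev))
        rs_stop(paste0("unknown group in pair: ", paste(p, collapse = "/")),
                "refsel_validation_error")
  }
  genes <- rownames(fit$means)
  m <- length(genes) * length(pairs)
  rows <- vector("list", m)
  r <- 0L
  for (i in seq_along(genes)) {
    gene <- genes[i]
    for (p in pairs) {
      a <- p[1]; b <- p[2]
      delta <- fit$means[gene, a] - fit$means[gene, b]
      se <- sqrt(fit$sigma2[gene] *
                   (1 / fit$n_g[[a]] + 1 / fit$n_g[[b]]))
      df <- fit$df[gene]
      tstat <- if (se == 0) ifelse(delta == 0, 0, sign(delta) * Inf) else
        delta / se
      p_raw <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
      tq <- qt(1 - (1 - conf_level) / 2, df = df)
      r <- r + 1L
      rows[[r]] <- data.frame(
        gene = gene, group_a = a, group_b = b,
        delta_log2 = delta, se = se, df = df, t = tstat, p_raw = p_raw,
        stringsAsFactors = FALSE,
        fold = 2^delta,
        fold_ci_lo = 2^(delta - tq * se),
        fold_ci_hi = 2^(delta + tq * se))
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$stars <- stars_of(out$p_bonferroni)
  out <- out[, c("gene", "group_a", "group_b", "delta_log2", "se", "df",
                 "t", "p_raw", "p_bonferroni", "stars", "fold",
                 "fold_ci_lo", "fold_ci_hi")]
  attr(out, "family_size") <- m
  out
}

#' Expression relative to a baseline group, with confidence intervals
#'
#' Per gene, the log2 difference of each group's cell mean from the
#' baseline group's, reported as a fold change `2^delta` with a
#' t-interval on the log2 scale exponentiated at the end. The baseline's
#' own entry is 1 with a degenerate CI by convention.
#'
#' @param fit a [fit_group_model()] result.
#' @param baseline_group name of the baseline group.
#' @param conf_level confidence level (default 0.95).
#' @return data frame: `gene`, `group`, `delta_log2`, `se`, `fold`,
#'   `fold_ci_lo`, `fold_ci_hi`.
#' @export
relative_expression <- function(fit, baseline_group, conf_level = 0.95) {
  stopifnot(inherits(fit, "group_model"))
  lev <- colnames(fit$means)
  if (!baseline_group %in% lev)
    rs_stop(paste0("unknown baseline group: ", baseline_group),
            "refsel_validation_error")
  rows <- list()
  for (gene in rownames(fit$means)) {
    for (g in lev) {
      if (g == baseline_group) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, group = g, delta_log2 = 0, se = 0, fold = 1,
          fold_ci_lo = 1, fold_ci_hi = 1, stringsAsFactors = FALSE)
        next
      }
      delta <- fit$means[gene, g] - fit$means[gene, baseline_group]
      se <- sqrt(fit$sigma2[gene] *
                   (1 / fit$n_g[[g]] + 1 / fit$n_g[[baseline_group]]))
      tq <- qt(1 - (1 - conf_level) / 2, df = fit$df[gene])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = g, delta_log2 = delta, se = se,
        fold = 2^delta, fold_ci_lo = 2^(delta - tq * se),
        fold_ci_hi = 2^(delta + tq * se), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
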