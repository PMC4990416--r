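# NormFinder: model-based stability for single genes and combinations,
# greedy (NormqPCR-style) stepwise selection, and the nested-loop
# all-combinations selection.
#
# Model, for gene i, group g, sample j (log2 scale):
#   q_igj = alpha_i + b_gj + d_ig + eps_igj,   Var(eps_igj) = sigma2_ig
# where b_gj is a per-sample loading effect common to all genes and d_ig
# the gene's systematic inter-group deviation (sum_i d_ig assumed ~ 0).
# Centering each sample on its across-gene mean removes alpha and b; the
# centered within-group variances are corrected for the correlation the
# centering induces, the d estimates are shrunk towards 0 with an
# empirical-Bayes factor, and the stability of gene i is
#   rho_i = mean_g( |d~_ig| + sqrt(sigma2_ig / n_g) ),
# balancing systematic inter-group deviation against intra-group noise.

#' Resolve a groups argument into a factor aligned to matrix columns
#' @noRd
resolve_groups <- function(q, groups) {
  samples <- colnames(q)
  if (is.null(groups)) {
    return(factor(rep("all", length(samples))))
  }
  if (is.data.frame(groups)) {
    if (!all(c("sample", "group") %in% names(groups)))
      rs_stop("annotation must have 'sample' and 'group' columns",
              "refsel_validation_error")
    groups <- validate_annotation(groups)
    miss <- setdiff(samples, groups$sample)
    if (length(miss) > 0)
      rs_stop(paste0("samples without annotation: ",
                     paste(head(miss, 5), collapse = ", ")),
              "refsel_validation_error")
    g <- groups$group[match(samples, groups$sample)]
  } else {
    if (is.null(names(groups))) {
      if (length(groups) != length(samples))
        rs_stop("unnamed groups vector must match the number of samples",
                "refsel_validation_error")
      g <- as.character(groups)
    } else {
      miss <- setdiff(samples, names(groups))
      if (length(miss) > 0)
        rs_stop(paste0("samples without annotation: ",
                       paste(head(miss, 5), collapse = ", ")),
                "refsel_validation_error")
      g <- as.character(groups[samples])
    }
  }
  factor(g, levels = unique(g))
}

#' NormFinder single-gene stability model
#'
#' Fits the inter/intra-group variance model and returns each candidate's
#' stability `rho` (lower = more stable). The fit proceeds by (1)
#' centering every sample on its across-gene mean, which removes sample
#' loading; (2) estimating each gene's inter-group deviation `d_ig` as
#' the group mean of the centered values minus the gene's overall mean
#' (weighted by group size); (3) estimating intra-group variances
#' `sigma2_ig` from the centered within-group variances with a moment
#' correction for the across-gene correlation the centering induces,
#' truncated at 0; (4) shrinking `d` with the empirical-Bayes factor
#' `gamma2 / (gamma2 + sigma2_ig/n_g)`, where `gamma2` is the variance of
#' the `d` estimates across genes and groups minus their mean sampling
#' variance (truncated at 0); and (5) averaging, over groups,
#' `|d~_ig| + sqrt(sigma2_ig/n_g)`.
#'
#' With a single group (`groups = NULL`) all `d` are 0 and `rho` reduces
#' to a purely intra-group variability measure.
#'
#' @param q a [logq_matrix()] or genes x samples matrix, >= 3 genes
#'   (sample centering needs several genes), no missing values.
#' @param groups sample annotation: a data frame with `sample`/`group`
#'   columns, a named character vector, or `NULL` for a single group.
#'   Every group needs >= 2 samples.
#' @return object of class `normfinder_fit`: list with `rho` (named, in
#'   row order), `ranking` (ascending rho, ties lexicographic), `d_hat`,
#'   `d_tilde`, `sigma2` (genes x groups matrices), `gamma2`, `n_g`,
#'   `groups` (factor aligned to samples), `genes`.
#' @examples
#' q <- logq_matrix(matrix(rnorm(60), 5, 12,
#'   dimnames = list(paste0("g", 1:5), paste0("s", 1:12))))
#' normfinder(q, groups = rep(c("a", "b"), each = 6))
#' @export
normfinder <- function(q, groups = NULL) {
  q <- as.matrix(q)
  k <- nrow(q)
  if (k < 3)
    rs_stop("NormFinder needs >= 3 genes", "refsel_validation_error")
  if (anyNA(q))
    rs_stop("NormFinder requires a complete matrix", "refsel_missing_error")
  g <- resolve_groups(q, groups)
  n_g <- table(g)
  if (any(n_g < 2))
    rs_stop(paste0("every group needs >= 2 samples; offending group(s): ",
                   paste(names(n_g)[n_g < 2], collapse = ", ")),
            "refsel_validation_error")
  G <- nlevels(g)
  N <- ncol(q)
  # (1) remove per-sample loading
  z <- sweep(q, 2, colMeans(q))
  # group means of centered values
  zbar <- t(apply(z, 1, function(r) tapply(r, g, mean)))
  if (G == 1) zbar <- matrix(rowMeans(z), ncol = 1,
                             dimnames = list(rownames(q), levels(g)))
  # (2) d_hat: deviation from the n_g-weighted overall gene mean
  w <- as.numeric(n_g) / N
  overall <- as.numeric(zbar %*% w)
  d_hat <- zbar - overall
  # (3) centered within-group variances, corrected for centering:
  #   E[v_ig] = sigma2_ig (1 - 2/k) + S_g / k^2, with S_g = sum_i sigma2_ig,
  # so S_g = (k/(k-1)) sum_i v_ig and
  #   sigma2_ig = (v_ig - S_g/k^2) * k/(k-2), truncated at 0.
  v <- matrix(NA_real_, k, G, dimnames = dimnames(zbar))
  for (gi in seq_len(G)) {
    zg <- z[, g == levels(g)[gi], drop = FALSE]
    v[, gi] <- apply(zg, 1, var)
  }
  S_g <- colSums(v) * k / (k - 1)
  sigma2 <- sweep(v, 2, S_g / k^2) * k / (k - 2)
  sigma2[sigma2 < 0] <- 0
  samp_var <- sweep(sigma2, 2, as.numeric(n_g), "/")
  # (4) shrinkage of d
  if (G > 1) {
    gamma2 <- max(0, sum(d_hat^2) / ((k - 1) * (G - 1)) - mean(samp_var))
    shrink <- gamma2 / (gamma2 + samp_var)
    shrink[samp_var == 0 & gamma2 == 0] <- 0
    d_tilde <- d_hat * shrink
  } else {
    gamma2 <- 0
    d_tilde <- d_hat * 0
  }
  # (5) stability
  rho <- rowMeans(abs(d_tilde) + sqrt(samp_var))
  ord <- order(rho, rownames(q), method = "radix")
  ranking <- rownames(q)[ord]
  structure(list(rho = setNames(rho, rownames(q)), ranking = ranking,
                 d_hat = d_hat, d_tilde = d_tilde, sigma2 = sigma2,
                 gamma2 = gamma2, n_g = n_g, groups = g,
                 genes = rownames(q)),
            class = "normfinder_fit")
}

#' @export
print.normfinder_fit <- function(x, ...) {
  cat(sprintf("NormFinder fit: %d genes, %d group(s)\n",
              length(x$genes), nlevels(x$groups)))
  cat("  rho (ascending):",
      paste(sprintf("%s=%.4f", x$ranking, x$rho[x$ranking]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stability of a reference-gene combination
#'
#' The combined normalization factor of a gene set S averages the member
#' quantities, so its inter-group deviation is the mean of the member
#' `d~_ig` (allowing deviations of opposite sign to cancel) and its
#' intra-group sampling term is `sqrt(sum_i sigma2_ig) / (|S| sqrt(n_g))`.
#' The set stability is the per-group sum of these, averaged over groups;
#' for a singleton it reduces exactly to the single-gene `rho`. The model
#' is the one fitted on the full candidate matrix: the set is scored, not
#' refitted.
#'
#' @param fit a [normfinder()] fit.
#' @param gene_set character vector of >= 2 genes from the fit.
#' @return list with `genes` (sorted), `rho_set`, `size`.
#' @export
rho_combination <- function(fit, gene_set) {
  stopifnot(inherits(fit, "normfinder_fit"))
  gene_set <- unique(as.character(gene_set))
  unknown <- setdiff(gene_set, fit$genes)
  if (length(unknown) > 0)
    rs_stop(paste0("unknown gene(s): ", paste(unknown, collapse = ", ")),
            "refsel_validation_error")
  if (length(gene_set) < 2)
    rs_stop("a combination needs >= 2 genes", "refsel_validation_error")
  list(genes = rs_sort(gene_set),
       rho_set = rho_set_value(fit, gene_set),
       size = length(gene_set))
}

#' @noRd
rho_set_value <- function(fit, gene_set) {
  s <- length(gene_set)
  inter <- abs(colMeans(fit$d_tilde[gene_set, , drop = FALSE]))
  intra <- sqrt(colSums(fit$sigma2[gene_set, , drop = FALSE]) /
                  as.numeric(fit$n_g)) / s
  mean(inter + intra)
}

#' Greedy stepwise combination selection (NormqPCR-style)
#'
#' Starts from the best pair over all pairs and grows the set one gene at
#' a time, each size-m set containing the chosen size-(m-1) set; at each
#' step the added gene minimises the combination stability. Ties are
#' broken lexicographically on the sorted member names.
#'
#' @param fit a [normfinder()] fit.
#' @param max_size largest set size to report (default: all genes).
#' @param genes candidate pool (default: all genes of the fit).
#' @return data frame with columns `size`, `genes` (semicolon-joined,
#'   sorted) and `rho`.
#' @export
nf_stepwise <- function(fit, max_size = NULL, genes = NULL) {
  stopifnot(inherits(fit, "normfinder_fit"))
  pool <- if (is.null(genes)) fit$genes else as.character(genes)
  if (is.null(max_size)) max_size <- length(pool)
  if (max_size > length(pool))
    rs_stop("max_size exceeds the candidate pool", "refsel_validation_error")
  if (length(pool) < 2 || max_size < 2)
    rs_stop("stepwise selection needs >= 2 genes", "refsel_validation_error")
  pairs <- combn(rs_sort(pool), 2, simplify = FALSE)
  rho_p <- vapply(pairs, function(p) rho_set_value(fit, p), numeric(1))
  current <- pairs[[best_set_index(rho_p, pairs)]]
  path <- data.frame(size = 2L, genes = paste(current, collapse = ";"),
                     rho = rho_set_value(fit, current),
                     stringsAsFactors = FALSE)
  while (length(current) < max_size) {
    left <- setdiff(pool, current)
    cand <- lapply(left, function(x) rs_sort(c(current, x)))
    rho_c <- vapply(cand, function(s) rho_set_value(fit, s), numeric(1))
    current <- cand[[best_set_index(rho_c, cand)]]
    path <- rbind(path, data.frame(size = length(current),
                                   genes = paste(current, collapse = ";"),
                                   rho = rho_set_value(fit, current),
                                   stringsAsFactors = FALSE))
  }
  path
}

#' Index of the minimum-rho set; lexicographic on joined names for ties
#' @noRd
best_set_index <- function(rho, sets) {
  keys <- vapply(sets, function(s) paste(rs_sort(s), collapse = ";"),
                 character(1))
  ord <- order(rho, keys, method = "radix")
  ord[1]
}

#' Nested-loop all-combinations NormFinder selection
#'
#' Extends the greedy stepwise procedure in two ways: at each step it
#' scores *all* combinations of each size (the best combination of m
#' genes need not contain the best combination of m-1, because deviations
#' of opposite sign can cancel), and the whole search is wrapped in an
#' outer elimination loop that drops the least stable candidate and
#' refits, reducing the bias that unstable candidates impose on the
#' across-gene centering. Optional filters exclude genes from
#' combination membership by stability value or rank.
#'
#' @param q genes x samples matrix, >= 3 genes.
#' @param groups sample annotation (see [normfinder()]).
#' @param min_stability genes with single-gene `rho` above this value are
#'   excluded from combinations (filter applied after each refit).
#' @param max_rank genes ranked worse than this are excluded from
#'   combinations.
#' @param max_subset_genes refuse all-subsets enumeration over more
#'   eligible genes than this unless `force = TRUE` (default 20).
#' @param force allow enumeration beyond `max_subset_genes`.
#' @return object of class `nf_ledger`: list with `ledger` (data frame
#'   `iteration`, `size`, `genes`, `rho`, `source` in
#'   `{"exhaustive", "stepwise"}` covering every evaluated combination and
#'   the greedy path), `best_per_size` (exhaustive winners only),
#'   `iterations` (per-iteration candidate set, per-gene rho, eligible
#'   set, eliminated gene), `filters`.
#' @export
nested_normfinder <- function(q, groups = NULL, min_stability = NULL,
                              max_rank = NULL, max_subset_genes = 20,
                              force = FALSE) {
  q <- as.matrix(q)
  if (nrow(q) < 3)
    rs_stop("nested selection needs >= 3 genes", "refsel_validation_error")
  candidates <- rownames(q)
  ledger <- list()
  iters <- list()
  it <- 0L
  while (length(candidates) >= 3) {
    it <- it + 1L
    fit <- normfinder(q[candidates, , drop = FALSE], groups)
    eligible <- fit$ranking
    if (!is.null(min_stability))
      eligible <- eligible[fit$rho[eligible] <= min_stability]
    if (!is.null(max_rank))
      eligible <- intersect(eligible, fit$ranking[seq_len(min(max_rank,
                                                  length(fit$ranking)))])
    rows <- NULL
    if (length(eligible) >= 2) {
      if (length(eligible) > max_subset_genes && !force)
        rs_stop(sprintf(
          "all-subsets enumeration over %d genes refused (limit %d); use force = TRUE",
          length(eligible), max_subset_genes), "refsel_guard_error")
      sets <- unlist(lapply(2:length(eligible), function(m)
        combn(rs_sort(eligible), m, simplify = FALSE)), recursive = FALSE)
      rho_s <- vapply(sets, function(s) rho_set_value(fit, s), numeric(1))
      rows <- data.frame(
        iteration = it,
        size = lengths(sets),
        genes = vapply(sets, paste, character(1), collapse = ";"),
        rho = rho_s, source = "exhaustive", stringsAsFactors = FALSE)
      sw <- nf_stepwise(fit, genes = eligible)
      rows <- rbind(rows, data.frame(iteration = it, size = sw$size,
                                     genes = sw$genes, rho = sw$rho,
                                     source = "stepwise",
                                     stringsAsFactors = FALSE))
    }
    eliminated <- rs_which_max(fit$rho)
    iters[[it]] <- list(candidates = candidates, rho = fit$rho,
                        eligible = eligible, eliminated = eliminated,
                        no_eligible_combination = length(eligible) < 2)
    if (!is.null(rows)) ledger[[length(ledger) + 1L]] <- rows
    candidates <- setdiff(candidates, eliminated)
  }
  ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else
    data.frame(iteration = integer(0), size = integer(0),
               genes = character(0), rho = numeric(0), source = character(0))
  ex <- ledger[ledger$source == "exhaustive", , drop = FALSE]
  best <- do.call(rbind, lapply(split(ex, list(ex$iteration, ex$size),
                                      drop = TRUE), function(d) {
    d[order(d$rho, d$genes, method = "radix")[1], , drop = FALSE]
  }))
  if (!is.null(best)) {
    best <- best[order(best$iteration, best$size), , drop = FALSE]
    rownames(best) <- NULL
  }
  rownames(ledger) <- NULL
  structure(list(ledger = ledger, best_per_size = best, iterations = iters,
                 filters = list(min_stability = min_stability,
                                max_rank = max_rank)),
            class = "nf_ledger")
}

#' @export
print.nf_ledger <- function(x, ...) {
  cat(sprintf("nested NormFinder selection: %d outer iteration(s), %d combinations scored\n",
              length(x$iterations), sum(x$ledger$source == "exhaustive")))
  if (!is.null(x$best_per_size) && nrow(x$best_per_size) > 0) {
    cat("best per size, first iteration:\n")
    print(x$best_per_size[x$best_per_size$iteration == 1,
                          c("size", "genes", "rho")], row.names = FALSE)
  }
  invisible(x)
}
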