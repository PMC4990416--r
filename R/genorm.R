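# geNorm: stability measure M, stepwise elimination, pairwise variation V.
#
# M_j is the mean, over all other candidates k, of the standard deviation
# across samples of the pairwise log-ratio q_j - q_k. Because the ratio is
# a difference of log2 quantities, M is invariant both to per-sample
# loading constants and to per-gene constants. Standard deviations use the
# n-1 denominator throughout.

#' geNorm stability measure M
#'
#' For each gene j, `M_j` is the average over the other genes k of the
#' sample standard deviation of the pairwise difference
#' `q_j,s - q_k,s` (the log2 expression ratio). Lower M = more stable;
#' M = 0 iff the gene's ratio with every other candidate is constant
#' across samples.
#'
#' @param q a [logq_matrix()] or plain genes x samples matrix (raw Ct
#'   matrices are accepted too; with equal slopes the ranking coincides).
#' @param na_policy `"complete"` (default) errors on any missing value;
#'   `"pairwise"` computes each pairwise SD over the samples where both
#'   genes are present (>= 3 shared samples required).
#' @return named numeric vector of M values, in the row order of `q`.
#' @export
genorm_m <- function(q, na_policy = c("complete", "pairwise")) {
  na_policy <- match.arg(na_policy)
  q <- as.matrix(q)
  k <- nrow(q)
  if (k < 2 || ncol(q) < 2)
    rs_stop("geNorm needs >= 2 genes and >= 2 samples",
            "refsel_validation_error")
  if (na_policy == "complete" && anyNA(q)) {
    idx <- which(is.na(q), arr.ind = TRUE)
    cells <- apply(head(idx, 5), 1, function(i)
      paste0(rownames(q)[i[1]], "/", colnames(q)[i[2]]))
    rs_stop(paste0("missing values under complete-matrix policy: ",
                   paste(cells, collapse = ", ")), "refsel_missing_error")
  }
  m <- numeric(k)
  for (j in seq_len(k)) {
    vjk <- vapply(seq_len(k)[-j], function(kk) {
      a <- q[j, ] - q[kk, ]
      a <- a[!is.na(a)]
      if (length(a) < 3 && na_policy == "pairwise")
        rs_stop(sprintf("fewer than 3 shared samples for pair %s/%s",
                        rownames(q)[j], rownames(q)[kk]),
                "refsel_missing_error")
      sd(a)
    }, numeric(1))
    m[j] <- mean(vjk)
  }
  setNames(m, rownames(q))
}

#' Stepwise geNorm elimination ranking
#'
#' Repeatedly recomputes M on the remaining genes and removes the gene
#' with the highest M (least stable) until two genes remain. The final
#' two genes cannot be resolved by geNorm and are reported as a tied
#' pair, listed lexicographically. Ties in the argmax are broken
#' lexicographically on gene name and recorded.
#'
#' @param q genes x samples matrix, >= 3 genes.
#' @param na_policy see [genorm_m()].
#' @return list with `elimination_order` (least stable first),
#'   `ranking` (most stable first; first two are the tied pair),
#'   `final_pair`, `m_trajectory` (max M of the remaining set at each
#'   elimination step, named by the gene removed), `ties` (genes whose
#'   removal involved a tie-break).
#' @export
genorm_rank <- function(q, na_policy = "complete") {
  q <- as.matrix(q)
  if (nrow(q) < 3)
    rs_stop("stepwise geNorm needs >= 3 genes", "refsel_validation_error")
  remaining <- rownames(q)
  elim <- character(0)
  traj <- numeric(0)
  ties <- character(0)
  while (length(remaining) > 2) {
    m <- genorm_m(q[remaining, , drop = FALSE], na_policy = na_policy)
    worst <- rs_which_max(m)
    if (sum(m >= max(m) - 1e-12) > 1) ties <- c(ties, worst)
    elim <- c(elim, worst)
    traj <- c(traj, setNames(max(m), worst))
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- rs_sort(remaining)
  list(elimination_order = elim,
       ranking = c(final_pair, rev(elim)),
       final_pair = final_pair,
       m_trajectory = traj,
       ties = ties)
}

#' geNorm pairwise variation V(n, n+1)
#'
#' `NF_n,s` is the normalization factor from the top n ranked genes (the
#' arithmetic mean of their log2 quantities, i.e. the log2 geometric mean
#' on the linear scale). `V(n, n+1)` is the standard deviation over
#' samples of `NF_n,s - NF_(n+1),s`: how much adding the (n+1)-th gene
#' changes sample normalization. The conventional criterion stops adding
#' genes at the smallest n with V below `cutoff` (0.15).
#'
#' @param q genes x samples matrix.
#' @param ranking ordered character vector of genes, most stable first;
#'   must cover >= 3 genes of `q`.
#' @param cutoff inclusion criterion on V (default 0.15).
#' @return list with `v_series` (named `V2:3`, ... for n = 2..k-1),
#'   `include_count` (smallest n with V < cutoff; k if never met) and
#'   `criterion_met`.
#' @export
pairwise_variation <- function(q, ranking, cutoff = 0.15) {
  q <- as.matrix(q)
  if (length(ranking) < 3)
    rs_stop("pairwise variation needs a ranking of >= 3 genes",
            "refsel_validation_error")
  if (!all(ranking %in% rownames(q)))
    rs_stop("ranking contains genes absent from the matrix",
            "refsel_validation_error")
  k <- length(ranking)
  nf <- function(n) colMeans(q[ranking[seq_len(n)], , drop = FALSE])
  v <- vapply(2:(k - 1), function(n) sd(nf(n) - nf(n + 1)), numeric(1))
  names(v) <- paste0("V", 2:(k - 1), ":", 3:k)
  below <- which(v < cutoff)
  list(v_series = v,
       include_count = if (length(below) > 0) below[1] + 1L else k,
       criterion_met = length(below) > 0)
}

#' Full geNorm analysis
#'
#' Runs [genorm_m()], the stepwise elimination of [genorm_rank()] and the
#' pairwise-variation criterion of [pairwise_variation()] in one call.
#'
#' @inheritParams genorm_rank
#' @inheritParams pairwise_variation
#' @return object of class `genorm_result`: the fields of [genorm_rank()]
#'   and [pairwise_variation()] plus `m_values` (initial M of every gene)
#'   and `cutoff`.
#' @examples
#' q <- logq_matrix(matrix(rnorm(40), 4, 10,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:10))))
#' genorm(q)
#' @export
genorm <- function(q, cutoff = 0.15, na_policy = "complete") {
  q <- as.matrix(q)
  rk <- genorm_rank(q, na_policy = na_policy)
  pv <- pairwise_variation(q, rk$ranking, cutoff = cutoff)
  structure(c(list(m_values = genorm_m(q, na_policy = na_policy),
                   cutoff = cutoff), rk, pv),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm analysis\n")
  cat("  M values:", paste(sprintf("%s=%.3f", names(x$m_values), x$m_values),
                           collapse = ", "), "\n")
  cat("  ranking (most stable first):", paste(x$ranking, collapse = " > "),
      sprintf("(first two tied: %s)\n", paste(x$final_pair, collapse = "/")))
  cat("  V series:", paste(sprintf("%s=%.3f", names(x$v_series), x$v_series),
                           collapse = ", "), "\n")
  cat(sprintf("  include %d genes (cutoff %.2f%s)\n", x$include_count,
              x$cutoff, if (x$criterion_met) "" else "; criterion never met"))
  invisible(x)
}
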