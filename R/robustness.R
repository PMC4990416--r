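# Leave-one-group-out robustness of reference-gene selection.

#' Leave-one-group-out perturbation of reference-gene ranking
#'
#' Re-runs the chosen selection method with each group (e.g. tissue)
#' omitted in turn and compares the resulting rankings with the all-data
#' ranking: per-gene rank ranges across omissions, and the number of
#' omissions whose top-m set equals the all-data top-m set. A selection
#' whose top set survives every omission is robust to the composition of
#' the sample panel.
#'
#' @param q genes x samples matrix.
#' @param groups sample annotation (see [normfinder()]); >= 3 groups.
#' @param method `"genorm"` or `"normfinder"`. geNorm rankings come from
#'   [genorm_rank()] (tied final pair listed lexicographically);
#'   NormFinder rankings are ascending in rho.
#' @param top_m size of the top set whose preservation is counted
#'   (default 4).
#' @return object of class `robustness_report`: list with `method`,
#'   `full_ranking`, `rankings` (named list, one per omitted group),
#'   `rank_range` (data frame `gene`, `min_rank`, `max_rank` across
#'   omissions), `top_m`, `top_m_preserved` (count of omissions whose
#'   top-m set matches), `n_groups`.
#' @export
leave_one_group_out <- function(q, groups, method = c("genorm", "normfinder"),
                                top_m = 4) {
  method <- match.arg(method)
  q <- as.matrix(q)
  g <- resolve_groups(q, groups)
  if (nlevels(g) < 3)
    rs_stop("leave-one-group-out needs >= 3 groups",
            "refsel_validation_error")
  rank_of <- function(mat, ann) {
    if (method == "genorm") genorm_rank(mat)$ranking
    else normfinder(mat, ann)$ranking
  }
  full <- rank_of(q, g)
  rankings <- list()
  for (lv in levels(g)) {
    keep <- g != lv
    if (method == "normfinder" && nlevels(droplevels(g[keep])) < 1)
      rs_stop("no groups left after omission", "refsel_validation_error")
    sub <- q[, keep, drop = FALSE]
    ann <- setNames(as.character(g[keep]), colnames(q)[keep])
    rankings[[lv]] <- rank_of(sub, ann)
  }
  genes <- rownames(q)
  pos <- vapply(rankings, function(rk) match(genes, rk),
                integer(length(genes)))
  rank_range <- data.frame(gene = genes,
                           min_rank = apply(pos, 1, min),
                           max_rank = apply(pos, 1, max),
                           full_rank = match(genes, full),
                           stringsAsFactors = FALSE)
  top_full <- rs_sort(full[seq_len(min(top_m, length(full)))])
  preserved <- sum(vapply(rankings, function(rk)
    identical(rs_sort(rk[seq_len(min(top_m, length(rk)))]), top_full),
    logical(1)))
  structure(list(method = method, full_ranking = full, rankings = rankings,
                 rank_range = rank_range, top_m = top_m,
                 top_m_preserved = preserved, n_groups = nlevels(g)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("leave-one-group-out (%s): %d omission runs\n",
              x$method, x$n_groups))
  cat(sprintf("  top-%d set preserved in %d/%d omissions\n",
              x$top_m, x$top_m_preserved, x$n_groups))
  print(x$rank_range, row.names = FALSE)
  invisible(x)
}
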