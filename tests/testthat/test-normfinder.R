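nf_groups2 <- function(n = 6) rep(c("a", "b"), each = n)

test_that("input contracts: group sizes, gene count, completeness", {
  set.seed(30)
  q <- rand_q(4, 6)
  expect_error(normfinder(q, c("a", "a", "a", "a", "a", "b")),
               class = "refsel_validation_error")
  expect_error(normfinder(q[1:2, ], rep(c("a", "b"), 3)),
               class = "refsel_validation_error")
  q[1, 1] <- NA
  expect_error(normfinder(q, rep(c("a", "b"), 3)),
               class = "refsel_missing_error")
})

test_that("a gene with a large inter-group deviation is ranked last", {
  set.seed(31)
  d <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  d["g3", ] <- c(1.5, -1.5)
  sim <- sim_nf_model(d, sigma = 0.1, n_g = c(10, 10))
  fit <- normfinder(sim$q, sim$groups)
  expect_equal(fit$ranking[5], "g3")
  expect_gt(fit$rho["g3"], 2 * max(fit$rho[setdiff(names(fit$rho), "g3")]))
})

test_that("rho is invariant to per-sample and per-gene constants", {
  set.seed(32)
  q <- rand_q(5, 12)
  g <- nf_groups2()
  f0 <- normfinder(q, g)
  f1 <- normfinder(sweep(q, 2, rnorm(12), "+"), g)
  f2 <- normfinder(sweep(q, 1, rnorm(5), "+"), g)
  expect_equal(f1$rho, f0$rho, tolerance = 1e-10)
  expect_equal(f2$rho, f0$rho, tolerance = 1e-10)
})

test_that("with one group, rho ignores annotation labels entirely", {
  set.seed(33)
  q <- rand_q(5, 10)
  f0 <- normfinder(q, NULL)
  f1 <- normfinder(q, rep("anything", 10))
  expect_equal(f1$rho, f0$rho)
  expect_true(all(f0$d_tilde == 0))
})

test_that("null groups give exchangeable ranks across genes", {
  # all genes generated identically: no gene should be preferred
  set.seed(34)
  k <- 5
  counts <- matrix(0, k, k, dimnames = list(paste0("g", 1:k), NULL))
  d <- matrix(0, k, 2, dimnames = list(paste0("g", 1:k), c("a", "b")))
  for (rep in 1:1000) {
    sim <- sim_nf_model(d, sigma = 0.3, n_g = c(5, 5))
    fit <- normfinder(sim$q, sim$groups)
    for (r in 1:k) counts[fit$ranking[r], r] <- counts[fit$ranking[r], r] + 1
  }
  # chi-square for uniformity of each gene's rank distribution
  for (i in 1:k) {
    p <- chisq.test(counts[i, ], p = rep(1 / k, k))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("sigma2 and ranking are recovered from the exact model", {
  set.seed(35)
  des <- nf_recovery_design(n_g = 50)
  nrep <- 200
  sig2_hat <- matrix(0, 8, 3)
  rank_ok <- 0
  true_rank <- names(sort(setNames(des$true_rho, rownames(des$d))))
  for (rep in seq_len(nrep)) {
    sim <- sim_nf_model(des$d, des$sigma, des$n_g)
    fit <- normfinder(sim$q, sim$groups)
    sig2_hat <- sig2_hat + fit$sigma2 / nrep
    if (identical(fit$ranking, true_rank)) rank_ok <- rank_ok + 1
  }
  rel_bias <- rowMeans(sig2_hat) / des$sigma^2 - 1
  expect_lt(max(abs(rel_bias)), 0.05)
  expect_gte(rank_ok / nrep, 0.95)
})

test_that("compensating inter-group deviations make pairs beat singles", {
  set.seed(36)
  d <- matrix(0, 6, 3,
              dimnames = list(paste0("g", 1:6), c("A", "B", "C")))
  d["g5", ] <- c(0.6, -0.6, 0)
  d["g6", ] <- c(-0.6, 0.6, 0)
  sim <- sim_nf_model(d, sigma = 0.2, n_g = rep(8, 3))
  fit <- normfinder(sim$q, sim$groups)
  pair <- rho_combination(fit, c("g5", "g6"))
  expect_lt(pair$rho_set, min(fit$rho[c("g5", "g6")]))
})

test_that("combination stability follows the averaging algebra", {
  set.seed(37)
  q <- rand_q(4, 12)
  q <- rbind(q, g4bis = q["g4", ]) # identical rows
  fit <- normfinder(q, nf_groups2())
  pair <- rho_combination(fit, c("g4", "g4bis"))
  # identical rows: inter term equals the single gene's, intra term is
  # sqrt(2 sigma2)/2 = single's intra / sqrt(2)
  single_intra <- sqrt(fit$sigma2["g4", ] / as.numeric(fit$n_g))
  expect_equal(pair$rho_set,
               mean(abs(fit$d_tilde["g4", ]) + single_intra / sqrt(2)),
               tolerance = 1e-10)
  expect_error(rho_combination(fit, c("g1", "nope")),
               class = "refsel_validation_error")
})

test_that("best pair matches exhaustive enumeration", {
  set.seed(38)
  for (rep in 1:5) {
    q <- rand_q(6, 12)
    fit <- normfinder(q, nf_groups2())
    pairs <- combn(rownames(q), 2, simplify = FALSE)
    rhos <- vapply(pairs, function(p) rho_combination(fit, p)$rho_set,
                   numeric(1))
    best_or <- pairs[[which.min(rhos)]]
    sw <- nf_stepwise(fit, max_size = 2)
    expect_equal(sw$genes[1], paste(sort(best_or), collapse = ";"))
    expect_equal(sw$rho[1], min(rhos), tolerance = 1e-12)
  }
})

test_that("greedy stepwise nests its sets and covers all sizes", {
  set.seed(39)
  q <- rand_q(5, 12)
  fit <- normfinder(q, nf_groups2())
  sw <- nf_stepwise(fit)
  expect_equal(sw$size, 2:5)
  sets <- lapply(strsplit(sw$genes, ";"), identity)
  for (i in 2:length(sets))
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  expect_equal(sets[[4]], sort(rownames(q)))
})

test_that("3-gene stepwise path is forced", {
  set.seed(40)
  q <- rand_q(3, 8)
  fit <- normfinder(q, rep(c("a", "b"), each = 4))
  sw <- nf_stepwise(fit)
  expect_equal(sw$size, 2:3)
  expect_equal(sw$genes[2], paste(sort(rownames(q)), collapse = ";"))
})

test_that("nested loop enumerates all subsets and dominates greedy", {
  set.seed(41)
  q <- rand_q(4, 12)
  led <- nested_normfinder(q, nf_groups2())
  it1 <- led$ledger[led$ledger$iteration == 1 &
                      led$ledger$source == "exhaustive", ]
  expect_equal(nrow(it1), choose(4, 2) + choose(4, 3) + choose(4, 4))
  # outer loop shrinks by one candidate per iteration: 4 then 3
  expect_equal(length(led$iterations), 2L)
  expect_equal(length(led$iterations[[2]]$candidates), 3L)
  # dominance: best exhaustive of each size <= greedy at that size
  for (it in unique(led$ledger$iteration)) {
    sw <- led$ledger[led$ledger$iteration == it &
                       led$ledger$source == "stepwise", ]
    for (r in seq_len(nrow(sw))) {
      ex <- led$best_per_size[led$best_per_size$iteration == it &
                                led$best_per_size$size == sw$size[r], ]
      expect_lte(ex$rho, sw$rho[r] + 1e-12)
    }
  }
})

test_that("stability filters restrict membership without erroring out", {
  set.seed(42)
  d <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  d["g5", ] <- c(2, -2)
  sim <- sim_nf_model(d, sigma = 0.15, n_g = c(8, 8))
  led <- nested_normfinder(sim$q, sim$groups, max_rank = 3)
  it1 <- led$ledger[led$ledger$iteration == 1, ]
  members <- unique(unlist(strsplit(it1$genes, ";")))
  fit1 <- normfinder(sim$q, sim$groups)
  expect_true(all(members %in% fit1$ranking[1:3]))
  # a filter that excludes (almost) everything records, not throws
  led2 <- nested_normfinder(sim$q, sim$groups, min_stability = -1)
  expect_true(all(vapply(led2$iterations,
                         function(x) x$no_eligible_combination, logical(1))))
  expect_equal(nrow(led2$ledger), 0L)
})

test_that("first nested iteration without filters equals exhaustive search", {
  set.seed(43)
  q <- rand_q(6, 12)
  g <- nf_groups2()
  led <- nested_normfinder(q, g)
  fit <- normfinder(q, g)
  it1 <- led$ledger[led$ledger$iteration == 1 &
                      led$ledger$source == "exhaustive", ]
  sets <- unlist(lapply(2:6, function(m)
    combn(sort(rownames(q)), m, simplify = FALSE)), recursive = FALSE)
  expect_equal(nrow(it1), length(sets))
  for (i in seq_along(sets)) {
    key <- paste(sets[[i]], collapse = ";")
    expect_equal(it1$rho[it1$genes == key],
                 rho_combination(fit, sets[[i]])$rho_set, tolerance = 1e-12)
  }
})

test_that("the enumeration guard refuses very large eligible sets", {
  set.seed(44)
  q <- rand_q(21, 8, prefix = "gene")
  expect_error(nested_normfinder(q, rep(c("a", "b"), each = 4)),
               class = "refsel_guard_error")
})
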