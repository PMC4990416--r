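# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, textbook formulas) and independent
# of the package implementation paths they check.

# random genes x samples matrix with named dims
rand_q <- function(k, n, sd = 1, prefix = "g") {
  matrix(rnorm(k * n, sd = sd), k, n,
         dimnames = list(paste0(prefix, seq_len(k)), paste0("s", seq_len(n))))
}

# closed-form OLS of y on x: slope, intercept, slope se, R^2
oracle_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       r_squared = 1 - sum(resid^2) / sum((y - yb)^2))
}

# geNorm M by explicit pair enumeration (n-1 sd)
oracle_genorm_m <- function(q) {
  k <- nrow(q)
  m <- numeric(k)
  for (j in 1:k) {
    tot <- 0
    for (kk in 1:k) {
      if (kk == j) next
      a <- q[j, ] - q[kk, ]
      tot <- tot + sqrt(sum((a - mean(a))^2) / (length(a) - 1))
    }
    m[j] <- tot / (k - 1)
  }
  names(m) <- rownames(q)
  m
}

# full stepwise elimination recomputing M from scratch each step
oracle_genorm_elim <- function(q) {
  remaining <- rownames(q)
  elim <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(q[remaining, , drop = FALSE])
    top <- names(m)[m >= max(m) - 1e-12]
    worst <- sort(top, method = "radix")[1]
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(elim = elim, final = sort(remaining, method = "radix"))
}

# V series straight from the NF definitions
oracle_v_series <- function(q, ranking) {
  k <- length(ranking)
  v <- numeric(k - 2)
  for (n in 2:(k - 1)) {
    nf_n <- apply(q[ranking[1:n], , drop = FALSE], 2, mean)
    nf_n1 <- apply(q[ranking[1:(n + 1)], , drop = FALSE], 2, mean)
    dd <- nf_n - nf_n1
    v[n - 1] <- sqrt(sum((dd - mean(dd))^2) / (length(dd) - 1))
  }
  v
}

# simulate straight from the NormFinder generative model
sim_nf_model <- function(d, sigma, n_g, tau = 0.4) {
  k <- nrow(d); G <- ncol(d)
  samples <- character(0); grp <- character(0)
  q <- NULL
  for (g in 1:G) {
    b <- rnorm(n_g[g], 0, tau)
    block <- d[, g] + matrix(rep(b, each = k), k) +
      matrix(rnorm(k * n_g[g], 0, sigma), k)
    q <- cbind(q, block)
    grp <- c(grp, rep(colnames(d)[g], n_g[g]))
  }
  colnames(q) <- paste0("s", seq_len(ncol(q)))
  rownames(q) <- rownames(d)
  list(q = q, groups = setNames(grp, colnames(q)))
}

# the design used for NormFinder parameter recovery: 8 genes, 3 groups,
# fixed deviation matrix with zero column sums (the panel-average
# stability assumption holds exactly) and mean |d| per gene of
# 0, 0.15, ..., 0.90, 1.65 — adjacent true stabilities separated by
# >= 0.15 so the true ranking is recoverable at n_g = 50.
nf_recovery_design <- function(n_g = 50) {
  d <- matrix(c(0, 0, 0,
                0.225, 0, -0.225,
                0, -0.45, 0.45,
                0.675, 0, -0.675,
                0, 0.9, -0.9,
                1.125, 0, -1.125,
                -1.35, 1.35, 0,
                -0.675, -1.8, 2.475),
              nrow = 8, byrow = TRUE,
              dimnames = list(paste0("g", 1:8), c("A", "B", "C")))
  sigma <- seq(0.10, 0.45, length.out = 8)
  true_rho <- rowMeans(abs(d)) + sigma / sqrt(n_g)
  list(d = d, sigma = sigma, n_g = rep(n_g, 3), true_rho = true_rho)
}
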