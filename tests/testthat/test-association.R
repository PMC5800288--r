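# Brute-force oracles used here are deliberately longhand implementations
# of the textbook formulas, independent of the package code paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_ols <- function(y, X) {
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  resid <- y - A %*% beta
  df <- length(y) - ncol(A)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(t(A) %*% A)) * s2)
  t <- as.vector(beta) / se
  list(beta = as.vector(beta), t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

test_that("pearson matches the longhand formula on random instances", {
  expect_equal(pearson(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    got <- pearson(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_true(got$p >= 0 && got$p <= 1)
  }
  expect_error(pearson(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson(1:2, 1:2))
})

test_that("multiple regression matches the normal-equation oracle", {
  set.seed(13)
  for (i in 1:20) {
    X <- matrix(rnorm(12), 6, 2)
    y <- rnorm(6)
    got <- multiple_regression(y, X)
    want <- oracle_ols(y, X)
    expect_equal(got$intercept, want$beta[1], tolerance = 1e-10)
    expect_equal(got$coefficients$coef, want$beta[-1], tolerance = 1e-10)
    expect_equal(got$coefficients$t, want$t[-1], tolerance = 1e-10)
    expect_equal(got$coefficients$p, want$p[-1], tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_true(all(abs(got$coefficients$partial_r) <= 1))
  }
})

test_that("regression recovers planted coefficients and degenerates correctly", {
  set.seed(17)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  pirna <- rlnorm(6, log(1000), 1)
  kp <- rlnorm(6, log(2), 0.5)
  y <- -3 * z(pirna) - 1 * z(kp)   # noise-free planted model
  # exact interpolation: summary.lm warns about the perfect fit by design
  fit <- suppressWarnings(multiple_regression(y, cbind(pirna = pirna, kp = kp)))
  expect_equal(fit$coefficients$coef_zx, c(-3, -1), tolerance = 1e-9)

  # y identical to one predictor, second orthogonal: coefficients (1, 0)
  x1 <- c(1, 2, 4, 8, 9, 12)
  x2 <- rnorm(6)
  x2 <- x2 - mean(x2)
  x2 <- x2 - x1 * sum(x2 * x1) / sum(x1 * x1)   # orthogonalized noise
  fit2 <- suppressWarnings(multiple_regression(x1, cbind(a = x1, b = x2)))
  expect_equal(fit2$coefficients$std_coef, c(1, 0), tolerance = 1e-10)

  # one predictor: fully standardized coefficient equals pearson R
  x <- rnorm(8); yy <- rnorm(8)
  expect_equal(multiple_regression(yy, cbind(x = x))$coefficients$std_coef,
               pearson(x, yy)$r, tolerance = 1e-12)

  expect_error(multiple_regression(rnorm(6), cbind(x1, 2 * x1)), "rank")
  expect_error(multiple_regression(rnorm(3), matrix(rnorm(6), 3, 2)))
})

test_that("complete linkage matches stats::hclust on tie-free instances", {
  set.seed(19)
  for (i in 1:20) {
    m <- matrix(rnorm(7 * 3), 7, 3)
    rownames(m) <- letters[1:7]
    got <- hcluster(m, scale_features = FALSE)
    want <- stats::hclust(stats::dist(m), method = "complete")
    expect_equal(stats::cophenetic(got)[lower.tri(diag(7))],
                 stats::cophenetic(want)[lower.tri(diag(7))],
                 tolerance = 1e-10)
  }
})

test_that("dendrogram geometry and tie-breaks are deterministic", {
  # coincident pair among three merges first at height zero
  m <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 2, byrow = TRUE)
  hc <- hcluster(m, labels = c("a", "b", "c"), scale_features = FALSE)
  expect_equal(hc$height[1], 0)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # four collinear points: near pairs merge before the final join
  m2 <- matrix(c(0, 1, 10, 11), ncol = 1)
  hc2 <- hcluster(m2, labels = c("p0", "p1", "p10", "p11"),
                  scale_features = FALSE)
  expect_true(all(hc2$height[1:2] < hc2$height[3]))
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
  expect_equal(sort(hc2$merge[2, ]), c(-4, -3))

  # permutation invariance, including a tie (square of side 1)
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  labs <- c("a", "b", "c", "d")
  base <- hcluster(sq, labels = labs, scale_features = FALSE)
  co_base <- stats::cophenetic(base)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    hc_p <- hcluster(sq[perm, , drop = FALSE], labels = labs[perm],
                     scale_features = FALSE)
    co_p <- stats::cophenetic(hc_p)
    expect_equal(as.matrix(co_p)[labs, labs], as.matrix(co_base)[labs, labs],
                 tolerance = 1e-12)
  }

  # newick export parses back to the same topology
  nwk <- dendrogram_newick(base)
  expect_true(grepl("^\\(", nwk))
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), labs)
})

test_that("t test matches the pooled-variance oracle and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  expect_lt(t_test_groups(a, b)$p, 0.05)
  same <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3, mean = 1)
    got <- t_test_groups(x, y)
    want <- oracle_pooled_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  # zero variance conventions
  expect_equal(t_test_groups(c(2, 2), c(2, 2)), list(t = 0, p = 1))
  deg <- t_test_groups(c(2, 2), c(5, 5))
  expect_equal(deg$p, 0)

  # welch flag reproduces stats::t.test default behavior
  w <- t_test_groups(c(1, 2, 3), c(2, 4, 9), welch = TRUE)
  ref <- stats::t.test(c(1, 2, 3), c(2, 4, 9))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})

test_that("phenotype labels apply the strict 10% criterion per cross", {
  expect_equal(as.character(label_phenotype(0, "A")), "low")
  expect_equal(as.character(label_phenotype(10.0, "A")), "high")  # strict
  expect_equal(as.character(label_phenotype(100, "A")), "high")
  expect_equal(attr(label_phenotype(5, "A"), "phenotype"), "inducibility")
  expect_equal(attr(label_phenotype(5, "A*"), "phenotype"), "susceptibility")
  expect_equal(as.character(label_phenotype(c(9.9, 10, 50), "A")),
               c("low", "high", "high"))
  expect_error(label_phenotype(120, "A"))
})
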