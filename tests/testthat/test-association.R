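test_that("group comparison matches the closed-form t-test and sign convention", {
  m <- rbind(S1 = 0.1, S2 = 0.2, S3 = 0.15, S4 = 0.8, S5 = 0.9, S6 = 0.85)
  colnames(m) <- "drugX"
  labels <- c(S1 = "R", S2 = "R", S3 = "R", S4 = "PD", S5 = "PD", S6 = "PD")
  res <- compare_groups(m, labels, "R", "PD", var_equal = TRUE)

  # pooled-variance two-sample t computed from first principles
  x1 <- c(0.1, 0.2, 0.15); x2 <- c(0.8, 0.9, 0.85)
  sp2 <- (2 * var(x1) + 2 * var(x2)) / 4
  t_oracle <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  # responders more sensitive ex vivo -> negative mean difference
  expect_lt(res$mean_diff, 0)

  # identical constant groups: no evidence of a difference
  m0 <- matrix(0.5, 6, 1, dimnames = list(names(labels), "flat"))
  res0 <- compare_groups(m0, labels, "R", "PD")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("group comparison is invariant to sample order and antisymmetric in groups", {
  set.seed(31)
  n <- 12
  m <- matrix(rnorm(n * 4, 0.6, 0.2), n, 4,
              dimnames = list(sprintf("S%02d", 1:n), paste0("d", 1:4)))
  labels <- setNames(rep(c("R", "PD"), each = n / 2), rownames(m))
  a <- compare_groups(m, labels, "R", "PD")
  perm <- sample(n)
  b <- compare_groups(m[perm, ], labels[perm], "R", "PD")
  expect_equal(a, b, ignore_attr = TRUE)
  c <- compare_groups(m, labels, "PD", "R")
  expect_equal(c$p, a$p)
  expect_equal(c$mean_diff, -a$mean_diff)
})

test_that("pathway averaging is the available-case mean per sample", {
  m <- rbind(S1 = c(0.4, 0.6, 0.9), S2 = c(0.2, NA, 0.8))
  colnames(m) <- c("d1", "d2", "d3")
  cls <- c(d1 = "pwA", d2 = "pwA", d3 = "pwB")
  pw <- pathway_average(m, cls)
  expect_equal(pw$values["S1", "pwA"], 0.5)
  expect_equal(pw$values["S2", "pwA"], 0.2) # mean over observed drugs only
  expect_equal(pw$values[, "pwB"], c(S1 = 0.9, S2 = 0.8)) # singleton pathway
  m2 <- m; m2[2, c("d1", "d2")] <- NA
  expect_true(is.na(pathway_average(m2, cls)$values["S2", "pwA"]))
})

test_that("BH adjustment equals the textbook step-up on all permutations", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(32)
  p <- round(runif(6), 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in seq_len(nrow(perms))) {
    pp <- p[perms[i, ]]
    expect_equal(adjust_bh(pp), bh_oracle(pp))
    expect_true(all(adjust_bh(pp) >= pp))
  }
})

test_that("correlations match known values and the pairwise Kendall oracle", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlate(x, -x, "kendall")$estimate, -1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")

  tau_oracle <- function(x, y) {
    s <- 0; n <- length(x)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    s / (n * (n - 1) / 2)
  }
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    x <- runif(n); y <- runif(n) # continuous draws: ties have measure zero
    expect_equal(correlate(x, y, "kendall")$estimate, tau_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("blocking adjusts for strata and detects aliasing", {
  set.seed(34)
  n <- 200
  stratum <- sample(1:4, n, replace = TRUE)
  group <- rbinom(n, 1, 0.5)
  y <- 0.5 * group + c(0, 1, 2, 3)[stratum] + rnorm(n)
  res <- blocked_group_test(y, group, factor(stratum))
  expect_lt(res$p, 0.01) # true group effect found despite strong strata
  expect_equal(res$strata_used, 4)

  # continuous blocking variable is binned at quartiles
  res2 <- blocked_group_test(y, group, rnorm(n))
  expect_equal(res2$strata_used, 4)

  # group perfectly confounded with stratum
  expect_error(blocked_group_test(y, group, factor(group)), "aliased")
})

test_that("drug-drug correlations recover structure and stay bounded under noise", {
  set.seed(35)
  base <- rnorm(100)
  m <- cbind(a = base + rnorm(100, 0, 0.01), b = base + rnorm(100, 0, 0.01),
             noise1 = rnorm(100), noise2 = rnorm(100))
  r <- drug_correlation_matrix(m)
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 1))
  expect_gt(r["a", "b"], 0.99)

  # independent columns: |r| < 0.3 for at least 95% of pairs at n = 100
  mn <- matrix(rnorm(100 * 20), 100, 20,
               dimnames = list(NULL, paste0("n", 1:20)))
  rn <- drug_correlation_matrix(mn)
  off <- abs(rn[upper.tri(rn)])
  expect_gte(mean(off < 0.3), 0.95)

  # too few complete pairs -> NA
  mp <- m; mp[4:100, "noise2"] <- NA
  rp <- drug_correlation_matrix(mp, min_pairs = 5)
  expect_true(is.na(rp["a", "noise2"]))
})
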