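test_that("noiseless planted designs are recovered exactly", {
  n <- 40
  pheno <- rep(c(1, 1, 0, 0), n / 4)
  geno <- rep(c(1, 0, 1, 0), n / 4)
  samples <- sprintf("s%02d", 1:n)
  resp <- data.frame(sample = samples, drug = "cisplatin",
                     value = -1.0 * pheno + 0 * geno, metric_kind = "z_ic50")
  res <- suppressWarnings(  # lm warns on the exact-interpolation fit
    drug_sensitivity_lm(resp, stats::setNames(pheno, samples),
                        stats::setNames(geno, samples), "cisplatin"))
  expect_lt(abs(res$coef[res$covariate == "phenocopy"] - (-1.0)), 1e-10)
  expect_lt(abs(res$coef[res$covariate == "genotype"]), 1e-10)
  expect_identical(res$n, c(40L, 40L))
})

test_that("orthogonal predictors reproduce the univariate coefficients", {
  set.seed(12)
  n <- 200
  x1 <- rep(c(1, 1, -1, -1), n / 4)   # mean zero, exactly orthogonal
  x2 <- rep(c(1, -1, 1, -1), n / 4)
  y <- 0.7 * x1 - 0.3 * x2 + rnorm(n)
  samples <- sprintf("s%03d", 1:n)
  resp <- data.frame(sample = samples, drug = "d", value = y,
                     metric_kind = "z_ic50")
  multi <- drug_sensitivity_lm(resp, stats::setNames(x1, samples),
                               stats::setNames(x2, samples), "d")
  uni1 <- unname(coef(lm(y ~ x1))["x1"])
  uni2 <- unname(coef(lm(y ~ x2))["x2"])
  expect_equal(multi$coef[multi$covariate == "phenocopy"], uni1,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(multi$coef[multi$covariate == "genotype"], uni2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("flipping the response sign flips coefficients, not p-values", {
  set.seed(13)
  n <- 120
  samples <- sprintf("s%03d", 1:n)
  pheno <- runif(n); geno <- rbinom(n, 1, 0.3)
  y <- -0.5 * pheno + rnorm(n)
  resp <- data.frame(sample = samples, drug = "d", value = y,
                     metric_kind = "z_ic50")
  flipped <- resp; flipped$value <- -resp$value
  a <- drug_sensitivity_lm(resp, stats::setNames(pheno, samples),
                           stats::setNames(geno, samples), "d")
  b <- drug_sensitivity_lm(flipped, stats::setNames(pheno, samples),
                           stats::setNames(geno, samples), "d")
  expect_equal(a$coef, -b$coef, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("degenerate linear designs are rejected", {
  samples <- sprintf("s%02d", 1:20)
  x <- rbinom(20, 1, 0.5)
  resp <- data.frame(sample = samples, drug = "d", value = rnorm(20),
                     metric_kind = "z_ic50")
  expect_error(drug_sensitivity_lm(resp, stats::setNames(x, samples),
                                   stats::setNames(x, samples), "d"),
               "collinear")
  expect_error(drug_sensitivity_lm(resp[1:4, ],
                                   stats::setNames(x[1:4], samples[1:4]),
                                   stats::setNames(1 - x[1:4], samples[1:4]),
                                   "d"),
               "too few")
})

test_that("planted drug coefficient is covered by its 95% CI at nominal rate", {
  set.seed(500)
  n <- 500
  samples <- sprintf("s%03d", 1:n)
  hits <- replicate(100, {
    pheno <- runif(n)
    geno <- rbinom(n, 1, 0.3)
    y <- -0.5 * pheno + 0.2 * geno + rnorm(n, 0, 1)
    resp <- data.frame(sample = samples, drug = "d", value = y,
                       metric_kind = "z_ic50")
    r <- drug_sensitivity_lm(resp, stats::setNames(pheno, samples),
                             stats::setNames(geno, samples), "d")
    i <- r$covariate == "phenocopy"
    half <- qt(0.975, r$n[i] - 3) * r$se[i]
    abs(r$coef[i] - (-0.5)) <= half
  })
  expect_gte(sum(hits), 93L)
  expect_lte(sum(hits), 97L)
})

test_that("Fisher p matches exhaustive enumeration on worked examples", {
  r <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p, fisher_enum_p(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               tolerance = 1e-12)
  bal <- fisher_exact_2x2(matrix(1, 2, 2))
  expect_identical(bal$p, 1)
  expect_equal(attr(bal, "odds_ratio"), 1)
  deg <- fisher_exact_2x2(matrix(c(5, 0, 0, 0), 2, byrow = TRUE))
  expect_identical(deg$p, 1)
  expect_true(attr(deg, "degenerate"))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Fisher p equals enumeration for every 2x2 table up to n = 12", {
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("trend statistic is zero under equal proportions and degenerate-safe", {
  flat <- rbind(c(10, 20, 30), c(10, 20, 30))
  r <- cochran_armitage_trend(flat)
  expect_equal(r$stat, 0)
  expect_identical(r$p, 1)
  empty_row <- rbind(c(0, 0, 0), c(5, 5, 5))
  rd <- cochran_armitage_trend(empty_row)
  expect_identical(rd$p, 1)
  expect_true(attr(rd, "degenerate"))
})

test_that("squared trend statistic equals the 2x2 chi-square at k = 2", {
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    z <- cochran_armitage_trend(tab)$stat
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_lt(abs(z^2 - unname(chi)), 1e-10)
  }
})

test_that("trend p is invariant under affine score transforms", {
  set.seed(15)
  tab <- matrix(rpois(8, 40), 2)
  base <- cochran_armitage_trend(tab, scores = 0:3)
  aff <- cochran_armitage_trend(tab, scores = 7 + 3 * (0:3))
  expect_equal(base$stat, aff$stat, tolerance = 1e-12)
  expect_equal(base$p, aff$p, tolerance = 1e-12)
})

test_that("trend p agrees with a permutation null on a monotone table", {
  set.seed(16)
  probs <- c(0.25, 0.4, 0.55, 0.7)
  counts <- sapply(probs, function(p) rbinom(1, 100, p))
  tab <- rbind(counts, 100 - counts)
  r <- cochran_armitage_trend(tab)
  p_perm <- trend_permutation_p(tab, 0:3, draws = 2e4)
  se <- sqrt(max(r$p, 1 / 2e4) * (1 - max(r$p, 1 / 2e4)) / 2e4)
  expect_lt(abs(r$p - p_perm), 3 * se + 1e-6)
})

test_that("adjusted pCR model covers a planted log-OR and flags separation", {
  set.seed(17)
  n <- 1000
  hits <- replicate(60, {
    d <- data.frame(sample = sprintf("s%04d", 1:n),
                    pcr = NA, grade = sample(1:3, n, TRUE),
                    t_stage = sample(1:4, n, TRUE),
                    n_stage = sample(0:3, n, TRUE))
    pheno <- rbinom(n, 1, 0.4)
    d$pcr <- rbinom(n, 1, plogis(-1.5 + 1.0 * pheno + 0.1 * d$grade))
    r <- adjusted_pcr_model(d, stats::setNames(pheno == 1, d$sample))
    i <- r$covariate == "phenocopy"
    abs(r$coef[i] - 1.0) <= 1.96 * r$se[i]
  })
  expect_gte(mean(hits), 0.89)   # 95% nominal, binomial slack at 60 draws
  # exact separation: pcr == phenocopy
  d <- data.frame(sample = sprintf("s%02d", 1:40), pcr = rep(0:1, 20),
                  grade = sample(1:3, 40, TRUE),
                  t_stage = sample(1:4, 40, TRUE),
                  n_stage = sample(0:3, 40, TRUE))
  expect_error(adjusted_pcr_model(d, stats::setNames(d$pcr == 1, d$sample)),
               "separation")
})

test_that("null adjusted pCR Wald p-values are uniform", {
  set.seed(18)
  n <- 500
  ps <- replicate(150, {
    d <- data.frame(sample = sprintf("s%04d", 1:n),
                    grade = sample(1:3, n, TRUE),
                    t_stage = sample(1:4, n, TRUE),
                    n_stage = sample(0:3, n, TRUE))
    pheno <- rbinom(n, 1, 0.4)
    d$pcr <- rbinom(n, 1, plogis(-1 + 0.15 * d$grade))
    r <- adjusted_pcr_model(d, stats::setNames(pheno == 1, d$sample))
    r$p[r$covariate == "phenocopy"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("phenocopy rate summaries use exact binomial intervals", {
  calls <- data.frame(sample = sprintf("s%02d", 1:10),
                      score = runif(10),
                      phenocopy = c(rep(TRUE, 8), rep(FALSE, 2)))
  r <- summarize_phenocopy_rates(calls,
    stats::setNames(rep("A", 10), calls$sample))
  expect_equal(r$proportion, 0.8)
  expect_equal(r$lower, 0.4439, tolerance = 1e-3)
  expect_equal(r$upper, 0.9748, tolerance = 1e-3)
  # single stratum equals the overall rate; empty stratum reports n = 0
  r2 <- summarize_phenocopy_rates(calls,
    factor(rep("A", 10), levels = c("A", "B")))
  expect_identical(r2$n, c(10L, 0L))
  expect_true(is.na(r2$proportion[2]))
})

test_that("longitudinal phenocopy proportions decrease under planted depletion", {
  co <- simulate_cohorts(quick_config(n_samples_per_cohort = 800L,
                                      n_cohorts = 1L, seed = 31L))
  truth_calls <- data.frame(sample = co$truth$sample,
                            score = as.numeric(co$truth$phenotype_positive),
                            phenocopy = co$truth$phenotype_positive)
  r <- summarize_phenocopy_rates(truth_calls,
    data.frame(sample = co$clinical$sample, stratum = co$clinical$timepoint))
  props <- stats::setNames(r$proportion, r$stratum)
  expect_gt(props[["pre"]], props[["on"]])
  expect_gt(props[["on"]], props[["post"]])
})
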