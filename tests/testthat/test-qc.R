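test_that("bsa computes Mosteller (and Du Bois) surface area", {
  expect_equal(bsa(180, 80), 2.0)
  expect_equal(bsa(160, 57.6), 1.6)
  expect_error(bsa(0, 70), "positive")
  expect_error(bsa(170, -1), "positive")
  # Du Bois at the classic reference point stays close to Mosteller
  expect_equal(bsa(180, 80, method = "dubois"),
               0.007184 * 180^0.725 * 80^0.425)
})

test_that("zscoreFlags matches the direct formula and its invariances", {
  v <- c(rep(0, 99), 100)
  fl <- zscoreFlags(v, k = 3)
  zref <- (v - mean(v)) / sd(v)          # direct formula, sample SD
  expect_equal(fl$zscore, zref)
  expect_identical(which(fl$excluded), 100L)

  expect_false(any(zscoreFlags(rep(5, 10))$excluded))   # SD = 0 rule
  expect_equal(zscoreFlags(rep(5, 10))$zscore, rep(0, 10))
  expect_false(any(zscoreFlags(rnorm(50), k = 1e6)$excluded))
  expect_error(zscoreFlags(3), "at least 2")

  # affine invariance: flags identical under v -> a*v + b
  set.seed(42)
  x <- rnorm(200)
  expect_identical(zscoreFlags(x, 2.5)$excluded,
                   zscoreFlags(-3.2 * x + 7, 2.5)$excluded)
})

test_that("k = 3 exclusion removes about 0.27% of a large normal cohort", {
  set.seed(7)
  n <- 500000
  fl <- zscoreFlags(rnorm(n), k = 3)
  p <- mean(fl$excluded)
  expected <- 2 * pnorm(-3)              # 0.0027
  tol <- 4 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p - expected), tol)
})

test_that("compareToManual summarizes and regresses percentage differences", {
  auto <- c(30, 32, 28, 35, 31)
  # identity: all zeros
  rep0 <- compareToManual(auto, auto)
  expect_equal(rep0$mean_diff_mm, 0)
  expect_equal(rep0$mean_pct_diff, 0)

  # injected multiplicative bias is recovered exactly
  rep1 <- compareToManual(auto * 1.023, auto)
  expect_equal(rep1$mean_pct_diff, 0.023)

  # antisymmetry of the mean difference under role swap
  manual <- auto * 1.01
  expect_equal(compareToManual(auto, manual)$mean_diff_mm,
               -compareToManual(manual, auto)$mean_diff_mm)

  expect_error(compareToManual(auto, c(30, 32, 28, 35, 0)), "positive")
  expect_error(compareToManual(30, 31), "at least 2")
})

test_that("error-model slopes match the closed-form OLS oracle", {
  set.seed(11)
  n <- 120
  cov <- data.frame(age = rnorm(n, 64, 8), bsa = rnorm(n, 1.9, 0.2),
                    sex = rbinom(n, 1, 0.5))
  manual <- rnorm(n, 30, 3)
  auto <- manual * (1 + rnorm(n, 0, 0.02))   # error independent of covariates
  rep <- compareToManual(auto, manual, covariates = cov)
  expect_false(rep$rank_deficient)

  # closed-form OLS: beta = (X'X)^{-1} X'y, SE from sigma^2 (X'X)^{-1}
  y <- (auto - manual) / manual
  X <- cbind(1, as.matrix(cov))
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(diag(sigma2 * solve(crossprod(X))))
  expect_equal(unname(rep$coefficients$slope), unname(as.numeric(beta)))
  expect_equal(unname(rep$coefficients$se), unname(se))

  # covariate-independent error: every slope within 3 SE of zero
  sl <- rep$coefficients[-1, ]
  expect_true(all(abs(sl$slope) < 3 * sl$se))

  # rank-deficient design flagged, coefficients withheld
  cov2 <- cov; cov2$age2 <- cov$age
  rep2 <- compareToManual(auto, manual, covariates = cov2)
  expect_true(rep2$rank_deficient)
  expect_null(rep2$coefficients)
})

test_that("exportPhenotypes writes QC'd tab-delimited phenotypes", {
  rec <- data.frame(
    subject_id = sprintf("S%d", 1:5),
    mitral_systole_mm = c(34, 35, 33, 36, 60),
    mitral_diastole_mm = c(28, 29, 27, 30, 55),
    sex = c(0, 1, 0, 1, 0), age = c(60, 62, 64, 66, 68),
    height = c(170, 180, NA, 175, 168),
    weight = c(70, 85, 66, 80, 72),
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  f <- tempfile(fileext = ".tsv")
  exportPhenotypes(rec, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 4L)                    # 5 records, 1 excluded
  expect_true(is.na(back$bsa[3]))                 # missing height -> empty BSA
  expect_equal(back$bsa[1], bsa(170, 70), tolerance = 1e-9)
  expect_equal(back$mitral_systole_mm, rec$mitral_systole_mm[1:4],
               tolerance = 1e-9)

  expect_error(exportPhenotypes(rec[rec$excluded, ], f), "no non-excluded")
})
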