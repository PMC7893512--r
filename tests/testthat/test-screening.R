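# Attenuation-corrected correlations, collinearity pruning, transforms.

test_that("attenuation correction follows the scalar formula", {
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  plain <- cor(x)
  expect_equal(attenuation_corrected_corr(x), plain,
               ignore_attr = TRUE)
  rel <- c(0.8, 0.9, 1.0)
  rc <- attenuation_corrected_corr(x, rel)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_equal(rc[i, j], 1)
    else expect_equal(rc[i, j], plain[i, j] / sqrt(rel[i] * rel[j]),
                      tolerance = 1e-12)
  }
})

test_that("corrected correlations above 1 are capped with a warning", {
  set.seed(4)
  z <- rnorm(200)
  x <- cbind(a = z, b = z + rnorm(200, 0, 0.1), c = rnorm(200))
  expect_warning(rc <- attenuation_corrected_corr(x, c(0.5, 0.5, 1)),
                 "capped")
  expect_equal(rc["a", "b"], 1)
  expect_true(attr(rc, "capped")["a", "b"])
})

test_that("pruning removes exactly one of a duplicated pair and is idempotent", {
  set.seed(6)
  x <- matrix(rnorm(500), 100, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  x[, 2] <- x[, 1]                                # exact duplicate
  rep1 <- prune_collinear(suppressWarnings(cor(x)))
  expect_equal(rep1$removed$variable, "v2")       # earlier-listed kept
  expect_setequal(rep1$retained, c("v1", "v3", "v4", "v5"))
  rep2 <- prune_collinear(rep1$corr)
  expect_equal(nrow(rep2$removed), 0)             # idempotent
  # nothing removed when all correlations are below threshold
  low <- diag(4); low[low == 0] <- 0.3
  colnames(low) <- rownames(low) <- paste0("w", 1:4)
  expect_equal(nrow(prune_collinear(low)$removed), 0)
  # outcome correlation drives which member is kept
  oc <- c(v1 = 0.1, v2 = 0.5, v3 = 0, v4 = 0, v5 = 0)
  rep3 <- prune_collinear(suppressWarnings(cor(x)), outcome_corr = oc)
  expect_equal(rep3$removed$variable, "v1")
})

test_that("a 69-variable set with built-in clones prunes to 38", {
  # 38 independent base variables + 31 near-clones of the first 31:
  # the greedy rule removes exactly the clones
  set.seed(8)
  n <- 400
  base <- matrix(rnorm(n * 38), n, 38,
                 dimnames = list(NULL, sprintf("base_%02d", 1:38)))
  clones <- base[, 1:31] + matrix(rnorm(n * 31, 0, 0.2), n, 31)
  colnames(clones) <- sprintf("clone_%02d", 1:31)
  x <- cbind(base, clones)
  rep <- prune_collinear(attenuation_corrected_corr(x), threshold = 0.70)
  expect_length(rep$retained, 38)
  expect_true(all(grepl("^base_", rep$retained)))
  expect_true(all(abs(rep$corr[upper.tri(rep$corr)]) <= 0.70))
})

test_that("transforms standardize, center and symmetrize as specified", {
  set.seed(10)
  x <- data.frame(cont = rnorm(1000),
                  pois = rpois(1000, 0.7),
                  bin = rbinom(1000, 1, 0.3))
  x$bin[1:300] <- 1; x$bin[301:1000] <- 0   # force mean exactly 0.3
  rec <- fit_transforms(x, c("continuous", "count", "binary"))
  xt <- apply_transforms(x, rec)
  # near-standard input: transform close to identity
  expect_lt(abs(rec$cont$location), 0.1)
  expect_gt(rec$cont$scale, 0.9); expect_lt(rec$cont$scale, 1.1)
  # skewed count: log1p applied before centering, skewness reduced
  expect_equal(rec$pois$skew_fix, "log1p")
  expect_lt(abs(e1071::skewness(xt$pois)),
            abs(e1071::skewness(x$pois)))
  # binary centered at its mean
  expect_setequal(round(unique(xt$bin), 10), c(-0.3, 0.7))
  # replaying the record on the training data is bit-identical
  expect_identical(xt, apply_transforms(x, rec))
  # standardizing a constant errors
  expect_error(fit_transforms(data.frame(k = rep(1, 10)), "continuous"),
               "zero-variance")
})

test_that("negative skewed variables get the shifted square root", {
  set.seed(12)
  v <- -rpois(500, 0.7) - 1
  rec <- fit_transforms(data.frame(v = v), "count")
  expect_equal(rec$v$skew_fix, "sqrt_shift")
  expect_equal(rec$v$shift, min(v))
  expect_false(anyNA(apply_transforms(data.frame(v = v), rec)$v))
})

test_that("transform records survive a JSON round trip", {
  set.seed(14)
  x <- data.frame(a = rnorm(50), b = rpois(50, 3))
  rec <- fit_transforms(x, c("continuous", "count"))
  f <- tempfile(fileext = ".json")
  write_transforms_json(rec, f)
  rec2 <- read_transforms_json(f)
  expect_equal(apply_transforms(x, rec2), apply_transforms(x, rec))
  unlink(f)
})
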