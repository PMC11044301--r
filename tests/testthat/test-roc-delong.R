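test_that("empirical AUC matches hand-computed pairwise values", {
  expect_equal(empirical_auc(c(3, 5), c(1, 4)), 0.75)
  x <- c(2, 5, 5, 9)
  expect_equal(empirical_auc(x, x), 0.5)           # identical multisets
  expect_equal(empirical_auc(c(10, 11), c(1, 2)), 1)
  expect_error(empirical_auc(numeric(0), 1), "non-empty")
})

test_that("empirical AUC equals the brute-force pairwise oracle on tied integer data", {
  set.seed(1)
  for (rep in 1:60) {
    m <- sample(1:12, 1); n <- sample(1:12, 1)
    pos <- sample(0:8, m, replace = TRUE)
    neg <- sample(0:8, n, replace = TRUE)
    expect_equal(empirical_auc(pos, neg), auc_bruteforce(pos, neg))
  }
})

test_that("empirical AUC agrees with pROC on continuous data", {
  skip_if_not_installed("pROC")
  set.seed(2)
  pos <- rnorm(40, 1); neg <- rnorm(30)
  r <- pROC::roc(rep(c(1, 0), c(40, 30)), c(pos, neg), quiet = TRUE,
                 direction = "<")
  expect_equal(empirical_auc(pos, neg), as.numeric(pROC::auc(r)))
})

test_that("DeLong variance matches the hand-computed structural components", {
  expect_equal(delong_variance(c(3, 5), c(1, 4)), 0.125)
  # perfect separation: all components degenerate, variance 0
  expect_equal(delong_variance(c(10, 11, 12), c(1, 2, 3)), 0)
  expect_error(delong_variance(1, c(1, 2)), ">= 2")
})

test_that("AUC and DeLong variance are invariant under strictly monotone transforms", {
  set.seed(3)
  pos <- rnorm(25, 1); neg <- rnorm(20)
  tr <- function(v) exp(3 * v) - 5
  expect_equal(empirical_auc(tr(pos), tr(neg)), empirical_auc(pos, neg))
  expect_equal(delong_variance(tr(pos), tr(neg)), delong_variance(pos, neg))
})

test_that("paired DeLong self-comparison gives z = 0, p = 1 for any data", {
  set.seed(4)
  for (rep in 1:5) {
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    m <- rnorm(30)
    dl <- delong_test(m, m, y)
    expect_equal(dl$z, 0)
    expect_equal(dl$p, 1)
  }
})

test_that("paired and unpaired DeLong tests agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rep(c(1, 0), c(35, 30))
  a <- rnorm(65, y); b <- rnorm(65, 0.5 * y)
  dl <- delong_test(a, b, y)
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                       pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p, pr$p.value)
  y2 <- rep(c(1, 0), c(28, 32))
  c2 <- rnorm(60, 0.8 * y2)
  dl2 <- delong_test(a, c2, y, labels_b = y2, design = "unpaired")
  pr2 <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y2, c2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  # same statistic; pROC refers it to a Welch t instead of the normal
  expect_equal(dl2$z, unname(pr2$statistic))
})

test_that("paired DeLong has power against an uninformative competitor", {
  set.seed(6)
  rejections <- 0
  for (rep in 1:40) {
    y <- rep(c(1, 0), each = 50)
    strong <- rnorm(100, 1.85 * y)     # AUC ~0.9
    weak <- rnorm(100)                 # AUC ~0.5
    if (delong_test(strong, weak, y)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 40, 0.8)
})

test_that("degenerate variance is handled: identical AUCs give p = 1, differing AUCs error", {
  y <- rep(c(1, 0), each = 3)
  a <- c(10, 11, 12, 1, 2, 3)          # perfect separation, variance 0
  b <- c(1, 2, 3, 10, 11, 12)          # perfect in the other direction
  expect_equal(delong_test(a, a, y)$p, 1)
  expect_error(delong_test(a, b, y), "degenerate variance")
})

test_that("AUC confidence interval is Wald with clipping", {
  expect_equal(unname(auc_ci(0.8, 0.0025)), c(0.702, 0.898), tolerance = 1e-3)
  expect_equal(unname(auc_ci(0.7, 0)), c(0.7, 0.7))
  expect_equal(auc_ci(0.99, 0.01)[["hi"]], 1)
})

test_that("ROC curve runs (0,0) to (1,1) monotonically and integrates to the AUC", {
  set.seed(8)
  pos <- rnorm(30, 1); neg <- rnorm(25)
  rc <- roc_curve(pos, neg)
  expect_equal(rc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(rc[nrow(rc), ]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
  expect_equal(trap, empirical_auc(pos, neg))
})

test_that("AUC bands follow the conventional boundaries", {
  expect_equal(auc_band(0.909), "excellent")
  expect_equal(auc_band(c(0.49, 0.5, 0.69, 0.7, 0.79, 0.8, 0.89, 0.9, 1)),
               c("worse than chance", "poor", "poor", "fair", "fair",
                 "good", "good", "excellent", "excellent"))
})
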