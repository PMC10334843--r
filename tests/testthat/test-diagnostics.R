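test_that("physiology formulas match hand arithmetic", {
  expect_identical(homa_ir(22.5, 1), 1)
  expect_identical(homa_ir(0, 50), 0)
  expect_equal(homa_ir(5, 9), 2)
  expect_error(homa_ir(-1, 2), "non-negative")
  expect_identical(bulk_redox_ratio(7, 0), 1)
  expect_identical(bulk_redox_ratio(3, 3), 0.5)
  expect_equal(bulk_redox_ratio(3, 7), 0.3)
  expect_error(bulk_redox_ratio(0, 0), "both")
})

test_that("bioenergetic metrics follow the injection-difference formulas", {
  ocr <- data.frame(epoch = rep(c("baseline", "oligomycin", "FCCP", "rot_aa"),
                                each = 3),
                    rate = rep(c(100, 40, 160, 20), each = 3))
  m <- seahorse_metrics(ocr, "OCR")
  expect_equal(m$basal_respiration, 80)
  expect_equal(m$atp_production, 60)
  expect_equal(m$maximal_respiration, 140)
  flat <- transform(ocr, rate = 55)
  mf <- seahorse_metrics(flat, "OCR")
  expect_equal(unlist(mf), c(basal_respiration = 0, atp_production = 0,
                             maximal_respiration = 0))
  ecar <- data.frame(epoch = c("baseline", "glucose", "oligomycin", "2-DG"),
                     rate = c(5, 30, 50, 8))
  me <- seahorse_metrics(ecar, "ECAR")
  expect_equal(me$glycolysis, 30)
  expect_equal(me$glycolytic_capacity, 50)
  expect_equal(me$glycolytic_reserve, 20)
  expect_error(seahorse_metrics(ocr[ocr$epoch != "FCCP", ], "OCR"), "FCCP")
})

make_readouts <- function(n = 10, shift = c(OR1 = 0), seed = 1) {
  withr::with_seed(seed, {
    ctrl <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    test <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(ctrl) <- names(test) <- paste0("OR", 1:9)
    for (cn in names(shift)) test[[cn]] <- test[[cn]] + shift[[cn]]
    ctrl$group <- "control"; test$group <- "prediabetic"
    rbind(ctrl, test)
  })
}

test_that("Z-scoring centres the reference group and is invertible", {
  tab <- make_readouts(n = 20, shift = c(OR1 = 1), seed = 2)
  zs <- zscore_table(tab, "control")
  ref <- zs$z[zs$z$group == "control", paste0("OR", 1:9)]
  expect_true(all(abs(colMeans(ref)) < 1e-12))
  expect_true(all(abs(apply(ref, 2, sd) - 1) < 1e-12))
  back <- unzscore_table(zs$z, zs)
  expect_true(all(abs(as.matrix(back[paste0("OR", 1:9)]) -
                      as.matrix(tab[paste0("OR", 1:9)])) < 1e-10))
  # shifting a test group by +1 reference SD moves its mean Z to ~1
  tab2 <- make_readouts(n = 400, seed = 3)
  sd1 <- sd(tab2$OR3[tab2$group == "control"])
  tab2$OR3[tab2$group == "prediabetic"] <-
    tab2$OR3[tab2$group == "prediabetic"] + sd1
  zs2 <- zscore_table(tab2, "control")
  expect_equal(zs2$heat["prediabetic", "OR3"], 1, tolerance = 0.2)
})

test_that("Z-scoring matches a hand-computed table and flags zero SD", {
  tab <- data.frame(OR1 = c(1, 3, 10, 20), OR2 = c(2, 2, 5, 9),
                    group = c("control", "control", "sick", "sick"))
  zs <- zscore_table(tab, "control")
  expect_equal(zs$z$OR1, (c(1, 3, 10, 20) - 2) / sqrt(2))
  expect_equal(zs$flagged, "OR2")
  expect_true(all(is.na(zs$z$OR2)))
  expect_error(zscore_table(tab, "nope"), "not present")
})

test_that("logistic fits recover the 2x2 odds ratio and flag separation", {
  # grouped binary exposure/outcome: OR = ad/bc
  a <- 20; b <- 10; cc <- 8; d <- 25
  x <- c(rep(1, a + b), rep(0, cc + d))
  y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  m <- logistic_fit(data.frame(x = x), y)
  expect_equal(unname(m$or[2]), (a * d) / (b * cc), tolerance = 1e-6)
  expect_false(m$separation)

  set.seed(8)
  noise <- data.frame(x = rnorm(60))
  yy <- rep(0:1, 30)
  mn <- logistic_fit(noise, yy)
  expect_gt(mn$p[[2]], 0.05)
  expect_equal(unname(mn$or[2]), 1, tolerance = 0.5)

  sep <- data.frame(x = c(1:5, 11:15))
  ys <- rep(0:1, each = 5)
  expect_warning(ms <- logistic_fit(sep, ys), "separation")
  expect_true(ms$separation)
  expect_true(all(abs(ms$coefficients) <= 15))
  expect_error(logistic_fit(data.frame(x = 1:4), c(1, 1, 1, 1)), "classes")
})

test_that("logistic coefficients equal an independent Newton solver", {
  set.seed(10)
  X <- cbind(rnorm(20), runif(20, -1, 1))
  y <- rbinom(20, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  m <- logistic_fit(as.data.frame(X), y)
  Xd <- cbind(1, X)
  beta <- rep(0, 3)
  for (it in 1:50) {
    p <- plogis(Xd %*% beta)
    W <- as.numeric(p * (1 - p))
    beta <- beta + solve(t(Xd) %*% (Xd * W), t(Xd) %*% (y - p))
  }
  expect_equal(unname(m$coefficients), as.numeric(beta), tolerance = 1e-6)
})

test_that("the univariate screen isolates bad columns and flags real effects", {
  tab <- make_readouts(n = 30, shift = c(OR2 = 1.5), seed = 12)
  tab$OR7 <- 1                                  # constant column
  y <- as.integer(tab$group == "prediabetic")
  sc <- univariate_screen(tab, y)
  expect_equal(nrow(sc), 9)
  bad <- sc[sc$readout == "OR7", ]
  expect_false(is.na(bad$error))
  expect_true(all(is.na(sc$p[sc$readout == "OR7"])))
  expect_false(any(!is.na(sc$error[sc$readout != "OR7"])))
  strong <- sc[sc$readout == "OR2", ]
  expect_true(strong$flagged)
  expect_gt(strong$ci_lo, 1)                    # CI excludes 1
})

test_that("LOOCV equals an explicit refit loop and sits below resubstitution", {
  X <- data.frame(x = c(-2.1, -1.4, -0.9, 0.8, 1.7, 2.3))
  y <- c(0, 0, 0, 1, 1, 1)
  res <- suppressWarnings(loocv_accuracy(X, y))
  manual <- sapply(1:6, function(i) {
    g <- suppressWarnings(glm(yy ~ x, data = cbind(X[-i, , drop = FALSE],
                                                   yy = y[-i]),
                              family = binomial()))
    as.integer(predict(g, newdata = X[i, , drop = FALSE],
                       type = "response") >= 0.5)
  })
  expect_identical(res$predictions, manual)
  expect_equal(res$resubstitution, 1)           # perfectly separated data

  # label-independent features: LOOCV near majority-class fraction, and
  # on average no better than resubstitution
  set.seed(14)
  gap <- replicate(25, {
    Xn <- data.frame(x = rnorm(60))
    yn <- rep(0:1, each = 30)
    r <- suppressWarnings(loocv_accuracy(Xn, yn))
    c(r$loocv, r$resubstitution)
  })
  expect_lt(mean(gap[1, ]), mean(gap[2, ]))
  expect_lt(abs(mean(gap[1, ]) - 0.5), 0.12)
})

test_that("ROC analysis matches rank statistics and tie conventions", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  r <- roc_auc(scores, y)
  expect_equal(r$auc, 0.75)
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  # Mann-Whitney oracle on random fixtures, including ties
  set.seed(15)
  for (rep in 1:5) {
    s <- sample(round(runif(40, 0, 5), 1))
    yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    r1 <- sum(rank(s)[yy == 1])
    u <- r1 - sum(yy) * (sum(yy) + 1) / 2
    expect_equal(roc_auc(s, yy)$auc, u / (sum(yy) * sum(1 - yy)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "classes")
})

test_that("ROC curves are monotone and agree with an established library", {
  skip_if_not_installed("pROC")
  set.seed(16)
  s <- rnorm(50); y <- rbinom(50, 1, plogis(s))
  r <- roc_auc(s, y)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$auc, as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-12)
})

test_that("PCA returns orthonormal sign-fixed loadings matching eigen analysis", {
  set.seed(17)
  x <- matrix(rnorm(15), 5, 3)
  p <- pca_fit(x, n_components = 3, standardize = TRUE)
  g <- t(p$loadings) %*% p$loadings
  expect_equal(g, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  ev <- eigen(stats::cov(scale(x)))
  for (j in 1:3)
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_equal(p$all_prop_var, ev$values / sum(ev$values), tolerance = 1e-10)
  for (j in 1:3)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # data varying along a single axis: PC1 carries all the variance
  t1 <- seq(-1, 1, length.out = 8)
  one <- cbind(2 * t1, -t1, 0.5 * t1) + matrix(5, 8, 3)
  p1 <- pca_fit(one, standardize = FALSE)
  expect_equal(p1$prop_var[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(cbind(1:4, rep(2, 4))), "zero-variance")
})

test_that("group comparisons reproduce textbook statistics", {
  a <- c(5.1, 4.9, 5.6, 4.7, 5.0)
  b <- c(6.0, 6.2, 5.8, 6.4, 6.1)
  g <- group_compare(c(a, b), rep(c("x", "y"), each = 5))
  sp <- sqrt((4 * var(a) + 4 * var(b)) / 8)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 5))
  expect_equal(g$statistic, t_hand)
  expect_equal(g$method, "t-test")
  # two-group ANOVA F equals t^2
  f2 <- summary(aov(v ~ gr, data = data.frame(v = c(a, b),
                                              gr = rep(c("x", "y"), each = 5))))
  expect_equal(f2[[1]][["F value"]][1], t_hand^2)
  g3 <- group_compare(c(a, b, a + 3), rep(c("x", "y", "z"), each = 5))
  expect_equal(g3$method, "anova+tukey")
  expect_equal(nrow(g3$tukey), 3)
  expect_error(group_compare(1:3, c("x", "x", "y")), ">= 2 values")
})

test_that("null group comparisons produce uniform p-values", {
  ps <- sapply(1:400, function(s) {
    withr::with_seed(s, group_compare(rnorm(20), rep(c("a", "b"), each = 10))$p)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
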