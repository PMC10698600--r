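test_that("design matrices follow the feature-group selectors", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, seed = 4))
  expect_equal(ncol(build_design(co, "GA")$x), 1)
  expect_equal(ncol(build_design(co, "L")$x), 78)
  expect_equal(ncol(build_design(co, "PC")$x), 7)
  expect_equal(ncol(build_design(co, "PCL")$x), 85)
  expect_error(build_design(co, "XY"), "selector")

  # missing values are excluded with a logged count
  co$gestational_age_wk[1:3] <- NA
  expect_message(d <- build_design(co, "P"), "excluded 3")
  expect_equal(nrow(d$x), 57)
  expect_equal(d$n_excluded, 3)

  # constant columns are dropped with a warning
  co2 <- generate_cohort(cohort_spec(n_subjects = 40, seed = 5))
  co2$sex <- 1
  expect_warning(d2 <- build_design(co2, "P"), "constant")
  expect_false("sex" %in% colnames(d2$x))
})

test_that("scaling is fitted on training folds only (no test-fold leakage)", {
  set.seed(2)
  x <- matrix(stats::rnorm(200 * 5, mean = 3), 200, 5)
  tr <- 1:150; te <- 151:200
  pp <- lungmorph:::make_preproc(x[tr, ], factor(rep(1:2, 75)),
                                 rep(TRUE, 5), "none", list())
  expect_equal(unname(colMeans(pp(x[tr, , drop = FALSE]))), rep(0, 5),
               tolerance = 1e-10)
  expect_gt(max(abs(colMeans(pp(x[te, , drop = FALSE])))), 0.01)
})

test_that("a perfectly separating feature drives nested-CV AUC to 1", {
  co <- generate_cohort(cohort_spec(n_subjects = 80, seed = 6))
  co$left_volume_mm3 <- as.numeric(co$severity != "none")  # oracle feature
  des <- build_design(co, "L")
  res <- nested_cv_classify(des, "bpd_any", "elastic_net", "none",
                            plan = cv_plan(repetitions = 2, seed = 3),
                            search_budget = 4)
  expect_equal(glance(res)$mean_auc, 1, tolerance = 1e-6)
})

test_that("nested CV is reproducible and errors when a class cannot be stratified", {
  co <- generate_cohort(cohort_spec(n_subjects = 70, seed = 8))
  des <- build_design(co, "PC")
  plan <- cv_plan(repetitions = 2, seed = 11)
  r1 <- nested_cv_classify(des, "bpd_any", "elastic_net", "none", plan, 3)
  r2 <- nested_cv_classify(des, "bpd_any", "elastic_net", "none", plan, 3)
  expect_identical(r1$per_repetition$auc, r2$per_repetition$auc)

  # a singleton class is necessarily absent from one outer training fold
  co1 <- co[co$severity != "moderate", ]
  co1 <- rbind(co1, co[co$severity == "moderate", ][1, ])
  des1 <- build_design(co1, "PC")
  expect_error(
    nested_cv_classify(des1, "multinomial", "elastic_net", "none", plan, 2),
    "stratification error"
  )
})

test_that("multinomial macro-weighted AUC equals the plain mean for balanced classes", {
  set.seed(13)
  y <- factor(rep(bpd_grades(), each = 25), levels = bpd_grades())
  prob <- matrix(stats::runif(100 * 4), 100, 4,
                 dimnames = list(NULL, bpd_grades()))
  prob <- prob / rowSums(prob)
  a <- lungmorph:::pooled_auc(y, prob)
  expect_equal(unname(a["auc"]), unname(a["auc_unweighted"]), tolerance = 1e-12)
})

test_that("regression: constant baseline, planted ordering, finite MAE on overdispersion", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, seed = 11))
  des <- build_design(co, "PCL")
  des_ga <- build_design(co, "GA")
  plan <- cv_plan(repetitions = 5, seed = 5)
  mae_pcl <- mean(suppressWarnings(
    nested_cv_regress(des, model = "poisson", plan = plan, search_budget = 6)
  )$mae)
  mae_ga <- mean(suppressWarnings(
    nested_cv_regress(des_ga, model = "poisson", plan = plan, search_budget = 6)
  )$mae)
  expect_true(is.finite(mae_pcl))  # robust under negative-binomial responses
  expect_lt(mae_pcl, mae_ga)       # lung features add signal beyond GA

  # constant response: the fitted constant predictor achieves MAE 0
  des0 <- des_ga
  r0 <- suppressWarnings(
    nested_cv_regress(des0, response = rep(5L, nrow(des0$x)),
                      model = "poisson",
                      plan = cv_plan(repetitions = 1, seed = 2),
                      search_budget = 2)
  )
  expect_lt(r0$mae[1], 0.05)
  expect_error(nested_cv_regress(des0, response = c(-1, rep(1, nrow(des0$x) - 1)),
                                 model = "poisson"), "nonnegative")
})

test_that("permutation importance ranks a separating feature first, noise near zero", {
  set.seed(3)
  n <- 150
  y <- factor(rep(c("neg", "pos"), length.out = n))
  x <- cbind(sep = as.numeric(y == "pos") + stats::rnorm(n, sd = 0.1),
             noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  fit <- fit_classifier(x, y, "elastic_net",
                        params = list(alpha = 0.5, lambda = 0.01))
  imp <- permutation_importance(fit, x, y, n_repeats = 100, seed = 5)
  expect_equal(imp$feature[1], "sep")
  noise_imp <- imp$importance[imp$feature != "sep"]
  expect_true(all(abs(noise_imp) < 0.02))

  # invariant to column order
  imp2 <- permutation_importance(fit2 <- fit, x[, c(1, 3, 2)], y,
                                 n_repeats = 100, seed = 5)
  # refit on permuted columns for a fair check
  fitp <- fit_classifier(x[, c(2, 1, 3)], y, "elastic_net",
                         params = list(alpha = 0.5, lambda = 0.01))
  impp <- permutation_importance(fitp, x[, c(2, 1, 3)], y,
                                 n_repeats = 100, seed = 5)
  expect_equal(impp$feature[1], "sep")

  # single column: the unpenalized fallback separates perfectly, so glm's
  # separation warnings are expected here
  imp1 <- suppressWarnings(permutation_importance(
    fit_classifier(x[, 1, drop = FALSE], y, "elastic_net"),
    x[, 1, drop = FALSE], y, n_repeats = 10, seed = 1
  ))
  expect_match(attr(imp1, "note"), "single-column")
})

test_that("Spearman matrix reproduces the textbook rank formula and flags constants", {
  dat <- data.frame(x = 1:6, y = c(10, 20, 30, 50, 40, 60),
                    z = c(2, 4, 6, 8, 10, 12), k = rep(1, 6))
  cm <- feature_correlation_matrix(dat, features = c("x", "k"),
                                   targets = c("y", "z"))
  # ranks of y differ from 1:6 by two swaps: rho = 1 - 6*2/(6*35)
  expect_equal(cm$rho[cm$feature == "x" & cm$target == "y"], 1 - 12 / 210)
  # monotone transform: rank invariance
  expect_equal(cm$rho[cm$feature == "x" & cm$target == "z"], 1)
  expect_match(cm$flag[cm$feature == "k"][1], "undefined")
  expect_equal(attr(cm, "alpha_adjusted"), 0.05 / 4)
  # self correlation
  cs <- feature_correlation_matrix(dat, "x", "x")
  expect_equal(cs$rho, 1)
})

test_that("severity group tests expose Kruskal-Wallis and Bonferroni pairwise results", {
  co <- generate_cohort(cohort_spec(n_subjects = 150, seed = 9))
  st <- severity_group_tests(co, "left_volume_mm3")
  expect_lt(st$kruskal_p, 0.01)  # planted effect separates grades
  expect_true(all(c("group1", "group2", "p_adjusted") %in% names(st$pairwise)))
  expect_true(all(st$pairwise$p_adjusted <= 1))
  null_st <- severity_group_tests(co, "left_intensity_entropy")
  expect_gt(null_st$kruskal_p, 0.001)
})
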