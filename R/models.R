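#' Nested cross-validation plan
#'
#' Stratified k-fold plans for the outer (performance estimation) and
#' inner (hyperparameter selection) loops, repeated with reshuffled folds.
#'
#' @param outer_folds,inner_folds stratified fold counts (default 5 / 5).
#' @param repetitions independent repetitions (default 10).
#' @param seed integer; all fold shuffles and search draws derive from it.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 5L, inner_folds = 5L, repetitions = 10L,
                    seed = 1L) {
  assert_that(outer_folds >= 2 && inner_folds >= 2,
              "fold counts must be >= 2")
  assert_that(repetitions >= 1, "repetitions must be >= 1")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Build a design matrix from a cohort by feature groups
#'
#' Selects columns by the grouped explanatory variables: `L` (the 78 lung
#' MRI features), `P` (patient attributes: gestational age, birth weight,
#' body size, sex) and `C` (postnatal clinical adaptation: 5-minute Apgar,
#' early-onset infection, steroid treatment); the selector `"GA"` uses
#' gestational age alone as the clinical baseline. Subjects with missing
#' values in the selected columns are excluded with a logged count.
#' Continuous columns are flagged for standardization, which is fitted on
#' training folds only inside the cross-validation loops (never here).
#'
#' @param cohort a [generate_cohort()] tibble (or a data frame with the
#'   same columns).
#' @param selector `"GA"` or any combination of the letters `L`, `P`, `C`
#'   (e.g. `"PC"`, `"PCL"`).
#' @return A list of class `bpd_design`: `x` (numeric matrix), `y`
#'   (severity factor), `continuous` (logical per column), `selector`,
#'   `n_excluded`, plus the indicator columns `ventilation_days` /
#'   `oxygen_days` when present.
#' @export
build_design <- function(cohort, selector = "PCL") {
  p_cols <- c("gestational_age_wk", "birth_weight_g", "body_size_cm", "sex")
  c_cols <- c("apgar5", "early_infection", "steroids")
  l_cols <- feature_manifest()$name
  selector <- toupper(selector)
  cols <- if (selector == "GA") {
    "gestational_age_wk"
  } else {
    assert_that(grepl("^[LPC]+$", selector),
                "selector must be 'GA' or a combination of L, P, C")
    unique(c(
      if (grepl("P", selector)) p_cols,
      if (grepl("C", selector)) c_cols,
      if (grepl("L", selector)) l_cols
    ))
  }
  missing_cols <- setdiff(cols, names(cohort))
  assert_that(length(missing_cols) == 0,
              paste("cohort lacks columns:",
                    paste(utils::head(missing_cols, 5), collapse = ", ")))
  keep <- stats::complete.cases(cohort[, c(cols, "severity")])
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("excluded %d subject(s) with missing values", n_excluded))
  }
  dat <- cohort[keep, ]
  x <- as.matrix(dat[, cols])
  storage.mode(x) <- "double"
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning(sprintf("dropped %d all-constant column(s): %s",
                    sum(constant),
                    paste(utils::head(cols[constant], 5), collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  binary <- apply(x, 2, function(v) all(v %in% c(0, 1)))
  structure(
    list(x = x, y = factor(dat$severity, levels = bpd_grades()),
         continuous = !binary, selector = selector,
         n_excluded = n_excluded,
         ventilation_days = dat$ventilation_days %||% NULL,
         oxygen_days = dat$oxygen_days %||% NULL,
         subject_id = dat$subject_id %||% NULL),
    class = "bpd_design"
  )
}

# ---- internal CV machinery ----------------------------------------------

# stratified fold assignment; preserves class proportions within +-1
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- sample(which(y == cl))
    if (length(idx)) {
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  }
  fold
}

check_training_classes <- function(y, fold, k) {
  for (f in seq_len(k)) {
    present <- unique(y[fold != f])
    if (length(present) < length(levels(factor(y)))) {
      stop("stratification error: class '",
           setdiff(levels(factor(y)), present)[1],
           "' absent from an outer training fold", call. = FALSE)
    }
  }
}

scenario_labels <- function(y, scenario) {
  switch(scenario,
         bpd_any = factor(ifelse(y == "none", "neg", "pos"),
                          levels = c("neg", "pos")),
         modsev = factor(ifelse(y %in% c("none", "mild"), "neg", "pos"),
                         levels = c("neg", "pos")),
         multinomial = factor(as.character(y), levels = bpd_grades()),
         stop("unknown scenario: ", scenario, call. = FALSE))
}

draw_params <- function(model, p) {
  if (model == "elastic_net") {
    list(alpha = stats::runif(1), lambda = 10^stats::runif(1, -4, 0.5))
  } else {
    list(num_trees = sample(c(100L, 200L, 300L), 1),
         mtry = max(1L, floor(stats::runif(1, 0.1, 0.9) * p)),
         min_node = sample(1:10, 1))
  }
}

draw_reduction <- function(reduction, p) {
  if (reduction == "ufs") {
    ks <- unique(pmin(p, c(5L, 10L, 20L, 40L, p)))
    list(k = sample(ks, 1))
  } else if (reduction == "pca") {
    list(ncomp = sample(2:max(2, min(20L, p)), 1))
  } else {
    list()
  }
}

# ANOVA F score per column (between/within group variance ratio)
anova_f_scores <- function(x, y) {
  y <- factor(y)
  n <- nrow(x)
  gm <- colMeans(x)
  ssb <- 0 * gm
  ssw <- 0 * gm
  for (cl in levels(y)) {
    xs <- x[y == cl, , drop = FALSE]
    nc <- nrow(xs)
    if (nc == 0) next
    mc <- colMeans(xs)
    ssb <- ssb + nc * (mc - gm)^2
    ssw <- ssw + colSums(sweep(xs, 2, mc)^2)
  }
  dfb <- nlevels(y) - 1
  dfw <- n - nlevels(y)
  f <- (ssb / dfb) / (ssw / dfw)
  f[!is.finite(f)] <- 0
  f
}

# fit scaling + optional reduction on training data only
make_preproc <- function(xtr, ytr, continuous, reduction, rpar) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  mu[!continuous] <- 0
  sdv[!continuous] <- 1
  scale_fun <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  xs <- scale_fun(xtr)
  if (reduction == "ufs") {
    keep <- order(-anova_f_scores(xs, ytr))[seq_len(min(rpar$k, ncol(xs)))]
    function(x) scale_fun(x)[, keep, drop = FALSE]
  } else if (reduction == "pca") {
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    nc <- min(rpar$ncomp, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(nc), drop = FALSE]
    function(x) scale_fun(x) %*% rot
  } else {
    scale_fun
  }
}

#' Fit a severity classifier
#'
#' Single-model fit used inside the nested cross-validation and for
#' permutation importance: elastic-net-regularized logistic regression
#' (binomial or multinomial, via glmnet) or a probability random forest
#' (via ranger). One-column designs fall back to an unpenalized GLM /
#' multinomial logit.
#'
#' @param x numeric design matrix (preprocessed).
#' @param y factor of class labels (2 or more levels).
#' @param model `"elastic_net"` or `"random_forest"`.
#' @param params hyperparameter list (`alpha`/`lambda`, or
#'   `num_trees`/`mtry`/`min_node`); sensible defaults when `NULL`.
#' @param seed integer seed (random forest only).
#' @return An object of class `lung_classifier` with a
#'   [predict_prob()] method.
#' @export
fit_classifier <- function(x, y, model = c("elastic_net", "random_forest"),
                           params = NULL, seed = 1L) {
  model <- match.arg(model)
  y <- droplevels(factor(y))
  assert_that(nlevels(y) >= 2, "need at least 2 classes present")
  if (model == "elastic_net") {
    params <- params %||% list(alpha = 0.5, lambda = 0.01)
    if (ncol(x) < 2) {
      df <- data.frame(y = y, x1 = x[, 1])
      fit <- if (nlevels(y) == 2) {
        stats::glm(y ~ x1, data = df, family = stats::binomial())
      } else {
        nnet::multinom(y ~ x1, data = df, trace = FALSE)
      }
      obj <- list(kind = "glm1", fit = fit, levels = levels(y))
    } else {
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x, y, family = fam, alpha = params$alpha,
                            lambda = params$lambda)
      obj <- list(kind = "glmnet", fit = fit, lambda = params$lambda,
                  levels = levels(y))
    }
  } else {
    params <- params %||% list(num_trees = 200L,
                               mtry = max(1L, floor(sqrt(ncol(x)))),
                               min_node = 5L)
    dat <- data.frame(.y = y, x, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = params$num_trees, mtry = min(params$mtry, ncol(x)),
      min.node.size = params$min_node, probability = TRUE,
      seed = as.integer(seed), num.threads = 1
    )
    obj <- list(kind = "ranger", fit = fit, levels = levels(y))
  }
  structure(obj, class = "lung_classifier")
}

#' Class-probability predictions from a fitted classifier
#'
#' @param object a [fit_classifier()] result.
#' @param x numeric matrix on the same columns the model was fitted on.
#' @return A matrix (rows = samples, columns = class levels) of
#'   probabilities.
#' @export
predict_prob <- function(object, x) {
  lv <- object$levels
  if (object$kind == "glm1") {
    if (inherits(object$fit, "glm")) {
      p <- stats::predict(object$fit, newdata = data.frame(x1 = x[, 1]),
                          type = "response")
      cbind(1 - p, p, deparse.level = 0) -> out
    } else {
      out <- stats::predict(object$fit,
                            newdata = data.frame(x1 = x[, 1]), type = "probs")
      if (is.null(dim(out))) out <- cbind(1 - out, out, deparse.level = 0)
    }
  } else if (object$kind == "glmnet") {
    pr <- stats::predict(object$fit, newx = x, s = object$lambda,
                         type = "response")
    out <- if (length(dim(pr)) == 3) {
      pr[, , 1]
    } else {
      cbind(1 - pr[, 1], pr[, 1], deparse.level = 0)
    }
  } else {
    out <- stats::predict(object$fit, data = data.frame(x, check.names = FALSE),
                          num.threads = 1)$predictions
  }
  out <- as.matrix(out)
  if (!is.null(colnames(out)) && all(lv %in% colnames(out))) {
    out <- out[, lv, drop = FALSE]
  } else {
    colnames(out) <- lv[seq_len(ncol(out))]
  }
  out
}

# AUC of pooled predictions; macro-weighted one-vs-rest for > 2 classes
pooled_auc <- function(y, prob) {
  y <- factor(y)
  if (nlevels(y) == 2) {
    a <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = prob[, 2],
      levels = levels(y), direction = "<", quiet = TRUE
    )))
    return(c(auc = a, auc_unweighted = a))
  }
  aucs <- w <- numeric(0)
  for (cl in levels(y)) {
    truth <- factor(ifelse(y == cl, "pos", "neg"), levels = c("neg", "pos"))
    if (length(unique(truth)) < 2) next
    a <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = prob[, cl],
      levels = c("neg", "pos"), direction = "<", quiet = TRUE
    )))
    aucs <- c(aucs, a)
    w <- c(w, mean(y == cl))
  }
  c(auc = sum(aucs * w / sum(w)), auc_unweighted = mean(aucs))
}

#' Nested cross-validated severity classification
#'
#' Estimates out-of-sample discrimination with a repeated, stratified
#' nested cross-validation: hyperparameters are chosen by randomized
#' search scored on inner folds strictly inside each outer training fold;
#' scaling and any dimensionality reduction are fitted on training folds
#' only; outer-fold predictions are pooled per repetition and summarized
#' as AUC (macro-weighted one-vs-rest for the multinomial scenario, with
#' the unweighted mean reported alongside).
#'
#' @param design a [build_design()] result.
#' @param scenario `"bpd_any"` (no BPD vs BPD), `"modsev"` (no/mild vs
#'   moderate/severe) or `"multinomial"` (4 grades).
#' @param model `"elastic_net"` or `"random_forest"`.
#' @param reduction `"none"`, `"ufs"` (univariate ANOVA-F selection, k
#'   tuned by the inner loop) or `"pca"` (component count tuned).
#' @param plan a [cv_plan()].
#' @param search_budget randomized-search draws per inner loop.
#' @return An object of class `bpd_cv_result`; see [tidy.bpd_cv_result()]
#'   and [glance.bpd_cv_result()].
#' @export
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_spec(n_subjects = 80, seed = 2))
#' des <- build_design(co, "PCL")
#' res <- nested_cv_classify(des, "bpd_any",
#'   plan = cv_plan(repetitions = 2, seed = 1), search_budget = 4)
#' glance(res)
#' }
nested_cv_classify <- function(design, scenario = "bpd_any",
                               model = c("elastic_net", "random_forest"),
                               reduction = c("none", "ufs", "pca"),
                               plan = cv_plan(), search_budget = 20L) {
  model <- match.arg(model)
  reduction <- match.arg(reduction)
  assert_that(inherits(design, "bpd_design"), "design must come from build_design()")
  x <- design$x
  labels <- scenario_labels(design$y, scenario)
  assert_that(nlevels(droplevels(labels)) >= 2,
              "need at least 2 classes present in the labels")
  p <- ncol(x)
  reps <- vector("list", plan$repetitions)
  for (r in seq_len(plan$repetitions)) {
    reps[[r]] <- with_seed(child_seed(plan$seed, r), {
      fold <- stratified_folds(labels, plan$outer_folds)
      check_training_classes(labels, fold, plan$outer_folds)
      pooled_prob <- matrix(NA_real_, nrow(x), nlevels(labels),
                            dimnames = list(NULL, levels(labels)))
      best_params <- list()
      for (f in seq_len(plan$outer_folds)) {
        tr <- which(fold != f)
        te <- which(fold == f)
        inner_fold <- stratified_folds(labels[tr], plan$inner_folds)
        best <- NULL
        for (d in seq_len(search_budget)) {
          par <- draw_params(model, p)
          rpar <- draw_reduction(reduction, p)
          iprob <- matrix(NA_real_, length(tr), nlevels(labels),
                          dimnames = list(NULL, levels(labels)))
          ok <- TRUE
          for (g in seq_len(plan$inner_folds)) {
            itr <- tr[inner_fold != g]
            ite <- tr[inner_fold == g]
            if (length(unique(labels[itr])) < nlevels(droplevels(labels)) ||
                length(ite) == 0) {
              next
            }
            pp <- make_preproc(x[itr, , drop = FALSE], labels[itr],
                               design$continuous, reduction, rpar)
            fit <- fit_classifier(pp(x[itr, , drop = FALSE]), labels[itr],
                                  model, par, seed = child_seed(plan$seed, r * 100 + d))
            iprob[match(ite, tr), ] <- predict_prob(fit, pp(x[ite, , drop = FALSE]))
          }
          scored <- !is.na(iprob[, 1])
          if (!any(scored)) ok <- FALSE
          score <- if (ok) {
            pooled_auc(droplevels(labels[tr][scored]),
                       iprob[scored, , drop = FALSE])["auc"]
          } else {
            -Inf
          }
          if (is.null(best) || score > best$score) {
            best <- list(score = score, par = par, rpar = rpar)
          }
        }
        pp <- make_preproc(x[tr, , drop = FALSE], labels[tr],
                           design$continuous, reduction, best$rpar)
        fit <- fit_classifier(pp(x[tr, , drop = FALSE]), labels[tr], model,
                              best$par, seed = child_seed(plan$seed, r))
        pooled_prob[te, ] <- predict_prob(fit, pp(x[te, , drop = FALSE]))
        best_params[[f]] <- best$par
      }
      a <- pooled_auc(labels, pooled_prob)
      tibble::tibble(repetition = r, auc = a["auc"],
                     auc_unweighted = a["auc_unweighted"],
                     best_alpha = mean(vapply(best_params, function(b) b$alpha %||% NA_real_, 1)),
                     best_lambda = mean(vapply(best_params, function(b) b$lambda %||% NA_real_, 1)))
    })
  }
  out <- structure(
    list(per_repetition = dplyr::bind_rows(reps), scenario = scenario,
         model = model, reduction = reduction, plan = plan,
         selector = design$selector, n = nrow(x), p = p),
    class = "bpd_cv_result"
  )
  out
}

#' @export
print.bpd_cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bpd_cv_result> %s | %s | %s | reduction %s\n  mean AUC %.3f +- %.3f over %d repetitions (n=%d, p=%d)\n",
    x$scenario, x$selector, x$model, x$reduction,
    g$mean_auc, g$sd_auc, x$plan$repetitions, x$n, x$p
  ))
  invisible(x)
}

#' Nested cross-validated regression for continuous BPD indicators
#'
#' Estimates the duration of respiratory support (nonnegative day counts)
#' with a Poisson regression or a random-forest regressor under the same
#' nested scheme and leakage discipline as the classifier; reports the
#' outer-fold mean absolute error (MAE) per repetition. The Poisson model
#' is elastic-net penalized (glmnet, penalty tuned on inner folds): with
#' p of the order of n an unpenalized Poisson GLM separates and its
#' exponential inverse link overflows on held-out subjects. Predictions
#' are additionally capped at ten times the largest training response so
#' the MAE stays finite even under gross misspecification.
#'
#' @param design a [build_design()] result.
#' @param response nonnegative integer counts (e.g. ventilation days);
#'   defaults to the design's `ventilation_days`.
#' @param model `"poisson"` or `"random_forest"`.
#' @param plan a [cv_plan()].
#' @param search_budget randomized-search draws per inner loop.
#' @return A tibble with `repetition` and `mae`, of class
#'   `bpd_regression_result`.
#' @export
nested_cv_regress <- function(design, response = design$ventilation_days,
                              model = c("poisson", "random_forest"),
                              plan = cv_plan(), search_budget = 10L) {
  model <- match.arg(model)
  assert_that(inherits(design, "bpd_design"), "design must come from build_design()")
  assert_that(!is.null(response), "no response supplied")
  assert_that(all(response >= 0), "responses must be nonnegative counts")
  x <- design$x
  n <- nrow(x)
  rows <- vector("list", plan$repetitions)
  for (r in seq_len(plan$repetitions)) {
    rows[[r]] <- with_seed(child_seed(plan$seed, 500 + r), {
      fold <- sample(rep_len(seq_len(plan$outer_folds), n))
      pred <- rep(NA_real_, n)
      for (f in seq_len(plan$outer_folds)) {
        tr <- which(fold != f)
        te <- which(fold == f)
        pp <- make_preproc(x[tr, , drop = FALSE], response[tr],
                           design$continuous, "none", list())
        xtr <- pp(x[tr, , drop = FALSE])
        xte <- pp(x[te, , drop = FALSE])
        ytr <- response[tr]
        inner_fold <- sample(rep_len(seq_len(plan$inner_folds), length(tr)))
        best <- NULL
        for (d in seq_len(search_budget)) {
          par <- draw_reg_params(model, ncol(xtr))
          ipred <- rep(NA_real_, length(tr))
          for (g in seq_len(plan$inner_folds)) {
            itr <- which(inner_fold != g)
            ite <- which(inner_fold == g)
            fit <- fit_regressor(xtr[itr, , drop = FALSE], ytr[itr], model,
                                 par, seed = child_seed(plan$seed, d))
            ipred[ite] <- predict_regressor(fit, xtr[ite, , drop = FALSE])
          }
          score <- -mean(abs(ipred - ytr), na.rm = TRUE)
          if (is.null(best) || score > best$score) {
            best <- list(score = score, par = par)
          }
        }
        fit <- fit_regressor(xtr, ytr, model, best$par,
                             seed = child_seed(plan$seed, r))
        pred[te] <- predict_regressor(fit, xte)
      }
      tibble::tibble(repetition = r, mae = mean(abs(pred - response)))
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bpd_regression_result", class(out))
  attr(out, "model") <- model
  attr(out, "selector") <- design$selector
  out
}

draw_reg_params <- function(model, p) {
  if (model == "poisson") {
    list(alpha = stats::runif(1), lambda = 10^stats::runif(1, -3, 1))
  } else {
    draw_params("random_forest", p)
  }
}

# penalized Poisson / random-forest count regressors with capped predictions
fit_regressor <- function(x, y, model, par, seed = 1L) {
  cap <- 10 * max(y) + 10
  if (model == "poisson") {
    if (ncol(x) < 2) {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::poisson())
      )
      list(kind = "glm", fit = fit, cap = cap)
    } else {
      fit <- glmnet::glmnet(x, y, family = "poisson", alpha = par$alpha,
                            lambda = par$lambda)
      list(kind = "glmnet", fit = fit, lambda = par$lambda, cap = cap)
    }
  } else {
    dat <- data.frame(.y = y, x, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = par$num_trees, mtry = min(par$mtry, ncol(x)),
      min.node.size = par$min_node, seed = as.integer(seed), num.threads = 1
    )
    list(kind = "ranger", fit = fit, cap = cap)
  }
}

predict_regressor <- function(obj, x) {
  p <- switch(obj$kind,
    glm = suppressWarnings(
      stats::predict(obj$fit, newdata = data.frame(x, check.names = FALSE),
                     type = "response")
    ),
    glmnet = as.numeric(
      stats::predict(obj$fit, newx = x, s = obj$lambda, type = "response")
    ),
    ranger = stats::predict(obj$fit,
                            data = data.frame(x, check.names = FALSE),
                            num.threads = 1)$predictions
  )
  p[!is.finite(p)] <- obj$cap
  pmin(p, obj$cap)
}

#' Permutation feature importance
#'
#' Mean AUC drop on held-out data when one column is shuffled, over
#' `n_repeats` seeded permutations; the standard model-agnostic importance
#' measure.
#'
#' @param fit a [fit_classifier()] result.
#' @param x held-out design matrix (same columns as the fit).
#' @param y held-out labels.
#' @param n_repeats permutations per column (default 100).
#' @param seed integer seed.
#' @return A tibble with `feature`, `importance` (mean AUC drop) and `sd`,
#'   sorted decreasing; a single-column design carries a `note` attribute.
#' @export
permutation_importance <- function(fit, x, y, n_repeats = 100L, seed = 1L) {
  y <- factor(y)
  base <- pooled_auc(y, predict_prob(fit, x))["auc"]
  with_seed(seed, {
    rows <- lapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        base - pooled_auc(y, predict_prob(fit, xp))["auc"]
      }, 1.0)
      tibble::tibble(feature = colnames(x)[j] %||% paste0("x", j),
                     importance = mean(drops), sd = stats::sd(drops))
    })
    out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$importance))
    if (ncol(x) == 1) {
      attr(out, "note") <- "single-column design: importance is trivially the whole model"
    }
    attr(out, "baseline_auc") <- as.numeric(base)
    out
  })
}

#' Spearman correlation matrix with Bonferroni flags
#'
#' Pairwise Spearman rank correlations between lung features and clinical
#' target columns, with two-sided p values and significance flags at the
#' Bonferroni-adjusted level `alpha / n_tests`. Constant columns yield an
#' undefined correlation and are flagged.
#'
#' @param data a data frame (typically a [generate_cohort()] tibble).
#' @param features,targets column-name character vectors.
#' @param alpha family-wise error level before correction (default 0.05).
#' @return A tibble with `feature`, `target`, `rho`, `p_value`,
#'   `significant`, `flag`; attribute `alpha_adjusted`.
#' @export
feature_correlation_matrix <- function(data, features, targets,
                                       alpha = 0.05) {
  assert_that(all(c(features, targets) %in% names(data)),
              "some requested columns are absent from the data")
  combos <- expand.grid(feature = features, target = targets,
                        stringsAsFactors = FALSE)
  n_tests <- nrow(combos)
  alpha_adj <- alpha / n_tests
  rows <- lapply(seq_len(n_tests), function(i) {
    xf <- as.numeric(data[[combos$feature[i]]])
    xt <- as.numeric(data[[combos$target[i]]])
    ok <- stats::complete.cases(xf, xt)
    if (sum(ok) < 3 || stats::sd(xf[ok]) == 0 || stats::sd(xt[ok]) == 0) {
      return(tibble::tibble(feature = combos$feature[i],
                            target = combos$target[i], rho = NA_real_,
                            p_value = NA_real_, significant = NA,
                            flag = "undefined (constant or too few pairs)"))
    }
    ct <- suppressWarnings(
      stats::cor.test(xf[ok], xt[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(feature = combos$feature[i], target = combos$target[i],
                   rho = unname(ct$estimate), p_value = ct$p.value,
                   significant = ct$p.value < alpha_adj, flag = "")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "n_tests") <- n_tests
  out
}

#' Group comparisons of a feature across severity grades
#'
#' Kruskal-Wallis H test across the four grades plus pairwise
#' Mann-Whitney U tests with Bonferroni correction - the standard
#' non-parametric battery for per-feature severity discrimination.
#'
#' @param data a cohort data frame with a `severity` column.
#' @param feature feature column name.
#' @return A list with `kruskal_p` and a tibble `pairwise` of
#'   Bonferroni-adjusted pairwise p values.
#' @export
severity_group_tests <- function(data, feature) {
  assert_that(feature %in% names(data), "feature column absent")
  v <- as.numeric(data[[feature]])
  g <- factor(data$severity)
  kw <- stats::kruskal.test(v, g)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(v, g, p.adjust.method = "bonferroni")
  )
  tab <- as.data.frame(as.table(pw$p.value))
  tab <- tab[!is.na(tab$Freq), ]
  list(
    kruskal_p = kw$p.value,
    pairwise = tibble::tibble(group1 = as.character(tab$Var1),
                              group2 = as.character(tab$Var2),
                              p_adjusted = tab$Freq)
  )
}
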