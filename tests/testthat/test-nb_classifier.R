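test_that("train_panel delegates to the marginal fit and is symmetric", {
  cfg <- two_site_config(n_analytes = 3, n_cases = 40, n_controls = 40, seed = 2)
  co <- generate_cohort(cfg)
  ann <- co$annotations
  clf <- train_panel(co$matrix, ann, "A0002")
  is_case <- ann$class_label == "case"
  direct <- fit_lognormal_cdf(co$matrix[is_case, "A0002"])
  expect_equal(clf$case_models$mu, direct$mu)
  expect_equal(clf$case_models$sigma, direct$sigma)
  # identical case and control data -> identical class models
  m2 <- rbind(co$matrix[is_case, , drop = FALSE],
              co$matrix[is_case, , drop = FALSE])
  rownames(m2) <- sprintf("X%03d", seq_len(nrow(m2)))
  ann2 <- tiny_annotations(rep(c("case", "control"), each = sum(is_case)))
  ann2$sample_id <- rownames(m2)
  sym <- train_panel(m2, ann2, "A0001")
  expect_equal(sym$case_models$mu, sym$control_models$mu, tolerance = 1e-10)
  expect_equal(sym$case_models$sigma, sym$control_models$sigma,
               tolerance = 1e-10)
  expect_error(train_panel(co$matrix, ann, "missing"), "missing")
})

test_that("LLR matches hand computations for a single marker", {
  clf <- manual_classifier(mu_case = 1, sigma_case = 1,
                           mu_ctrl = 0, sigma_ctrl = 1)
  m <- tiny_matrix(list(A1 = exp(c(0.5, 1))), c("s1", "s2"))
  llr <- log_likelihood_ratio(clf, m)
  expect_equal(unname(llr), c(0, 0.5))
  # identical models -> LLR identically zero
  same <- manual_classifier(mu_case = 2, sigma_case = 0.3,
                            mu_ctrl = 2, sigma_ctrl = 0.3)
  expect_equal(unname(log_likelihood_ratio(same, m)), c(0, 0))
  expect_error(log_likelihood_ratio(clf, tiny_matrix(list(B = c(1, 2)),
                                                     c("s1", "s2"))),
               "missing")
})

test_that("posterior applies the prior through the logistic link", {
  same <- manual_classifier(mu_case = 0, sigma_case = 1,
                            mu_ctrl = 0, sigma_ctrl = 1)
  m <- tiny_matrix(list(A1 = exp(0)), "s1")
  expect_equal(unname(posterior_case(same, m)), 0.5)
  same$prior_case <- 0.2
  expect_equal(unname(posterior_case(same, m)), 0.2)
  clf <- manual_classifier(mu_case = 1, sigma_case = 1,
                           mu_ctrl = 0, sigma_ctrl = 1)
  m2 <- tiny_matrix(list(A1 = exp(1)), "s1")   # LLR = 0.5
  expect_equal(unname(posterior_case(clf, m2)), 1 / (1 + exp(-0.5)))
})

test_that("LLR is additive over disjoint panels and thresholds match priors", {
  cfg <- two_site_config(n_analytes = 6, n_cases = 30, n_controls = 60,
                         disease_markers = data.frame(analyte = 1:2,
                                                      delta = c(1, -1)),
                         seed = 14)
  co <- generate_cohort(cfg)
  pa <- c("A0001", "A0003"); pb <- c("A0002", "A0005")
  ca <- train_panel(co$matrix, co$annotations, pa)
  cb <- train_panel(co$matrix, co$annotations, pb)
  cab <- train_panel(co$matrix, co$annotations, c(pa, pb))
  expect_equal(log_likelihood_ratio(cab, co$matrix),
               log_likelihood_ratio(ca, co$matrix) +
                 log_likelihood_ratio(cb, co$matrix))
  for (prior in c(0.2, 0.5, 0.8)) {
    cab$prior_case <- prior
    post <- posterior_case(cab, co$matrix)
    llr <- log_likelihood_ratio(cab, co$matrix)
    expect_equal(post > 0.5, llr > log((1 - prior) / prior))
  }
})

test_that("AUC equals the brute-force pairwise count, ties at one half", {
  expect_equal(auc_concordance(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_equal(auc_concordance(c(5, 6), c(1, 2)), 1)
  withr::with_seed(15, {
    for (r in 1:50) {
      n1 <- sample(1:15, 1); n0 <- sample(1:15, 1)
      a <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)
      b <- sample(seq(0, 1, by = 0.1), n0, replace = TRUE)
      expect_equal(auc_concordance(a, b), auc_brute(a, b))
    }
  })
})

test_that("evaluate_classifier computes confusion metrics and subsets", {
  # one marker, call = case iff log value > 0
  clf <- manual_classifier(mu_case = 1, sigma_case = 1,
                           mu_ctrl = -1, sigma_ctrl = 1)
  logv <- c(rep(1, 9), -1,            # cases: 9 TP, 1 FN
            rep(-1, 8), 1, 1)         # controls: 8 TN, 2 FP
  ann <- tiny_annotations(rep(c("case", "control"), each = 10))
  ann$stage[ann$class_label == "case"] <- c(rep("I", 5), rep("III", 5))
  m <- tiny_matrix(list(A1 = exp(logv)), ann$sample_id)
  met <- evaluate_classifier(clf, m, ann)
  expect_equal(met$sensitivity, 0.9)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$score, 1.7)
  expect_equal(met$stage1_sensitivity, 1.0)  # the FN case is stage III
  expect_equal(c(met$tp, met$fn, met$tn, met$fp), c(9, 1, 8, 2))
  # control-only subset: sensitivity undefined, specificity present
  sub <- evaluate_classifier(clf, m, ann, subset = ann$class_label == "control")
  expect_true(is.na(sub$sensitivity))
  expect_equal(sub$specificity, 0.8)
})

test_that("raising the prior never lowers sensitivity or raises specificity", {
  cfg <- two_site_config(n_analytes = 3, n_cases = 50, n_controls = 100,
                         disease_markers = data.frame(analyte = 1, delta = 0.8),
                         seed = 16)
  co <- generate_cohort(cfg)
  sens <- spec <- numeric(0)
  for (prior in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    clf <- train_panel(co$matrix, co$annotations, "A0001", prior)
    met <- evaluate_classifier(clf, co$matrix, co$annotations)
    sens <- c(sens, met$sensitivity); spec <- c(spec, met$specificity)
  }
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(spec) <= 0))
})
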