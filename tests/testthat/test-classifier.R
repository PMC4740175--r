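test_that("panel selection returns the smallest-p probes in order", {
  tab <- tibble::tibble(probe_id = sprintf("p%02d", 1:20),
                        p = (1:20) / 1000, delta_beta = runif(20, 0.05, 0.2),
                        significant = TRUE)
  expect_equal(select_panel(tab, k = 9, top = 200),
               sprintf("p%02d", 1:9))
  # pool of exactly k: panel equals pool under either rule
  tab9 <- tab[1:9, ]
  expect_setequal(select_panel(tab9, k = 9), tab9$probe_id)
  expect_setequal(select_panel(tab9, k = 9, rule = "spread"), tab9$probe_id)
  expect_error(select_panel(tab[1:5, ], k = 9),
               class = "cphcap_selection_error")
})

test_that("the selected panel has a larger effect than the probe-wide average", {
  panel <- default_model()$panel
  tab <- tidy(default_fit())
  expect_gt(mean(tab$delta_beta[tab$probe_id %in% panel]),
            mean(tab$delta_beta))
  expect_true(all(panel %in% tab$probe_id[tab$significant]))
})

test_that("the threshold is the midpoint of the printed CI bounds", {
  # groups constructed so the LDC upper CI bound is exactly 0.40 and the
  # HDC lower bound exactly 0.52; midpoint 0.46
  ldc <- lines_with_ci(0.36, 0.04, prefix = "l")
  hdc <- lines_with_ci(0.56, 0.04, prefix = "h")
  beta <- as_beta_tbl(matrix(c(hdc, ldc), nrow = 1, byrow = TRUE),
                      probes = "panel1", samples = c(names(hdc), names(ldc)))
  groups <- setNames(rep(c("HDC", "LDC"), each = 4), c(names(hdc), names(ldc)))
  model <- derive_threshold(beta, "panel1", groups)
  expect_equal(unname(model$ldc_ci["upper"]), 0.40)
  expect_equal(unname(model$hdc_ci["lower"]), 0.52)
  expect_equal(model$threshold, 0.46)
  expect_false(model$ci_overlap)
})

test_that("symmetric groups about one half give a threshold of one half", {
  ldc <- lines_with_ci(0.40, 0.03, prefix = "l")
  hdc <- lines_with_ci(0.60, 0.03, prefix = "h")
  beta <- as_beta_tbl(matrix(c(hdc, ldc), nrow = 1, byrow = TRUE),
                      probes = "panel1", samples = c(names(hdc), names(ldc)))
  groups <- setNames(rep(c("HDC", "LDC"), each = 4), c(names(hdc), names(ldc)))
  expect_equal(derive_threshold(beta, "panel1", groups)$threshold, 0.5)
})

test_that("overlapping group CIs are flagged with a warning", {
  ldc <- lines_with_ci(0.45, 0.08, prefix = "l")
  hdc <- lines_with_ci(0.50, 0.08, prefix = "h")
  beta <- as_beta_tbl(matrix(c(hdc, ldc), nrow = 1, byrow = TRUE),
                      probes = "panel1", samples = c(names(hdc), names(ldc)))
  groups <- setNames(rep(c("HDC", "LDC"), each = 4), c(names(hdc), names(ldc)))
  expect_warning(model <- derive_threshold(beta, "panel1", groups), "overlap")
  expect_true(model$ci_overlap)
})

test_that("the discovery threshold lies strictly between the group means", {
  model <- default_model()
  expect_gt(model$threshold, 0.37)
  expect_lt(model$threshold, unname(model$hdc_ci["mean"]))
  expect_gt(model$threshold, unname(model$ldc_ci["mean"]))
  expect_false(model$ci_overlap)
})

test_that("prediction applies the tie-to-HDC rule and reports deviations", {
  model <- structure(list(panel = c("a", "b"), threshold = 0.458,
                          hdc_ci = c(mean = 0.55, lower = 0.52, upper = 0.58),
                          ldc_ci = c(mean = 0.37, lower = 0.34, upper = 0.40),
                          ci_overlap = FALSE, conf = 0.95,
                          provenance = list()),
                     class = "capacity_model")
  beta <- as_beta_tbl(cbind(tie = c(0.458, 0.458), low = c(0.30, 0.30)),
                      probes = c("a", "b"))
  pred <- predict_capacity(beta, model)
  expect_equal(pred$predicted[pred$line_id == "tie"], "HDC")
  expect_equal(pred$predicted[pred$line_id == "low"], "LDC")
  expect_equal(pred$deviation[pred$line_id == "low"], -0.158)
})

test_that("prediction is monotone in a line's panel methylation", {
  model <- default_model()
  k <- length(model$panel)
  grid <- seq(0.2, 0.8, by = 0.05)
  preds <- vapply(grid, function(v) {
    beta <- as_beta_tbl(matrix(v, k, 1), probes = model$panel, samples = "x")
    predict_capacity(beta, model)$predicted
  }, character(1))
  expect_true(all(diff(preds == "HDC") >= 0))
})

test_that("missing panel probes error, and mostly-missing lines are unpredictable", {
  model <- default_model()
  beta <- cph_line_beta()
  expect_error(predict_capacity(beta[-match(model$panel[1], beta$probe_id), ],
                                model),
               model$panel[1], class = "cphcap_validation_error")
  holes <- beta
  holes[match(model$panel[1:4], holes$probe_id), 2] <- NA  # 4/9 missing
  pred <- predict_capacity(holes, model)
  expect_true(is.na(pred$predicted[1]))
  expect_false(anyNA(pred$predicted[-1]))
})

test_that("evaluation counts a 2-error 25-line table as 92% accuracy", {
  pred <- tibble::tibble(line_id = sprintf("L%02d", 1:25),
                         panel_mean = 0.5, deviation = 0,
                         predicted = c(rep("HDC", 15), rep("LDC", 10)),
                         true = c(rep("HDC", 14), "LDC",
                                  "HDC", rep("LDC", 9)))
  ev <- evaluate_predictions(pred)
  expect_equal(ev$accuracy, 23 / 25)
  expect_equal(sum(ev$confusion$n), 25)

  all_right <- dplyr::mutate(pred, true = predicted)
  expect_equal(evaluate_predictions(all_right)$accuracy, 1)
  inverted <- dplyr::mutate(pred, true = ifelse(predicted == "HDC", "LDC", "HDC"))
  expect_equal(evaluate_predictions(inverted)$accuracy, 0)
})

test_that("a serialised model predicts identically after JSON round-trip", {
  model <- default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_capacity_model(model, path)
  back <- read_capacity_model(path)
  expect_equal(back$threshold, model$threshold)
  expect_identical(back$panel, model$panel)
  beta <- cph_line_beta()
  expect_equal(predict_capacity(beta, back)$predicted,
               predict_capacity(beta, model)$predicted)
})

test_that("threshold derivation is invariant to line order", {
  beta <- cph_line_beta()
  perm <- c("probe_id", sample(setdiff(names(beta), "probe_id")))
  m1 <- derive_threshold(beta, default_model()$panel, default_groups())
  m2 <- derive_threshold(beta[, perm], default_model()$panel, default_groups())
  expect_equal(m1$threshold, m2$threshold)
})
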