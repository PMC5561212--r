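toy_table <- function(ldc, cmax, class,
                      ic25a = rep(1e6, length(ldc)),
                      ic25h = rep(1e6, length(ldc)),
                      ldc_censored = rep(FALSE, length(ldc))) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  df <- data.frame(name = paste0("C", seq_along(ldc)), class = class,
                   ic25_ahdf = ic25a, ic25_h9 = ic25h, cmax = cmax,
                   ldc = paste0(ifelse(ldc_censored, ">", ""), ldc))
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  load_compound_table(tmp)
}

test_that("step 1 compares the LDC to both cytotoxicity thresholds", {
  tbl <- fixture_table()
  s1 <- setNames(step1(tbl), tbl$name)
  expect_false(s1[["Acetaminophen"]])   # LDC 160 > IC25H9 71
  expect_true(s1[["Busulfan"]])         # LDC 0.2 below both
  expect_true(s1[["Thiamine"]])         # censored IC25s act as +Inf
  expect_false(s1[["Sitagliptin"]])     # censored LDC always fails
  expect_true(s1[["Doxylamine"]])       # LDC 45 = IC25aHDF 45, inclusive
})

test_that("step 2 compares the LDC to k times Cmax, boundary inclusive", {
  tbl <- fixture_table()
  s2 <- setNames(step2(tbl, k = 10), tbl$name)
  expect_true(s2[["Bosentan"]])               # 16 <= 81.7
  expect_false(s2[["Diethylstilbestrol"]])    # 5 > 0.056
  expect_false(s2[["Amoxicillin"]])           # 150 > 144

  exact <- toy_table(ldc = 50, cmax = 5, class = "TER")
  expect_true(step2(exact, k = 10))           # 50 = 10 * 5 exactly
})

test_that("classify reproduces the published screen calls at k = 10", {
  tbl <- fixture_table()
  out <- classify_compounds(tbl, k = 10)
  pred <- setNames(as.character(out$predicted), out$name)
  expect_equal(pred[["Lovastatin"]], "TER")
  expect_equal(pred[["Diethylstilbestrol"]], "NON")
  expect_true(is.na(out$step2_pass[out$name == "Sitagliptin"]))
  # step 2 evaluated iff step 1 passed; TER iff both passed
  expect_equal(is.na(out$step2_pass), !out$step1_pass)
  expect_equal(out$predicted == "TER",
               out$step1_pass & !is.na(out$step2_pass) & out$step2_pass)
})

test_that("screen metrics recompute exactly from the confusion counts", {
  perfect <- toy_table(ldc = c(1, 1000), cmax = c(10, 1),
                       class = c("TER", "NON"))
  p <- screen_compounds(perfect, k = 10)$performance
  expect_equal(c(p$tp, p$fp, p$tn, p$fn), c(1, 0, 1, 0))
  expect_equal(c(p$sensitivity, p$specificity, p$accuracy), c(100, 100, 100))

  # inverting the labels turns hits into misses: both rates drop to 0
  flipped <- toy_table(ldc = c(1, 1000), cmax = c(10, 1),
                       class = c("NON", "TER"))
  q <- screen_compounds(flipped, k = 10)$performance
  expect_equal(c(q$tp, q$fp, q$tn, q$fn), c(0, 1, 0, 1))
  expect_equal(q$sensitivity, 0)
  expect_equal(q$specificity, 0)
  # counts always partition the input
  expect_equal(p$tp + p$fp + p$tn + p$fn, 2)
  expect_equal(q$tp + q$fp + q$tn + q$fn, 2)
})

test_that("rank AUC equals the exhaustive pair-counting oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    positive <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    score <- sample(seq_len(10), n, replace = TRUE) / 2  # forces ties
    expect_equal(rank_auc(score, positive, direction = "low"),
                 pair_count_auc(score, positive))
    expect_equal(rank_auc(score, positive, direction = "high"),
                 1 - pair_count_auc(score, positive))
  }
})

test_that("rank AUC agrees with pROC on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(4)
  score <- rnorm(40)
  positive <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = positive, predictor = score, quiet = TRUE,
    direction = ">", levels = c(FALSE, TRUE))))
  expect_equal(rank_auc(score, positive, direction = "low"), ref)
})

test_that("scale-factor search recovers the published optimum window", {
  s <- scale_factor_search(fixture_table())
  expect_equal(s$n_passers, 21L)
  expect_equal(s$best_k_set, 7:10)
  expect_equal(max(s$n_correct), 20)  # only Diethylstilbestrol wrong
  expect_equal(s$auc_full, 1 - 4 / 90)
  # the optimum window is contiguous
  expect_equal(s$best_k_set, seq(min(s$best_k_set), max(s$best_k_set)))
  # leave-one-out: every run's optimum set intersects the full-data set
  overlap <- vapply(s$loo_best, function(k) length(intersect(k, 7:10)) > 0,
                    TRUE)
  expect_true(all(overlap))
})

test_that("scale-factor search rejects degenerate single-class input", {
  one_class <- toy_table(ldc = c(1, 2, 3), cmax = c(1, 1, 1),
                         class = rep("TER", 3))
  expect_error(scale_factor_search(one_class), "each class")
})

test_that("a perfectly separated toy set gives AUC 1 and a spanning k window", {
  tbl <- toy_table(ldc = c(1, 2, 300, 400), cmax = c(1, 1, 10, 10),
                   class = c("TER", "TER", "NON", "NON"))
  s <- scale_factor_search(tbl, k_grid = 1:40)
  expect_equal(s$auc_full, 1)
  # ratios: TER at 1, 2; NON at 30, 40 -> every k in [2, 29] is optimal
  expect_equal(s$best_k_set, 2:29)
})

test_that("predictions are monotone in k: TER set only grows", {
  tbl <- fixture_table()
  prev <- rep(FALSE, nrow(tbl))
  sens_prev <- -1
  spec_prev <- 101
  for (k in 1:20) {
    out <- classify_compounds(tbl, k)
    now <- out$predicted == "TER"
    expect_true(all(prev <= now))
    p <- screen_compounds(tbl, k)$performance
    expect_gte(p$sensitivity, sens_prev)
    expect_lte(p$specificity, spec_prev)
    prev <- now
    sens_prev <- p$sensitivity
    spec_prev <- p$specificity
  }
})

test_that("LOO verification classifiers behave sanely", {
  # linearly separable toy set -> AUC 1 for both models
  sep <- toy_table(ldc = c(0.1, 0.2, 0.3, 0.4, 100, 200, 300, 400),
                   cmax = rep(1, 8),
                   class = rep(c("TER", "NON"), each = 4))
  auc <- reference_classifiers_loo(sep)
  expect_equal(unname(auc[["logistic"]]), 1)
  expect_equal(unname(auc[["svm"]]), 1)

  # censored-LDC rows are excluded with a warning
  cen <- toy_table(ldc = c(1, 2, 500, 600, 100), cmax = rep(1, 5),
                   class = c("TER", "TER", "NON", "NON", "NON"),
                   ldc_censored = c(rep(FALSE, 4), TRUE))
  expect_warning(reference_classifiers_loo(cen), "censored")

  # label shuffles should hover around chance level
  set.seed(21)
  base <- fixture_table()
  base <- base[!base$ldc_censored, ]
  aucs <- replicate(30, {
    shuf <- base
    shuf$in_vivo_class <- sample(shuf$in_vivo_class)
    tryCatch(reference_classifiers_loo(shuf)[["logistic"]],
             error = function(e) NA_real_)
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.15)

  # on the screen's step-1 passers both models reach a high AUC
  passers <- fixture_table()
  passers <- passers[step1(passers), ]
  auc_scr <- reference_classifiers_loo(passers)
  expect_gt(auc_scr[["logistic"]], 0.7)
  expect_gt(auc_scr[["svm"]], 0.7)
})
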