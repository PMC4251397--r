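# Independent brute-force information gain used as the oracle.
brute_gain <- function(values, labels, cuts) {
  ent <- function(y) {
    p <- table(y) / length(y)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  bins <- findInterval(values, cuts)
  h <- ent(labels)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + mean(sel) * ent(labels[sel])
  }
  h - cond
}

test_that("information gain matches hand-computed entropies", {
  y <- rep(c("a", "b"), each = 10)
  expect_equal(info_gain(c(rep(0, 10), rep(1, 10)), y, cuts = 0.5), 1)
  expect_equal(info_gain(rep(1, 20), y), 0)
  # 4-row table with bins {0}, {1}
  v <- c(0, 0, 1, 1); y4 <- c("c1", "c1", "c1", "c2")
  expect_equal(round(info_gain(v, y4, cuts = 0.5), 4), 0.3113)
})

test_that("information gain equals the brute-force oracle on small tables", {
  set.seed(5)
  for (rep_ in 1:8) {
    n <- sample(10:30, 1)
    v <- rnorm(n)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    cuts <- discretize(v, y)
    expect_equal(info_gain(v, y, cuts = cuts), brute_gain(v, y, cuts),
                 tolerance = 1e-10)
  }
})

test_that("MDL discretization accepts real cuts and rejects noise", {
  sep <- c(rnorm(30, 0, 0.3), rnorm(30, 10, 0.3))
  ysep <- rep(c("a", "b"), each = 30)
  cuts <- discretize(sep, ysep)
  expect_gte(length(cuts), 1)
  expect_true(any(cuts > 2 & cuts < 8))

  expect_length(discretize(rep(1, 40), ysep[1:40]), 0)

  inter <- seq_len(40)
  yint <- rep(c("a", "b"), 20)     # perfectly interleaved labels
  expect_length(discretize(inter, yint), 0)
  expect_equal(info_gain(inter, yint), 0)
})

test_that("ranking orders by merit with alphabetical ties and a threshold", {
  set.seed(6)
  n <- 120
  y <- rep(c(1L, 2L), each = n / 2)
  tab <- data.frame(
    zz_dup = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
    noise = rnorm(n),
    class = y)
  tab$aa_dup <- tab$zz_dup
  class(tab) <- c("apw_feature_table", "data.frame")
  rk <- rank_features(tab)
  expect_equal(rk$merit[rk$name == "aa_dup"], rk$merit[rk$name == "zz_dup"])
  expect_lt(which(rk$name == "aa_dup"), which(rk$name == "zz_dup"))
  expect_false(rk$selected[rk$name == "noise"])

  shuf <- tab
  set.seed(7)
  shuf$class <- sample(shuf$class)
  expect_error(rank_features(shuf), "threshold")
})

test_that("the synthetic cohorts retain the systolic-time attribute", {
  # pi_t retention needs the full-size corpus and is asserted in the
  # acceptance suite; the small fixture still separates on SP timing
  tab <- fixture_feature_table()
  rk <- rank_features(tab)
  expect_true(rk$selected[rk$name == "sp_t"])
  expect_setequal(rk$name,
                  setdiff(names(tab), c("class", "subject")))
})

test_that("all four classifiers separate a separable table", {
  tab <- separable_table()
  models <- train_classifiers(tab, seed = 2)
  probs <- predict_models(models, tab)
  for (nm in c("forest", "tree", "rules", "bayes")) {
    pred <- colnames(probs[[nm]])[max.col(probs[[nm]], ties.method = "first")]
    expect_gte(mean(pred == as.character(tab$class)), 0.97,
               label = paste("training accuracy of", nm))
  }
})

test_that("label shuffling drops cross-validated accuracy to chance", {
  tab <- separable_table(n = 60)
  set.seed(8)
  tab$class <- sample(tab$class)
  cv <- cross_validate(tab, k = 5, seed = 8, algos = "forest", ntree = 60)
  acc <- cv$classifiers$forest$accuracy
  expect_lt(acc, 65)   # binomial noise around 50%
  expect_gt(acc, 35)
})

test_that("the same seed reproduces forest predictions exactly", {
  tab <- separable_table()
  m1 <- train_classifiers(tab, algos = "forest", seed = 4)
  m2 <- train_classifiers(tab, algos = "forest", seed = 4)
  expect_identical(predict_models(m1, tab), predict_models(m2, tab))
})

test_that("degenerate tables are rejected with a clear error", {
  tab <- separable_table()
  tab$class <- 1L
  expect_error(train_classifiers(tab), "2 classes")
  expect_error(train_classifiers(separable_table(n = 5)), "20 rows")
  expect_error(cross_validate(separable_table(n = 8), k = 10), "k rows")
})

test_that("the ROC follows its closed forms and agrees with pROC", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("a", "a", "b", "b"), "a")
  expect_equal(perfect$auc, 1)
  set.seed(9)
  y <- sample(c("a", "b"), 400, TRUE)
  s <- runif(400)
  mine <- roc_curve(s, y, "a")$auc
  expect_lt(abs(mine - 0.5), 0.1)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("b", "a"), direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("majority voting follows the stated tie rules", {
  expect_equal(majority_vote(c("1", "1", "1", "2"), c(0.9, 0.8, 0.7, 0.2)), "1")
  expect_equal(majority_vote(c("1", "1", "2", "2"), c(0.9, 0.9, 0.3, 0.7)), "1")
  expect_equal(majority_vote(c("1", "1", "2", "2"), c(0.5, 0.5, 0.5, 0.5)), "2")
  expect_error(majority_vote(c("1", NA, "2", "2"), rep(0.5, 4)), "missing")
})

test_that("subject predictions are a two-class partition", {
  tab <- separable_table()
  models <- train_classifiers(tab, seed = 3)
  one <- tab[tab$class == 1, ]
  pred <- predict_subject(one, models, subject = "X")
  expect_equal(pred$pct_A + pred$pct_B, 100)
  expect_gt(pred$pct_A, 90)   # class-1 pulses vote class 1
  expect_equal(pred$n_pulses, nrow(one))
})
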