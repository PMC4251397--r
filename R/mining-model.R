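# Multi-classifier training (four families), stratified k-fold
# cross-validation with ROC/AUC, majority voting and per-subject prediction.

#' @noRd
feature_matrix <- function(table) {
  feats <- setdiff(names(table), c("class", "subject"))
  feats <- feats[vapply(table[feats], is.numeric, TRUE)]
  as.data.frame(table[feats])
}

# ---- RIPPER-style rule learner ---------------------------------------------

# A compact rule-induction learner: rules are grown greedily for the
# minority class by FOIL information gain on a grow split, then pruned on a
# held-out prune split by rule-value (p - n)/(p + n); the default prediction
# is the majority class. Numeric conditions use <=/>= thresholds drawn from
# training quantiles.
#' @noRd
fit_ripper <- function(x, y, seed = 1L, max_rules = 10) {
  y <- as.character(y)
  tab <- sort(table(y))
  target <- names(tab)[1]          # minority class gets the rules
  default <- names(tab)[length(tab)]
  with_seed(seed, {
    n <- nrow(x)
    grow_idx <- sample(n, round(2 * n / 3))
  }) -> grow_idx
  rules <- list()
  pos <- y == target
  covered <- rep(FALSE, n)
  cand_thresholds <- lapply(x, function(v)
    unique(as.numeric(quantile(v, probs = seq(0.05, 0.95, by = 0.05),
                               na.rm = TRUE))))
  rule_matches <- function(rule, data) {
    m <- rep(TRUE, nrow(data))
    for (cond in rule) {
      v <- data[[cond$feature]]
      m <- m & !is.na(v) & if (cond$op == "<=") v <= cond$value else v >= cond$value
    }
    m
  }
  for (r in seq_len(max_rules)) {
    act <- !covered
    gi <- intersect(which(act), grow_idx)
    pi_ <- setdiff(which(act), grow_idx)
    if (sum(pos[gi]) < 2) break
    # grow
    rule <- list()
    sel <- rep(TRUE, length(gi))
    repeat {
      p0 <- sum(pos[gi][sel]); n0 <- sum(!pos[gi][sel])
      if (p0 == 0 || n0 == 0) break
      best <- NULL; best_gain <- 1e-9
      for (f in names(x)) for (th in cand_thresholds[[f]]) for (op in c("<=", ">=")) {
        v <- x[[f]][gi]
        m <- sel & !is.na(v) & (if (op == "<=") v <= th else v >= th)
        p1 <- sum(pos[gi][m]); n1 <- sum(!pos[gi][m])
        if (p1 == 0) next
        gain <- p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
        if (gain > best_gain) {
          best_gain <- gain
          best <- list(feature = f, op = op, value = th, m = m)
        }
      }
      if (is.null(best)) break
      rule[[length(rule) + 1]] <- best[c("feature", "op", "value")]
      sel <- best$m
      if (length(rule) >= 4) break
    }
    if (!length(rule)) break
    # prune: drop trailing conditions to maximize (p - n)/(p + n)
    if (length(pi_)) {
      value_of <- function(rl) {
        m <- rule_matches(rl, x[pi_, , drop = FALSE])
        p <- sum(pos[pi_][m]); ng <- sum(!pos[pi_][m])
        if (p + ng == 0) -1 else (p - ng) / (p + ng)
      }
      vals <- vapply(seq_along(rule), function(k) value_of(rule[seq_len(k)]), 0)
      keep <- which.max(vals)
      if (vals[keep] <= 0) break   # rule no better than chance: stop
      rule <- rule[seq_len(keep)]
    }
    m_all <- rule_matches(rule, x)
    prec <- sum(pos & m_all & !covered) / max(sum(m_all & !covered), 1)
    rules[[length(rules) + 1]] <- list(conds = rule, precision = prec)
    covered <- covered | m_all
    if (all(pos <= covered)) break
  }
  base_rate <- mean(pos)
  structure(list(rules = rules, target = target, default = default,
                 base_rate = base_rate, classes = sort(unique(y))),
            class = "apw_ripper")
}

#' @export
predict.apw_ripper <- function(object, newdata, type = "prob", ...) {
  n <- nrow(newdata)
  p_target <- rep(NA_real_, n)
  matched <- rep(FALSE, n)
  for (rl in object$rules) {
    m <- rep(TRUE, n)
    for (cond in rl$conds) {
      v <- newdata[[cond$feature]]
      m <- m & !is.na(v) &
        if (cond$op == "<=") v <= cond$value else v >= cond$value
    }
    hit <- m & !matched
    p_target[hit] <- rl$precision
    matched <- matched | m
  }
  # unmatched rows fall to the default class
  p_target[!matched] <- min(object$base_rate, 0.35)
  prob <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  prob[, object$target] <- p_target
  prob[, setdiff(object$classes, object$target)] <- 1 - p_target
  if (type == "class") {
    factor(ifelse(prob[, 1] >= 0.5, colnames(prob)[1], colnames(prob)[2]),
           levels = object$classes)
  } else prob
}

# ---- discretized Bayesian classifier ---------------------------------------

#' @noRd
fit_bayes_disc <- function(x, y) {
  y <- factor(y)
  cuts <- lapply(x, function(v) discretize(v, y))
  xf <- as.data.frame(lapply(names(x), function(f) {
    b <- if (length(cuts[[f]])) findInterval(x[[f]], cuts[[f]]) else
      rep(0L, nrow(x))
    b[is.na(x[[f]])] <- -1L
    factor(b)
  }), col.names = names(x))
  fit <- e1071::naiveBayes(xf, y, laplace = 1)
  structure(list(fit = fit, cuts = cuts, levels = lapply(xf, levels),
                 classes = levels(y)),
            class = "apw_bayes_disc")
}

#' @export
predict.apw_bayes_disc <- function(object, newdata, type = "prob", ...) {
  xf <- as.data.frame(lapply(names(object$cuts), function(f) {
    b <- if (length(object$cuts[[f]]))
      findInterval(newdata[[f]], object$cuts[[f]]) else
      rep(0L, nrow(newdata))
    b[is.na(newdata[[f]])] <- -1L
    factor(b, levels = object$levels[[f]])
  }), col.names = names(object$cuts))
  pr <- predict(object$fit, xf, type = "raw")
  if (type == "class")
    factor(colnames(pr)[max.col(pr)], levels = object$classes)
  else pr
}

# ---- training ---------------------------------------------------------------

#' Train the four classifier families
#'
#' Fits a bagged randomized-tree ensemble (forest), a single pruned decision
#' tree, a rule-induction learner with reduced-error pruning, and a
#' probabilistic Bayesian classifier on MDL-discretized features. All
#' classifiers expose class-probability predictions via
#' [predict_models()].
#'
#' @param table Labeled `apw_feature_table` (class column with two levels).
#' @param algos Character subset of `c("forest", "tree", "rules", "bayes")`.
#' @param seed Integer seed controlling every stochastic fit.
#' @param ntree Trees in the forest.
#' @return An `apw_models` list.
#' @export
train_classifiers <- function(table, algos = c("forest", "tree", "rules", "bayes"),
                              seed = 1L, ntree = 100) {
  stopifnot("class" %in% names(table))
  y <- factor(table$class)
  if (nlevels(y) < 2) stop("fit error: need at least 2 classes")
  if (nrow(table) < 20) stop("fit error: need at least 20 rows")
  x <- feature_matrix(table)
  models <- list()
  if ("forest" %in% algos) {
    models$forest <- with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = ntree))
  }
  if ("tree" %in% algos) {
    dat <- cbind(x, .class = y)
    fit <- with_seed(seed, rpart::rpart(.class ~ ., data = dat,
                                        method = "class"))
    cp <- fit$cptable
    best <- cp[which.min(cp[, "xerror"]), "CP"]
    models$tree <- rpart::prune(fit, cp = best)
  }
  if ("rules" %in% algos) models$rules <- fit_ripper(x, y, seed = seed)
  if ("bayes" %in% algos) models$bayes <- fit_bayes_disc(x, y)
  structure(list(models = models, features = names(x),
                 classes = levels(y), seed = seed),
            class = "apw_models")
}

#' Class-probability predictions from a trained ensemble
#'
#' @param models An `apw_models` object.
#' @param table Feature table (rows to predict).
#' @return Named list of probability matrices (rows x classes), one per
#'   classifier.
#' @export
predict_models <- function(models, table) {
  stopifnot(inherits(models, "apw_models"))
  x <- as.data.frame(table)[models$features]
  out <- list()
  for (nm in names(models$models)) {
    m <- models$models[[nm]]
    pr <- switch(nm,
      forest = predict(m, x, type = "prob"),
      tree = predict(m, x, type = "prob"),
      rules = predict(m, x, type = "prob"),
      bayes = predict(m, x, type = "prob"))
    pr <- pr[, models$classes, drop = FALSE]
    out[[nm]] <- pr
  }
  out
}

# ---- ROC / cross-validation -------------------------------------------------

#' ROC points and trapezoid AUC
#'
#' @param scores Numeric scores for the positive class.
#' @param labels Labels; `positive` names the positive class.
#' @param positive Positive-class label.
#' @return List with `points` (data frame of FPR/TPR) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive) {
  pos <- labels == positive
  o <- order(-scores)
  tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
  tpr <- c(0, tp / max(sum(pos), 1))
  fpr <- c(0, fp / max(sum(!pos), 1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified k-fold cross-validation of the four classifiers
#'
#' Splits rows into `k` stratified folds, trains on k-1 folds and tests on
#' the held-out fold; the global accuracy of each classifier is the mean of
#' its fold accuracies, and one ROC per classifier is built from the pooled
#' test-fold probabilities (AUC by the trapezoid rule).
#'
#' @param table Labeled `apw_feature_table`.
#' @param k Number of folds.
#' @param seed Fold-assignment and fit seed.
#' @param algos Classifier subset (see [train_classifiers()]).
#' @param ntree Trees in the forest.
#' @return An `apw_cv_report`: per-classifier accuracy (%), fold accuracies,
#'   AUC and ROC points, plus the fold assignment.
#' @export
cross_validate <- function(table, k = 10, seed = 1L,
                           algos = c("forest", "tree", "rules", "bayes"),
                           ntree = 100) {
  y <- factor(table$class)
  if (min(table(y)) < k) stop("parameter error: need at least k rows per class")
  folds <- integer(nrow(table))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  acc <- list(); pooled <- list()
  for (a in algos) { acc[[a]] <- numeric(k); pooled[[a]] <- NULL }
  pooled_truth <- NULL
  for (fold in seq_len(k)) {
    tr <- table[folds != fold, , drop = FALSE]
    te <- table[folds == fold, , drop = FALSE]
    models <- train_classifiers(tr, algos = algos, seed = seed + fold,
                                ntree = ntree)
    probs <- predict_models(models, te)
    truth <- as.character(te$class)
    pooled_truth <- c(pooled_truth, truth)
    for (a in algos) {
      pred <- colnames(probs[[a]])[max.col(probs[[a]], ties.method = "first")]
      acc[[a]][fold] <- mean(pred == truth)
      pooled[[a]] <- rbind(pooled[[a]], probs[[a]])
    }
  }
  classes <- levels(y)
  per <- lapply(algos, function(a) {
    roc <- roc_curve(pooled[[a]][, 1], pooled_truth, positive = classes[1])
    list(accuracy = 100 * mean(acc[[a]]), fold_accuracies = 100 * acc[[a]],
         auc = roc$auc, roc = roc$points)
  })
  names(per) <- algos
  structure(list(classifiers = per, k = k, seed = seed, classes = classes),
            class = "apw_cv_report")
}

#' @export
print.apw_cv_report <- function(x, ...) {
  cat("<apw_cv_report>", x$k, "fold stratified CV\n")
  for (a in names(x$classifiers)) {
    ci <- x$classifiers[[a]]
    cat(sprintf("  %-7s accuracy %6.2f%%  AUC %.3f\n", a, ci$accuracy, ci$auc))
  }
  invisible(x)
}

# ---- voting and subject prediction ------------------------------------------

#' Majority vote across the classifier ensemble
#'
#' Modal label across the classifiers' predictions; a 2-2 tie is broken by
#' the higher mean class-A probability, and an exact probability tie falls
#' to class B (the benign default).
#'
#' @param labels Character vector of predicted labels (one per classifier).
#' @param probs Numeric vector of class-A probabilities aligned with
#'   `labels`.
#' @param class_a,class_b The two class labels.
#' @return The fused label.
#' @export
majority_vote <- function(labels, probs, class_a = "1", class_b = "2") {
  if (any(is.na(labels))) stop("ensemble error: missing classifier output")
  na <- sum(labels == class_a); nb <- sum(labels == class_b)
  if (na > nb) return(class_a)
  if (nb > na) return(class_b)
  pa <- mean(probs)
  if (pa > 0.5) class_a else class_b
}

#' Per-subject class percentages from majority voting
#'
#' Applies the trained ensemble to each of a subject's pulses, fuses the
#' four labels per pulse with [majority_vote()], and reports the share of
#' class-A and class-B pulses together with the subject's AIx summary.
#'
#' @param table Feature rows of one subject's non-anomalous pulses.
#' @param models An `apw_models` ensemble.
#' @param subject Subject identifier.
#' @return An `apw_subject_prediction` row: `subject`, `pct_A`, `pct_B`,
#'   `n_pulses`, `aix_mean`, `aix_sd`.
#' @export
predict_subject <- function(table, models, subject = "S1") {
  if (!nrow(table)) {
    warning("subject ", subject, " has no usable pulses; skipped")
    return(NULL)
  }
  probs <- predict_models(models, table)
  cls <- models$classes
  votes <- vapply(seq_len(nrow(table)), function(i) {
    labs <- vapply(probs, function(pr)
      cls[which.max(pr[i, ])], "")
    pa <- vapply(probs, function(pr) pr[i, 1], 0)
    majority_vote(labs, pa, class_a = cls[1], class_b = cls[2])
  }, "")
  aix <- table$aix
  # under paper parity a missing Pi is coded as zeroed pi_t/aix; exclude
  # those beats from the AIx summary
  if ("pi_t" %in% names(table)) aix <- aix[!(table$pi_t == 0 & aix == 0)]
  aix <- aix[!is.na(aix)]
  data.frame(subject = subject,
             pct_A = 100 * mean(votes == cls[1]),
             pct_B = 100 * mean(votes == cls[2]),
             n_pulses = nrow(table),
             aix_mean = if (length(aix)) mean(aix) else NA_real_,
             aix_sd = if (length(aix) > 1) sd(aix) else NA_real_)
}
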