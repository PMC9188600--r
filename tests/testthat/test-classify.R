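# Relief-F ranking, LOOCV Gaussian-SVM, confusion metrics, and phoneme
# combination.

# literal transcription of the binary Relief-F update rule, for tiny tables
relief_oracle <- function(x, y, k) {
  rng <- apply(x, 2, function(c) diff(range(c)))
  xs <- sweep(x, 2, apply(x, 2, min))
  xs[, rng > 0] <- sweep(xs[, rng > 0, drop = FALSE], 2, rng[rng > 0], "/")
  xs[, rng == 0] <- 0
  m <- nrow(xs)
  w <- numeric(ncol(xs))
  for (i in seq_len(m)) {
    d <- sqrt(colSums((t(xs) - xs[i, ])^2))
    hit_i <- setdiff(which(y == y[i]), i)
    mis_i <- which(y != y[i])
    hits <- hit_i[order(d[hit_i])][seq_len(k)]
    miss <- mis_i[order(d[mis_i])][seq_len(k)]
    for (f in seq_len(ncol(xs))) {
      w[f] <- w[f] - mean(abs(xs[hits, f] - xs[i, f])) / m +
        mean(abs(xs[miss, f] - xs[i, f])) / m
    }
  }
  w
}

test_that("Relief-F matches a literal transcription on tiny tables", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 8
    x <- cbind(c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 2, 0.5)), rnorm(n))
    y <- rep(c("CO", "PD"), each = n / 2)
    tab <- data.frame(a_feat = x[, 1], b_feat = x[, 2], group = y)
    ours <- relief_f(tab, k = 2)
    w <- relief_oracle(x[, order(c("a_feat", "b_feat"))], y, k = 2)
    expect_equal(ours$weight[match(c("a_feat", "b_feat"), ours$feature)],
                 w, tolerance = 1e-12)
  }
})

test_that("Relief-F weight symmetries hold", {
  set.seed(8)
  tab <- cluster_table(n_per_class = 15, p = 2, sep = 3)
  tab$dup1 <- tab$f1
  names(tab)[names(tab) == "dup1"] <- "f1copy"
  tab$const <- 1
  rk <- relief_f(tab, k = 5)
  expect_equal(rk$weight[rk$feature == "f1"],
               rk$weight[rk$feature == "f1copy"], tolerance = 1e-12)
  expect_equal(rk$weight[rk$feature == "const"], 0)
  expect_error(relief_f(tab, k = 20), class = "phonemark_insufficient_class")
})

test_that("Relief-F ranks a separating feature first in almost every draw", {
  first <- vapply(1:40, function(seed) {
    set.seed(seed)
    n <- 50
    tab <- data.frame(sep = c(rnorm(n, 0, 0.3), rnorm(n, 3, 0.3)),
                      n1 = rnorm(2 * n), n2 = rnorm(2 * n),
                      n3 = rnorm(2 * n), n4 = rnorm(2 * n),
                      group = rep(c("CO", "PD"), each = n))
    relief_f(tab, k = 10)$feature[1] == "sep"
  }, logical(1))
  expect_gte(mean(first), 0.95)
})

test_that("confusion metrics follow their defining ratios", {
  m <- confusion_metrics(126, 127, 23, 24)
  expect_equal(unname(round(m, 1)), c(84.3, 84.0, 84.7))
  expect_equal(unname(confusion_metrics(10, 10, 0, 0)), c(100, 100, 100))
  expect_equal(unname(confusion_metrics(0, 10, 0, 10)), c(50, 0, 100))
  expect_warning(m2 <- confusion_metrics(0, 10, 5, 0), "sensitivity")
  expect_true(is.na(m2["sensitivity"]))
  expect_error(confusion_metrics(0, 0, 0, 0),
               class = "phonemark_invalid_argument")
  # accuracy decomposes over class prevalences exactly
  m3 <- confusion_metrics(7, 12, 3, 5)
  p <- 7 + 5; n <- 12 + 3
  expect_equal(unname(m3["accuracy"]),
               (m3[["sensitivity"]] * p + m3[["specificity"]] * n) / (p + n))
})

test_that("LOOCV separates distant clusters and stays at chance when labels lie", {
  tab <- cluster_table(n_per_class = 20, p = 4, sep = 10, seed = 1)
  rep1 <- loocv_svm(tab)
  expect_equal(unname(rep1$metrics["accuracy"]), 100)
  expect_equal(rep1$tp + rep1$tn + rep1$fp + rep1$fn, 40)

  accs <- vapply(1:20, function(seed) {
    t2 <- cluster_table(n_per_class = 10, p = 4, sep = 10, seed = 2)
    set.seed(seed + 500)
    t2$group <- sample(t2$group)
    if (min(table(t2$group)) < 2) return(NA_real_)
    loocv_svm(t2)$metrics[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs, na.rm = TRUE) - 50), 15)
})

test_that("LOOCV is deterministic and guards against degenerate tables", {
  tab <- cluster_table(n_per_class = 8, p = 3, sep = 4, seed = 5)
  expect_identical(loocv_svm(tab)$predictions, loocv_svm(tab)$predictions)
  one <- tab[tab$group == "CO", ]
  expect_error(loocv_svm(one), class = "phonemark_invalid_argument")
  # identical row under both labels: at least one of the pair must err
  amb <- tab
  amb[1, c("f1", "f2", "f3")] <- amb[9, c("f1", "f2", "f3")]
  rep_a <- loocv_svm(amb)
  pair_err <- with(rep_a$predictions,
                   sum(truth[c(1, 9)] != predicted[c(1, 9)]))
  expect_gte(pair_err, 1)
})

test_that("fold-wise scaling does not leak the held-out label", {
  tab <- cluster_table(n_per_class = 10, p = 2, sep = 0, seed = 3)  # no signal
  tab$oracle_feat <- ifelse(tab$group == "PD", 1, 0)
  with_leak <- loocv_svm(tab)
  expect_equal(unname(with_leak$metrics["accuracy"]), 100)
  without <- loocv_svm(tab, features = c("f1", "f2"))
  expect_lt(abs(without$metrics[["accuracy"]] - 50), 25)
})

test_that("phoneme tables concatenate by subject and repetition", {
  ta <- cluster_table(n_per_class = 5, p = 4, sep = 1, seed = 6)
  tb <- ta; tb$phoneme <- "e"
  comb <- combine_phonemes(list(a = ta, e = tb),
                           features = paste0("f", 1:4))
  expect_equal(nrow(comb), nrow(ta))
  expect_equal(sum(grepl("^[ae]\\.f", names(comb))), 8L)
  expect_equal(unique(comb$phoneme), "a+e")

  # a subject missing one phoneme is dropped, with a message
  tb2 <- tb[tb$subject_id != "s01", ]
  expect_message(c2 <- combine_phonemes(list(a = ta, e = tb2)), "dropped 1")
  expect_false("s01" %in% c2$subject_id)

  tb3 <- tb; tb3$subject_id <- paste0("x", tb3$subject_id)
  expect_error(combine_phonemes(list(a = ta, e = tb3)),
               class = "phonemark_invalid_argument")

  # combining a table with itself duplicates features, loses no rows
  cc <- combine_phonemes(list(a = ta, a2 = ta))
  expect_equal(nrow(cc), nrow(ta))
})
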