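test_that("score fusion averages the streams present for each image", {
  df <- data.frame(image_id = c(1, 1, 2, 2),
                   stream = c("left", "right", "left", "right"),
                   score = c(0.4, 0.8, -0.1, 0.1),
                   label = c(TRUE, TRUE, FALSE, FALSE))
  st <- fuse_scores(df)
  expect_equal(st$fused_score, c(0.6, 0))
  # idempotence: identical scores on all streams
  df3 <- data.frame(image_id = rep(1:2, 3),
                    stream = rep(c("left", "right", "bottom"), each = 2),
                    score = rep(c(0.7, -0.2), 3),
                    label = rep(c(TRUE, FALSE), 3))
  expect_equal(fuse_scores(df3)$fused_score, c(0.7, -0.2))
  # coverage error
  expect_error(fuse_scores(df, all_image_ids = 1:3), "no score")
  # single-stream pass-through
  one <- df[df$stream == "left", ]
  expect_equal(fuse_scores(one)$fused_score, one$score)
  # inconsistent labels
  bad <- df; bad$label[2] <- FALSE
  expect_error(fuse_scores(bad), "inconsistent labels")
})

test_that("fusing independent noisy replicates of the truth improves AUC", {
  set.seed(7)
  wins <- replicate(100, {
    truth <- rep(c(1, 0), c(200, 1800))
    s1 <- truth + rnorm(2000); s2 <- truth + rnorm(2000); s3 <- truth + rnorm(2000)
    af <- roc_auc((s1 + s2 + s3) / 3, truth)$auc
    af >= roc_auc(s1, truth)$auc && af >= roc_auc(s2, truth)$auc &&
      af >= roc_auc(s3, truth)$auc
  })
  expect_gte(mean(wins), 0.95)
})

test_that("thresholding reproduces the ROC operating points", {
  set.seed(1)
  sc <- rnorm(50)
  labels <- sc + rnorm(50) > 0
  st <- data.frame(image_id = 1:50, fused_score = sc, label = labels)
  expect_true(all(classify_by_threshold(st, -Inf)))
  expect_false(any(classify_by_threshold(st, Inf)))
  roc <- roc_auc(sc, labels)
  swept <- t(vapply(sort(unique(sc), decreasing = TRUE), function(thr) {
    d <- classify_by_threshold(st, thr - 1e-12)  # include the threshold point
    c(fpr = sum(d & !labels) / sum(!labels), tpr = sum(d & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  expect_equal(unname(as.matrix(roc$curve[-1, c("fpr", "tpr")])),
               unname(swept))
})

test_that("the rank-statistic AUC matches oracles and handles edge cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  set.seed(2)
  big <- rnorm(4000)
  expect_lt(abs(roc_auc(big, rep(c(TRUE, FALSE), 2000))$auc - 0.5), 0.03)
  # O(n^2) pairwise oracle, including ties
  for (rep in 1:5) {
    sc <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    labels <- runif(40) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(sc, labels)$auc, pairwise_auc(sc, labels))
  }
  # curve is monotone from (0,0) to (1,1)
  r <- roc_auc(rnorm(100), runif(100) < 0.3)
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_error(roc_auc(rnorm(5), rep(TRUE, 5)), "both classes")
})

test_that("rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- rnorm(200)
  labels <- sc + rnorm(200) > 0.3
  ours <- roc_auc(sc, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation folds are grouped by image and reproducible", {
  s <- generate_schedule(n_streams = 2, n_blocks = 1, images_per_block = 60,
                         targets_per_block = 6, min_target_gap_frames = 5,
                         seed = 3)
  rec <- simulate_recording(s, fs_hz = 600, seed = 3)
  ep <- preprocess(rec, s)
  cv <- kfold_cv(ep, "hdca", k = 3, seed = 9)
  # no image straddles folds
  by_img <- tapply(cv$scores$fold, cv$scores$image_id,
                   function(f) length(unique(f)))
  expect_true(all(by_img == 1))
  # determinism
  cv2 <- kfold_cv(ep, "hdca", k = 3, seed = 9)
  expect_identical(cv$fold_aucs, cv2$fold_aucs)
  expect_identical(cv$fold_of_image, cv2$fold_of_image)
  # stratification keeps targets balanced across folds
  img_lab <- tapply(cv$scores$label, cv$scores$image_id, unique)
  tab <- table(cv$fold_of_image[names(img_lab)], unlist(img_lab))
  expect_true(all(tab[, "TRUE"] == 2))
  expect_error(kfold_cv(ep, "hdca", k = 20, seed = 1), "stratify")
})

test_that("the exact signed-rank test reproduces known p-values", {
  a <- c(0.88, 0.79, 0.90, 0.89, 0.88, 0.86, 0.92, 0.91)
  expect_error(paired_wilcoxon(a, a), "degenerate")
  w <- paired_wilcoxon(a + 1, a)
  expect_equal(unname(w$statistic), 8 * 9 / 2)
  expect_equal(w$p.value, 0.0078125)   # 2 / 2^8
  # antisymmetry
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  w1 <- paired_wilcoxon(x, y); w2 <- paired_wilcoxon(y, x)
  expect_equal(w1$p.value, w2$p.value)
  expect_equal(unname(w1$statistic + w2$statistic), 10 * 11 / 2)
  # agreement with stats::wilcox.test when there are no ties
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w1$p.value, ref$p.value)
  expect_equal(unname(w1$statistic), unname(ref$statistic))
  expect_error(paired_wilcoxon(1:3, 3:1), "at least 5")
})

test_that("midpoint threshold separates well-separated classes", {
  sc <- c(rnorm(50, 0), rnorm(50, 10))
  labels <- rep(c(FALSE, TRUE), each = 50)
  thr <- midpoint_threshold(sc, labels)
  st <- data.frame(image_id = 1:100, fused_score = sc, label = labels)
  expect_equal(unname(classify_by_threshold(st, thr)), labels)
})
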