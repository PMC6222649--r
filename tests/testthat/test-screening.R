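test_that("applicability-domain bounds are training min/max widened by 30% of range", {
  D <- cbind(a = c(0, 4, 10), b = c(-1, 0, 1))
  bounds <- compute_ad(D)
  expect_equal(unname(bounds$lo), c(-3, -1.6))
  expect_equal(unname(bounds$hi), c(13, 1.6))
  expect_true(all(bounds$lo <= bounds$min & bounds$min <= bounds$max &
                    bounds$max <= bounds$hi))
  # every training row is inside its own domain
  expect_true(all(check_ad(bounds, D)))
  expect_warning(bd <- compute_ad(cbind(a = rep(5, 4))), "zero-range")
  expect_equal(unname(bd$lo), 5 - bd$epsilon)
  expect_equal(unname(bd$hi), 5 + bd$epsilon)
})

test_that("domain membership uses closed intervals on every descriptor simultaneously", {
  D <- cbind(a = c(0, 10), b = c(0, 10))
  bounds <- compute_ad(D)
  centre <- c(a = 5, b = 5)
  on_edge <- c(a = unname(bounds$hi["a"]), b = 5)
  past_edge <- c(a = unname(bounds$hi["a"]) + 1e-9, b = 5)
  expect_true(check_ad(bounds, centre))
  expect_true(check_ad(bounds, on_edge))
  expect_false(check_ad(bounds, past_edge))
  expect_error(check_ad(bounds, c(a = 1)), "lacks")
})

test_that("enlarging the training set can only widen the domain", {
  set.seed(21)
  base <- matrix(runif(60, 2, 8), 30, 2, dimnames = list(NULL, c("a", "b")))
  extra <- matrix(runif(20, 0, 10), 10, 2, dimnames = list(NULL, c("a", "b")))
  b1 <- compute_ad(base)
  b2 <- compute_ad(rbind(base, extra))
  expect_true(all(b2$lo <= b1$lo + 1e-12))
  expect_true(all(b2$hi >= b1$hi - 1e-12))
})

test_that("prefilters apply in order with exact removal accounting", {
  train <- matrix(runif(100 * 3, 0, 10), 100, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  bounds <- compute_ad(train)
  lib <- gen_screening_library(200, bounds, frac_outside = 0.1, seed = 31,
                               n_mw_violations = 7, n_duplicates = 5,
                               n_nonpurchasable = 4, n_missing = 3)
  pf <- prefilter_library(lib)
  expect_identical(pf$removal_log$duplicates, 5L)
  expect_identical(pf$removal_log$missing_descriptors, 3L)
  expect_identical(pf$removal_log$mw_over_limit, 7L)
  expect_identical(pf$removal_log$non_purchasable, 4L)
  expect_identical(pf$removal_log$retained, 200L - 19L)
  expect_false(anyNA(pf$library$descriptors))
  expect_false(any(duplicated(pf$library$ids)))
})

test_that("molecular weight exactly at the limit is retained; duplicates keep the first record", {
  lib <- list(ids = c("x", "y", "x", "z"),
              descriptors = matrix(1, 4, 1, dimnames = list(NULL, "a")),
              mw = c(600.0, 600.1, 100, 50),
              purchasable = rep(TRUE, 4))
  lib$descriptors[, 1] <- c(1, 2, 3, 4)
  pf <- prefilter_library(lib)
  expect_identical(pf$library$ids, c("x", "z"))
  expect_identical(pf$removal_log$duplicates, 1L)  # second "x"
  expect_identical(pf$removal_log$mw_over_limit, 1L)  # "y"
  expect_equal(pf$library$descriptors[, 1], c(1, 4))  # first "x" kept
})

test_that("consensus screening averages both models, ranks only in-domain records, and enriches actives", {
  spec <- synthetic_spec(150, 5, informative_indices = 1:3,
                         true_coefficients = c(2, 0.6, -0.4, 0.3),
                         noise_sd = 0.1, seed = 41)
  train <- gen_linear_dataset(spec)
  mlr <- fit_ols(train$descriptors[, 1:3], train$activity)
  ann <- train_ann(train, arch = c(5, 4, 1),
                   config = train_config(eta = 0.02, alpha = 0.1,
                                         max_epochs = 400, patience = 400,
                                         seed = 8))
  # the network consumes all 5 descriptors; AD on their union
  bounds <- compute_ad(train$descriptors)
  lib <- gen_screening_library(500, bounds, frac_outside = 0.2, seed = 42,
                               n_missing = 1)
  pf <- prefilter_library(lib)
  res <- consensus_screen(pf$library, ann, mlr, bounds)
  expect_equal(res$pred_avg, (res$pred_ann + res$pred_mlr) / 2)
  # ranks are 1..n_in_ad over in-domain records only
  ranked <- res[!is.na(res$rank), ]
  expect_identical(sort(ranked$rank), seq_len(sum(res$in_ad)))
  expect_true(all(is.na(res$rank[!res$in_ad])))
  expect_true(all(res$in_ad[!is.na(res$rank)]))
  # ascending by average prediction
  expect_true(!is.unsorted(ranked$pred_avg[order(ranked$rank)]))
  # enrichment: true activity of the top decile beats the bottom decile
  truth_fun <- function(ids) {
    D <- pf$library$descriptors[match(ids, pf$library$ids), , drop = FALSE]
    2 + drop(D[, 1:3] %*% c(0.6, -0.4, 0.3))
  }
  n_dec <- max(1, floor(nrow(ranked) / 10))
  ord <- ranked[order(ranked$rank), ]
  top <- truth_fun(head(ord$compound_id, n_dec))
  bottom <- truth_fun(utils::tail(ord$compound_id, n_dec))
  expect_lt(mean(top), mean(bottom))
})

test_that("an out-of-domain record never outranks anyone no matter its prediction", {
  train <- gen_linear_dataset(synthetic_spec(80, 3, informative_indices = 1:2,
                                             true_coefficients = c(0, 1, 1),
                                             noise_sd = 0.1, seed = 51))
  mlr <- fit_ols(train$descriptors[, 1:2], train$activity)
  ann <- train_ann(train, arch = c(3, 3, 1),
                   config = train_config(max_epochs = 100, patience = 100,
                                         seed = 3))
  bounds <- compute_ad(train$descriptors)
  lib <- list(ids = c("in1", "out1"),
              descriptors = rbind(train$descriptors[1, ],
                                  bounds$hi + 1),
              mw = c(100, 100), purchasable = c(TRUE, TRUE))
  rownames(lib$descriptors) <- NULL
  res <- consensus_screen(lib, ann, mlr, bounds)
  expect_true(is.na(res$rank[res$compound_id == "out1"]))
  expect_identical(res$rank[res$compound_id == "in1"], 1L)
})

test_that("top selection is a prefix of the ranking with an optional fractional cut", {
  res <- data.frame(compound_id = sprintf("c%03d", 1:150),
                    pred_avg = sort(rnorm(150)),
                    rank = 1:150)
  short <- top_selection(res, n = 100)
  expect_identical(nrow(short), 100L)
  expect_identical(short$rank, 1:100)
  cut <- top_selection(res, n = 100, fraction = 0.4)
  expect_identical(nrow(cut), 40L)
  expect_identical(cut$rank, 1:40)
  all_of_them <- top_selection(res[1:30, ], n = 100)
  expect_identical(nrow(all_of_them), 30L)
})
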