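make_score_fixture <- function(n = 300, seed = 21) {
  set.seed(seed)
  ids <- paste0("v", 1:6)
  ss <- toy_ss(rep(0, 6), ids = ids)
  am <- annotation_map(list(v1 = "a", v2 = "a", v3 = "b", v4 = "b",
                            v5 = "b", v6 = "a"))
  design <- expand_overlap(am, ss)
  G <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, ids))
  list(G = G, design = design)
}

test_that("group scores decompose the total PRS by annotation group", {
  fx <- make_score_fixture()
  beta <- c(1, -1, 0.5, 0.2, 0, 0.3)
  sc <- group_scores(fx$G, beta, fx$design)
  expect_equal(names(sc), c("sample_id", "a", "b"))
  total <- fx$G %*% beta
  expect_equal(sc$a + sc$b, drop(total))
  expect_true(all(group_scores(fx$G, rep(0, 6), fx$design)$a == 0))
})

test_that("group scores match hand multiplication on a two-variant case", {
  ids <- c("r1", "r2")
  ss <- toy_ss(c(0, 0), ids = ids)
  am <- annotation_map(list(r1 = "g1", r2 = "g2"))
  design <- expand_overlap(am, ss)
  G <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, ids))
  sc <- group_scores(G, c(1, 1), design)
  expect_equal(unname(as.matrix(sc[, c("g1", "g2")])), matrix(c(1, 2), 1))
})

test_that("overlap copies contribute to each of their groups", {
  ids <- c("r1", "r2")
  ss <- toy_ss(c(0, 0), ids = ids)
  am <- annotation_map(list(r1 = c("g1", "g2"), r2 = "g2"))
  design <- expand_overlap(am, ss)  # copies: r1/g1, r1/g2, r2/g2
  G <- matrix(c(2, 3), 1, 2, dimnames = list(NULL, ids))
  sc <- group_scores(G, c(0.5, 0.25, 1), design)
  expect_equal(sc$g1, 1)            # 2 * 0.5
  expect_equal(sc$g2, 2 * 0.25 + 3) # copy of r1 in g2 plus r2
})

test_that("cross-validated weights recover a perfectly predictive group", {
  fx <- make_score_fixture(n = 400)
  set.seed(31)
  sc <- tibble::tibble(sample_id = paste0("I", 1:400),
                       a = rnorm(400), b = rnorm(400))
  attr(sc, "groups") <- c("a", "b")
  y <- sc$a + rnorm(400, sd = 0.01)
  w <- fit_alpha_cv(sc, y, "quantitative", seed = 5)
  expect_equal(unname(w$alpha["a"]), 1, tolerance = 0.05)
  expect_equal(unname(w$alpha["b"]), 0, tolerance = 0.05)
  expect_equal(nrow(w$fold_metrics), 10)
  expect_gt(mean(w$fold_metrics$r2), 0.99)
})

test_that("null scores give chance-level held-out AUC", {
  set.seed(41)
  aucs <- replicate(20, {
    sc <- tibble::tibble(sample_id = paste0("I", 1:300),
                         a = rnorm(300), b = rnorm(300))
    attr(sc, "groups") <- c("a", "b")
    y <- rnorm(300)
    mean(fit_alpha_cv(sc, y, "quantitative",
                      seed = sample.int(1e6, 1))$fold_metrics$auc)
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("a single group reduces to the simple regression slope", {
  set.seed(51)
  sc <- tibble::tibble(sample_id = paste0("I", 1:200), a = rnorm(200))
  attr(sc, "groups") <- "a"
  y <- 2 * sc$a           # exact linear relation: slope identical in folds
  w <- fit_alpha_cv(sc, y, "quantitative", seed = 1)
  expect_equal(unname(w$alpha["a"]), 2, tolerance = 1e-10)
})

test_that("constant score columns are dropped with zero weight", {
  sc <- tibble::tibble(sample_id = paste0("I", 1:200),
                       a = rnorm(200), b = rep(1, 200))
  attr(sc, "groups") <- c("a", "b")
  y <- sc$a
  expect_warning(w <- fit_alpha_cv(sc, y, "quantitative", seed = 1), "constant")
  expect_equal(unname(w$alpha["b"]), 0)
})

test_that("binary traits use logistic weights and report Efron R2", {
  set.seed(61)
  sc <- tibble::tibble(sample_id = paste0("I", 1:400), a = rnorm(400))
  attr(sc, "groups") <- "a"
  y <- rbinom(400, 1, stats::plogis(2 * sc$a))
  w <- fit_alpha_cv(sc, y, "binary", seed = 2)
  expect_true("efron_r2" %in% names(w$fold_metrics))
  expect_gt(mean(w$fold_metrics$auc), 0.7)
  expect_gt(unname(w$alpha["a"]), 0)
})

test_that("shifting a score column leaves held-out AUC unchanged", {
  set.seed(71)
  sc <- tibble::tibble(sample_id = paste0("I", 1:300),
                       a = rnorm(300), b = rnorm(300))
  attr(sc, "groups") <- c("a", "b")
  y <- sc$a + 0.5 * sc$b + rnorm(300, sd = 0.5)
  w1 <- fit_alpha_cv(sc, y, "quantitative", seed = 9)
  sc2 <- sc; sc2$a <- sc2$a + 100
  w2 <- fit_alpha_cv(sc2, y, "quantitative", seed = 9)
  expect_equal(w1$fold_metrics$auc, w2$fold_metrics$auc, tolerance = 1e-8)
})

test_that("score combination follows the fitted weights", {
  sc <- tibble::tibble(sample_id = "I1", a = 1, b = 3)
  attr(sc, "groups") <- c("a", "b")
  w <- structure(list(alpha = c(a = 0.5, b = 0.5), gamma = NA_real_),
                 class = "alpha_weights")
  expect_equal(combine_scores(sc, w), 2)
  w_e <- structure(list(alpha = c(a = 1, b = 0), gamma = NA_real_),
                   class = "alpha_weights")
  expect_equal(combine_scores(sc, w_e), 1)
  expect_error(combine_scores(sc, w, mode = "hybrid"), "external")
  w_h <- structure(list(alpha = c(a = 1, b = 0), gamma = 0),
                   class = "alpha_weights")
  expect_equal(combine_scores(sc, w_h, external = 7, mode = "hybrid"),
               combine_scores(sc, w_h))
})

test_that("hybrid weights are fitted jointly with the external score", {
  set.seed(81)
  sc <- tibble::tibble(sample_id = paste0("I", 1:300), a = rnorm(300))
  attr(sc, "groups") <- "a"
  ext <- rnorm(300)
  y <- 0.2 * sc$a + ext + rnorm(300, sd = 0.05)
  w <- fit_alpha_cv(sc, y, "quantitative", seed = 3, external = ext)
  expect_equal(w$gamma, 1, tolerance = 0.05)
  final <- combine_scores(sc, w, external = ext, mode = "hybrid")
  expect_gt(cor(final, y), 0.99)
})
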