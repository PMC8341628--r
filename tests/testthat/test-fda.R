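test_that("stratified partitions respect per-species counts and guards", {
  tab <- data.frame(species_id = rep(c("A", "B", "C"), c(10, 2, 5)))
  set.seed(1)
  part <- stratified_partition(tab, 0.7)
  expect_setequal(c(part$train, part$test), 1:17)
  expect_length(intersect(part$train, part$test), 0)
  sp <- tab$species_id
  expect_equal(sum(sp[part$train] == "A"), 7)
  expect_equal(sum(sp[part$test] == "A"), 3)
  # nonemptiness guard for tiny species
  expect_equal(sum(sp[part$train] == "B"), 1)
  expect_equal(sum(sp[part$test] == "B"), 1)
  set.seed(2)
  part2 <- stratified_partition(tab, 0.7)
  expect_false(identical(part$train, part2$train))
  expect_equal(table(sp[part$train]), table(sp[part2$train]))
  expect_error(stratified_partition(data.frame(species_id = c("A", "A", "B")), 0.7),
               "fewer than 2.*B")
  expect_error(stratified_partition(tab, 1.2), "train_frac")
})

test_that("well-separated classes are classified perfectly", {
  set.seed(5)
  x <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, 10), ncol = 2))
  y <- rep(c("a", "b"), each = 200)
  fit <- fit_fda(x, y)
  expect_equal(mean(predict(fit, as.data.frame(x)) == y), 1)
})

test_that("linear-basis predictions reproduce classical LDA exactly", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    p <- sample(2:6, 1)
    n <- 40 + K * 10
    y <- factor(sample(letters[1:K], n, replace = TRUE,
                       prob = runif(K, 0.5, 1.5)))
    while (any(table(y) < p + 2)) y <- factor(sample(letters[1:K], n, TRUE))
    x <- matrix(rnorm(n * p), n, p) +
      1.5 * stats::model.matrix(~ y - 1) %*% matrix(rnorm(K * p), K, p)
    colnames(x) <- paste0("f", seq_len(p))
    fit <- fit_fda(x, y)
    xnew <- matrix(rnorm(50 * p), 50, p,
                   dimnames = list(NULL, colnames(x)))
    ours <- predict(fit, as.data.frame(xnew))
    lda_fit <- MASS::lda(x, y)
    theirs <- predict(lda_fit, xnew)$class
    expect_identical(as.character(ours), as.character(theirs))
  }
})

test_that("permuted labels give chance-level accuracy", {
  tab <- gaussian_trait_table(n_species = 4, n_per_species = 50, effect = 0,
                              seed = 8)
  res <- cv_success_rate(tab, paste0("t", 1:4), n_reps = 100, seed = 8)
  expect_gt(res$mean_accuracy, 0.20)
  expect_lt(res$mean_accuracy, 0.30)
})

test_that("prediction is deterministic with documented tie-breaking", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
             matrix(rnorm(100, 5, 0.5), ncol = 2))
  colnames(x) <- c("u", "v")
  y <- rep(c("a", "b"), each = 50)
  fit <- fit_fda(x, y)
  # training points classify consistently on repeated calls
  p1 <- predict(fit, as.data.frame(x))
  p2 <- predict(fit, as.data.frame(x))
  expect_identical(p1, p2)
  expect_gt(mean(p1 == y), 0.99)
  # a point at a class centroid belongs to that class
  mu_b <- colMeans(x[y == "b", ])
  expect_equal(as.character(predict(fit, data.frame(u = mu_b[1], v = mu_b[2]))), "b")
  # an exact distance tie (balanced priors, centroids at -1/+1 on one
  # discriminant function, query mapping to 0) goes to the first class in
  # label order
  tie_model <- fit
  tie_model$feature_names <- "u"
  tie_model$coef <- matrix(c(0, 1), 2, 1)       # eta(u) = u
  tie_model$centroids <- matrix(c(-1, 1), 2, 1,
                                dimnames = list(c("a", "b"), "DF1"))
  tie_model$weights <- 1
  tie_model$priors <- c(a = 0.5, b = 0.5)
  tie_model$ndim <- 1L
  expect_equal(as.character(predict(tie_model, data.frame(u = 0))), "a")
  expect_error(predict(fit, data.frame(u = 1)), "lacks feature")
})

test_that("singular designs demand a ridge penalty and accept one", {
  set.seed(10)
  x <- matrix(rnorm(20), 10, 2)
  x <- cbind(x, x[, 1] + x[, 2])               # collinear
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("u", "v"), 5)
  expect_error(fit_fda(x, y), "lambda|singular")
  fit <- fit_fda(x, y, lambda = 1e-6)
  expect_s3_class(fit, "spore_fda")
  expect_length(predict(fit, as.data.frame(x)), 10)
})

test_that("cross-validation is reproducible and near-perfect when separable", {
  sep <- gaussian_trait_table(n_species = 4, n_per_species = 15, effect = 8,
                              seed = 11)
  expect_gte(cv_success_rate(sep, paste0("t", 1:4), n_reps = 30,
                             seed = 3)$mean_accuracy, 0.99)
  # seed sensitivity needs an imperfectly separable table, where different
  # partitions give different replicate accuracies
  tab <- gaussian_trait_table(n_species = 4, n_per_species = 15, effect = 1.2,
                              seed = 11)
  r1 <- cv_success_rate(tab, paste0("t", 1:4), n_reps = 30, seed = 3)
  r2 <- cv_success_rate(tab, paste0("t", 1:4), n_reps = 30, seed = 3)
  expect_identical(r1$accuracies, r2$accuracies)
  r3 <- cv_success_rate(tab, paste0("t", 1:4), n_reps = 30, seed = 100)
  expect_false(identical(r1$accuracies, r3$accuracies))
})

test_that("feature sets share identical partitions (paired design)", {
  tab <- gaussian_trait_table(n_species = 3, n_per_species = 12, effect = 2,
                              seed = 12)
  cmp <- compare_feature_sets(tab, list(m1 = c("t1", "t2"), m2 = c("t1", "t2")),
                              n_reps = 25, seed = 5)
  # identical feature sets under paired partitions give identical replicate
  # accuracies, which can only happen if the splits are shared
  expect_identical(cmp$accuracies[, "m1"], cmp$accuracies[, "m2"])
  expect_equal(paired_differences(cmp, "m1", "m2"), rep(0, 25))
})

test_that("length+width beats the ratio when species share their ratio", {
  # species differ in L and W but share L/W ~ 3: Q is uninformative
  set.seed(13)
  lengths <- rep(c(9, 12, 15), each = 30) * exp(rnorm(90, 0, 0.04))
  tab <- data.frame(species_id = rep(c("A", "B", "C"), each = 30),
                    length_um = lengths,
                    width_um = lengths / 3 * exp(rnorm(90, 0, 0.02)))
  tab$q_ratio <- tab$length_um / tab$width_um
  cmp <- compare_feature_sets(tab, list(LW = c("length_um", "width_um"),
                                        Q = "q_ratio"),
                              n_reps = 40, seed = 6)
  acc <- setNames(cmp$summary$mean_accuracy, cmp$summary$model)
  expect_gt(acc["LW"], acc["Q"] + 0.2)
  expect_error(compare_feature_sets(tab, list(bad = "no_such_column"),
                                    n_reps = 2, seed = 1), "unknown trait")
})

test_that("the named feature sets match their standard definitions", {
  fs <- feature_sets()
  expect_identical(fs$S, "symmetric_PC1")
  expect_identical(fs$A, paste0("asymmetric_PC", 1:3))
  expect_identical(fs$G, paste0("global_PC", 1:2))
  expect_identical(fs$LW, c("length_um", "width_um"))
  expect_identical(fs$Q, "q_ratio")
  expect_identical(fs$SALW, c("symmetric_PC1", paste0("asymmetric_PC", 1:3),
                              "length_um", "width_um"))
  expect_identical(fs$SIZEINT, "size_int")
  expect_error(feature_sets("XYZ"), "unknown feature set")
})
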