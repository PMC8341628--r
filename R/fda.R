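# Flexible discriminant analysis by optimal scoring: regress the class
# indicator matrix on (optionally basis-expanded) features, solve the
# K x K generalized eigenproblem of the fitted scores, and classify by
# nearest class centroid in the eigenvalue-weighted discriminant space
# with priors proportional to training class frequencies. With the linear
# basis this reproduces classical linear discriminant analysis exactly.

#' Named feature sets for the model comparison
#'
#' The standard descriptor combinations compared for identification
#' success: S = symmetric shape variation (PC1), A = asymmetric shape
#' variation (PC1-PC3), G = global shape variation (PC1-PC2),
#' LW = length + width, Q = length/width ratio, QLW = Q + LW,
#' GLW = G + LW, SALW = S + A + LW, SIZEINT = integrated size
#' sqrt(length * width).
#'
#' @param labels Character vector of set labels to build (default: the
#'   eight compared sets plus SIZEINT).
#' @return Named list mapping label to trait column names.
#' @export
feature_sets <- function(labels = c("S", "A", "G", "LW", "Q", "QLW",
                                    "GLW", "SALW", "SIZEINT")) {
  defs <- list(
    S = "symmetric_PC1",
    A = c("asymmetric_PC1", "asymmetric_PC2", "asymmetric_PC3"),
    G = c("global_PC1", "global_PC2"),
    LW = c("length_um", "width_um"),
    Q = "q_ratio",
    QLW = c("q_ratio", "length_um", "width_um"),
    GLW = c("global_PC1", "global_PC2", "length_um", "width_um"),
    SALW = c("symmetric_PC1", "asymmetric_PC1", "asymmetric_PC2",
             "asymmetric_PC3", "length_um", "width_um"),
    SIZEINT = "size_int"
  )
  unknown <- setdiff(labels, names(defs))
  if (length(unknown))
    stop("unknown feature set label(s): ", paste(unknown, collapse = ", "))
  defs[labels]
}

#' Stratified train/test partition
#'
#' Splits observations into train and test portions per species:
#' round(train_frac * n) rows to train, the rest to test, adjusted by one
#' row where rounding would empty either portion. Draws from the current
#' RNG stream.
#'
#' @param table Data frame with a `species_id` column.
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @return List with integer row indices `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_partition <- function(table, train_frac = 0.7) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  sp <- as.character(table$species_id)
  counts <- table(sp)
  if (any(counts < 2L))
    stop("species with fewer than 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  train <- integer(0L)
  for (s in names(counts)) {
    rows <- which(sp == s)
    n_s <- length(rows)
    k <- round(train_frac * n_s)
    if (k < 1L) k <- 1L
    if (k > n_s - 1L) k <- n_s - 1L
    train <- c(train, sample(rows, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

# basis expansions for the optimal-scoring regression
expand_basis <- function(x, basis, degree, df_check = TRUE) {
  x <- as.matrix(x)
  if (basis == "linear") return(x)
  if (basis == "poly") {
    cols <- lapply(seq_len(ncol(x)), function(j) {
      m <- outer(x[, j], seq_len(degree), "^")
      colnames(m) <- paste0(colnames(x)[j], "_p", seq_len(degree))
      m
    })
    return(do.call(cbind, cols))
  }
  stop("unknown basis: ", basis)
}

#' Fit a flexible discriminant model by optimal scoring
#'
#' Regresses the class indicator matrix on the basis-expanded features,
#' eigen-decomposes the fitted class scores, and stores the discriminant
#' directions, class centroids and priors. The default linear basis makes
#' the model equivalent to classical linear discriminant analysis with
#' priors proportional to the training class frequencies; polynomial
#' bases and a ridge penalty generalize it.
#'
#' @param x Numeric feature matrix or data frame (n x p).
#' @param y Class labels (factor or character).
#' @param basis "linear" or "poly".
#' @param degree Polynomial degree when `basis = "poly"`.
#' @param lambda Ridge penalty (>= 0) added to the regression Gram matrix;
#'   required when it is singular.
#' @return Object of class `spore_fda` with a [predict.spore_fda()]
#'   method.
#' @export
fit_fda <- function(x, y, basis = c("linear", "poly"), degree = 2L, lambda = 0) {
  basis <- match.arg(basis)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 1L) || anyNA(y)) stop("every class must be present")
  n <- nrow(x)
  if (n != length(y)) stop("x and y disagree in length")
  feature_names <- colnames(x)
  xb <- expand_basis(x, basis, degree)
  p <- ncol(xb)
  K <- nlevels(y)
  Y <- stats::model.matrix(~ y - 1)
  X1 <- cbind(`(Intercept)` = 1, xb)
  G <- crossprod(X1)
  if (lambda > 0) G <- G + diag(c(0, rep(lambda, p)))
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    if (lambda > 0) stop("regression remains singular despite ridge penalty")
    stop("singular optimal-scoring regression (n <= p or collinear features); ",
         "set lambda > 0 to regularize")
  }
  B <- solve(qrG, crossprod(X1, Y))
  Yhat <- X1 %*% B
  Dp <- colMeans(Y)                      # class priors (training proportions)
  M <- crossprod(Y, Yhat) / n
  Ms <- diag(1 / sqrt(Dp)) %*% M %*% diag(1 / sqrt(Dp))
  Ms <- (Ms + t(Ms)) / 2
  e <- eigen(Ms, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  # leading eigenvector is the trivial constant score; the rest carry the
  # discriminant structure
  lam <- e$values[ord][-1L]
  theta <- (diag(1 / sqrt(Dp)) %*% e$vectors[, ord, drop = FALSE])[, -1L, drop = FALSE]
  ndim <- min(K - 1L, p)
  lam <- pmin(pmax(lam[seq_len(ndim)], 1e-12), 1 - 1e-12)
  theta <- theta[, seq_len(ndim), drop = FALSE]
  coef <- B %*% theta                    # (1 + p) x ndim discriminant functions
  eta <- X1 %*% coef
  centroids <- apply(eta, 2L, function(col) tapply(col, y, mean))
  centroids <- matrix(centroids, nrow = K,
                      dimnames = list(levels(y), paste0("DF", seq_len(ndim))))
  structure(list(
    basis = basis, degree = if (basis == "poly") degree else 1L,
    lambda = lambda,
    feature_names = feature_names,
    coef = coef,
    eigenvalues = lam,
    # the (n - K)/n factor matches the unbiased within-class variance
    # convention of classical LDA, making the -2 log(prior) penalty
    # commensurate with the distances
    weights = ((n - K) / n) / (lam * (1 - lam)),
    centroids = centroids,
    priors = Dp,
    levels = levels(y),
    ndim = ndim
  ), class = "spore_fda")
}

#' @export
print.spore_fda <- function(x, ...) {
  cat(sprintf("flexible discriminant model (%s basis): %d classes, %d dimension(s)\n",
              x$basis, length(x$levels), x$ndim))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Predict species with a fitted discriminant model
#'
#' Nearest-centroid assignment in the eigenvalue-weighted discriminant
#' space, penalized by -2 log(prior). Deterministic; exact distance ties
#' go to the first class in label order.
#'
#' @param object A `spore_fda`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param type "class" for labels, "distance" for the score matrix.
#' @param ... Unused.
#' @return Factor of predicted labels (or the n x K distance matrix).
#' @export
predict.spore_fda <- function(object, newdata, type = c("class", "distance"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (!all(object$feature_names %in% names(newdata)))
    stop("newdata lacks feature column(s): ",
         paste(setdiff(object$feature_names, names(newdata)), collapse = ", "))
  x <- as.matrix(newdata[object$feature_names])
  storage.mode(x) <- "double"
  xb <- expand_basis(x, object$basis, object$degree)
  eta <- cbind(1, xb) %*% object$coef
  K <- length(object$levels)
  dists <- vapply(seq_len(K), function(k) {
    colSums(object$weights * (t(eta) - object$centroids[k, ])^2) -
      2 * log(object$priors[k])
  }, numeric(nrow(eta)))
  dists <- matrix(dists, ncol = K, dimnames = list(NULL, object$levels))
  if (type == "distance") return(dists)
  factor(object$levels[max.col(-dists, ties.method = "first")],
         levels = object$levels)
}

#' Cross-validated identification success of one feature set
#'
#' Repeats a stratified 70/30 (by default) split `n_reps` times; each
#' replicate fits the discriminant model on the training portion and
#' records the fraction of correct species assignments on the test
#' portion. The mean over replicates is the identification success rate.
#' Replicate r draws its partition from a stream seeded `seed + r`, so
#' results are reproducible and partitions can be shared across feature
#' sets.
#'
#' @param table Trait table (one row per image) with `species_id`.
#' @param columns Trait columns to use as features.
#' @param label Name recorded for the feature set.
#' @param n_reps Number of replicates (default 1000).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Root seed.
#' @param basis,degree,lambda Passed to [fit_fda()].
#' @return Object of class `cv_result`: label, per-replicate accuracies,
#'   mean accuracy, and the settings.
#' @export
cv_success_rate <- function(table, columns, label = paste(columns, collapse = "+"),
                            n_reps = 1000L, train_frac = 0.7, seed = 1L,
                            basis = "linear", degree = 2L, lambda = 0) {
  if (!all(columns %in% names(table)))
    stop("unknown trait column(s): ",
         paste(setdiff(columns, names(table)), collapse = ", "))
  if (n_reps < 1L) stop("n_reps must be at least 1")
  acc <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    part <- stratified_partition(table, train_frac)
    fit <- fit_fda(table[part$train, columns, drop = FALSE],
                   table$species_id[part$train],
                   basis = basis, degree = degree, lambda = lambda)
    pred <- predict(fit, table[part$test, columns, drop = FALSE])
    acc[r] <- mean(as.character(pred) == as.character(table$species_id[part$test]))
  }
  structure(list(label = label, columns = columns, accuracies = acc,
                 mean_accuracy = mean(acc), n_reps = n_reps,
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: mean identification success %.1f%% (%d replicates, sd %.1f%%)\n",
              x$label, 100 * x$mean_accuracy, x$n_reps,
              100 * stats::sd(x$accuracies)))
  invisible(x)
}

#' Compare feature sets under paired cross-validation
#'
#' Evaluates every feature set on the identical sequence of replicate
#' partitions (replicate r of every set uses the stream seeded
#' `seed + r`), so per-replicate accuracies are paired across sets and
#' mean differences are free of partition noise.
#'
#' @param table Trait table (one row per image).
#' @param specs Named list mapping feature-set label to trait columns,
#'   e.g. [feature_sets()].
#' @param n_reps,train_frac,seed,basis,degree,lambda As in
#'   [cv_success_rate()].
#' @return Object of class `cv_comparison`: `results` (list of
#'   `cv_result`), `summary` (data frame ranked by mean accuracy), and the
#'   paired per-replicate accuracy matrix.
#' @export
compare_feature_sets <- function(table, specs = feature_sets(), n_reps = 1000L,
                                 train_frac = 0.7, seed = 1L,
                                 basis = "linear", degree = 2L, lambda = 0) {
  if (length(specs) < 1L) stop("specs must name at least one feature set")
  if (is.null(names(specs)) || any(names(specs) == ""))
    stop("specs must be a named list")
  results <- lapply(names(specs), function(lab)
    cv_success_rate(table, specs[[lab]], label = lab, n_reps = n_reps,
                    train_frac = train_frac, seed = seed,
                    basis = basis, degree = degree, lambda = lambda))
  names(results) <- names(specs)
  accmat <- vapply(results, function(r) r$accuracies, numeric(n_reps))
  accmat <- matrix(accmat, nrow = n_reps, dimnames = list(NULL, names(specs)))
  smry <- data.frame(
    model = names(specs),
    mean_accuracy = vapply(results, function(r) r$mean_accuracy, 0),
    sd = apply(accmat, 2L, stats::sd),
    n_reps = n_reps, seed = as.integer(seed),
    row.names = NULL
  )
  smry <- smry[order(-smry$mean_accuracy), , drop = FALSE]
  rownames(smry) <- NULL
  structure(list(results = results, summary = smry, accuracies = accmat,
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("identification success by feature set (paired cross-validation):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %5.1f%%  (sd %.1f%%)\n", s$model[i],
                100 * s$mean_accuracy[i], 100 * s$sd[i]))
  invisible(x)
}

#' Paired accuracy differences between two compared feature sets
#'
#' @param comparison A `cv_comparison`.
#' @param a,b Feature-set labels.
#' @return Numeric vector of per-replicate differences (a minus b).
#' @export
paired_differences <- function(comparison, a, b) {
  stopifnot(inherits(comparison, "cv_comparison"))
  if (!all(c(a, b) %in% colnames(comparison$accuracies)))
    stop("both labels must be present in the comparison")
  comparison$accuracies[, a] - comparison$accuracies[, b]
}
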