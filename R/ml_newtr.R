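NEWTR_ALGORITHMS <- c("LINEAR", "RIDGE", "LASSO", "ELASTIC_NET",
                      "RANDOM_FOREST", "SVR_RBF")

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either
#'   vector is constant.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Two-sample Student's t-test (two-tailed)
#'
#' Pooled-variance classical variant by default; Welch's unequal-variance
#' form by flag.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param welch use Welch's correction instead of pooled variance.
#' @return List with `t` and `p` (two-tailed).
#' @export
ttest_two_tailed <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (!welch) {
    n1 <- length(group_a); n2 <- length(group_b)
    sp2 <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
      (n1 + n2 - 2)
    if (sp2 == 0) stop("zero pooled variance")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Deterministic train/test split of gene ids
#'
#' @param gene_ids character vector (n >= 2).
#' @param ratio training fraction in (0, 1); `round(ratio * n)` genes go to
#'   the training set.
#' @param seed integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
train_test_split <- function(gene_ids, ratio = 0.8, seed = 1) {
  n <- length(gene_ids)
  if (n < 2) stop("need at least 2 genes to split")
  stopifnot(ratio > 0, ratio < 1)
  train_n <- round(ratio * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- sample(gene_ids, train_n)
  list(train = train, test = setdiff(gene_ids, train))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specify a New_TR regression model
#'
#' @param algorithm one of `"LINEAR"`, `"RIDGE"`, `"LASSO"`,
#'   `"ELASTIC_NET"`, `"RANDOM_FOREST"`, `"SVR_RBF"`.
#' @param hyperparams named list overriding the per-family defaults
#'   (`lambda` for the penalized linear models, `num.trees` for the forest,
#'   `cost`/`gamma`/`epsilon` for the SVR).
#' @param seed integer seed controlling the split and any model randomness.
#' @param target `"PA"` or `"PA_PER_MRNA"`.
#' @param log_transform_target log10-transform the response before fitting
#'   (Spearman evaluation is unaffected; default TRUE).
#' @return A `model_spec` object.
#' @export
model_spec <- function(algorithm = "SVR_RBF", hyperparams = list(), seed = 1,
                       target = c("PA", "PA_PER_MRNA"),
                       log_transform_target = TRUE) {
  algorithm <- match.arg(algorithm, NEWTR_ALGORITHMS)
  target <- match.arg(target)
  structure(list(algorithm = algorithm, hyperparams = hyperparams,
                 seed = seed, target = target,
                 log_transform_target = log_transform_target),
            class = "model_spec")
}

response_column <- function(target) {
  switch(target, PA = "pa", PA_PER_MRNA = "pa_per_mrna")
}

# Fit one regressor on training rows and predict for all rows.
# X matrices are already standardized.
fit_predict <- function(x_train, y_train, x_all, algorithm, hyperparams, seed) {
  hp <- hyperparams
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  switch(algorithm,
    LINEAR = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- lm(.y ~ ., data = df)
      list(fit = fit, pred = unname(predict(fit, as.data.frame(x_all))))
    },
    RIDGE = glmnet_fit(x_train, y_train, x_all, alpha = 0,
                       lambda = hp$lambda %||% 0.1),
    LASSO = glmnet_fit(x_train, y_train, x_all, alpha = 1,
                       lambda = hp$lambda %||% 0.01),
    ELASTIC_NET = glmnet_fit(x_train, y_train, x_all,
                             alpha = hp$alpha %||% 0.5,
                             lambda = hp$lambda %||% 0.01),
    RANDOM_FOREST = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- ranger::ranger(.y ~ ., data = df,
                            num.trees = hp$num.trees %||% 500,
                            seed = seed, num.threads = 1)
      list(fit = fit,
           pred = predict(fit, as.data.frame(x_all), num.threads = 1)$predictions)
    },
    SVR_RBF = {
      fit <- e1071::svm(x_train, y_train, type = "eps-regression",
                        kernel = "radial", cost = hp$cost %||% 1,
                        gamma = hp$gamma %||% (1 / ncol(x_train)),
                        epsilon = hp$epsilon %||% 0.1, scale = FALSE)
      list(fit = fit, pred = unname(predict(fit, x_all)))
    })
}

glmnet_fit <- function(x_train, y_train, x_all, alpha, lambda) {
  # glmnet needs >= 2 columns; pad a zero column for single-feature fits
  pad <- ncol(x_train) == 1
  if (pad) {
    x_train <- cbind(x_train, .pad = 0)
    x_all <- cbind(x_all, .pad = 0)
  }
  fit <- glmnet::glmnet(x_train, y_train, alpha = alpha, lambda = lambda,
                        standardize = FALSE)
  list(fit = fit, pred = as.numeric(predict(fit, x_all, s = lambda)))
}

standardize_train <- function(x_train, x_all) {
  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  if (any(sg == 0)) {
    stop("degenerate (constant) input column: ",
         paste(colnames(x_train)[sg == 0], collapse = ", "))
  }
  list(train = scale(x_train, mu, sg), all = scale(x_all, mu, sg))
}

#' Fit the learned translation rate (New_TR)
#'
#' Trains one regressor on the two biophysical predictors — log10
#' initiation rate and elongation rate, z-scored on training statistics —
#' against the (log10) response on an 80:20 split, predicts New_TR for all
#' genes, and scores Spearman correlation on the test split and the full
#' set against the untransformed response.
#'
#' @param rates tibble with `gene_id`, `InitRate`, `ElongRate` (from
#'   [compute_rate_profiles()]); genes with `NA` rates are excluded before
#'   the split.
#' @param responses tibble from [build_response()].
#' @param spec a [model_spec()].
#' @param ratio training fraction (default 0.8).
#' @return A `newtr_fit` object.
#' @export
fit_new_tr <- function(rates, responses, spec = model_spec(), ratio = 0.8) {
  dat <- dplyr::inner_join(
    dplyr::filter(rates, !is.na(.data$InitRate), !is.na(.data$ElongRate)),
    responses, by = "gene_id")
  if (nrow(dat) < 5) stop("too few genes with rates and responses")
  y_raw <- dat[[response_column(spec$target)]]
  y <- if (spec$log_transform_target) log10(y_raw) else y_raw
  x <- cbind(log10_init = log10(dat$InitRate), elong = dat$ElongRate)
  rownames(x) <- dat$gene_id

  split <- train_test_split(dat$gene_id, ratio, spec$seed)
  tr <- dat$gene_id %in% split$train
  sx <- standardize_train(x[tr, , drop = FALSE], x)
  fp <- fit_predict(sx$train, y[tr], sx$all, spec$algorithm,
                    spec$hyperparams, spec$seed)
  new_tr <- setNames(fp$pred, dat$gene_id)
  structure(list(
    spec = spec,
    new_tr = tibble::tibble(gene_id = dat$gene_id, new_tr = unname(new_tr)),
    spearman_test = spearman_cor(new_tr[split$test], y_raw[match(split$test, dat$gene_id)]),
    spearman_total = spearman_cor(unname(new_tr), y_raw),
    split_sizes = c(train_n = length(split$train), test_n = length(split$test)),
    split = split, model = fp$fit), class = "newtr_fit")
}

#' @export
print.newtr_fit <- function(x, ...) {
  cat(sprintf("New_TR fit [%s -> %s]: Spearman test %.4f, total %.4f (n = %d/%d train/test)\n",
              x$spec$algorithm, x$spec$target, x$spearman_test,
              x$spearman_total, x$split_sizes["train_n"], x$split_sizes["test_n"]))
  invisible(x)
}

#' @export
tidy.newtr_fit <- function(x, ...) x$new_tr

#' @export
glance.newtr_fit <- function(x, ...) {
  tibble::tibble(algorithm = x$spec$algorithm, target = x$spec$target,
                 spearman_test = x$spearman_test,
                 spearman_total = x$spearman_total,
                 train_n = unname(x$split_sizes["train_n"]),
                 test_n = unname(x$split_sizes["test_n"]))
}

#' Compare the six New_TR regressor families
#'
#' Fits every algorithm for one or both targets with a shared split seed
#' and tabulates Spearman scores (the layout of a models-by-targets report
#' table).
#'
#' @param rates,responses as in [fit_new_tr()].
#' @param targets character vector of targets.
#' @param seed shared split seed.
#' @param ratio training fraction.
#' @return A tibble `algorithm`, `target`, `spearman_test`, `spearman_total`.
#' @export
compare_newtr_models <- function(rates, responses,
                                 targets = c("PA", "PA_PER_MRNA"),
                                 seed = 1, ratio = 0.8) {
  grid <- tidyr::expand_grid(algorithm = NEWTR_ALGORITHMS, target = targets)
  purrr::pmap_dfr(grid, function(algorithm, target) {
    fit <- fit_new_tr(rates, responses,
                      model_spec(algorithm, seed = seed, target = target),
                      ratio)
    glance(fit)
  })
}
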