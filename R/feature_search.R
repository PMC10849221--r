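CANONICAL_FEATURES <- c("Type", "uAUG", "Start", "Stop", "CAI", "tAI",
                        "MFE_p1_p30", "Length", "Nend", "Instability")

#' Enumerate feature subsets to combine with New_TR
#'
#' Yields every subset of each size exactly once, sizes `k_min..k_max`, in
#' lexicographic order within a size. New_TR itself is implicitly part of
#' every model and is not listed.
#'
#' @param optional_features candidate feature names (default the canonical
#'   ten).
#' @param k_min,k_max subset-size range.
#' @return A list of character vectors (possibly including the empty
#'   subset, i.e. New_TR alone).
#' @export
enumerate_subsets <- function(optional_features = CANONICAL_FEATURES,
                              k_min = 0, k_max = length(optional_features)) {
  if (anyDuplicated(optional_features)) stop("duplicate feature names")
  stopifnot(k_min >= 0, k_max <= length(optional_features), k_min <= k_max)
  out <- list()
  for (k in seq(k_min, k_max)) {
    if (k == 0) {
      out[[length(out) + 1]] <- character(0)
    } else {
      cmb <- combn(optional_features, k, simplify = FALSE)
      out <- c(out, cmb)
    }
  }
  out
}

#' Exhaustive feature-combination search around New_TR
#'
#' For every subset of the optional features (sizes in `k_range`), trains a
#' regressor on New_TR plus the subset's encoded columns using one shared
#' train/test split (scores are comparable across subsets), records the
#' per-size argmax of the test-set Spearman correlation (ties broken by
#' enumeration order), and re-evaluates each winner on the full dataset.
#'
#' @param feature_tbl encoded feature table from [build_feature_table()]
#'   with a `new_tr` column (see [add_new_tr()]).
#' @param spec a [model_spec()]; its seed fixes the shared split.
#' @param k_range subset sizes to search (default 0:10).
#' @param optional_features candidate features (default the canonical ten,
#'   intersected with what the table retains).
#' @param ratio training fraction.
#' @return A `feature_search` object: per-k winners (`best`), the full
#'   score log (`all_scores`) and `n_models`.
#' @export
search_best <- function(feature_tbl, spec = model_spec(), k_range = 0:10,
                        optional_features = NULL, ratio = 0.8) {
  if (length(k_range) == 0) stop("empty k_range")
  if (!"new_tr" %in% names(feature_tbl)) {
    stop("feature table lacks a new_tr column; call add_new_tr() first")
  }
  blocks <- attr(feature_tbl, "feature_blocks")
  if (is.null(blocks)) stop("feature table lacks encoding blocks; use build_feature_table()")
  if (is.null(optional_features)) {
    optional_features <- intersect(CANONICAL_FEATURES, names(blocks))
  }
  k_range <- k_range[k_range <= length(optional_features)]

  y_raw <- feature_tbl[[response_column(spec$target)]]
  y <- if (spec$log_transform_target) log10(y_raw) else y_raw
  split <- train_test_split(feature_tbl$gene_id, ratio, spec$seed)
  tr <- feature_tbl$gene_id %in% split$train
  te <- !tr

  score_subset <- function(subset) {
    cols <- c("new_tr", unlist(blocks[subset], use.names = FALSE))
    x <- as.matrix(feature_tbl[cols])
    keep <- apply(x[tr, , drop = FALSE], 2, sd) > 0
    keep["new_tr"] <- TRUE
    x <- x[, keep, drop = FALSE]
    sx <- standardize_train(x[tr, , drop = FALSE], x)
    fp <- fit_predict(sx$train, y[tr], sx$all, spec$algorithm,
                      spec$hyperparams, spec$seed)
    list(test = suppressWarnings(spearman_cor(fp$pred[te], y_raw[te])),
         total = suppressWarnings(spearman_cor(fp$pred, y_raw)))
  }

  all_rows <- list()
  best_rows <- list()
  n_models <- 0L
  for (k in sort(k_range)) {
    subsets <- enumerate_subsets(optional_features, k, k)
    best_score <- -Inf
    best_subset <- NULL
    best_total <- NA_real_
    for (subset in subsets) {
      sc <- score_subset(subset)
      n_models <- n_models + 1L
      all_rows[[length(all_rows) + 1]] <- tibble::tibble(
        k = k, subset = paste(subset, collapse = "+"),
        spearman_test = sc$test, spearman_total = sc$total)
      if (!is.na(sc$test) && sc$test > best_score) {
        best_score <- sc$test
        best_subset <- subset
        best_total <- sc$total
      }
    }
    best_rows[[length(best_rows) + 1]] <- tibble::tibble(
      k = k, subset = paste(best_subset, collapse = "+"),
      spearman_test = best_score, spearman_total = best_total)
  }
  structure(list(best = dplyr::bind_rows(best_rows),
                 all_scores = dplyr::bind_rows(all_rows),
                 n_models = n_models, spec = spec, split = split),
            class = "feature_search")
}

#' Attach New_TR predictions to a feature table
#'
#' @param feature_tbl encoded feature table.
#' @param fit a `newtr_fit`.
#' @return The table with a `new_tr` column (inner join on `gene_id`).
#' @export
add_new_tr <- function(feature_tbl, fit) {
  out <- dplyr::inner_join(feature_tbl, tidy(fit), by = "gene_id")
  attr(out, "feature_blocks") <- attr(feature_tbl, "feature_blocks")
  out
}

#' @export
print.feature_search <- function(x, ...) {
  cat(sprintf("Feature-combination search: %d models (%s, target %s)\n",
              x$n_models, x$spec$algorithm, x$spec$target))
  print(x$best)
  invisible(x)
}

#' @export
tidy.feature_search <- function(x, ...) x$best

#' @export
glance.feature_search <- function(x, ...) {
  i <- which.max(x$best$spearman_test)
  tibble::tibble(n_models = x$n_models, best_k = x$best$k[i],
                 best_subset = x$best$subset[i],
                 spearman_test = x$best$spearman_test[i],
                 spearman_total = x$best$spearman_total[i])
}
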