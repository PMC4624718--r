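# Feature assembly and the random-forest ddG model with repeated k-fold and
# leave-one-protein-out cross-validation.

#' Assemble the model feature table
#'
#' One row per curated mutation record: the 13 profile features, the six
#' sequence features (computed from the mutation tokens), and any optional
#' external potential columns, in a fixed, documented column order. Records
#' without a matching profile-feature row are listed in an exclusion report
#' (attribute `exclusions`), never silently dropped.
#'
#' @param curated curated mutation table (see [curate_mutations()]); rows
#'   are identified by `complex_id|chain|mutations`.
#' @param profile_features data frame of the 13 profile features with a
#'   `record_id` column matching `complex_id|chain|mutations`.
#' @param external optional data frame of additional numeric potential
#'   columns with a `record_id` column.
#' @return Data frame with columns: record_id, complex_id, the 13 profile
#'   features, d_hydrophobic...d_volume, any external columns, and ddg_exp.
#' @export
assemble_features <- function(curated, profile_features, external = NULL) {
  rid <- paste(curated$complex_id, curated$chain, curated$mutations,
               sep = "|")
  hit <- match(rid, profile_features$record_id)
  excl <- rid[is.na(hit)]
  keep <- !is.na(hit)
  sf <- t(vapply(which(keep), function(i) {
    s <- parse_mutations(curated$mutations[i])
    c(pharmacophore_deltas(s$wt, s$mut), d_volume = volume_delta(s$wt, s$mut))
  }, numeric(6)))
  pf <- profile_features[hit[keep], setdiff(names(profile_features),
                                            "record_id"), drop = FALSE]
  out <- data.frame(record_id = rid[keep],
                    complex_id = curated$complex_id[keep],
                    pf, sf,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(external)) {
    ehit <- match(rid[keep], external$record_id)
    ext <- external[ehit, setdiff(names(external), "record_id"),
                    drop = FALSE]
    if (anyNA(ehit)) stop("external columns missing for ",
                          sum(is.na(ehit)), " record(s)")
    out <- cbind(out, ext)
  }
  out$ddg_exp <- curated$ddg_exp[keep]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("record_id", "complex_id", "ddg_exp"))
}

#' Train the random-forest ddG model
#'
#' Fits a regression forest of `ntree` trees. When `mtry` is not given it is
#' tuned over {2, 4, 6, 8, floor(p/3)} by RMSE on an internal testing split
#' (15% of the rows) and the final forest is refit on all rows. Feature
#' importance is reported both as the permutation increase in residual error
#' and as total node-purity gain.
#'
#' @param table feature table from [assemble_features()] (columns
#'   `record_id`/`complex_id` optional); must contain `ddg_exp`.
#' @param ntree number of trees.
#' @param mtry variables tried per split; NULL to tune.
#' @param seed RNG seed recorded in the model.
#' @param test_fraction fraction of rows held out for mtry tuning.
#' @return Object of class `ddg_rf`: the fitted forest, column schema,
#'   configuration and importance table.
#' @export
train_rf <- function(table, ntree = 500L, mtry = NULL, seed = 1L,
                     test_fraction = 0.15) {
  stopifnot("ddg_exp" %in% names(table))
  y <- table$ddg_exp
  if (length(y) < 30L) stop("need at least 30 rows with experimental ddG")
  if (sd(y) == 0) stop("constant target")
  cols <- feature_columns(table)
  x <- as.matrix(table[, cols, drop = FALSE])
  p <- length(cols)
  set.seed(seed)
  if (is.null(mtry)) {
    cand <- sort(unique(pmin(p, c(2L, 4L, 6L, 8L, max(1L, p %/% 3L)))))
    n <- nrow(x)
    test_idx <- sample.int(n, max(1L, round(test_fraction * n)))
    rmse <- vapply(cand, function(m) {
      fit <- randomForest::randomForest(x[-test_idx, , drop = FALSE],
                                        y[-test_idx], ntree = ntree,
                                        mtry = m)
      sqrt(mean((predict(fit, x[test_idx, , drop = FALSE]) -
                   y[test_idx])^2))
    }, numeric(1))
    mtry <- cand[which.min(rmse)]
  }
  fit <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry,
                                    importance = TRUE)
  structure(list(forest = fit, schema = cols,
                 config = list(ntree = ntree, mtry = mtry, seed = seed),
                 importance = randomForest::importance(fit)),
            class = "ddg_rf")
}

#' @export
print.ddg_rf <- function(x, ...) {
  cat("ddg_rf: ", x$config$ntree, " trees, mtry = ", x$config$mtry,
      ", ", length(x$schema), " features, seed = ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Predict ddG for new mutations
#'
#' @param object a trained `ddg_rf` model.
#' @param newdata data frame containing all training feature columns.
#' @param ... unused.
#' @return Numeric vector of predicted ddG values (kcal/mol).
#' @export
predict.ddg_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$schema, names(newdata))
  if (length(missing) > 0L) {
    stop("schema mismatch; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(newdata) == 0L) return(numeric(0))
  as.numeric(predict(object$forest,
                     as.matrix(newdata[, object$schema, drop = FALSE])))
}

#' Cross-validate the ddG model
#'
#' Two schemes: `"kfold_repeated"` (k folds, `repeats` repeats; the Pearson
#' correlation between pooled out-of-fold predictions and experiment is
#' computed per repeat and summarized as mean +/- sd) and
#' `"leave_one_protein_out"` (every mutation record of one complex held out
#' at a time; the standard error of prediction -- the RMS residual -- is
#' reported per protein and pooled, with proteins having more than 10
#' mutants flagged).
#'
#' @param table feature table with `ddg_exp` and, for the protein-held-out
#'   scheme, `complex_id`.
#' @param scheme `"kfold_repeated"` or `"leave_one_protein_out"`.
#' @param k folds.
#' @param repeats repetitions of the k-fold scheme.
#' @param ntree,mtry forest parameters (mtry defaults to p/3 here; tuning
#'   belongs to [train_rf()]).
#' @param seed RNG seed.
#' @return For k-fold: list with `c_mean`, `c_sd`, `per_repeat`, `rmse`.
#'   For leave-one-protein-out: list with `per_protein` (data frame:
#'   complex_id, n, rmse), `rmse` (pooled standard error of prediction) and
#'   `big_proteins` (subset with more than 10 mutants).
#' @export
crossvalidate <- function(table, scheme = c("kfold_repeated",
                                            "leave_one_protein_out"),
                          k = 10L, repeats = 3L, ntree = 500L, mtry = NULL,
                          seed = 1L) {
  scheme <- match.arg(scheme)
  y <- table$ddg_exp
  cols <- feature_columns(table)
  x <- as.matrix(table[, cols, drop = FALSE])
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, p %/% 3L)
  set.seed(seed)
  if (scheme == "kfold_repeated") {
    cs <- numeric(repeats)
    rmses <- numeric(repeats)
    for (r in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(k)) {
        te <- fold == f
        fit <- randomForest::randomForest(x[!te, , drop = FALSE], y[!te],
                                          ntree = ntree, mtry = mtry)
        pred[te] <- predict(fit, x[te, , drop = FALSE])
      }
      cs[r] <- cor(pred, y)
      rmses[r] <- sqrt(mean((pred - y)^2))
    }
    list(scheme = scheme, c_mean = mean(cs), c_sd = sd(cs),
         per_repeat = cs, rmse = mean(rmses))
  } else {
    stopifnot("complex_id" %in% names(table))
    prot <- table$complex_id
    pred <- numeric(n)
    for (pid in unique(prot)) {
      te <- prot == pid
      fit <- randomForest::randomForest(x[!te, , drop = FALSE], y[!te],
                                        ntree = ntree, mtry = mtry)
      pred[te] <- predict(fit, x[te, , drop = FALSE])
    }
    per <- do.call(rbind, lapply(unique(prot), function(pid) {
      te <- prot == pid
      data.frame(complex_id = pid, n = sum(te),
                 rmse = sqrt(mean((pred[te] - y[te])^2)),
                 stringsAsFactors = FALSE)
    }))
    list(scheme = scheme, per_protein = per,
         rmse = sqrt(mean((pred - y)^2)),
         big_proteins = per[per$n > 10L, , drop = FALSE],
         c = cor(pred, y))
  }
}
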