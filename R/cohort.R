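# Cohort statistics: group comparison across the marker panel, and the
# model-agnostic importance-ranking harness with undersampling-repeat
# stability.

#' Compare markers between case and control groups
#'
#' Per marker, missing values are dropped pairwise, group means/SDs are
#' reported, and two two-sided tests are run: Welch's t test (pooled-variance
#' optional) and the Wilcoxon rank-sum test. No multiple-testing correction is
#' applied to the primary p-value columns; Benjamini-Hochberg adjusted columns
#' are emitted alongside.
#'
#' @param cohort a [MarkerCohort-class].
#' @param pooledVariance use the pooled-variance t test instead of Welch
#'   (default FALSE).
#' @return data.frame, one row per marker in panel order: marker, per-group n,
#'   mean, sd, \code{p_t}, \code{p_w}, \code{p_t_bh}, \code{p_w_bh}.
#' @export
compareGroups <- function(cohort, pooledVariance = FALSE) {
  M <- markerMatrix(cohort)
  g <- groupLabels(cohort)
  ca <- g == "case"
  if (!any(ca) || all(ca)) stop("both groups must be non-empty")
  rows <- lapply(rownames(M), function(mk) {
    x <- M[mk, ca]; y <- M[mk, !ca]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    pt <- pw <- NA_real_
    if (length(x) >= 2 && length(y) >= 2 && (sd(x) > 0 || sd(y) > 0)) {
      pt <- t.test(x, y, var.equal = pooledVariance)$p.value
      pw <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }
    data.frame(marker = mk,
               case_n = length(x), case_mean = mean(x), case_sd = sd(x),
               control_n = length(y), control_mean = mean(y), control_sd = sd(y),
               p_t = pt, p_w = pw)
  })
  out <- do.call(rbind, rows)
  out$p_t_bh <- p.adjust(out$p_t, method = "BH")
  out$p_w_bh <- p.adjust(out$p_w, method = "BH")
  out
}

# ---- importance backends ---------------------------------------------------
# Uniform contract: .fitBackend(backend, X, y, seed) -> model;
# .backendImportance(backend, model, X) -> named non-negative scores.
# Backends are consumed as established model/attribution engines; none of the
# attribution algorithms is reimplemented here.

.BACKENDS <- c("tree_shap", "additive_boosting", "attention_tabular")

.fitBackend <- function(backend, X, y, seed) {
  d <- xgb.DMatrix(X, label = y)
  if (backend == "tree_shap") {
    # gradient-boosted trees; global importance = mean |TreeSHAP| contribution
    params <- list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                   nthread = 1, seed = seed)
    xgb.train(params = params, data = d, nrounds = 100, verbose = 0)
  } else if (backend == "additive_boosting") {
    # depth-1 boosting = an additive (GAM-style) boosted model
    params <- list(objective = "binary:logistic", max_depth = 1, eta = 0.1,
                   nthread = 1, seed = seed)
    xgb.train(params = params, data = d, nrounds = 300, verbose = 0)
  } else if (backend == "attention_tabular") {
    stop("backend missing: no attention-based tabular network implementation ",
         "is available in this installation")
  } else {
    stop("unknown backend '", backend, "'; available: ",
         paste(.BACKENDS, collapse = ", "))
  }
}

.backendImportance <- function(model, X) {
  contrib <- predict(model, xgb.DMatrix(X), predcontrib = TRUE)
  sc <- colMeans(abs(contrib))
  sc[intersect(colnames(contrib), colnames(X))]  # drop the bias column
}

#' Available importance backends
#' @return character vector of backend identifiers.
#' @export
importanceBackends <- function() .BACKENDS

# features-by-participants matrix -> participants-by-features model matrix,
# median-filled; covariates optionally appended as features
.featureMatrix <- function(cohort, includeCovariates) {
  X <- t(markerMatrix(cohort))
  if (includeCovariates) {
    cd <- as.data.frame(colData(cohort))
    for (k in setdiff(colnames(cd), "group")) {
      v <- cd[[k]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- k
    }
  }
  filled <- 0L
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) {
      X[na, j] <- median(X[, j], na.rm = TRUE)
      filled <- filled + sum(na)
    }
  }
  attr(X, "medianFilled") <- filled
  X
}

#' Rank marker importance with a pluggable model backend
#'
#' Fits the named backend on the marker matrix (binary case/control labels)
#' and returns a global importance ranking. Backends satisfy one contract —
#' fit(features, labels), then a global importance score per feature — so the
#' harness does not depend on any particular attribution algorithm's
#' internals. Missing marker values are median-filled (the count is logged in
#' the report).
#'
#' @param cohort a [MarkerCohort-class].
#' @param backend one of [importanceBackends()].
#' @param includeCovariates also feed age/sex/bmi as features (default FALSE).
#' @param seed integer; fixed-seed runs are reproducible bit-for-bit.
#' @return list of class "importanceReport": \code{backend}, \code{scores}
#'   (named, original feature order), \code{ranking} (features ordered by
#'   decreasing importance), \code{seed}, \code{medianFilled}.
#' @export
rankImportance <- function(cohort, backend = "tree_shap",
                           includeCovariates = FALSE, seed = 1L) {
  backend <- match.arg(backend, .BACKENDS)
  X <- .featureMatrix(cohort, includeCovariates)
  y <- as.integer(groupLabels(cohort) == "case")
  model <- .fitBackend(backend, X, y, seed)
  scores <- .backendImportance(model, X)
  structure(list(backend = backend, scores = scores,
                 ranking = names(sort(scores, decreasing = TRUE)),
                 seed = as.integer(seed),
                 medianFilled = attr(X, "medianFilled")),
            class = "importanceReport")
}

#' @export
print.importanceReport <- function(x, ...) {
  cat(sprintf("importanceReport <%s>%s: top features\n", x$backend,
              if (!is.null(x$repeats)) sprintf(" (%d undersampled repeats)",
                                               length(x$repeats)) else ""))
  top <- utils::head(x$ranking, 10)
  for (i in seq_along(top))
    cat(sprintf("  %2d. %-14s %.4f\n", i, top[i], x$scores[top[i]]))
  if (!is.null(x$topkFrequency)) {
    cat(sprintf("top-%d frequency across repeats:\n", x$k))
    f <- sort(x$topkFrequency[x$topkFrequency > 0], decreasing = TRUE)
    for (nm in names(utils::head(f, 10)))
      cat(sprintf("  %-14s %d/%d\n", nm, f[nm], length(x$repeats)))
  }
  invisible(x)
}

#' Importance stability under majority-group undersampling
#'
#' Each repeat draws a without-replacement subsample of the majority group of
#' the same size as the minority group, refits the backend, and re-ranks; the
#' per-feature count of top-k appearances across repeats measures ranking
#' stability under class rebalancing.
#'
#' @inheritParams rankImportance
#' @param k top-k membership threshold (default 10).
#' @param repeats number of undersampled refits (default 5).
#' @return an "importanceReport" (fitted on the full data) with added
#'   \code{repeats} (list of rankings), \code{topkFrequency} and \code{k}.
#' @export
undersampleStability <- function(cohort, backend = "tree_shap", k = 10L,
                                 repeats = 5L, seed = 1L,
                                 includeCovariates = FALSE) {
  g <- groupLabels(cohort)
  nCase <- sum(g == "case"); nCtrl <- sum(g == "control")
  if (nCase == nCtrl)
    warning("groups already balanced: repeats differ only by model seed")
  minority <- if (nCase <= nCtrl) "case" else "control"
  majority <- setdiff(c("case", "control"), minority)
  m <- min(nCase, nCtrl)
  full <- rankImportance(cohort, backend, includeCovariates, seed)
  reps <- lapply(seq_len(repeats), function(r) {
    repSeed <- .deriveSeed(seed, sprintf("undersample_%d", r))
    set.seed(repSeed)
    keepMaj <- sample(which(g == majority), m)
    sub <- cohort[, sort(c(which(g == minority), keepMaj))]
    rankImportance(sub, backend, includeCovariates, repSeed)$ranking
  })
  feats <- names(full$scores)
  topk <- setNames(integer(length(feats)), feats)
  for (r in reps) {
    hit <- utils::head(r, k)
    topk[hit] <- topk[hit] + 1L
  }
  full$repeats <- reps
  full$topkFrequency <- topk
  full$k <- as.integer(k)
  full
}

#' Write an importance report (CSV ranking + JSON stability summary)
#'
#' @param report an "importanceReport".
#' @param csvPath ranking CSV path.
#' @param jsonPath optional stability JSON path (needs the jsonlite package).
#' @return invisible NULL.
#' @export
writeImportanceReport <- function(report, csvPath, jsonPath = NULL) {
  df <- data.frame(rank = seq_along(report$ranking), feature = report$ranking,
                   score = unname(report$scores[report$ranking]))
  .atomicWrite(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("# circamark %s importance (%s backend, seed %d)",
                       packageVersion("circamark"), report$backend, report$seed), con)
    write.csv(df, con, row.names = FALSE)
  }, csvPath)
  if (!is.null(jsonPath)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for the JSON stability report")
    payload <- list(backend = report$backend, seed = report$seed,
                    k = report$k, repeats = report$repeats,
                    topkFrequency = as.list(report$topkFrequency))
    .atomicWrite(function(tmp)
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE),
      jsonPath)
  }
  invisible(NULL)
}
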