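#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate dnorm median optim pnorm predict quantile
#'   rbinom rlnorm rnorm runif rpois sd setNames var complete.cases
#' @importFrom utils head read.csv tail write.csv
NULL

# Deterministic sub-seed from a base seed and any tags; always in [1, 2^31-2]
# so nested RNG streams never collide across (round, algorithm, trial).
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 31 + code) %% 2147483629
    }
  }
  as.integer(h %% 2147483645) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Shannon entropy in bits of a discrete distribution given counts.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Model quality: AUC for categorical targets, R-squared for continuous
#'
#' Binary targets are scored by the area under the ROC curve of the
#' positive-class score; multi-class targets by macro-averaged one-vs-rest
#' AUC; continuous targets by the coefficient of determination.
#'
#' @param truth observed target (factor or numeric).
#' @param score for classification, a matrix of class scores with one column
#'   per class level (a single numeric vector is taken as the positive-class
#'   score of a binary problem); for regression, predicted values.
#' @return a single number: AUC in \[0, 1\] or R-squared (<= 1).
#' @export
model_quality <- function(truth, score) {
  if (is.factor(truth)) {
    lev <- levels(truth)
    if (is.null(dim(score))) {
      stopifnot(length(lev) == 2L)
      score <- cbind(1 - score, score)
      colnames(score) <- lev
    }
    if (length(unique(truth)) < 2L) return(NA_real_)
    if (length(lev) == 2L) {
      return(auc_binary(truth == lev[2L], score[, lev[2L]]))
    }
    aucs <- vapply(lev, function(cl) {
      if (!any(truth == cl) || all(truth == cl)) return(NA_real_)
      auc_binary(truth == cl, score[, cl])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  } else {
    ss_res <- sum((truth - score)^2)
    ss_tot <- sum((truth - mean(truth))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - ss_res / ss_tot
  }
}

auc_binary <- function(pos, score) {
  as.numeric(pROC::auc(response = factor(pos, levels = c(FALSE, TRUE)),
                       predictor = as.numeric(score),
                       quiet = TRUE, direction = "<"))
}

# Median/mode imputation fitted on one table, applied to another.
fit_imputer <- function(df) {
  lapply(df, function(col) {
    if (is.numeric(col)) {
      m <- median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    } else {
      tab <- table(col)
      if (length(tab) == 0) NA else names(tab)[which.max(tab)]
    }
  })
}

apply_imputer <- function(df, imp) {
  for (nm in names(imp)) {
    col <- df[[nm]]
    idx <- is.na(col)
    if (any(idx)) {
      col[idx] <- imp[[nm]]
      df[[nm]] <- col
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
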