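# Learner adapters: a uniform train/predict contract over the shipped
# roster. Training is pure given the seed. Classification adapters return a
# score matrix with one column per class level; regression adapters return
# predicted values.

train_learner <- function(algorithm, X, y, hp, seed) {
  set.seed(seed)
  classif <- is.factor(y)
  model <- switch(algorithm,
    dtree = {
      df <- data.frame(X, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df,
                   method = if (classif) "class" else "anova",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  maxdepth = hp$maxdepth,
                                                  minsplit = hp$minsplit,
                                                  xval = 0))
    },
    rforest = {
      mtry <- max(1L, min(ncol(X), round(hp$mtry_frac * ncol(X))))
      randomForest::randomForest(X, y, ntree = hp$ntree, mtry = mtry,
                                 nodesize = hp$nodesize)
    },
    gboost = {
      obj <- if (classif) {
        if (nlevels(y) == 2L) "binary:logistic" else "multi:softprob"
      } else "reg:squarederror"
      label <- if (classif) as.numeric(y) - 1 else y
      params <- list(objective = obj, eta = hp$eta, max_depth = hp$max_depth,
                     nthread = 1)
      if (classif && nlevels(y) > 2L) params$num_class <- nlevels(y)
      xgboost::xgboost(data = as.matrix(X), label = label, params = params,
                       nrounds = hp$nrounds, verbose = 0)
    },
    knn = list(X = X, y = y, k = hp$k),  # lazy learner: store the sample
    logreg = {
      Xg <- as.matrix(X)
      if (ncol(Xg) < 2L) Xg <- cbind(Xg, .pad = 0)
      fam <- if (classif) {
        if (nlevels(y) == 2L) "binomial" else "multinomial"
      } else "gaussian"
      glmnet::glmnet(Xg, y, family = fam, alpha = hp$alpha,
                     lambda = hp$lambda)
    },
    nbayes = e1071::naiveBayes(as.data.frame(X), y, laplace = hp$laplace),
    lsvm = e1071::svm(X, y, kernel = "linear", cost = hp$cost,
                      probability = TRUE),
    stop("unknown algorithm: ", algorithm)
  )
  structure(list(algorithm = algorithm, model = model, hp = hp,
                 classif = classif,
                 levels = if (classif) levels(y), seed = seed),
            class = "fitted_learner")
}

predict_learner <- function(fit, X) {
  m <- fit$model
  lev <- fit$levels
  if (fit$classif) {
    score <- switch(fit$algorithm,
      dtree = predict(m, data.frame(X, check.names = FALSE), type = "prob"),
      rforest = predict(m, X, type = "prob"),
      gboost = {
        p <- predict(m, as.matrix(X))
        if (length(lev) == 2L) cbind(1 - p, p)
        else matrix(p, ncol = length(lev), byrow = TRUE)
      },
      knn = {
        set.seed(fit$seed)
        pred <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
        pwin <- attr(pred, "prob")
        score <- matrix(0, nrow = nrow(X), ncol = length(lev))
        for (j in seq_along(lev)) {
          hit <- pred == lev[j]
          score[hit, j] <- pwin[hit]
          score[!hit, j] <- (1 - pwin[!hit]) / max(1L, length(lev) - 1L)
        }
        score
      },
      logreg = {
        Xg <- as.matrix(X)
        if (ncol(Xg) < 2L) Xg <- cbind(Xg, .pad = 0)
        p <- predict(m, Xg, type = "response")
        if (length(lev) == 2L) cbind(1 - p[, 1L], p[, 1L])
        else p[, , 1L]
      },
      nbayes = predict(m, as.data.frame(X), type = "raw"),
      lsvm = {
        p <- attr(predict(m, X, probability = TRUE), "probabilities")
        p[, lev, drop = FALSE]
      })
    score <- as.matrix(score)
    colnames(score) <- lev
    score
  } else {
    switch(fit$algorithm,
      dtree = predict(m, data.frame(X, check.names = FALSE)),
      rforest = predict(m, X),
      gboost = predict(m, as.matrix(X)),
      logreg = {
        Xg <- as.matrix(X)
        if (ncol(Xg) < 2L) Xg <- cbind(Xg, .pad = 0)
        drop(predict(m, Xg))
      },
      stop("algorithm ", fit$algorithm, " has no regression adapter"))
  }
}

# --- feature selection techniques ------------------------------------------

evaluator_scores <- function(evaluator, X, y, seed) {
  y_num <- if (is.factor(y)) as.numeric(y) else y
  switch(evaluator,
    none = rep(1, ncol(X)),
    infogain = apply(X, 2L, function(col) {
      if (is.factor(y)) information_gain(col, y) else variance_reduction(col, y)
    }),
    correlation = apply(X, 2L, function(col) {
      if (sd(col) == 0) return(0)
      abs(stats::cor(col, y_num))
    }),
    variance = apply(X, 2L, var),
    sym_uncert = apply(X, 2L, function(col) {
      if (!is.factor(y)) return(variance_reduction(col, y))
      f <- discretize_feature(col)
      hx <- entropy_bits(table(f))
      hy <- entropy_bits(table(y))
      if (hx + hy == 0) return(0)
      2 * information_gain(col, y) / (hx + hy)
    }),
    model_importance = {
      set.seed(seed)
      df <- data.frame(X, .y = y, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df,
                          method = if (is.factor(y)) "class" else "anova",
                          control = rpart::rpart.control(cp = 1e-4, xval = 0))
      imp <- fit$variable.importance
      out <- setNames(rep(0, ncol(X)), colnames(X))
      if (!is.null(imp)) out[names(imp)] <- imp
      out
    },
    stop("unknown evaluator: ", evaluator))
}

# Feature search methods over evaluator scores. "topk" ranks and keeps the
# top fraction; "forward" greedily adds the feature maximizing score minus a
# redundancy penalty (mean |correlation| with already-selected features).
select_features <- function(fs, X, y, mandatory = character(), seed = 1L) {
  feats <- colnames(X)
  free <- setdiff(feats, mandatory)
  if (fs$evaluator == "none" || length(free) == 0) return(feats)
  scores <- evaluator_scores(fs$evaluator, X[, free, drop = FALSE], y, seed)
  k <- max(1L, ceiling(fs$k_frac * length(free)))
  chosen <- if (fs$search == "topk") {
    free[order(-scores, seq_along(free))][seq_len(k)]
  } else {
    sel <- character()
    remaining <- free
    while (length(sel) < k && length(remaining) > 0) {
      penal <- vapply(remaining, function(f) {
        if (length(sel) == 0) return(0)
        cs <- abs(suppressWarnings(stats::cor(X[, f], X[, sel, drop = FALSE])))
        mean(cs, na.rm = TRUE)
      }, numeric(1))
      gain <- scores[match(remaining, free)] - 0.5 * penal
      pick <- remaining[order(-gain, seq_along(remaining))][1L]
      sel <- c(sel, pick)
      remaining <- setdiff(remaining, pick)
    }
    sel
  }
  union(mandatory, chosen)
}

# --- trial execution -------------------------------------------------------

# Numeric design matrix: factors one-hot encoded, ids/target dropped.
design_matrix <- function(tbl) {
  feats <- feature_names(tbl)
  cols <- list()
  for (nm in feats) {
    col <- tbl[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- col
    } else {
      f <- factor(col)
      for (lv in levels(f)) {
        cols[[paste0(nm, ".", lv)]] <- as.numeric(f == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- instance_ids(tbl)
  X
}

# Train one configuration on (X_train, y_train), score a list of evaluation
# sets; imputation and feature selection are fitted on the training fold
# only. Returns quality on the first evaluation set plus stored predictions.
execute_trial <- function(config, X_train, y_train, eval_sets, mandatory,
                          seed) {
  imp <- fit_imputer(as.data.frame(X_train))
  Xtr <- as.matrix(apply_imputer(as.data.frame(X_train), imp))
  keep <- select_features(config$fs, Xtr, y_train, mandatory, seed)
  Xtr <- Xtr[, keep, drop = FALSE]
  fit <- train_learner(config$algorithm, Xtr, y_train, config$hp, seed)
  preds <- lapply(eval_sets, function(es) {
    Xe <- as.matrix(apply_imputer(as.data.frame(es$X), imp))[, keep, drop = FALSE]
    predict_learner(fit, Xe)
  })
  quality <- model_quality(eval_sets[[1L]]$y, preds[[1L]])
  list(quality = quality, preds = preds, features = keep, fit = fit)
}
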