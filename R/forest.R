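# Random-forest engines.
#
# Gini-criterion forests and all probability classification use ranger.
# No installed forest implementation offers the entropy split criterion, so
# entropy-criterion importance comes from a bagged ensemble of rpart trees
# grown with split = "information" on bootstrap samples and sqrt(p)-sized
# random feature subspaces; per-variable importance is the summed impurity
# improvement of the primary splits, accumulated over trees — the same
# impurity-decrease notion ranger reports for gini.

fit_importance <- function(X, y, criterion, n_trees, seed) {
  y <- factor(y)
  if (nlevels(y) < 2) abort("labels contain a single class")
  if (criterion == "gini") {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = n_trees,
      importance = "impurity", seed = seed, num.threads = 1,
      classification = TRUE
    )
    imp <- fit$variable.importance
    out <- setNames(numeric(ncol(X)), colnames(X))
    out[names(imp)] <- imp
    return(out)
  }
  # entropy: bagged information-criterion trees
  set.seed(seed)
  p <- ncol(X)
  mtry <- max(1L, floor(sqrt(p)))
  imp <- setNames(numeric(p), colnames(X))
  n <- nrow(X)
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (b in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sample.int(p, mtry)
    df <- as.data.frame(X[rows, feats, drop = FALSE])
    df$.y <- y[rows]
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = "information"),
                        control = ctrl)
    sp <- fit$splits
    if (!is.null(sp) && nrow(sp) > 0) {
      # with maxcompete = maxsurrogate = 0 all rows are primary splits
      gains <- tapply(sp[, "improve"], rownames(sp), sum)
      imp[names(gains)] <- imp[names(gains)] + gains
    }
  }
  imp / n_trees
}

# Probability forest (ranger) trained once; returns P(first level) for the
# test rows.
forest_prob <- function(X_train, y_train, X_test, n_trees, seed,
                        positive) {
  y <- factor(y_train)
  fit <- ranger::ranger(
    x = as.data.frame(X_train), y = y, num.trees = n_trees,
    probability = TRUE, seed = seed, num.threads = 1
  )
  pr <- predict(fit, data = as.data.frame(X_test),
                num.threads = 1)$predictions
  pr[, positive]
}
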