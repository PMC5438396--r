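#' Classifier specification
#'
#' One constructor for the five classifier families used by the sweep,
#' with their stated hyperparameters as defaults: Gaussian naive Bayes
#' with Laplace-smoothed class priors; C-SVC with RBF kernel and
#' convergence tolerance 1e-3 (C = 1, gamma = 1/p as conventional
#' defaults); sequential-covering rule induction with pureness 0.99 and
#' information-gain scoring; 3-nearest-neighbour with Manhattan distance
#' and inverse-distance vote weights; and a 1-hidden-layer (20 sigmoid
#' units) perceptron trained 10,000 full-batch epochs at learning rate 0.2
#' with momentum 0.15. Unknown hyperparameter names are rejected.
#'
#' @param kind One of `"nb"`, `"svm"`, `"rule"`, `"knn"`, `"ann"`.
#' @param ... Hyperparameter overrides (see defaults in source).
#' @param seed Seed for stochastic fits (ANN weight initialization).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("nb", "svm", "rule", "knn", "ann"),
                            ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    nb = list(laplace = 1, var_floor_frac = 1e-9),
    svm = list(cost = 1, gamma = NULL, tolerance = 0.001),
    rule = list(pureness = 0.99, min_coverage = 2, max_conditions = 8),
    knn = list(k = 3, weighted = TRUE),
    ann = list(hidden = 20, epochs = 10000, learning_rate = 0.2,
               momentum = 0.15)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameters for ", kind, ": ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(list(kind = kind, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

standardizes <- function(kind) kind %in% c("svm", "knn", "ann")

sigmoid <- function(x) 1 / (1 + exp(-x))

fit_ann <- function(X, y01, hp, seed) {
  set.seed(seed)
  p <- ncol(X); h <- hp$hidden; n <- nrow(X)
  W1 <- matrix(stats::runif((p + 1) * h, -0.5, 0.5), p + 1, h)
  W2 <- matrix(stats::runif(h + 1, -0.5, 0.5), h + 1, 1)
  V1 <- W1 * 0; V2 <- W2 * 0
  Xb <- cbind(1, X)
  for (e in seq_len(hp$epochs)) {
    H <- sigmoid(Xb %*% W1)
    Hb <- cbind(1, H)
    o <- sigmoid(Hb %*% W2)
    d_o <- (o - y01) * o * (1 - o)            # squared-error loss
    g2 <- crossprod(Hb, d_o) / n
    d_h <- (d_o %*% t(W2[-1, , drop = FALSE])) * H * (1 - H)
    g1 <- crossprod(Xb, d_h) / n
    V2 <- hp$momentum * V2 - hp$learning_rate * g2
    V1 <- hp$momentum * V1 - hp$learning_rate * g1
    W2 <- W2 + V2
    W1 <- W1 + V1
  }
  list(W1 = W1, W2 = W2)
}

#' Train a classifier on a cohort table restricted to a feature list
#'
#' SVM, kNN and ANN inputs are standardized (z-score with center/scale fit
#' on the training split only); naive Bayes and rule induction operate on
#' raw values. Prediction rejects feature sets not matching training.
#'
#' @param spec A [classifier_spec()] (or a kind string).
#' @param data Training data frame.
#' @param features Feature column names.
#' @param label_col Class label column (binary).
#' @return Object of class `et_model` with a [predict()] method.
#' @export
train_classifier <- function(spec, data, features, label_col = "group") {
  if (is.character(spec)) spec <- classifier_spec(spec)
  labels <- as.character(data[[label_col]])
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training data must contain 2 classes")
  if (spec$kind %in% c("nb", "svm", "ann") &&
      min(table(labels)) < 2) {
    stop("need at least 2 subjects per class for ", spec$kind)
  }
  X <- as.matrix(data[features])
  storage.mode(X) <- "double"
  center <- scale_ <- NULL
  if (standardizes(spec$kind)) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$kind,
    nb = {
      gvar <- apply(X, 2, stats::var)
      by_class <- lapply(classes, function(cl) {
        Xi <- X[labels == cl, , drop = FALSE]
        list(mean = colMeans(Xi),
             var = pmax(apply(Xi, 2, stats::var),
                        hp$var_floor_frac * gvar, 1e-12))
      })
      names(by_class) <- classes
      n_c <- table(factor(labels, classes))
      priors <- (as.numeric(n_c) + hp$laplace) /
        (length(labels) + hp$laplace * length(classes))
      list(by_class = by_class,
           log_prior = stats::setNames(log(priors), classes))
    },
    svm = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(X) else hp$gamma
      e1071::svm(X, factor(labels, classes), type = "C-classification",
                 kernel = "radial", cost = hp$cost, gamma = gamma,
                 tolerance = hp$tolerance, scale = FALSE)
    },
    rule = induce_rules(data, features, label_col,
                        pureness = hp$pureness,
                        min_coverage = hp$min_coverage,
                        max_conditions = hp$max_conditions),
    knn = list(X = X, y = labels),
    ann = fit_ann(X, as.numeric(labels == classes[[2]]), hp, spec$seed)
  )
  structure(list(spec = spec, fit = fit, features = features,
                 classes = classes, center = center, scale = scale_),
            class = "et_model")
}

predict_knn <- function(model, X) {
  hp <- model$spec$hyperparameters
  tr <- model$fit$X; y <- model$fit$y
  classes <- model$classes
  apply(X, 1, function(q) {
    d <- colSums(abs(t(tr) - q))
    if (any(d == 0)) {
      tab <- table(factor(y[d == 0], classes))
      return(names(which.max(tab)))
    }
    k <- min(hp$k, length(d))
    nn <- order(d)[seq_len(k)]
    w <- if (isTRUE(hp$weighted)) 1 / d[nn] else rep(1, k)
    votes <- tapply(w, factor(y[nn], classes), sum, default = 0)
    names(which.max(votes))
  })
}

#' Predict class labels (and scores) for new subjects
#'
#' @param object An `et_model` from [train_classifier()].
#' @param newdata Data frame containing the training features.
#' @param type `"class"` for labels, `"prob"` for class scores (naive
#'   Bayes posterior probabilities; ANN sigmoid output; others fall back
#'   to 0/1 indicator scores).
#' @param ... Unused.
#' @return Character vector of labels, or a matrix of class scores.
#' @export
predict.et_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks training features: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(newdata) == 0) {
    return(if (type == "class") character(0) else
      matrix(numeric(0), 0, 2, dimnames = list(NULL, object$classes)))
  }
  X <- as.matrix(newdata[object$features])
  storage.mode(X) <- "double"
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  classes <- object$classes
  kind <- object$spec$kind
  if (kind == "nb") {
    ll <- vapply(classes, function(cl) {
      par <- object$fit$by_class[[cl]]
      rowSums(stats::dnorm(X, rep(par$mean, each = nrow(X)),
                           rep(sqrt(par$var), each = nrow(X)),
                           log = TRUE)) + object$fit$log_prior[[cl]]
    }, numeric(nrow(X)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1,
                                       dimnames = list(NULL, classes))
    post <- exp(ll - apply(ll, 1, max))
    post <- post / rowSums(post)
    if (type == "prob") return(post)
    return(classes[max.col(post, ties.method = "first")])
  }
  if (kind == "svm") {
    lab <- as.character(predict(object$fit, X))
    if (type == "class") return(lab)
  } else if (kind == "rule") {
    lab <- apply_rules(object$fit, newdata)$label
    if (type == "class") return(lab)
  } else if (kind == "knn") {
    lab <- predict_knn(object, X)
    if (type == "class") return(lab)
  } else if (kind == "ann") {
    H <- sigmoid(cbind(1, X) %*% object$fit$W1)
    o <- as.numeric(sigmoid(cbind(1, H) %*% object$fit$W2))
    if (type == "prob") {
      return(matrix(c(1 - o, o), ncol = 2,
                    dimnames = list(NULL, classes)))
    }
    return(ifelse(o >= 0.5, classes[[2]], classes[[1]]))
  }
  # indicator scores for non-probabilistic kinds
  ind <- outer(lab, classes, "==") * 1
  dimnames(ind) <- list(NULL, classes)
  ind
}
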