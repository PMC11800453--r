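#' Optimizer and initialization settings for Angle-GMLVQ
#'
#' @param prototypes_per_class Number of prototypes per class (default 1).
#' @param max_iter Maximum number of full-batch gradient iterations.
#' @param tol Convergence threshold on the decrease of the summed cost
#'   between accepted iterations.
#' @param eta_prototype,eta_relevance Base step sizes for the prototype and
#'   relevance-transform updates. The relevance transform learns more slowly
#'   than the prototypes, the usual arrangement for matrix-relevance LVQ.
#' @param init_jitter Scale of the seeded Gaussian jitter added to the
#'   class-mean prototype initialization. Must be positive so that
#'   prototypes are well-defined directions even when a class mean is close
#'   to the origin (as it is for z-scored data with weak class separation).
#' @param max_halvings Maximum number of backtracking step halvings per
#'   iteration before declaring convergence.
#' @param seed Integer seed for the prototype jitter; the fit is otherwise
#'   deterministic.
#' @return A list of class `gmlvq_control`.
#' @export
gmlvq_control <- function(prototypes_per_class = 1L,
                          max_iter = 500L,
                          tol = 1e-7,
                          eta_prototype = 0.5,
                          eta_relevance = 0.1,
                          init_jitter = 0.05,
                          max_halvings = 30L,
                          seed = 1L) {
  stopifnot(prototypes_per_class >= 1, max_iter >= 1, tol > 0,
            eta_prototype > 0, eta_relevance > 0, init_jitter > 0,
            max_halvings >= 1)
  structure(list(prototypes_per_class = as.integer(prototypes_per_class),
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 eta_prototype = eta_prototype,
                 eta_relevance = eta_relevance,
                 init_jitter = init_jitter,
                 max_halvings = as.integer(max_halvings),
                 seed = as.integer(seed)),
            class = "gmlvq_control")
}

NORM_EPS <- 1e-12

#' Angle-based dissimilarity between relevance-transformed vectors
#'
#' The dissimilarity at the heart of Angle-GMLVQ:
#' \deqn{d(x, w) = \frac{1 - \cos\theta}{2}, \qquad
#'   \cos\theta = \frac{\langle \Omega x, \Omega w\rangle}
#'                     {\lVert\Omega x\rVert\,\lVert\Omega w\rVert},}
#' which ranges over \[0, 1\] and depends only on the *directions* of the
#' transformed vectors: `d(a*x, b*w) == d(x, w)` for any positive scalars
#' `a`, `b`. It therefore captures relative differences (angles) between
#' feature patterns rather than absolute magnitudes.
#'
#' @param x,w Numeric vectors of equal length.
#' @param omega Optional relevance transform matrix (rows map feature space
#'   to the learned subspace); identity if `NULL`.
#' @return A single number in \[0, 1\].
#' @examples
#' angular_dissimilarity(c(1, 0), c(0, 1))  # right angle -> 0.5
#' @export
angular_dissimilarity <- function(x, w, omega = NULL) {
  stopifnot(length(x) == length(w))
  if (!is.null(omega)) {
    x <- drop(omega %*% x)
    w <- drop(omega %*% w)
  }
  nx <- sqrt(sum(x^2))
  nw <- sqrt(sum(w^2))
  if (nx < NORM_EPS || nw < NORM_EPS) {
    stop("degenerate input: transformed vector has (near-)zero norm",
         call. = FALSE)
  }
  ct <- sum(x * w) / (nx * nw)
  (1 - min(1, max(-1, ct))) / 2
}

# Cost and gradients of the GLVQ relative-distance cost under the angular
# dissimilarity, fully vectorized over samples. W: K x nfeat prototypes,
# omega: p x nfeat, X: n x nfeat, y_idx: class index per sample,
# proto_class: class index per prototype.
gmlvq_cost_grad <- function(W, omega, X, y_idx, proto_class,
                            gradients = TRUE) {
  U <- X %*% t(omega)                 # n x p transformed samples
  V <- W %*% t(omega)                 # K x p transformed prototypes
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  if (any(nu < NORM_EPS)) {
    stop("degenerate sample(s): zero norm after relevance transform",
         call. = FALSE)
  }
  if (any(nv < NORM_EPS)) {
    stop("degenerate prototype: zero norm after relevance transform",
         call. = FALSE)
  }
  C <- (U %*% t(V)) / outer(nu, nv)
  C[C > 1] <- 1
  C[C < -1] <- -1
  D <- (1 - C) / 2                    # n x K angular dissimilarities

  n <- nrow(X)
  K <- nrow(W)
  same <- matrix(proto_class[rep(seq_len(K), each = n)] ==
                   y_idx, n, K)
  Dp <- D
  Dp[!same] <- Inf
  Dm <- D
  Dm[same] <- Inf
  jp <- max.col(-Dp, ties.method = "first")
  jm <- max.col(-Dm, ties.method = "first")
  dp <- Dp[cbind(seq_len(n), jp)]
  dm <- Dm[cbind(seq_len(n), jm)]
  dd <- dp + dm
  ok <- dd > NORM_EPS
  mu <- ifelse(ok, (dp - dm) / dd, 0)
  cost <- sum(mu)
  if (!gradients) {
    return(list(cost = cost, mu = mu, dp = dp, dm = dm))
  }

  # dcost/d(cos_ik) lands only on each sample's two winning prototypes;
  # the -1/2 factor is d(d)/d(cos).
  gp <- ifelse(ok, 2 * dm / dd^2, 0)
  gm <- ifelse(ok, -2 * dp / dd^2, 0)
  G <- matrix(0, n, K)
  G[cbind(seq_len(n), jp)] <- -gp / 2
  G[cbind(seq_len(n), jm)] <- G[cbind(seq_len(n), jm)] - gm / 2

  Gn <- G / nu                        # G_ik / |u_i|
  gradV <- matrix(0, K, ncol(U))
  gradOmega <- matrix(0, nrow(omega), ncol(omega))
  sGC <- colSums(G * C)               # per-prototype sum of G * cos
  for (k in seq_len(K)) {
    a_k <- crossprod(U, Gn[, k]) / nv[k]          # p-vector
    b_k <- sGC[k] / nv[k]^2
    gradV[k, ] <- a_k - b_k * V[k, ]
    xg_k <- crossprod(X, Gn[, k])                 # nfeat-vector
    gradOmega <- gradOmega +
      tcrossprod(V[k, ], xg_k) / nv[k] +          # via u_i, x_i term
      tcrossprod(a_k, W[k, ]) -                   # via v_k, w_k term
      b_k * tcrossprod(V[k, ], W[k, ])
  }
  h <- rowSums(G * C) / nu^2
  gradOmega <- gradOmega - crossprod(U * h, X)
  gradW <- gradV %*% omega

  list(cost = cost, mu = mu, dp = dp, dm = dm,
       gradW = gradW, gradOmega = gradOmega)
}

#' Fit an Angle-GMLVQ classifier
#'
#' Learns class prototypes `W` and a square relevance transform `Omega`
#' jointly, by full-batch gradient descent on the GLVQ relative-distance
#' cost
#' \deqn{E = \sum_i \mu_i, \qquad
#'   \mu_i = \frac{d^{+}_i - d^{-}_i}{d^{+}_i + d^{-}_i},}
#' where \eqn{d^{+}_i} is the angular dissimilarity of sample *i* to the
#' nearest prototype of its own class and \eqn{d^{-}_i} to the nearest
#' prototype of the other class. A sample is correctly classified exactly
#' when \eqn{\mu_i < 0}. After every accepted update, `Omega` is rescaled so
#' that the relevance matrix \eqn{\Lambda = \Omega^\top\Omega} has unit
#' trace, which stabilizes the subspace learning and makes the normalized
#' relevance scores `diag(Lambda)` directly comparable across fits. Steps
#' are backtracked (halved) until the cost does not increase, so the
#' recorded training history is non-increasing by construction.
#'
#' Prototypes are initialized at the class means plus a small seeded jitter
#' (shared across classes, so relabeling the classes yields the same model
#' up to prototype order); `Omega` starts as the identity scaled to unit
#' trace, i.e. uniform feature relevances.
#'
#' @param data A data frame whose `group` column holds exactly two class
#'   labels and whose remaining feature columns are named as in
#'   [feature_schema()] (an [adjust_features()] result qualifies). Any
#'   number of features >= 2 is accepted; the battery's 20 is the standard.
#' @param control A [gmlvq_control()] object.
#' @param features Character vector of feature column names; defaults to the
#'   schema features present in `data`, or all numeric non-label columns.
#' @return An object of class `angle_gmlvq` with elements `prototypes`,
#'   `prototype_class`, `omega`, `lambda`, `relevance_scores` (normalized to
#'   sum to 1), `classes`, `features`, `training_history`, `in_sample_wacc`,
#'   `converged`, `control`.
#' @examples
#' adj <- adjust_features(
#'   simulate_cohort(default_calibration("female"), seed = 7), "female")
#' fit <- angle_gmlvq(adj, control = gmlvq_control(max_iter = 50))
#' sum(fit$relevance_scores)
#' @export
angle_gmlvq <- function(data, control = gmlvq_control(), features = NULL) {
  if (!"group" %in% names(data)) {
    stop("`data` must contain a `group` column with the class labels",
         call. = FALSE)
  }
  if (is.null(features)) {
    features <- intersect(schema_ids(), names(data))
    if (length(features) == 0) {
      features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c("age", "iq", "ses"))
    }
  }
  X <- as.matrix(data[features])
  y <- as.character(data$group)
  fit_gmlvq_matrix(X, y, control, features)
}

fit_gmlvq_matrix <- function(X, y, control, features = colnames(X)) {
  if (any(!is.finite(X))) {
    stop("non-finite feature values passed to the classifier",
         call. = FALSE)
  }
  classes <- sort(unique(y), method = "radix")
  if (length(classes) != 2) {
    stop("exactly two classes required, got ", length(classes),
         call. = FALSE)
  }
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    stop("each class needs >= 2 samples (",
         paste(classes, counts, sep = ": ", collapse = ", "), ")",
         call. = FALSE)
  }
  y_idx <- match(y, classes)
  nfeat <- ncol(X)
  K_per <- control$prototypes_per_class

  # Shared per-slot jitter: each class's j-th prototype gets the same draw,
  # making the initialization invariant under class relabeling.
  set.seed(control$seed)
  jitter <- matrix(stats::rnorm(K_per * nfeat), K_per, nfeat) *
    control$init_jitter
  W <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    m <- colMeans(X[y_idx == ci, , drop = FALSE])
    sweep(jitter, 2, m, "+")
  }))
  proto_class <- rep(seq_along(classes), each = K_per)
  omega <- diag(nfeat) / sqrt(nfeat)   # trace(t(omega) %*% omega) == 1

  opt <- gmlvq_fit_loop_cpp(W, omega, X, y_idx, proto_class,
                            control$max_iter, control$tol,
                            control$eta_prototype, control$eta_relevance,
                            control$max_halvings)
  W <- opt$W
  omega <- opt$omega
  history <- opt$training_history
  converged <- opt$converged

  lambda <- crossprod(omega)
  rel <- diag(lambda) / sum(diag(lambda))
  names(rel) <- features

  model <- structure(
    list(prototypes = W,
         prototype_class = classes[proto_class],
         omega = omega,
         lambda = lambda,
         relevance_scores = rel,
         classes = classes,
         features = features,
         training_history = history,
         converged = converged,
         control = control),
    class = "angle_gmlvq")
  pred <- predict(model, X)
  model$in_sample_wacc <- weighted_accuracy(y, pred)
  model
}

#' Predict class labels with a fitted Angle-GMLVQ model
#'
#' Assigns each row the class of its nearest prototype under the model's
#' angular dissimilarity. Ties are broken toward the lower-indexed
#' prototype. Rows whose transformed vector has (near-)zero norm cannot be
#' placed in angle space; they are classified by the unweighted (identity
#' transform) angle instead, with a warning, and their indices are attached
#' as the `degenerate_rows` attribute.
#'
#' @param object An `angle_gmlvq` model.
#' @param newdata A data frame containing the model's feature columns, or a
#'   numeric matrix with the same column count.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.angle_gmlvq <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$features])
  stopifnot(ncol(X) == ncol(object$prototypes))
  D <- dissim_matrix(X, object$prototypes, object$omega)
  degenerate <- attr(D, "degenerate_rows")
  if (length(degenerate) > 0) {
    D_id <- dissim_matrix(X[degenerate, , drop = FALSE], object$prototypes,
                          omega = NULL)
    D[degenerate, ] <- D_id
    warning(length(degenerate), " row(s) had zero norm after the relevance ",
            "transform; classified by unweighted angle", call. = FALSE)
  }
  nearest <- max.col(-D, ties.method = "first")
  out <- object$prototype_class[nearest]
  if (length(degenerate) > 0) attr(out, "degenerate_rows") <- degenerate
  out
}

# n x K matrix of angular dissimilarities; rows whose transformed norm is
# (near-)zero get NA and are reported via the degenerate_rows attribute.
dissim_matrix <- function(X, W, omega = NULL) {
  U <- if (is.null(omega)) X else X %*% t(omega)
  V <- if (is.null(omega)) W else W %*% t(omega)
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  if (any(nv < NORM_EPS)) {
    stop("degenerate prototype: zero norm after relevance transform",
         call. = FALSE)
  }
  degenerate <- which(nu < NORM_EPS)
  nu[degenerate] <- 1
  C <- (U %*% t(V)) / outer(nu, nv)
  C[C > 1] <- 1
  C[C < -1] <- -1
  D <- (1 - C) / 2
  D[degenerate, ] <- NA_real_
  attr(D, "degenerate_rows") <- degenerate
  D
}

#' Normalized per-feature relevance scores
#'
#' Returns `diag(Lambda) / trace(Lambda)` with `Lambda = t(Omega) %*% Omega`:
#' nonnegative scores, one per feature, summing to 1, that quantify how much
#' each feature contributes to the learned dissimilarity.
#'
#' @param model An `angle_gmlvq` model.
#' @return Named numeric vector in schema order.
#' @export
relevance_scores <- function(model) {
  stopifnot(inherits(model, "angle_gmlvq"))
  model$relevance_scores
}

#' @export
print.angle_gmlvq <- function(x, ...) {
  cat("<angle_gmlvq>", length(x$features), "features,",
      nrow(x$prototypes), "prototypes (", paste(x$classes, collapse = " vs "),
      ")\n")
  cat("  in-sample wACC:", format(x$in_sample_wacc, digits = 3),
      "| iterations:", length(x$training_history) - 1,
      "| converged:", x$converged, "\n")
  top <- sort(x$relevance_scores, decreasing = TRUE)[1:3]
  cat("  top relevances:",
      paste(names(top), format(top, digits = 2), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the relevance profile of a fitted Angle-GMLVQ model
#'
#' @param x An `angle_gmlvq` model.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `domain` (where the feature is part of
#'   the standard battery) and `relevance`, sorted by schema order.
#' @method tidy angle_gmlvq
#' @export
tidy.angle_gmlvq <- function(x, ...) {
  dom <- schema_domains()
  tibble::tibble(
    feature_id = x$features,
    domain = unname(dom[x$features]),
    relevance = unname(x$relevance_scores))
}

#' One-row summary of a fitted Angle-GMLVQ model
#'
#' @param x An `angle_gmlvq` model.
#' @param ... Unused.
#' @return Tibble with `in_sample_wacc`, `n_iter`, `final_cost`,
#'   `converged`, `n_prototypes`.
#' @method glance angle_gmlvq
#' @export
glance.angle_gmlvq <- function(x, ...) {
  tibble::tibble(
    in_sample_wacc = x$in_sample_wacc,
    n_iter = length(x$training_history) - 1L,
    final_cost = x$training_history[length(x$training_history)],
    converged = x$converged,
    n_prototypes = nrow(x$prototypes))
}
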