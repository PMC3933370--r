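# Binary classifiers used on the per-cycle feature vectors: an extreme
# learning machine with radial-basis activation and a soft-margin RBF SVM.
# Label convention everywhere: abnormal = +1 (positive class), normal = -1.

encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be +/-1", call. = FALSE)
    return(as.numeric(labels))
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("normal", "abnormal"))) {
    stop("labels must be 'normal'/'abnormal' or +/-1", call. = FALSE)
  }
  ifelse(lab == "abnormal", 1, -1)
}

decode_labels <- function(y) ifelse(y >= 0, "abnormal", "normal")

# Fit/apply per-feature standardization (zero mean, unit variance) on the
# training fold only; RBF distances are meaningless across raw units.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values", call. = FALSE)
  x
}

rbf_hidden <- function(x, centers, widths) {
  # x: N x d, centers: H x d -> N x H matrix of exp(-width_j * ||x - c_j||^2)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-sweep(d2, 2L, widths, "*"))
}

# Moore-Penrose pseudoinverse solve via SVD with singular-value cutoff.
pinv_solve <- function(M, D, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1L]
  s$v[, keep, drop = FALSE] %*% ((t(s$u[, keep, drop = FALSE]) %*% D) / s$d[keep])
}

#' Train an extreme learning machine (ELM)
#'
#' Single-hidden-layer network with radial-basis activation whose hidden
#' parameters are drawn randomly and never tuned: only the output weights
#' are learned, as the minimum-norm least-squares solution
#' `beta = pinv(M) D` via the Moore-Penrose pseudoinverse of the hidden
#' output matrix `M`. Hidden centers are drawn uniformly from the
#' (standardized) training samples themselves — the classic RBF-network
#' placement, which keeps every unit active on the data manifold — and
#' widths uniformly on (0, 1] scaled by the inverse squared median
#' inter-sample distance, so activations stay non-degenerate regardless
#' of feature scale. The hidden layer has 10 nodes by default. All
#' randomness is controlled by `rng_seed`; centers are drawn from the
#' canonically (lexicographically) sorted sample pool, so reordering the
#' training set does not change the hidden layer.
#'
#' @param x Feature matrix or data frame (rows = cycles).
#' @param labels `"normal"`/`"abnormal"` or +/-1 per row; both classes
#'   must be present.
#' @param n_hidden Number of hidden nodes (default 10).
#' @param rng_seed Integer seed for the hidden-layer draw (default 1).
#' @return An object of class `elm_model` with elements `centers`,
#'   `widths`, `output_weights`, `scaler`, `n_hidden`, `rng_seed`.
#' @export
elm_train <- function(x, labels, n_hidden = 10L, rng_seed = 1L) {
  x <- as_feature_matrix(x)
  y <- encode_labels(labels)
  if (nrow(x) < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present for training", call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  d <- ncol(xs)

  # canonical (lexicographic) ordering makes the center draw invariant to
  # the ordering of the training set
  pool <- xs[do.call(order, as.data.frame(xs)), , drop = FALSE]
  # median pairwise distance (order-invariant); subsample very large sets
  idx <- if (nrow(xs) > 500L) {
    unique(round(seq(1L, nrow(xs), length.out = 500L)))
  } else seq_len(nrow(xs))
  med_d <- median(dist(xs[idx, , drop = FALSE]))
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1

  draws <- with_seed(rng_seed, {
    pick <- sample.int(nrow(pool), n_hidden, replace = nrow(pool) < n_hidden)
    u <- runif(n_hidden)
    list(pick = pick, u = u)
  })
  centers <- pool[draws$pick, , drop = FALSE]
  widths <- pmax(draws$u, .Machine$double.eps) / med_d^2

  M <- rbf_hidden(xs, centers, widths)
  beta <- pinv_solve(M, matrix(y, ncol = 1L))
  structure(list(centers = centers, widths = widths,
                 output_weights = beta, scaler = scaler,
                 n_hidden = as.integer(n_hidden), rng_seed = as.integer(rng_seed),
                 dim = d),
            class = "elm_model")
}

#' Predict with a trained ELM
#'
#' @param model An `elm_model` from [elm_train()].
#' @param x Feature matrix/data frame with the training dimensionality.
#' @return A data frame with columns `score` (real-valued network output)
#'   and `label` (`sign(score)`, zero scores mapped to `"abnormal"`).
#' @export
elm_predict <- function(model, x) {
  if (!inherits(model, "elm_model")) stop("model must be an elm_model", call. = FALSE)
  x <- as_feature_matrix(x)
  if (ncol(x) != model$dim) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 model$dim, ncol(x)), call. = FALSE)
  }
  xs <- apply_scaler(x, model$scaler)
  score <- drop(rbf_hidden(xs, model$centers, model$widths) %*% model$output_weights)
  data.frame(score = score, label = decode_labels(score))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d RBF hidden nodes, %d-dim input, seed %d\n",
              x$n_hidden, x$dim, x$rng_seed))
  invisible(x)
}

#' Train a soft-margin RBF-kernel support vector machine
#'
#' Solves the usual dual problem: maximize
#' `sum(alpha) - 0.5 * sum_ij alpha_i alpha_j d_i d_j K(y_i, y_j)` subject
#' to `sum(alpha_j d_j) = 0` and `0 <= alpha_j <= C`, with the Gaussian
#' kernel `K(y, y') = exp(-gamma ||y - y'||^2)` (a Mercer kernel). The
#' quadratic program is solved by libsvm (via \pkg{e1071}) at a tight
#' convergence tolerance; support vectors, dual coefficients
#' `alpha_j * d_j` and the bias are extracted into a transparent model
#' that [svm_predict()] evaluates directly as the kernel expansion.
#' Features are standardized on the training data first.
#'
#' @param x Feature matrix or data frame.
#' @param labels `"normal"`/`"abnormal"` or +/-1.
#' @param C Box constraint (default 1).
#' @param gamma RBF width; default `1/d` on standardized features
#'   (equivalently `1/(d * var)`).
#' @param tolerance libsvm termination tolerance (default 1e-8).
#' @return An object of class `svm_model_rbf` with `support_vectors`
#'   (standardized), `dual_coefs` (`alpha_j * d_j`), `bias`, `gamma`, `C`,
#'   `slack` (training hinge losses), `sv_index` (training rows of the
#'   support vectors), `scaler`.
#' @export
svm_train <- function(x, labels, C = 1, gamma = NULL, tolerance = 1e-8) {
  x <- as_feature_matrix(x)
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present for training", call. = FALSE)
  stopifnot(C > 0)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)

  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(xs, yf, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE,
                    tolerance = tolerance)
  sv <- unname(as.matrix(fit$SV))
  coefs <- as.numeric(fit$coefs) # alpha_j * d_j, up to libsvm's orientation
  bias <- -fit$rho
  # libsvm orients its decision toward whichever class it saw first; recover
  # the orientation from the decision-value column name ("pos/neg")
  dv <- attr(stats::predict(fit, xs[1L, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (!identical(strsplit(colnames(dv), "/")[[1L]][1L], "1")) {
    coefs <- -coefs
    bias <- -bias
  }

  model <- structure(list(support_vectors = sv, dual_coefs = coefs,
                          bias = bias, gamma = gamma, C = C,
                          scaler = scaler, dim = ncol(xs),
                          sv_index = as.integer(fit$index)),
                     class = "svm_model_rbf")
  f <- svm_decision(model, xs, standardized = TRUE)
  model$slack <- pmax(0, 1 - y * f)
  model
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

svm_decision <- function(model, x, standardized = FALSE) {
  if (!standardized) x <- apply_scaler(x, model$scaler)
  drop(rbf_kernel(x, model$support_vectors, model$gamma) %*% model$dual_coefs) +
    model$bias
}

#' Predict with a trained SVM
#'
#' Evaluates the kernel decision function
#' `f(y) = sum_j alpha_j d_j K(y, y_j) + b`; the predicted label is its
#' sign, with a zero margin broken toward the abnormal (positive) class.
#'
#' @param model An `svm_model_rbf` from [svm_train()].
#' @param x Feature matrix/data frame with the training dimensionality.
#' @return A data frame with columns `margin` and `label`.
#' @export
svm_predict <- function(model, x) {
  if (!inherits(model, "svm_model_rbf")) stop("model must be an svm_model_rbf", call. = FALSE)
  x <- as_feature_matrix(x)
  if (ncol(x) != model$dim) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 model$dim, ncol(x)), call. = FALSE)
  }
  margin <- svm_decision(model, x)
  data.frame(margin = margin, label = decode_labels(margin))
}

#' Dual objective value of a trained SVM
#'
#' `Q(alpha) = sum(alpha) - 0.5 * sum_ij alpha_i alpha_j d_i d_j K_ij`,
#' evaluated at the trained solution; useful for verifying the solver
#' against an independent quadratic program.
#'
#' @param model An `svm_model_rbf`.
#' @return Scalar dual objective.
#' @export
svm_dual_objective <- function(model) {
  K <- rbf_kernel(model$support_vectors, model$support_vectors, model$gamma)
  sum(abs(model$dual_coefs)) -
    0.5 * drop(t(model$dual_coefs) %*% K %*% model$dual_coefs)
}

#' @export
print.svm_model_rbf <- function(x, ...) {
  cat(sprintf("<svm_model_rbf> %d support vectors, gamma = %.4g, C = %g\n",
              nrow(x$support_vectors), x$gamma, x$C))
  invisible(x)
}

#' Serialize a trained classifier to JSON
#'
#' Writes every numeric component of an ELM or SVM model (plus a schema
#' version) as nested JSON arrays, enabling exact reload with
#' [load_model()].
#'
#' @param model An `elm_model` or `svm_model_rbf`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "elm_model")) "elm" else if
  (inherits(model, "svm_model_rbf")) "svm" else
    stop("model must be an elm_model or svm_model_rbf", call. = FALSE)
  payload <- list(schema = "lungmorph-model-1", kind = kind,
                  fields = lapply(unclass(model), function(f) {
                    if (is.matrix(f)) list(matrix = TRUE, nrow = nrow(f),
                                           data = as.numeric(f))
                    else f
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved with [save_model()]
#'
#' @param path JSON file written by [save_model()].
#' @return The restored `elm_model` or `svm_model_rbf`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "lungmorph-model-1")) {
    stop("unrecognized model schema", call. = FALSE)
  }
  fields <- lapply(payload$fields, function(f) {
    if (is.list(f) && isTRUE(f$matrix)) matrix(f$data, nrow = f$nrow) else f
  })
  # scalars serialized as length-1 vectors; integers may come back numeric
  for (nm in c("n_hidden", "rng_seed", "dim", "sv_index")) {
    if (!is.null(fields[[nm]])) fields[[nm]] <- as.integer(fields[[nm]])
  }
  if (!is.null(fields$scaler)) {
    fields$scaler <- list(mu = as.numeric(fields$scaler$mu),
                          sd = as.numeric(fields$scaler$sd))
  }
  cls <- if (payload$kind == "elm") "elm_model" else "svm_model_rbf"
  structure(fields, class = cls)
}
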