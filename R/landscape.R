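#' Fit a fitness-landscape model over genome space
#'
#' Kernel regression of fitness on the four oil fractions. Two routes:
#' `"svr"` -- support vector regression with an RBF kernel, hyperparameters
#' `(C, gamma)` chosen by exhaustive grid search under seeded 10-fold
#' cross-validated mean squared error (ties broken toward smaller `C`, then
#' smaller `gamma`), refit on all data; `"kernel_ridge"` -- closed-form
#' kernel ridge regression at fixed `(alpha, gamma)` (the variant used for
#' time-resolved landscape sequences, where one shared kernel keeps frames
#' comparable).
#'
#' Genome fractions are used as features directly (they are already bounded
#' on the simplex); set `scale = TRUE` to standardise instead.
#'
#' @param data data frame with the four oil columns and a `fitness` column
#'   (e.g. the `evaluation_log` of [run_ga()] -- each repeat is one point).
#' @param method `"svr"` or `"kernel_ridge"`.
#' @param c_grid SVR penalty grid.
#' @param gamma_grid SVR kernel-width grid.
#' @param folds cross-validation folds.
#' @param alpha,gamma kernel-ridge regularisation and kernel width.
#' @param seed seed for the fold assignment.
#' @param scale standardise features before fitting.
#' @return a `droplet_landscape` with `method`, `hyperparams`, `cv` (full
#'   grid-search table for SVR), `cv_mse` (mean and sd over folds at the
#'   chosen hyperparameters), and the fitted model.
#' @export
fit_landscape <- function(data, method = c("svr", "kernel_ridge"),
                          c_grid = c(0.01, 0.1, 1, 10, 100),
                          gamma_grid = c(0.01, 0.1, 1, 10, 100),
                          folds = 10, alpha = 10, gamma = 100, seed = 1L,
                          scale = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(data[, oil_names()])
  y <- as.numeric(data$fitness)
  if (anyNA(X) || anyNA(y)) stop("landscape data must be complete")
  if (any(y < 0)) stop("fitness must be non-negative")
  if (method == "svr") fit_svr(X, y, c_grid, gamma_grid, folds, seed, scale)
  else fit_kernel_ridge(X, y, alpha, gamma)
}

# degenerate folds (constant targets make the eps-insensitive fit empty)
# fall back to predicting the training mean
svm_safe <- function(X, y, cost, gamma, scale) {
  fit <- tryCatch(
    e1071::svm(X, y, type = "eps-regression", kernel = "radial",
               cost = cost, gamma = gamma, scale = scale),
    error = function(e) NULL)
  if (is.null(fit)) structure(list(mean = mean(y)), class = "constant_fit")
  else fit
}

predict_safe <- function(fit, X) {
  if (inherits(fit, "constant_fit")) rep(fit$mean, nrow(X))
  else tryCatch(as.numeric(predict(fit, X)),
                error = function(e) rep(mean(fitted(fit)), nrow(X)))
}

fit_svr <- function(X, y, c_grid, gamma_grid, folds, seed, scale) {
  n <- nrow(X)
  if (n < folds) stop("need at least as many points as folds")
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- expand.grid(C = c_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv_mean <- cv_sd <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    mse <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (!any(tr) || !any(!tr)) return(NA_real_)
      fit <- svm_safe(X[tr, , drop = FALSE], y[tr], grid$C[r], grid$gamma[r],
                      scale)
      mean((y[!tr] - predict_safe(fit, X[!tr, , drop = FALSE]))^2)
    }, numeric(1))
    cv_mean[r] <- mean(mse, na.rm = TRUE)
    cv_sd[r] <- stats::sd(mse, na.rm = TRUE)
  }
  # tie-break: smaller C first, then smaller gamma
  ord <- order(grid$C, grid$gamma)
  best <- ord[which.min(cv_mean[ord])]
  model <- svm_safe(X, y, grid$C[best], grid$gamma[best], scale)
  structure(list(method = "svr",
                 hyperparams = list(C = grid$C[best], gamma = grid$gamma[best]),
                 cv = cbind(grid, cv_mse = cv_mean, cv_mse_sd = cv_sd),
                 cv_mse = c(mean = cv_mean[best], sd = cv_sd[best]),
                 model = model, n = length(y), scale = scale),
            class = "droplet_landscape")
}

fit_kernel_ridge <- function(X, y, alpha, gamma) {
  K <- rbf_kernel(X, X, gamma)
  A <- K + diag(alpha, nrow(X))
  dual <- tryCatch(solve(A, y), error = function(e) {
    solve(A + diag(1e-8, nrow(X)), y)     # jittered solve for singular systems
  })
  structure(list(method = "kernel_ridge",
                 hyperparams = list(alpha = alpha, gamma = gamma),
                 cv = NULL, cv_mse = NULL,
                 model = list(X = X, dual = dual, gamma = gamma),
                 n = length(y), scale = FALSE),
            class = "droplet_landscape")
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' @export
print.droplet_landscape <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams),
              sep = "=", collapse = ", ")
  cat(sprintf("<droplet_landscape> %s on %d points (%s)\n", x$method, x$n, hp))
  if (!is.null(x$cv_mse))
    cat(sprintf("cross-validated MSE %.3f (sd %.3f)\n",
                x$cv_mse[["mean"]], x$cv_mse[["sd"]]))
  invisible(x)
}

#' Predict fitness from a landscape model
#'
#' @param object a `droplet_landscape`.
#' @param newdata data frame or matrix with the four oil fractions.
#' @param ... unused.
#' @return numeric vector of predicted fitness.
#' @export
predict.droplet_landscape <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata[, oil_names()])
       else if (is.null(dim(newdata))) matrix(as.numeric(newdata), 1)
       else as.matrix(newdata)
  if (object$method == "svr") unname(predict_safe(object$model, X))
  else as.numeric(rbf_kernel(X, object$model$X, object$model$gamma) %*%
                    object$model$dual)
}

#' Barycentric prediction grid over a ternary slice
#'
#' Evaluates the landscape on the simplex grid of three chosen oils with the
#' fourth held at zero -- the data behind a ternary heat-map panel. A
#' resolution `r` gives `choose(r + 2, 2)` grid points.
#'
#' @param model a `droplet_landscape`.
#' @param free_components three oil names (see [oil_names()]).
#' @param resolution grid subdivisions per edge.
#' @return data frame with the four fractions and the `prediction` column.
#' @export
ternary_grid <- function(model, free_components = c("octanol", "dep", "pentanol"),
                         resolution = 20) {
  stopifnot(inherits(model, "droplet_landscape"),
            length(free_components) == 3,
            all(free_components %in% oil_names()))
  idx <- match(free_components, oil_names())
  pts <- compositions0(resolution, 3) / resolution
  G <- matrix(0, nrow(pts), 4, dimnames = list(NULL, oil_names()))
  G[, idx] <- pts
  out <- as.data.frame(G)
  out$prediction <- predict(model, G)
  out
}

# ordered k-tuples of non-negative integers summing to total
compositions0 <- function(total, k) {
  if (k == 1L) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(first)
    cbind(first, compositions0(total - first, k - 1L))))
}

#' Plot a ternary slice of a fitness landscape
#'
#' Projects the barycentric grid of [ternary_grid()] to 2D and draws a
#' coloured point heat map of the predicted fitness.
#'
#' @param x a `droplet_landscape`.
#' @param free_components three oil names.
#' @param resolution grid resolution.
#' @param ... passed to [graphics::plot()].
#' @return the grid data frame, invisibly.
#' @export
plot.droplet_landscape <- function(x, free_components = c("octanol", "dep", "pentanol"),
                                   resolution = 40, ...) {
  grid <- ternary_grid(x, free_components, resolution)
  a <- grid[[free_components[1]]]; b <- grid[[free_components[2]]]
  c3 <- grid[[free_components[3]]]
  px <- b + c3 / 2
  py <- c3 * sqrt(3) / 2
  z <- grid$prediction
  zr <- range(z); if (diff(zr) == 0) zr <- zr + c(-0.5, 0.5)
  cols <- grDevices::hcl.colors(100, "viridis")[
    pmax(1, pmin(100, 1 + floor(99 * (z - zr[1]) / diff(zr))))]
  graphics::plot(px, py, col = cols, pch = 15, cex = 1.2, asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::text(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2) + c(-0.05, -0.05, 0.05),
                 free_components)
  invisible(grid)
}
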