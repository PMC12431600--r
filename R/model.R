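# Feed-forward 2-H-1 regression network trained by Levenberg-Marquardt.
# Hidden layer: hyperbolic tangent sigmoid; output layer: linear.

#' Training configuration for the firmness network
#'
#' @param hidden_size Hidden-layer width (default 7).
#' @param train_fraction Fraction of rows used for training (default 0.7).
#' @param cv_folds Folds for hidden-size selection (default 10).
#' @param hidden_grid Candidate hidden sizes (default 1:20).
#' @param max_iterations Levenberg-Marquardt iteration cap (default 1000).
#' @param tol_gradient Stop when the max absolute gradient of the
#'   sum-of-squares falls below this (default 1e-8).
#' @param lambda_init Initial damping factor (default 1e-3); multiplied by
#'   10 on step rejection and divided by 10 on acceptance.
#' @param restarts Seeded random restarts, keeping the best fit (default 5).
#' @param seed Integer seed controlling initialisation and data shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(hidden_size = 7, train_fraction = 0.7,
                         cv_folds = 10, hidden_grid = 1:20,
                         max_iterations = 1000, tol_gradient = 1e-8,
                         lambda_init = 1e-3, restarts = 5, seed = 1) {
  stopifnot(hidden_size >= 1, train_fraction > 0, train_fraction < 1,
            cv_folds >= 2, length(hidden_grid) >= 1, max_iterations >= 1,
            lambda_init > 0, restarts >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 hidden_grid = as.integer(hidden_grid),
                 max_iterations = as.integer(max_iterations),
                 tol_gradient = tol_gradient, lambda_init = lambda_init,
                 restarts = as.integer(restarts), seed = seed),
            class = "train_config")
}

# Parameter vector layout: [vec(W1) (H x p), b1 (H), w2 (H), b2 (1)].
.unpack <- function(theta, H, p) {
  list(W1 = matrix(theta[seq_len(H * p)], H, p),
       b1 = theta[H * p + seq_len(H)],
       w2 = theta[H * p + H + seq_len(H)],
       b2 = theta[H * p + 2 * H + 1])
}

#' Forward pass of the 2-H-1 network
#'
#' Computes `q = w2 . tanh(W1 p + b1) + b2` for each input row. Operates in
#' whatever units `x` is given in; [predict.firmness_net()] handles the
#' standardisation used during training.
#'
#' @param params List with `W1` (H x p), `b1` (H), `w2` (H), `b2` (scalar).
#' @param x Numeric matrix of inputs, one row per observation.
#' @return Numeric vector of outputs.
#' @export
network_forward <- function(params, x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("inputs must be finite")
  hid <- tanh(sweep(x %*% t(params$W1), 2, params$b1, "+"))
  as.numeric(hid %*% params$w2 + params$b2)
}

# Residuals and Jacobian of predictions w.r.t. the parameter vector.
.net_jacobian <- function(theta, x, y, H) {
  p <- ncol(x)
  pr <- .unpack(theta, H, p)
  z <- sweep(x %*% t(pr$W1), 2, pr$b1, "+")  # n x H pre-activations
  a <- tanh(z)
  pred <- as.numeric(a %*% pr$w2 + pr$b2)
  d <- (1 - a^2) * matrix(pr$w2, nrow(x), H, byrow = TRUE)  # n x H
  J <- matrix(0, nrow(x), length(theta))
  for (k in seq_len(p)) {
    J[, (k - 1) * H + seq_len(H)] <- d * x[, k]
  }
  J[, H * p + seq_len(H)] <- d
  J[, H * p + H + seq_len(H)] <- a
  J[, H * p + 2 * H + 1] <- 1
  list(resid = y - pred, J = J, pred = pred)
}

# Damped Gauss-Newton (Levenberg-Marquardt) on the full network Jacobian.
.lm_fit <- function(theta, x, y, H, cfg) {
  lambda <- cfg$lambda_init
  st <- .net_jacobian(theta, x, y, H)
  sse <- sum(st$resid^2)
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    g <- crossprod(st$J, st$resid)           # = -0.5 * gradient of SSE
    if (max(abs(g)) < cfg$tol_gradient) { converged <- TRUE; break }
    JtJ <- crossprod(st$J)
    accepted <- FALSE
    for (tries in 1:40) {
      step <- tryCatch(
        solve(JtJ + diag(lambda, ncol(JtJ)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        st2 <- .net_jacobian(cand, x, y, H)
        sse2 <- sum(st2$resid^2)
        if (is.finite(sse2) && sse2 < sse) {
          theta <- cand; st <- st2; sse <- sse2
          lambda <- lambda / 10
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- max(abs(g)) < 1e-4; break }
  }
  list(theta = theta, sse = sse, converged = converged)
}

#' Train the firmness network by Levenberg-Marquardt
#'
#' Standardises inputs and target on the training data, minimises the
#' sum-of-squares by damped Gauss-Newton on the full network Jacobian, and
#' repeats from `restarts` seeded uniform initialisations, keeping the
#' weights with the lowest prediction error (on `validation` when supplied,
#' otherwise on the training data). Deterministic given `cfg$seed`.
#'
#' @param x Numeric matrix (or data frame) of inputs, one row per fruit
#'   (typically damping ratio and natural frequency).
#' @param y Numeric target vector (firmness, MPa).
#' @param cfg A [train_config()].
#' @param validation Optional list `list(x = , y = )` scoring the restarts.
#' @return An object of class `firmness_net` with the parameters, the
#'   standardisation constants and the training RMSE (MPa).
#' @export
train_network <- function(x, y, cfg = train_config(), validation = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite data")
  H <- cfg$hidden_size; p <- ncol(x)
  xc <- colMeans(x); xs <- apply(x, 2, sd)
  xs[xs == 0] <- 1
  yc <- mean(y); ys <- sd(y)
  if (ys == 0) ys <- 1
  xs_ <- sweep(sweep(x, 2, xc), 2, xs, "/")
  ys_ <- (y - yc) / ys
  npar <- H * p + 2 * H + 1
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    theta0 <- withr::with_seed(cfg$seed + r - 1,
                               runif(npar, -0.5, 0.5))
    fit <- .lm_fit(theta0, xs_, ys_, H, cfg)
    params <- .unpack(fit$theta, H, p)
    score <- if (is.null(validation)) {
      sqrt(fit$sse / length(ys_))
    } else {
      vx <- sweep(sweep(as.matrix(validation$x), 2, xc), 2, xs, "/")
      pv <- network_forward(params, vx) * ys + yc
      sqrt(mean((validation$y - pv)^2))
    }
    if (is.null(best) || score < best$score) {
      best <- list(fit = fit, params = params, score = score)
    }
  }
  pred <- network_forward(best$params, xs_) * ys + yc
  structure(list(params = best$params, hidden_size = H,
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 training_rmse = sqrt(mean((y - pred)^2)),
                 converged = best$fit$converged,
                 input_names = colnames(x),
                 seed = cfg$seed),
            class = "firmness_net")
}

#' Predict firmness from modal features
#'
#' @param object A `firmness_net` from [train_network()].
#' @param newdata Numeric matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predicted firmness (MPa).
#' @export
predict.firmness_net <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (any(!is.finite(x))) stop("inputs must be finite")
  xs_ <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, "/")
  network_forward(object$params, xs_) * object$y_scale + object$y_center
}

#' @export
print.firmness_net <- function(x, ...) {
  cat(sprintf("<firmness_net> 2-%d-1 tanh network, training RMSE %.4g MPa\n",
              x$hidden_size, x$training_rmse))
  invisible(x)
}

#' Split rows into training and test sets
#'
#' Seeded uniform shuffle; the training set has `ceiling(fraction * n)`
#' rows, the test set the remainder; the two are disjoint and exhaustive.
#'
#' @param data Data frame or matrix.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train`, `test` and the row indices `train_idx`,
#'   `test_idx`.
#' @export
split_train_test <- function(data, fraction = 0.7, seed = 1) {
  n <- nrow(data)
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  idx <- withr::with_seed(seed, sample.int(n))
  ntr <- ceiling(fraction * n)
  tr <- sort(idx[seq_len(ntr)])
  te <- sort(idx[-seq_len(ntr)])
  list(train = data[tr, , drop = FALSE], test = data[te, , drop = FALSE],
       train_idx = tr, test_idx = te)
}

#' Select the hidden-layer size by k-fold cross-validation
#'
#' For each candidate width, trains on `cv_folds - 1` folds and scores RMSE
#' on the held-out fold; folds are contiguous blocks after one seeded
#' shuffle. The chosen width minimises the mean validation RMSE, with ties
#' broken toward the smaller width.
#'
#' @param x Input matrix, one row per fruit.
#' @param y Target vector.
#' @param cfg A [train_config()]; `hidden_grid`, `cv_folds`, `restarts` and
#'   `seed` are honoured.
#' @return List with `selection_table` (`hidden_size`, `mean_rmse`,
#'   `sd_rmse`) and `best_hidden_size`.
#' @export
cross_validate_hidden_size <- function(x, y, cfg = train_config()) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n >= cfg$cv_folds)
  # contiguous blocks over one seeded shuffle
  perm <- withr::with_seed(cfg$seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- cut(seq_len(n), breaks = cfg$cv_folds, labels = FALSE)
  res <- lapply(cfg$hidden_grid, function(H) {
    rmse <- vapply(seq_len(cfg$cv_folds), function(k) {
      tr <- fold_of != k
      if (sum(!tr) < 1) stop("empty validation fold")
      cfgH <- cfg; cfgH$hidden_size <- H
      fit <- train_network(x[tr, , drop = FALSE], y[tr], cfgH)
      sqrt(mean((y[!tr] - predict(fit, x[!tr, , drop = FALSE]))^2))
    }, numeric(1))
    c(mean = mean(rmse), sd = sd(rmse))
  })
  tab <- data.frame(hidden_size = cfg$hidden_grid,
                    mean_rmse = vapply(res, `[[`, numeric(1), "mean"),
                    sd_rmse = vapply(res, `[[`, numeric(1), "sd"))
  list(selection_table = tab,
       best_hidden_size = tab$hidden_size[which.min(tab$mean_rmse)])
}

#' Write a trained network to JSON
#'
#' Human-readable, diffable persistence of the weights, biases,
#' standardisation constants and seed.
#'
#' @param net A `firmness_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "firmness_net"))
  obj <- list(hidden_size = net$hidden_size,
              hidden_transfer = "tanh", output_transfer = "linear",
              W1 = net$params$W1, b1 = net$params$b1,
              w2 = net$params$w2, b2 = net$params$b2,
              x_center = net$x_center, x_scale = net$x_scale,
              y_center = net$y_center, y_scale = net$y_scale,
              training_rmse = net$training_rmse,
              input_names = net$input_names, seed = net$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a trained network from JSON
#'
#' @param path File written by [write_network_json()].
#' @return A `firmness_net`.
#' @export
read_network_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- if (is.matrix(o$W1)) o$W1 else {
    matrix(as.numeric(unlist(o$W1)), nrow = o$hidden_size, byrow = TRUE)
  }
  structure(list(params = list(W1 = W1, b1 = as.numeric(o$b1),
                               w2 = as.numeric(o$w2), b2 = as.numeric(o$b2)),
                 hidden_size = as.integer(o$hidden_size),
                 x_center = as.numeric(o$x_center),
                 x_scale = as.numeric(o$x_scale),
                 y_center = as.numeric(o$y_center),
                 y_scale = as.numeric(o$y_scale),
                 training_rmse = as.numeric(o$training_rmse),
                 converged = NA, input_names = o$input_names,
                 seed = o$seed),
            class = "firmness_net")
}
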