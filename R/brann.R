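# Two-layer feedforward regression network (tan-sigmoid hidden layer,
# linear output) trained by Levenberg-Marquardt under Bayesian
# regularization: the objective F = beta * E_D + alpha * E_W is minimised
# with MacKay evidence updates of the hyperparameters alpha (weight
# decay) and beta (noise precision) after every accepted step. gamma, the
# effective number of well-determined parameters, is tracked throughout.
# The Jacobian is exact (per-sample backpropagation), accumulated in row
# chunks as J'J and J'e so the full Jacobian is never materialised.

#' Training configuration for the Bayesian-regularized network
#'
#' @param n_hidden hidden-layer width (default 10 tan-sigmoid neurons).
#' @param max_epochs maximum number of Levenberg-Marquardt epochs.
#' @param mu_init initial LM damping parameter.
#' @param mu_inc,mu_dec multiplicative damping increase (on a rejected
#'   step) and decrease (after an accepted step).
#' @param mu_max damping cap; training stops when no improving step is
#'   found below it.
#' @param grad_tol stop when the infinity norm of the objective gradient
#'   falls below this.
#' @param seed seed of the weight initialisation.
#' @param chunk_size rows per Jacobian accumulation chunk (memory knob
#'   only; does not affect results).
#' @return an object of class `train_config`.
#' @export
train_config <- function(n_hidden = 10L, max_epochs = 1000L,
                         mu_init = 0.005, mu_inc = 10, mu_dec = 0.1,
                         mu_max = 1e10, grad_tol = 1e-7, seed = 1L,
                         chunk_size = 20000L) {
  stopifnot(n_hidden >= 1, max_epochs >= 1, mu_init > 0, mu_inc > 1,
            mu_dec > 0, mu_dec < 1, mu_max > mu_init, grad_tol >= 0,
            chunk_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Initialise network weights (Nguyen-Widrow hidden layer)
#'
#' Hidden-layer weight rows are random directions scaled to the
#' Nguyen-Widrow magnitude `0.7 * n_hidden^(1 / n_in)` over the `[-1, 1]`
#' input cube, with biases spread uniformly across the same range so the
#' active regions of the tanh units tile the input space; the linear
#' output layer starts small and uniform.
#'
#' @param n_in,n_hidden,n_out layer sizes (all >= 1).
#' @param seed integer RNG seed; identical seeds give identical weights.
#' @return list with `w1` (n_hidden x n_in), `b1`, `w2`
#'   (n_out x n_hidden), `b2`.
#' @export
init_network <- function(n_in, n_hidden, n_out, seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  set.seed(seed)
  magnitude <- 0.7 * n_hidden^(1 / n_in)
  w1 <- matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in)
  w1 <- w1 * magnitude / pmax(sqrt(rowSums(w1^2)), 1e-12)
  b1 <- magnitude * seq(-1, 1, length.out = n_hidden) *
    sign(stats::runif(n_hidden) - 0.5)
  w2 <- matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden) /
    sqrt(n_hidden)
  b2 <- stats::runif(n_out, -0.1, 0.1)
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

.pack_weights <- function(p) {
  c(as.numeric(p$w1), p$b1, as.numeric(p$w2), p$b2)
}

.unpack_weights <- function(w, n_in, n_hidden, n_out) {
  i1 <- n_hidden * n_in
  i2 <- i1 + n_hidden
  i3 <- i2 + n_out * n_hidden
  list(w1 = matrix(w[1:i1], n_hidden, n_in),
       b1 = w[(i1 + 1):i2],
       w2 = matrix(w[(i2 + 1):i3], n_out, n_hidden),
       b2 = w[(i3 + 1):(i3 + n_out)])
}

#' Forward pass of the two-layer network
#'
#' Computes `y = w2 %*% tanh(w1 %*% x + b1) + b2` for every row of `x`.
#' When `params` carries a column `signature` (as fitted models do) the
#' column names of `x` must match it.
#'
#' @param params a weight list as from [init_network()] or a fitted
#'   `brann` model.
#' @param x numeric matrix of normalized inputs, one row per sample.
#' @return matrix of normalized predictions, one row per sample.
#' @export
forward <- function(params, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(params$w1)) {
    stop(sprintf("forward: input has %d columns, network expects %d",
                 ncol(x), ncol(params$w1)), call. = FALSE)
  }
  if (!is.null(params$signature) && !is.null(colnames(x))) {
    expected <- strsplit(params$signature, "|", fixed = TRUE)[[1]]
    if (!identical(colnames(x), expected[seq_len(ncol(x))])) {
      stop("forward: input column signature does not match the trained model",
           call. = FALSE)
    }
  }
  h <- tanh(sweep(tcrossprod(x, params$w1), 2, params$b1, "+"))
  sweep(tcrossprod(h, params$w2), 2, params$b2, "+")
}

# Accumulate J'J, J'e and the sum squared error over row chunks.
# Residuals are e = y - t; rows of the stacked Jacobian are ordered
# (chunk, output) but only the accumulated products are kept, so the
# ordering is immaterial.
.br_accumulate <- function(p, x, t, chunk_size) {
  n <- nrow(x)
  n_in <- ncol(x)
  n_hidden <- nrow(p$w1)
  n_out <- nrow(p$w2)
  n_w <- n_hidden * n_in + n_hidden + n_out * n_hidden + n_out
  i_b1 <- n_hidden * n_in
  i_w2 <- i_b1 + n_hidden
  i_b2 <- i_w2 + n_out * n_hidden
  jtj <- matrix(0, n_w, n_w)
  jte <- numeric(n_w)
  e_d <- 0
  jrep <- rep(seq_len(n_hidden), times = n_in)
  krep <- rep(seq_len(n_in), each = n_hidden)
  starts <- seq(1, n, by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1, n)
    m <- length(rows)
    xc <- x[rows, , drop = FALSE]
    hc <- tanh(sweep(tcrossprod(xc, p$w1), 2, p$b1, "+"))
    yc <- sweep(tcrossprod(hc, p$w2), 2, p$b2, "+")
    ec <- yc - t[rows, , drop = FALSE]
    e_d <- e_d + sum(ec^2)
    sc <- 1 - hc^2
    for (o in seq_len(n_out)) {
      a <- sc * matrix(p$w2[o, ], m, n_hidden, byrow = TRUE)
      j <- matrix(0, m, n_w)
      j[, seq_len(i_b1)] <- a[, jrep] * xc[, krep]
      j[, (i_b1 + 1):i_w2] <- a
      j[, i_w2 + o + (seq_len(n_hidden) - 1) * n_out] <- hc
      j[, i_b2 + o] <- 1
      jtj <- jtj + crossprod(j)
      jte <- jte + drop(crossprod(j, ec[, o]))
    }
  }
  list(jtj = jtj, jte = jte, e_d = e_d)
}

#' Train the network by Levenberg-Marquardt with Bayesian regularization
#'
#' Minimises `F = beta * E_D + alpha * E_W` (sum squared error plus sum
#' squared weights) by damped Gauss-Newton steps
#' `dw = -(beta J'J + (alpha + mu) I)^{-1} (beta J'e + alpha w)`.
#' After each accepted step the evidence-framework hyperparameter
#' updates are applied: `gamma = N_w - alpha * tr(H^{-1})` with
#' `H = beta J'J + alpha I`, then `alpha = gamma / (2 E_W)` and
#' `beta = (N_D - gamma) / (2 E_D)`, where `N_D` counts pooled
#' observations (rows times targets). `alpha` starts at 0 and `beta` at
#' 1, so the first epoch is plain Levenberg-Marquardt. Training stops at
#' `max_epochs`, when the gradient infinity norm drops below `grad_tol`,
#' or when no improving step exists below the damping cap `mu_max`.
#'
#' @param x normalized input matrix (rows = samples; typically on
#'   `[-1, 1]`).
#' @param t normalized target matrix with the same number of rows.
#' @param config a [train_config()].
#' @param init optional weight list to start from (default: a fresh
#'   [init_network()] draw under `config$seed`).
#' @return an object of class `brann`: the weight matrices, final
#'   `alpha`, `beta`, `gamma`, `mu`, `n_w`, the stopping `reason`, and a
#'   per-epoch `history` data frame (columns `epoch`, `mu`, `alpha`,
#'   `beta`, `gamma`, `e_d`, `e_w`, `f_before`, `f_after`; the two
#'   objective columns are evaluated under that epoch's hyperparameters,
#'   so `f_after <= f_before` on every accepted step).
#' @export
train_brann <- function(x, t, config = train_config(), init = NULL) {
  x <- as.matrix(x)
  t <- as.matrix(t)
  stopifnot(inherits(config, "train_config"), nrow(x) == nrow(t))
  if (nrow(x) < config$n_hidden) {
    stop("train_brann: need at least n_hidden rows", call. = FALSE)
  }
  n_in <- ncol(x)
  n_out <- ncol(t)
  n_hidden <- config$n_hidden
  n_d <- nrow(x) * n_out
  p <- if (is.null(init)) init_network(n_in, n_hidden, n_out, config$seed) else
    init
  w <- .pack_weights(p)
  n_w <- length(w)
  alpha <- 0
  beta <- 1
  mu <- config$mu_init
  hist <- vector("list", config$max_epochs)
  reason <- "max_epochs"
  sse <- function(wvec) {
    q <- .unpack_weights(wvec, n_in, n_hidden, n_out)
    sum((forward(q, x) - t)^2)
  }
  for (epoch in seq_len(config$max_epochs)) {
    acc <- .br_accumulate(p, x, t, config$chunk_size)
    if (!is.finite(acc$e_d)) {
      stop(sprintf("train_brann: non-finite loss at epoch %d", epoch),
           call. = FALSE)
    }
    e_w <- sum(w^2)
    f_before <- beta * acc$e_d + alpha * e_w
    grad <- 2 * (beta * acc$jte + alpha * w)
    if (max(abs(grad)) < config$grad_tol) {
      reason <- "grad_tol"
      break
    }
    accepted <- FALSE
    w_new <- w
    f_after <- f_before
    e_d_new <- acc$e_d
    while (mu <= config$mu_max) {
      lhs <- beta * acc$jtj
      diag(lhs) <- diag(lhs) + alpha + mu
      step <- tryCatch(solve(lhs, beta * acc$jte + alpha * w),
                       error = function(e) NULL)
      if (!is.null(step)) {
        w_try <- w - step
        e_d_try <- sse(w_try)
        f_try <- beta * e_d_try + alpha * sum(w_try^2)
        if (is.finite(f_try) && f_try < f_before) {
          w_new <- w_try
          f_after <- f_try
          e_d_new <- e_d_try
          accepted <- TRUE
          mu <- max(mu * config$mu_dec, 1e-20)
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) {
      reason <- "mu_max"
      break
    }
    w <- w_new
    p <- .unpack_weights(w, n_in, n_hidden, n_out)
    e_w_new <- sum(w^2)
    # Evidence update from the Gauss-Newton Hessian at the accepted
    # step's linearisation point.
    h <- beta * acc$jtj
    diag(h) <- diag(h) + max(alpha, 1e-10)
    tr_hinv <- tryCatch(sum(diag(chol2inv(chol(h)))),
                        error = function(e) {
                          diag(h) <- diag(h) + 1e-6 * mean(diag(h))
                          sum(diag(chol2inv(chol(h))))
                        })
    gamma <- n_w - alpha * tr_hinv
    gamma <- min(max(gamma, 0), n_w)
    alpha <- gamma / (2 * max(e_w_new, 1e-12))
    beta <- max(n_d - gamma, 1e-3) / (2 * max(e_d_new, 1e-12))
    hist[[epoch]] <- data.frame(
      epoch = epoch, mu = mu, alpha = alpha, beta = beta, gamma = gamma,
      e_d = e_d_new, e_w = e_w_new, f_before = f_before, f_after = f_after)
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(c(p, list(
    alpha = alpha, beta = beta,
    gamma = if (nrow(history)) history$gamma[nrow(history)] else NA_real_,
    mu = mu, n_w = n_w, n_in = n_in, n_hidden = n_hidden, n_out = n_out,
    config = config, history = history, reason = reason,
    signature = NULL
  )), class = "brann")
}

#' @export
print.brann <- function(x, ...) {
  cat(sprintf(
    "brann: %d-%d-%d network, %d weights, %d epochs (stop: %s)\n",
    x$n_in, x$n_hidden, x$n_out, x$n_w,
    if (is.null(x$history)) 0L else nrow(x$history), x$reason))
  cat(sprintf("  alpha = %.4g, beta = %.4g, gamma = %.1f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
predict.brann <- function(object, newdata, ...) {
  forward(object, newdata)
}

#' Serialize / restore a fitted model as JSON
#'
#' The JSON file carries the layer shapes and weights, the final
#' hyperparameters, the training configuration, the frozen column
#' signature and (when attached, as [fit_milk_model()] does) the input
#' and target normalizers, so a restored model is fully self-contained.
#'
#' @param model a `brann` (or `milk_model`) object.
#' @param path file path to write to / read from.
#' @return `read_brann_json` returns the restored model; the writer
#'   returns `path` invisibly.
#' @export
write_brann_json <- function(model, path) {
  payload <- list(
    class = class(model)[1],
    n_in = model$n_in, n_hidden = model$n_hidden, n_out = model$n_out,
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    alpha = model$alpha, beta = model$beta, gamma = model$gamma,
    signature = model$signature,
    config = unclass(model$config),
    norm_x = if (!is.null(model$norm_x)) unclass(model$norm_x),
    norm_t = if (!is.null(model$norm_t)) unclass(model$norm_t)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_brann_json
#' @export
read_brann_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr, nc) {
    if (is.matrix(m)) m else matrix(unlist(m), nr, nc, byrow = TRUE)
  }
  model <- list(
    w1 = as_mat(j$w1, j$n_hidden, j$n_in),
    b1 = as.numeric(j$b1),
    w2 = as_mat(j$w2, j$n_out, j$n_hidden),
    b2 = as.numeric(j$b2),
    alpha = j$alpha, beta = j$beta, gamma = j$gamma,
    n_in = j$n_in, n_hidden = j$n_hidden, n_out = j$n_out,
    n_w = j$n_hidden * j$n_in + j$n_hidden + j$n_out * j$n_hidden + j$n_out,
    signature = j$signature,
    config = do.call(train_config, j$config[names(j$config) != ""]),
    reason = "restored", history = NULL
  )
  restore_norm <- function(nm) {
    if (is.null(nm)) return(NULL)
    structure(list(min = unlist(nm$min), max = unlist(nm$max),
                   cols = unlist(nm$cols)), class = "minmax_normalizer")
  }
  model$norm_x <- restore_norm(j$norm_x)
  model$norm_t <- restore_norm(j$norm_t)
  structure(model, class = unique(c(j$class, "brann")))
}
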