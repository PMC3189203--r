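#' Radial basis function kernel matrix
#'
#' `k(a, b) = exp(-||a - b||^2 / (2 width^2))`.
#'
#' @param x1,x2 Numeric matrices (rows = points) with equal column count.
#' @param width Kernel width (length scale), > 0.
#' @return `nrow(x1) x nrow(x2)` kernel matrix.
#' @export
rbf_kernel <- function(x1, x2, width) {
  stopifnot(width > 0)
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * width^2))
}

#' Median-heuristic kernel width
#'
#' The median of the pairwise Euclidean distances among training points, a
#' standard scale-free default for RBF kernels.
#'
#' @param x Numeric matrix of training points.
#' @return Positive width; 1 if all points coincide.
#' @export
median_kernel_width <- function(x) {
  d <- as.numeric(stats::dist(as.matrix(x)))
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

#' Train a relevance vector machine classifier
#'
#' Sparse Bayesian kernel classification: a logistic model over kernel
#' basis functions (one per training point, plus an always-present bias)
#' with independent zero-mean Gaussian priors whose precisions
#' (hyperparameters alpha) are tuned by type-II maximum likelihood.
#' Training uses the fast sequential marginal-likelihood algorithm: the
#' model starts (nearly) empty and at each step a single basis function is
#' added, re-estimated or deleted -- whichever action yields the largest
#' gain in the Laplace-approximated log marginal likelihood. Basis
#' functions whose precision diverges drop out, leaving a sparse set of
#' relevance vectors. The fitted model returns posterior class
#' probabilities.
#'
#' @param x Numeric matrix (trials x features).
#' @param y Binary vector (1 = accept, 0 = reject); both classes required.
#' @param kernel_width RBF width; `NULL` = median heuristic on `x` (or the
#'   warm model's width when `warm` is given).
#' @param max_iter Maximum add/delete/re-estimate steps (default 500).
#' @param tol Convergence tolerance on the marginal-likelihood change.
#' @param warm Optional previous `rvm_model` trained on a prefix of the
#'   same trials: its active set and hyperparameters seed the search,
#'   which typically cuts retraining cost sharply.
#' @return An object of class `rvm_model` with elements
#'   `relevance_vectors`, `rv_index` (training-point indices), `weights`,
#'   `bias`, `alpha`, `kernel_width`, `converged`, `iterations`,
#'   `n_train`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' y <- rep(c(0, 1), each = 10)
#' m <- rvm_train(x, y)
#' mean((rvm_predict(m, x) >= 0.5) == y)
#' @export
rvm_train <- function(x, y, kernel_width = NULL, max_iter = 500, tol = 1e-6,
                      warm = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 training samples")
  if (length(y) != n) stop("x and y lengths differ")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("single-class training set")
  if (is.null(kernel_width)) {
    kernel_width <- if (!is.null(warm)) warm$kernel_width else
      median_kernel_width(x)
  }
  phi <- cbind(1, rbf_kernel(x, x, kernel_width))  # n x (n+1); col 1 = bias
  nb <- ncol(phi)
  alpha_bias <- 1e-6  # bias effectively unpenalized and never deleted

  alpha <- rep(Inf, nb)
  alpha[1L] <- alpha_bias
  if (!is.null(warm)) {
    n_keep <- min(length(warm$alpha_full), nb)
    alpha[seq_len(n_keep)] <- warm$alpha_full[seq_len(n_keep)]
    alpha[1L] <- alpha_bias
  }

  active <- which(is.finite(alpha))
  w_act <- numeric(length(active))
  if (!is.null(warm)) {
    wf <- warm$weights_full
    w_act <- ifelse(active <= length(wf), wf[active], 0)
  }

  converged <- FALSE
  steps <- 0L
  fit <- NULL
  while (steps < max_iter) {
    steps <- steps + 1L
    pa <- phi[, active, drop = FALSE]
    # a short Newton refresh per action step suffices (the mode moves
    # little between single-basis updates); the final fit is run to full
    # convergence below
    fit <- rvm_laplace_mode(pa, y, alpha[active], w_act, max_newton = 4)
    w_act <- fit$w
    ch <- fit$chol_h                    # H = R'R, Sigma = H^{-1}
    eta <- drop(pa %*% w_act)
    p <- stats::plogis(eta)
    b <- pmax(p * (1 - p), 1e-10)
    t_hat <- eta + (y - p) / b          # Laplace effective targets
    bphi <- phi * b                     # rows scaled by beta
    pm <- crossprod(pa, bphi)           # |A| x nb, col m = Phi_A' B phi_m
    u <- backsolve(ch, backsolve(ch, pm, transpose = TRUE))  # Sigma %*% pm
    s_cap <- colSums(phi * bphi) - colSums(pm * u)
    z <- backsolve(ch, backsolve(ch, crossprod(pa, b * t_hat),
                                 transpose = TRUE))
    q_cap <- drop(crossprod(bphi, t_hat)) - drop(crossprod(pm, z))

    s <- s_cap
    q <- q_cap
    in_model <- seq_len(nb) %in% active
    denom <- alpha - s_cap
    ok_in <- in_model & is.finite(alpha) & denom > 1e-12
    s[ok_in] <- alpha[ok_in] * s_cap[ok_in] / denom[ok_in]
    q[ok_in] <- alpha[ok_in] * q_cap[ok_in] / denom[ok_in]
    theta <- q^2 - s

    delta <- rep(-Inf, nb)              # 2 * marginal-likelihood change
    # addition candidates
    add <- !in_model & theta > 0 & s_cap > 1e-12
    delta[add] <- (q_cap[add]^2 - s_cap[add]) / s_cap[add] +
      log(s_cap[add] / q_cap[add]^2)
    # re-estimation candidates
    re <- in_model & theta > 0 & ok_in
    if (any(re)) {
      a_new <- s[re]^2 / theta[re]
      d <- 1 / a_new - 1 / alpha[re]
      good <- a_new > 0 & is.finite(a_new) & (1 + s_cap[re] * d) > 0 &
        abs(d) > 1e-14
      v <- rep(-Inf, sum(re))
      v[good] <- q_cap[re][good]^2 / (s_cap[re][good] + 1 / d[good]) -
        log1p(s_cap[re][good] * d[good])
      delta[re] <- v
      alpha_re <- rep(NA_real_, nb)
      alpha_re[re] <- a_new
    } else {
      alpha_re <- rep(NA_real_, nb)
    }
    # deletion candidates
    del <- in_model & theta <= 0 & (alpha - s_cap) > 1e-12
    delta[del] <- q_cap[del]^2 / (s_cap[del] - alpha[del]) -
      log1p(-s_cap[del] / alpha[del])
    delta[1L] <- -Inf                    # bias is fixed

    best <- which.max(delta)
    if (!is.finite(delta[best]) || delta[best] < 2 * tol) {
      converged <- TRUE
      break
    }
    if (!in_model[best]) {
      alpha[best] <- s[best]^2 / theta[best]
      old_active <- active
      active <- sort(c(active, best))
      w_new <- numeric(length(active))
      w_new[match(old_active, active)] <- w_act
      w_act <- w_new
    } else if (theta[best] > 0) {
      alpha[best] <- alpha_re[best]
    } else {
      alpha[best] <- Inf
      keep <- active != best
      w_act <- w_act[keep]
      active <- active[keep]
    }
  }
  # final mode under the final hyperparameters
  pa <- phi[, active, drop = FALSE]
  fit <- rvm_laplace_mode(pa, y, alpha[active], w_act)
  w_full <- numeric(nb)
  w_full[active] <- fit$w

  rv_basis <- setdiff(active, 1L)
  structure(list(
    relevance_vectors = x[rv_basis - 1L, , drop = FALSE],
    rv_index = rv_basis - 1L,
    weights = w_full[rv_basis],
    bias = w_full[1L],
    alpha = alpha[active],
    alpha_full = alpha,
    weights_full = w_full,
    kernel_width = kernel_width,
    converged = converged,
    iterations = steps,
    n_train = n
  ), class = "rvm_model")
}

# Newton (IRLS) search for the posterior mode of the penalized logistic
# model; returns the mode, the Cholesky factor of the Hessian at the mode,
# and the data log-likelihood.
rvm_laplace_mode <- function(phi, y, alpha, w0,
                             max_newton = 50, newton_tol = 1e-8) {
  w <- w0
  obj <- function(w) {
    eta <- drop(phi %*% w)
    softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    ll <- sum(y * eta - softplus)
    list(ll = ll, pen = ll - 0.5 * sum(alpha * w^2), eta = eta)
  }
  cur <- obj(w)
  for (i in seq_len(max_newton)) {
    p <- stats::plogis(cur$eta)
    g <- drop(crossprod(phi, y - p)) - alpha * w
    b <- p * (1 - p)
    h <- crossprod(phi * sqrt(b)) + diag(alpha, length(alpha))
    ch <- tryCatch(chol(h), error = function(e) chol(h + diag(1e-8, nrow(h))))
    step <- backsolve(ch, backsolve(ch, g, transpose = TRUE))
    lambda <- 1
    repeat {
      w_new <- w + lambda * step
      nxt <- obj(w_new)
      if (is.finite(nxt$pen) && (nxt$pen >= cur$pen - 1e-12) || lambda < 1e-4)
        break
      lambda <- lambda / 2
    }
    done <- abs(nxt$pen - cur$pen) < newton_tol
    w <- w_new
    cur <- nxt
    if (done) break
  }
  p <- stats::plogis(cur$eta)
  b <- p * (1 - p)
  h <- crossprod(phi * sqrt(b)) + diag(alpha, length(alpha))
  ch <- tryCatch(chol(h), error = function(e) chol(h + diag(1e-8, nrow(h))))
  list(w = w, chol_h = ch, loglik = cur$ll)
}

#' Posterior class probability from a trained RVM
#'
#' @param model An `rvm_model`.
#' @param x Matrix (or single vector) of feature vectors to classify.
#' @return Posterior probability of class 1 (accept) per row, in `[0, 1]`.
#'   `P(accept) + P(reject) = 1` by construction.
#' @export
rvm_predict <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  eta <- rep(model$bias, nrow(x))
  if (length(model$weights)) {
    k <- rbf_kernel(x, model$relevance_vectors, model$kernel_width)
    eta <- eta + drop(k %*% model$weights)
  }
  stats::plogis(eta)
}

#' Hard accept/reject labels from posterior probabilities
#'
#' Accept (1) if the posterior probability of acceptance is at least 0.5;
#' the tie at exactly 0.5 resolves to accept, keeping the rule
#' deterministic.
#'
#' @param posterior Numeric vector of posteriors in `[0, 1]`.
#' @return Integer vector of 0/1 labels.
#' @export
posterior_to_label <- function(posterior) {
  as.integer(posterior >= 0.5)
}

#' @export
print.rvm_model <- function(x, ...) {
  cat("RVM classifier: ", length(x$weights), " relevance vectors (of ",
      x$n_train, " training points), kernel width ",
      signif(x$kernel_width, 4), ", ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " steps\n", sep = "")
  invisible(x)
}
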