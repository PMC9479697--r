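#' Initialize the state-to-action policy network
#'
#' Creates the parameters of the three-layer state-to-action mapping
#' network (152 input, 80 tanh hidden, 4 softmax output neurons by
#' default): symmetric uniform weights scaled by fan-in, zero biases, and
#' zeroed ADAM moment accumulators.
#'
#' @param sizes integer vector `c(input, hidden, actions)`.
#' @param init_scale half-width multiplier of the uniform init
#'   (`scale / sqrt(fan_in)`).
#' @param seed optional integer seed for reproducible initialization.
#' @return a `psa_policy` parameter list (`W1`, `b1`, `W2`, `b2`, ADAM
#'   moments, step counter).
#' @export
init_policy <- function(sizes = c(152L, 80L, 4L), init_scale = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r1 <- init_scale / sqrt(sizes[1])
  r2 <- init_scale / sqrt(sizes[2])
  theta <- list(
    W1 = matrix(runif(sizes[1] * sizes[2], -r1, r1), sizes[1], sizes[2]),
    b1 = numeric(sizes[2]),
    W2 = matrix(runif(sizes[2] * sizes[3], -r2, r2), sizes[2], sizes[3]),
    b2 = numeric(sizes[3]),
    sizes = sizes, step = 0L)
  theta$m <- lapply(theta[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  theta$v <- theta$m
  class(theta) <- "psa_policy"
  theta
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Policy forward pass
#'
#' Computes `softmax(W2' tanh(W1' s + b1) + b2)`: the action probability
#' vector of the policy for one mental-state vector.
#'
#' @param theta a `psa_policy`.
#' @param s state vector matching the input layer width.
#' @return probability vector over the action levels (sums to 1).
#' @export
policy_forward <- function(theta, s) {
  if (length(s) != theta$sizes[1])
    stop(sprintf("shape error: state length %d, input layer %d",
                 length(s), theta$sizes[1]))
  h <- tanh(drop(crossprod(theta$W1, s)) + theta$b1)
  softmax(drop(crossprod(theta$W2, h)) + theta$b2)
}

# Batched forward: S is n x din; returns list(H n x dh, P n x da).
policy_forward_batch <- function(theta, S) {
  H <- tanh(sweep(S %*% theta$W1, 2, theta$b1, "+"))
  Z <- sweep(H %*% theta$W2, 2, theta$b2, "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  list(H = H, P = E / rowSums(E))
}

#' Sample a speed action from the policy output
#'
#' Draws an action level from the categorical distribution given by
#' `probs`. Reproducible under a fixed seed (uses the global RNG stream).
#'
#' @param probs probability vector over action levels.
#' @param multipliers speed multiplier per level (default from
#'   [psa_config()]: descending, level 0 is fastest).
#' @return list with `level` (0-based integer) and `multiplier`.
#' @export
sample_action <- function(probs, multipliers = c(2.0, 1.5, 1.0, 0.5)) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6)
    stop("invalid distribution: probabilities must be nonnegative and sum to 1")
  lev <- sample.int(length(probs), 1L, prob = probs) - 1L
  list(level = lev, multiplier = multipliers[lev + 1L])
}

#' Exact gradient of the log action probability
#'
#' Analytic backpropagation of `d log p(a | s) / d theta` through the
#' softmax output and tanh hidden layer. The output-bias component equals
#' `one_hot(a) - probs` in closed form.
#'
#' @param theta a `psa_policy`.
#' @param s state vector.
#' @param a action level (0-based integer).
#' @return list of gradients shaped like `W1`, `b1`, `W2`, `b2`.
#' @export
grad_log_prob <- function(theta, s, a) {
  h <- tanh(drop(crossprod(theta$W1, s)) + theta$b1)
  p <- softmax(drop(crossprod(theta$W2, h)) + theta$b2)
  dz <- -p
  dz[a + 1L] <- dz[a + 1L] + 1
  dh <- drop(theta$W2 %*% dz) * (1 - h^2)
  list(W1 = outer(as.numeric(s), dh), b1 = dh,
       W2 = outer(h, dz), b2 = dz)
}

# One ADAM step on the four parameter blocks. `direction = +1` ascends the
# objective (policy gradient), `-1` descends (pretraining loss).
adam_step <- function(theta, grad, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, direction = 1) {
  theta$step <- theta$step + 1L
  t <- theta$step
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- grad[[nm]]
    theta$m[[nm]] <- beta1 * theta$m[[nm]] + (1 - beta1) * g
    theta$v[[nm]] <- beta2 * theta$v[[nm]] + (1 - beta2) * g^2
    mhat <- theta$m[[nm]] / (1 - beta1^t)
    vhat <- theta$v[[nm]] / (1 - beta2^t)
    theta[[nm]] <- theta[[nm]] + direction * lr * mhat / (sqrt(vhat) + eps)
  }
  theta
}

#' Pretrain the policy on labeled mental-state classes
#'
#' Supervised warm start of the state-to-action network: minimizes the
#' 4-way softmax cross-entropy between the policy output and class labels
#' (class index mapped directly to action index) with minibatch ADAM. The
#' default labeled source is the synthetic four-class
#' valence/arousal-corner emulator ([make_deap_like_dataset()]).
#'
#' @param theta a `psa_policy`.
#' @param X feature matrix, rows = observations.
#' @param y integer class labels in `0..(actions-1)`.
#' @param epochs training epochs (passes over the data).
#' @param batch_size minibatch size (default 50).
#' @param lr,beta1,beta2 ADAM settings.
#' @return list: `theta` (trained), `loss` (per-epoch mean cross-entropy),
#'   `accuracy` (final training accuracy).
#' @export
pretrain <- function(theta, X, y, epochs = 400L, batch_size = 50L,
                     lr = 0.001, beta1 = 0.9, beta2 = 0.999) {
  X <- as.matrix(X)
  y <- as.integer(y)
  da <- theta$sizes[3]
  if (any(y < 0 | y >= da)) stop("label error: classes must be in 0..", da - 1)
  if (length(unique(y)) < da) stop("label error: need at least one example per class")
  n <- nrow(X)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xi <- X[idx, , drop = FALSE]
      fb <- policy_forward_batch(theta, Xi)
      P <- fb$P
      m <- length(idx)
      onehot <- matrix(0, m, da)
      onehot[cbind(seq_len(m), y[idx] + 1L)] <- 1
      ep_loss <- ep_loss - sum(log(pmax(P[onehot == 1], 1e-300)))
      dz <- (P - onehot) / m                      # d(mean CE)/d logits
      dH <- (dz %*% t(theta$W2)) * (1 - fb$H^2)
      grad <- list(W1 = crossprod(Xi, dH), b1 = colSums(dH),
                   W2 = crossprod(fb$H, dz), b2 = colSums(dz))
      theta <- adam_step(theta, grad, lr, beta1, beta2, direction = -1)
    }
    loss_hist[ep] <- ep_loss / n
  }
  P <- policy_forward_batch(theta, X)$P
  acc <- mean(max.col(P) - 1L == y)
  list(theta = theta, loss = loss_hist, accuracy = acc)
}
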