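# Three-layer multi-input single-output backpropagation regression network.
# The flat genome layout is the contract shared with the PSO-GA optimizer:
# [input->hidden weights (row-major by hidden unit), hidden biases,
#  hidden->output weights, output biases].

#' Hidden-layer sizing rule
#'
#' Two printed forms of the empirical sizing rule are supported:
#' `"as-printed"` returns `n_input + n_output + a`; `"sqrt"` returns
#' `round(sqrt(n_input + n_output)) + a`.  The constant `a` must lie in
#' \[1, 9\].  The default (`"as-printed"`, `a = 2`) gives 13 hidden nodes
#' for a 10-input, 1-output regression network.
#'
#' @param n_input,n_output Layer sizes.
#' @param a Integer constant in \[1, 9\].
#' @param form Which form of the rule to apply.
#' @return Hidden node count.
#' @export
#' @examples
#' hidden_node_count(10, 1)            # 13
#' hidden_node_count(10, 1, a = 9, form = "sqrt")  # 12
hidden_node_count <- function(n_input, n_output, a = 2,
                              form = c("as-printed", "sqrt")) {
  form <- match.arg(form)
  n_input <- check_count(n_input, "n_input")
  n_output <- check_count(n_output, "n_output")
  check_number(a, "a")
  if (a < 1 || a > 9) stopf("'a' must lie in [1, 9]")
  if (form == "as-printed") {
    as.integer(n_input + n_output + a)
  } else {
    as.integer(round(sqrt(n_input + n_output)) + a)
  }
}

ACTIVATIONS <- list(
  tanh = list(f = tanh, df_from_h = function(h) 1 - h^2),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df_from_h = function(h) h * (1 - h)),
  linear = list(f = identity, df_from_h = function(h) rep(1, length(h)))
)

#' Network architecture
#'
#' @param n_input Input nodes (default 10, one per plantar region).
#' @param n_hidden Hidden nodes (default 13, from [hidden_node_count()]).
#' @param n_output Output nodes (default 1, the stiffness).
#' @param hidden_activation,output_activation Activation names among
#'   `"tanh"`, `"sigmoid"`, `"linear"`.  Defaults tanh / linear, the usual
#'   regression pairing.
#' @return An object of class `network_architecture`.
#' @export
network_architecture <- function(n_input = 10, n_hidden = 13, n_output = 1,
                                 hidden_activation = "tanh",
                                 output_activation = "linear") {
  n_input <- check_count(n_input, "n_input")
  n_hidden <- check_count(n_hidden, "n_hidden")
  n_output <- check_count(n_output, "n_output")
  hidden_activation <- match.arg(hidden_activation, names(ACTIVATIONS))
  output_activation <- match.arg(output_activation, names(ACTIVATIONS))
  structure(list(n_input = n_input, n_hidden = n_hidden, n_output = n_output,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "network_architecture")
}

#' Genome length of an architecture
#'
#' `n_input*n_hidden + n_hidden + n_hidden*n_output + n_output`; 157 for the
#' default 10-13-1 network.
#'
#' @param arch A [network_architecture()].
#' @return Integer length of the flat weight/bias vector.
#' @export
genome_length <- function(arch) {
  with(arch, n_input * n_hidden + n_hidden + n_hidden * n_output + n_output)
}

decode_genome <- function(genome, arch) {
  gl <- genome_length(arch)
  if (length(genome) != gl) {
    stopf("genome has length %d, architecture needs %d", length(genome), gl)
  }
  if (!all(is.finite(genome))) stopf("genome must be finite")
  ni <- arch$n_input; nh <- arch$n_hidden; no <- arch$n_output
  i <- 0L
  W1 <- matrix(genome[i + seq_len(nh * ni)], nrow = nh, byrow = TRUE)
  i <- i + nh * ni
  b1 <- genome[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(genome[i + seq_len(no * nh)], nrow = no, byrow = TRUE)
  i <- i + no * nh
  b2 <- genome[i + seq_len(no)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

encode_genome <- function(W1, b1, W2, b2) {
  c(as.vector(t(W1)), b1, as.vector(t(W2)), b2)
}

#' Forward pass of the network
#'
#' Computes \eqn{h = f_h(W_1 x + b_1)}, \eqn{\hat y = f_o(W_2 h + b_2)} for
#' every row of `X`, vectorized over samples.
#'
#' @param genome Flat weight/bias vector (see [genome_length()] layout).
#' @param arch A [network_architecture()].
#' @param X Input matrix (n x n_input) or a single input vector, on the
#'   normalized scale.
#' @return Numeric vector of n predictions (normalized scale) for
#'   single-output networks; an n x n_output matrix otherwise.
#' @export
nn_forward <- function(genome, arch, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != arch$n_input) {
    stopf("input has %d columns, architecture expects %d",
          ncol(X), arch$n_input)
  }
  p <- decode_genome(genome, arch)
  fh <- ACTIVATIONS[[arch$hidden_activation]]$f
  fo <- ACTIVATIONS[[arch$output_activation]]$f
  H <- fh(X %*% t(p$W1) + rep(p$b1, each = nrow(X)))
  Y <- fo(H %*% t(p$W2) + rep(p$b2, each = nrow(X)))
  if (arch$n_output == 1L) drop(Y) else Y
}

nn_mse <- function(genome, arch, X, y) {
  r <- nn_forward(genome, arch, X) - y
  mean(r^2)
}

#' Gradient of the mean squared error
#'
#' Analytic backpropagation gradient of \eqn{(1/n)\sum(\hat y - y)^2} with
#' respect to every weight and bias, returned in genome layout.
#' Single-output networks only.
#'
#' @inheritParams nn_forward
#' @param y Target vector (normalized scale), length `nrow(X)`.
#' @return Numeric vector with the same length and layout as `genome`.
#' @export
nn_gradient <- function(genome, arch, X, y) {
  if (arch$n_output != 1L) stopf("gradient implemented for single-output networks")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stopf("X and y row counts differ")
  p <- decode_genome(genome, arch)
  act_h <- ACTIVATIONS[[arch$hidden_activation]]
  act_o <- ACTIVATIONS[[arch$output_activation]]
  A1 <- X %*% t(p$W1) + rep(p$b1, each = n)      # n x nh pre-activations
  H <- act_h$f(A1)
  A2 <- drop(H %*% t(p$W2)) + p$b2
  yhat <- act_o$f(A2)
  # dL/dA2, with the output activation derivative expressed via its value
  d2 <- (2 / n) * (yhat - y) * act_o$df_from_h(yhat)     # length n
  gW2 <- matrix(colSums(d2 * H), nrow = 1L)               # 1 x nh
  gb2 <- sum(d2)
  dH <- outer(d2, drop(p$W2))                             # n x nh
  dA1 <- dH * act_h$df_from_h(H)
  gW1 <- t(dA1) %*% X                                     # nh x ni
  gb1 <- colSums(dA1)
  encode_genome(gW1, gb1, gW2, gb2)
}

#' Training configuration
#'
#' Defaults follow the study design: full-batch gradient descent for up to
#' 8000 epochs at learning rate 0.01, stopping early once the normalized
#' MSE reaches `goal_mse = 1e-6`.
#'
#' @param max_epochs Maximum training epochs.
#' @param goal_mse Target MSE on the normalized scale.
#' @param learning_rate Gradient-descent step size.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 8000, goal_mse = 1e-6,
                         learning_rate = 0.01) {
  max_epochs <- check_count(max_epochs, "max_epochs")
  check_number(goal_mse, "goal_mse", lower = 0, strict = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  structure(list(max_epochs = max_epochs, goal_mse = goal_mse,
                 learning_rate = learning_rate),
            class = "train_config")
}

#' Train the network by full-batch gradient descent
#'
#' Starting from `genome0` (typically the PSO-GA optimum), repeatedly steps
#' along the negative MSE gradient until `goal_mse` is reached or
#' `max_epochs` epochs have run.  Deterministic given its inputs: no
#' mini-batching and no random restarts.
#'
#' @param genome0 Initial genome.
#' @param arch A [network_architecture()].
#' @param X,y Normalized training inputs and targets.
#' @param config A [train_config()].
#' @return List of class `bp_training` with `genome`, `loss_history` (MSE
#'   before each update, plus the final MSE), `epochs` run and `converged`.
#' @export
train_bp <- function(genome0, arch, X, y, config = train_config()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (nrow(X) < 1L) stopf("empty training set")
  if (length(y) != nrow(X)) stopf("X and y row counts differ")
  genome <- as.numeric(genome0)
  history <- numeric(config$max_epochs + 1L)
  epochs <- 0L
  converged <- FALSE
  for (e in seq_len(config$max_epochs)) {
    L <- nn_mse(genome, arch, X, y)
    history[e] <- L
    if (L <= config$goal_mse) { converged <- TRUE; break }
    genome <- genome - config$learning_rate * nn_gradient(genome, arch, X, y)
    epochs <- e
  }
  final <- nn_mse(genome, arch, X, y)
  if (final <= config$goal_mse) converged <- TRUE
  history <- history[seq_len(epochs + 1L)]
  history[epochs + 1L] <- final
  structure(list(genome = genome, loss_history = history,
                 epochs = epochs, converged = converged),
            class = "bp_training")
}

#' Bundle a trained genome into a predictive model
#'
#' A `bp_model` carries everything prediction needs: the genome, the
#' architecture and the normalization parameters used at fit time, so
#' [predict.bp_model()] accepts raw-scale pressures and returns N/m.
#'
#' @param genome Trained genome.
#' @param arch A [network_architecture()].
#' @param normalizer A [fit_normalizer()] result.
#' @param training Optional `bp_training` record.
#' @return An object of class `bp_model`.
#' @export
bp_model <- function(genome, arch, normalizer, training = NULL) {
  decode_genome(genome, arch)  # validates length/finiteness
  structure(list(genome = as.numeric(genome), arch = arch,
                 normalizer = normalizer, training = training),
            class = "bp_model")
}

#' Predict stiffness from raw regional pressures
#'
#' @param object A [bp_model()].
#' @param newdata Raw-scale feature matrix (n x 10), a 10-vector, or a
#'   `pressure_dataset`.
#' @param ... Unused.
#' @return Predicted stiffness (N/m).
#' @export
predict.bp_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "pressure_dataset")) newdata$X else newdata
  Xn <- normalize_features(X, object$normalizer)
  denormalize_target(nn_forward(object$genome, object$arch, Xn),
                     object$normalizer)
}

#' @export
print.bp_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("BP regression network %d-%d-%d (%s/%s), genome length %d\n",
              a$n_input, a$n_hidden, a$n_output,
              a$hidden_activation, a$output_activation, genome_length(a)))
  if (!is.null(x$training)) {
    cat(sprintf("trained %d epochs, final normalized MSE %.3g\n",
                x$training$epochs, utils::tail(x$training$loss_history, 1)))
  }
  invisible(x)
}

#' Serialize / load a model as JSON
#'
#' The JSON carries the genome, the architecture and the normalization
#' parameters, everything needed to reproduce predictions bit-exactly.
#'
#' @param model A [bp_model()].
#' @param path JSON path.
#' @return `path` invisibly (writer); a `bp_model` (reader).
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(genome = model$genome,
                            arch = unclass(model$arch),
                            normalizer = unclass(model$normalizer)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- do.call(network_architecture, as.list(obj$arch))
  normalizer <- structure(list(x_min = as.numeric(obj$normalizer$x_min),
                               x_max = as.numeric(obj$normalizer$x_max),
                               y_min = obj$normalizer$y_min,
                               y_max = obj$normalizer$y_max),
                          class = "normalization_params")
  bp_model(as.numeric(obj$genome), arch, normalizer)
}
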