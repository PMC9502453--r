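## Multi-task feed-forward network in plain matrix algebra. Architecture:
## input -> shared fully connected layer (N units, activation AF) -> dropout
## -> second fully connected layer (NTS units, AF) -> one sigmoid output per
## fingerprint bit. Loss is the mean per-bit binary cross-entropy, the
## canonical likelihood for independent sigmoid outputs. Training is
## mini-batch backpropagation with Adam, SGD or RMSprop and early stopping
## on validation loss with best-weight restore.

#' Network hyperparameters
#'
#' The eight tunable settings of the multi-task network. Defaults are a
#' reasonable mid-scale configuration; \code{\link{tuningSpace}} carries the
#' search bounds used for optimisation.
#'
#' @param n_neurons width N of the shared hidden layer.
#' @param n_task_specific width NTS of the second ("task-specific") hidden
#'   layer feeding the per-task output weights.
#' @param learning_rate optimizer step size.
#' @param activation hidden-layer activation, \code{"sigmoid"} or
#'   \code{"relu"} (outputs are always sigmoid).
#' @param dropout dropout fraction after the shared layer, in [0, 0.5].
#' @param batch_size mini-batch size.
#' @param patience early-stopping patience in epochs.
#' @param optimizer \code{"adam"}, \code{"sgd"} or \code{"rmsprop"}.
#' @return a named list of class \code{Hyperparameters}.
#' @export
hyperparameters <- function(n_neurons = 100L, n_task_specific = 250L,
                            learning_rate = 0.006,
                            activation = c("sigmoid", "relu"),
                            dropout = 0.30, batch_size = 128L,
                            patience = 50L,
                            optimizer = c("rmsprop", "adam", "sgd")) {
    activation <- match.arg(activation)
    optimizer <- match.arg(optimizer)
    stopifnot(n_neurons >= 1, n_task_specific >= 1,
              learning_rate > 0, dropout >= 0, dropout <= 0.5,
              batch_size >= 1, patience >= 1)
    structure(list(n_neurons = as.integer(n_neurons),
                   n_task_specific = as.integer(n_task_specific),
                   learning_rate = learning_rate,
                   activation = activation,
                   dropout = dropout,
                   batch_size = as.integer(batch_size),
                   patience = as.integer(patience),
                   optimizer = optimizer),
              class = "Hyperparameters")
}

.act <- function(z, kind) {
    if (kind == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
}

.actGrad <- function(z, h, kind) {
    if (kind == "relu") (z > 0) * 1 else h * (1 - h)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Build a multi-task network
#'
#' Initialises weights with Glorot-uniform draws under \code{seed}; the
#' same seed always yields the same initial weights.
#'
#' @param hp a \code{\link{hyperparameters}} list.
#' @param n_inputs input dimension (bins or component scores).
#' @param n_tasks number of output bits (166 for MACCS keys).
#' @param seed integer seed for weight initialisation.
#' @return an untrained \linkS4class{MultiTaskNet}.
#' @export
buildNetwork <- function(hp, n_inputs, n_tasks = 166L, seed = 1L) {
    if (!inherits(hp, "Hyperparameters")) hp <- do.call(hyperparameters, hp)
    stopifnot(n_inputs >= 1, n_tasks >= 1)
    set.seed(seed)
    glorot <- function(fan_in, fan_out) {
        lim <- sqrt(6 / (fan_in + fan_out))
        matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    }
    w <- list(W1 = glorot(n_inputs, hp$n_neurons),
              b1 = numeric(hp$n_neurons),
              W2 = glorot(hp$n_neurons, hp$n_task_specific),
              b2 = numeric(hp$n_task_specific),
              W3 = glorot(hp$n_task_specific, n_tasks),
              b3 = numeric(n_tasks))
    new("MultiTaskNet", weights = w, hp = unclass(hp),
        nInputs = as.integer(n_inputs), nTasks = as.integer(n_tasks),
        seed = as.integer(seed),
        history = data.frame(epoch = integer(0), train_loss = numeric(0),
                             val_loss = numeric(0)))
}

.forward <- function(w, x, hp, dropmask = NULL) {
    z1 <- sweep(x %*% w$W1, 2L, w$b1, "+")
    h1 <- .act(z1, hp$activation)
    h1d <- if (is.null(dropmask)) h1 else h1 * dropmask
    z2 <- sweep(h1d %*% w$W2, 2L, w$b2, "+")
    h2 <- .act(z2, hp$activation)
    z3 <- sweep(h2 %*% w$W3, 2L, w$b3, "+")
    list(z1 = z1, h1 = h1, h1d = h1d, z2 = z2, h2 = h2,
         p = .sigmoid(z3))
}

.bce <- function(p, y) {
    eps <- 1e-12
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}

.optimInit <- function(w) {
    zeros <- lapply(w, function(m) m * 0)
    list(m = zeros, v = zeros, t = 0L)
}

.optimStep <- function(w, g, state, hp) {
    lr <- hp$learning_rate
    if (hp$optimizer == "sgd") {
        for (nm in names(w)) w[[nm]] <- w[[nm]] - lr * g[[nm]]
    } else if (hp$optimizer == "rmsprop") {
        rho <- 0.9; eps <- 1e-7
        for (nm in names(w)) {
            state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g[[nm]]^2
            w[[nm]] <- w[[nm]] - lr * g[[nm]] / (sqrt(state$v[[nm]]) + eps)
        }
    } else {                                   # adam
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        state$t <- state$t + 1L
        for (nm in names(w)) {
            state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g[[nm]]
            state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g[[nm]]^2
            mhat <- state$m[[nm]] / (1 - b1^state$t)
            vhat <- state$v[[nm]] / (1 - b2^state$t)
            w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
    }
    list(w = w, state = state)
}

#' Train a multi-task network
#'
#' Minimises mean per-bit binary cross-entropy by mini-batch
#' backpropagation. Training stops when the validation loss has not
#' improved for \code{patience} epochs (or at \code{max_epochs}), and the
#' weights of the best validation epoch are restored.
#'
#' @param net a \linkS4class{MultiTaskNet} from \code{\link{buildNetwork}}.
#' @param x_train,y_train training features and binary targets (rows
#'   aligned).
#' @param x_val,y_val validation features and targets for early stopping.
#' @param max_epochs hard epoch cap.
#' @param l1_shared L1 weight-decay coefficient on the input-to-shared
#'   weights. Spectral inputs are wide and sparse, and only a small subset
#'   of bins is informative for any bit, so an L1 penalty on the first
#'   layer steers hidden units toward few bins and markedly improves
#'   generalisation to unseen compounds; 0 disables it.
#' @param seed seed for batch shuffling and dropout masks (defaults to the
#'   network's initialisation seed).
#' @param verbose print per-epoch losses?
#' @return the trained \linkS4class{MultiTaskNet} with its history filled.
#' @export
trainNetwork <- function(net, x_train, y_train, x_val, y_val,
                         max_epochs = 300L, l1_shared = 0,
                         seed = net@seed, verbose = FALSE) {
    stopifnot(nrow(x_train) == nrow(y_train),
              nrow(x_val) == nrow(y_val),
              ncol(y_train) == net@nTasks)
    x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
    x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
    hp <- net@hp
    w <- net@weights
    state <- .optimInit(w)
    set.seed(seed)
    n <- nrow(x_train)
    bs <- min(hp$batch_size, n)
    best_loss <- Inf
    best_w <- w
    best_epoch <- 0L
    hist <- vector("list", max_epochs)

    for (epoch in seq_len(max_epochs)) {
        ord <- sample.int(n)
        batch_losses <- numeric(0)
        for (start in seq(1L, n, by = bs)) {
            idx <- ord[start:min(start + bs - 1L, n)]
            xb <- x_train[idx, , drop = FALSE]
            yb <- y_train[idx, , drop = FALSE]
            nb <- nrow(xb)
            dropmask <- NULL
            if (hp$dropout > 0)
                dropmask <- matrix(
                    (runif(nb * hp$n_neurons) >= hp$dropout) /
                        (1 - hp$dropout),
                    nb, hp$n_neurons)
            f <- .forward(w, xb, hp, dropmask)
            loss <- .bce(f$p, yb)
            if (!is.finite(loss))
                stop(sprintf("non-finite training loss at epoch %d; %s",
                             epoch, "reduce the learning rate"))
            batch_losses <- c(batch_losses, loss)

            dz3 <- (f$p - yb) / (nb * ncol(yb))
            g <- list()
            g$W3 <- crossprod(f$h2, dz3)
            g$b3 <- colSums(dz3)
            dh2 <- tcrossprod(dz3, w$W3)
            dz2 <- dh2 * .actGrad(f$z2, f$h2, hp$activation)
            g$W2 <- crossprod(f$h1d, dz2)
            g$b2 <- colSums(dz2)
            dh1 <- tcrossprod(dz2, w$W2)
            if (!is.null(dropmask)) dh1 <- dh1 * dropmask
            dz1 <- dh1 * .actGrad(f$z1, f$h1, hp$activation)
            g$W1 <- crossprod(xb, dz1)
            if (l1_shared > 0)
                g$W1 <- g$W1 + l1_shared * sign(w$W1)
            g$b1 <- colSums(dz1)
            g <- g[names(w)]
            upd <- .optimStep(w, g, state, hp)
            w <- upd$w
            state <- upd$state
        }
        val_loss <- .bce(.forward(w, x_val, hp)$p, y_val)
        hist[[epoch]] <- c(epoch = epoch,
                           train_loss = mean(batch_losses),
                           val_loss = val_loss)
        if (verbose)
            message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                            mean(batch_losses), val_loss))
        if (val_loss < best_loss) {
            best_loss <- val_loss
            best_w <- w
            best_epoch <- epoch
        } else if (epoch - best_epoch >= hp$patience) {
            break
        }
    }
    net@weights <- best_w
    net@history <- as.data.frame(do.call(rbind,
                                         hist[!vapply(hist, is.null,
                                                      logical(1))]))
    net
}

#' Per-bit activation probabilities
#'
#' Forward pass without dropout.
#'
#' @param object a trained \linkS4class{MultiTaskNet}.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return matrix of probabilities in (0, 1), one column per bit.
#' @export
setMethod("predict", "MultiTaskNet", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object@nInputs)
        stop("newdata has ", ncol(newdata), " columns; network expects ",
             object@nInputs)
    .forward(object@weights, newdata, object@hp)$p
})
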