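#' Misclassification cost matrix for target-decoy learning
#'
#' The 2x2 cost table driving the cost-sensitive classifier. Decoy hits
#' (class 0) have labels that are correct by construction, so the cost of a
#' false positive (misclassifying a decoy) is set at or above the cost of a
#' false negative; correct classifications carry zero cost. Raising `cfp`
#' biases the model toward class 0, which relabels the wrong target hits —
#' the ones statistically identical to decoys — to class 0.
#'
#' @param cfp Cost of a false positive, >= `cfn` and >= 1.
#' @param cfn Cost of a false negative (default 1).
#' @return A `cost_matrix` object with fields `cfp`, `cfn`, `ctn = 0`,
#'   `ctp = 0`.
#' @examples
#' cost_matrix(10) # decoys weigh 10x targets during training
#' @export
cost_matrix <- function(cfp = 1, cfn = 1) {
  if (cfp < 1) abort("cfp must be >= 1")
  if (cfn < 0) abort("cfn must be >= 0")
  if (cfp < cfn) abort("cfp must be >= cfn (decoy labels are the trusted ones)")
  structure(list(cfp = cfp, cfn = cfn, ctn = 0, ctp = 0), class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("Cost matrix (rows = actual, cols = predicted)\n")
  m <- matrix(c(x$ctn, x$cfp, x$cfn, x$ctp), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("0", "1"), predicted = c("0", "1")))
  print(m)
  invisible(x)
}

#' Network hyperparameters
#'
#' Hyperparameters of the 6-input, single-sigmoid-output feed-forward
#' network. The defaults — 4 hidden nodes, learning rate 0.3, momentum 0.2,
#' 1000 epochs — are the method's standard configuration.
#'
#' @param hidden_nodes Hidden-layer size.
#' @param learning_rate Gradient-descent step size.
#' @param momentum Classical momentum coefficient.
#' @param epochs Number of training epochs (one weight update per epoch).
#' @param seed Integer seed for weight initialization.
#' @return An `ann_hyperparams` object.
#' @export
ann_hyperparams <- function(hidden_nodes = 4, learning_rate = 0.3,
                            momentum = 0.2, epochs = 1000, seed = 1) {
  stopifnot(hidden_nodes >= 1, epochs >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "ann_hyperparams")
}

#' Per-record training weights from a cost matrix
#'
#' Realizes the cost matrix as instance weighting: every class-0 (decoy)
#' record weighs `cfp`, every class-1 (target) record weighs `cfn`. Each
#' record's contribution to the training loss is scaled by its weight, so an
#' integer weight `w` is equivalent to replicating the record `w` times.
#'
#' @param psms A labeled PSM table.
#' @param cost A [cost_matrix()].
#' @return Numeric weight vector, one entry per record.
#' @export
make_instance_weights <- function(psms, cost = cost_matrix(1)) {
  if (!"class_label" %in% names(psms) || anyNA(psms$class_label)) {
    abort("all records must carry a class_label")
  }
  ifelse(psms$class_label == 0L, cost$cfp, cost$cfn)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# min/max affine map of each score column onto [-1, 1]
fit_normalization <- function(X) {
  mins <- apply(X, 2, min)
  ranges <- pmax(apply(X, 2, max) - mins, .Machine$double.eps)
  list(mins = mins, ranges = ranges)
}

apply_normalization <- function(X, norm) {
  sweep(sweep(X, 2, norm$mins), 2, norm$ranges, "/") * 2 - 1
}

score_matrix <- function(psms) {
  for (col in psm_score_cols) {
    if (!col %in% names(psms)) abort(paste0("missing score column '", col, "'"))
    bad <- which(!is.finite(psms[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-finite %s for record '%s'", col, psms$spectrum_id[bad[1]]))
    }
  }
  as.matrix(psms[, psm_score_cols])
}

#' Train the cost-sensitive network
#'
#' Fits the 6 -> `hidden_nodes` -> 1 sigmoid network on the dataset itself
#' (in target-decoy rescoring the data to be analyzed is the training set:
#' class 0 = decoy, class 1 = target). Training minimizes the
#' weight-normalized mean squared error by full-batch gradient descent with
#' classical momentum, with per-record weights from [make_instance_weights()].
#' Inputs are affinely mapped to \[-1, 1\] by their training min/max, and
#' the map is stored in the model. Initial weights are uniform on
#' \[-0.5, 0.5\] from the seeded generator; the run is fully deterministic
#' given the seed.
#'
#' @param psms A labeled PSM table containing both classes, all six scores
#'   finite.
#' @param cost A [cost_matrix()]; `cost_matrix(1, 1)` gives the unweighted
#'   baseline.
#' @param hp An [ann_hyperparams()].
#' @param verbose If `TRUE`, report the training loss every 100 epochs.
#' @return A `cost_ann` model: input normalization, layer weights, the
#'   hyperparameters and cost matrix used, and a loss trace sampled every
#'   100 epochs.
#' @examples
#' sim <- simulate_psms(n_targets = 300, n_decoys = 300, seed = 1)
#' fit <- train_cost_ann(sim$psms, cost_matrix(5), ann_hyperparams(epochs = 50))
#' @export
train_cost_ann <- function(psms, cost = cost_matrix(1), hp = ann_hyperparams(),
                           verbose = FALSE) {
  psms <- tibble::as_tibble(psms)
  if (!"class_label" %in% names(psms)) abort("PSM table must carry class_label")
  if (length(unique(psms$class_label)) < 2) {
    abort("training requires records of both classes (targets and decoys)")
  }
  X <- score_matrix(psms)
  y <- as.numeric(psms$class_label)
  w <- make_instance_weights(psms, cost)
  norm <- fit_normalization(X)
  Xs <- apply_normalization(X, norm)
  n_in <- ncol(Xs)
  h <- hp$hidden_nodes
  weights <- withr::with_seed(hp$seed, list(
    W1 = matrix(stats::runif(n_in * h, -0.5, 0.5), n_in, h),
    b1 = stats::runif(h, -0.5, 0.5),
    W2 = matrix(stats::runif(h, -0.5, 0.5), h, 1),
    b2 = stats::runif(1, -0.5, 0.5)
  ))
  v <- list(W1 = weights$W1 * 0, b1 = weights$b1 * 0,
            W2 = weights$W2 * 0, b2 = 0)
  w_total <- sum(w)
  lr <- hp$learning_rate
  mom <- hp$momentum
  trace <- numeric(0)
  for (epoch in seq_len(hp$epochs)) {
    H <- sigmoid(sweep(Xs %*% weights$W1, 2, weights$b1, "+"))
    o <- as.vector(sigmoid(H %*% weights$W2 + weights$b2))
    err <- y - o
    d_out <- -2 * w * err * o * (1 - o) / w_total
    g_W2 <- crossprod(H, d_out)
    g_b2 <- sum(d_out)
    d_hid <- (d_out %*% t(weights$W2)) * H * (1 - H)
    g_W1 <- crossprod(Xs, d_hid)
    g_b1 <- colSums(d_hid)
    v$W2 <- mom * v$W2 - lr * g_W2; weights$W2 <- weights$W2 + v$W2
    v$b2 <- mom * v$b2 - lr * g_b2; weights$b2 <- weights$b2 + v$b2
    v$W1 <- mom * v$W1 - lr * g_W1; weights$W1 <- weights$W1 + v$W1
    v$b1 <- mom * v$b1 - lr * g_b1; weights$b1 <- weights$b1 + v$b1
    if (epoch %% 100 == 0 || epoch == hp$epochs) {
      loss <- sum(w * err^2) / w_total
      trace <- c(trace, stats::setNames(loss, epoch))
      if (verbose) message(sprintf("epoch %d: weighted MSE %.6f", epoch, loss))
    }
  }
  weights <- purrr::map(weights, unname)
  structure(list(normalization = norm, weights = weights, hyperparams = hp,
                 cost = cost, n_train = nrow(psms), loss_trace = trace),
            class = "cost_ann")
}

# network forward pass on raw score matrix
forward_cost_ann <- function(model, X) {
  Xs <- apply_normalization(X, model$normalization)
  H <- sigmoid(sweep(Xs %*% model$weights$W1, 2, model$weights$b1, "+"))
  p <- as.vector(sigmoid(H %*% model$weights$W2 + model$weights$b2))
  pmin(pmax(p, 1e-9), 1 - 1e-9)
}

#' Score PSMs with a trained network
#'
#' Writes the network output — a probability-like score in (0, 1) combining
#' the six search scores — into the `raw_prob` column. Idempotent; no other
#' column is touched.
#'
#' @param model A trained `cost_ann`.
#' @param psms A PSM table with all six scores present and finite.
#' @return The table with `raw_prob` set.
#' @export
predict_probabilities <- function(model, psms) {
  stopifnot(inherits(model, "cost_ann"))
  psms <- tibble::as_tibble(psms)
  psms$raw_prob <- forward_cost_ann(model, score_matrix(psms))
  psms
}

#' @export
#' @rdname predict_probabilities
#' @param object,newdata,... S3 method interface: `predict(fit, psms)`
#'   returns the numeric score vector.
predict.cost_ann <- function(object, newdata, ...) {
  forward_cost_ann(object, score_matrix(tibble::as_tibble(newdata)))
}

#' @export
print.cost_ann <- function(x, ...) {
  cat(sprintf("Cost-sensitive ANN: 6 -> %d -> 1 (sigmoid), cfp = %g, cfn = %g\n",
              x$hyperparams$hidden_nodes, x$cost$cfp, x$cost$cfn))
  cat(sprintf("  trained %d epochs on %d PSMs; final weighted MSE %.6f\n",
              x$hyperparams$epochs, x$n_train,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom generics augment
generics::augment

#' Tidy a trained network into one row per connection weight
#'
#' @param x A `cost_ann` model.
#' @param ... Unused.
#' @return A tibble with `layer`, `from`, `to`, `estimate`.
#' @export
tidy.cost_ann <- function(x, ...) {
  w <- x$weights
  dplyr::bind_rows(
    tidyr::expand_grid(to = paste0("h", seq_len(ncol(w$W1))),
                       from = c(psm_score_cols, "bias")) %>%
      dplyr::mutate(layer = "hidden",
                    estimate = as.vector(rbind(w$W1, w$b1))),
    tibble::tibble(layer = "output",
                   from = c(paste0("h", seq_len(nrow(w$W2))), "bias"),
                   to = "out", estimate = c(as.vector(w$W2), w$b2))
  ) %>%
    dplyr::select("layer", "from", "to", "estimate")
}

#' @rdname tidy.cost_ann
#' @return For `glance()`: a one-row tibble with the configuration and the
#'   final training loss.
#' @export
glance.cost_ann <- function(x, ...) {
  tibble::tibble(hidden_nodes = x$hyperparams$hidden_nodes,
                 learning_rate = x$hyperparams$learning_rate,
                 momentum = x$hyperparams$momentum,
                 epochs = x$hyperparams$epochs,
                 cfp = x$cost$cfp, cfn = x$cost$cfn,
                 n_train = x$n_train,
                 final_loss = unname(x$loss_trace[length(x$loss_trace)]))
}

#' Save / load a trained network as versioned JSON
#'
#' The document stores the normalization parameters, layer weights,
#' hyperparameters and cost matrix at full double precision, so
#' `read_cost_ann(write_cost_ann(m, f))` reproduces the model exactly.
#'
#' @param model A `cost_ann`.
#' @param path Output/input JSON path.
#' @return `write_cost_ann()` returns `path` invisibly; `read_cost_ann()`
#'   returns the model.
#' @export
write_cost_ann <- function(model, path) {
  stopifnot(inherits(model, "cost_ann"))
  doc <- list(
    format = "psmrescore-cost-ann", version = 1L,
    normalization = list(mins = unname(model$normalization$mins),
                         ranges = unname(model$normalization$ranges)),
    weights = list(W1 = model$weights$W1, b1 = model$weights$b1,
                   W2 = model$weights$W2, b2 = model$weights$b2),
    hyperparams = unclass(model$hyperparams),
    cost = unclass(model$cost),
    n_train = model$n_train,
    loss_trace = list(epoch = as.integer(names(model$loss_trace)),
                      loss = unname(model$loss_trace))
  )
  # I(17): 17 significant digits, enough to round-trip binary64 exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cost_ann
#' @export
read_cost_ann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "psmrescore-cost-ann")) {
    abort("not a psmrescore cost-ann model file")
  }
  norm <- list(mins = stats::setNames(doc$normalization$mins, psm_score_cols),
               ranges = stats::setNames(doc$normalization$ranges, psm_score_cols))
  structure(list(
    normalization = norm,
    weights = list(W1 = doc$weights$W1, b1 = doc$weights$b1,
                   W2 = matrix(doc$weights$W2, ncol = 1), b2 = doc$weights$b2),
    hyperparams = do.call(ann_hyperparams, doc$hyperparams[
      c("hidden_nodes", "learning_rate", "momentum", "epochs", "seed")]),
    cost = cost_matrix(doc$cost$cfp, doc$cost$cfn),
    n_train = doc$n_train,
    loss_trace = stats::setNames(doc$loss_trace$loss,
                                 doc$loss_trace$epoch)
  ), class = "cost_ann")
}
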