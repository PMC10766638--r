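reset_code <- function(reset) {
  match(reset, c("soft", "hard", "none")) - 1L
}

layer_to_cpp <- function(layer) {
  list(
    n = layer$n, m = layer$m, d = layer$d,
    W = layer$W, U = layer$U,
    alpha = layer_alpha(layer), beta = layer_beta(layer),
    learn_alpha = layer$alpha_learnable, learn_beta = layer$beta_learnable,
    reset = reset_code(layer$reset), u_th = layer$u_th, R = layer$R
  )
}

# stack a list of structurally identical samples into kernel arrays
samples_to_arrays <- function(samples) {
  T_len <- nrow(samples[[1]]$spikes)
  C <- ncol(samples[[1]]$spikes)
  xs <- vapply(samples, function(s) as_matrix(s$spikes), matrix(0, T_len, C))
  labels <- vapply(samples, function(s) {
    l <- s$labels; l[is.na(l)] <- -1L; as.integer(l)
  }, integer(T_len))
  list(
    x = aperm(xs, c(2, 3, 1)),                       # C x B x T
    labels = matrix(labels, nrow = T_len),           # T x B
    mask = as.numeric(samples[[1]]$decision_mask)
  )
}

# one batch through the compiled kernel
run_batch <- function(model, samples, grad = TRUE, record = FALSE) {
  arr <- samples_to_arrays(samples)
  if (model$readout$kind != "linear_per_step") {
    stop("training/evaluation kernel supports the linear_per_step readout; ",
         "use readout() for the other decode variants", call. = FALSE)
  }
  res <- cpp_run_batch(
    lapply(model$layers, layer_to_cpp), model$readout,
    arr$x, arr$labels, arr$mask, grad,
    model$config$surrogate, record
  )
  if (grad) {
    for (l in seq_along(model$layers)) {
      lay <- model$layers[[l]]
      for (d in seq_len(lay$d)) {
        res$grads$layers[[l]]$W[[d]] <-
          res$grads$layers[[l]]$W[[d]] * lay$mask_W[[d]]
        if (!is.null(lay$U)) {
          res$grads$layers[[l]]$U[[d]] <-
            res$grads$layers[[l]]$U[[d]] * lay$mask_U[[d]]
        }
      }
    }
  }
  res
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * g
  opt$v <- beta2 * opt$v + (1 - beta2) * g^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  opt$delta <- -lr * mhat / (sqrt(vhat) + eps)
  opt
}

#' Per-decision classification accuracy
#'
#' Decisions are contiguous masked windows (identified by `decision_id`);
#' each decision's class scores are averaged over its window and the argmax
#' compared with the label. With `decision_id = NULL` every masked timestep
#' counts as its own decision.
#'
#' @param scores `T x n_classes` matrix of class scores/probabilities.
#' @param labels per-timestep integer labels (`NA` outside the mask).
#' @param mask logical decision mask of length `T`.
#' @param decision_id optional integer vector (0 outside windows) grouping
#'   masked timesteps into decisions.
#' @return accuracy in percent.
#' @export
accuracy <- function(scores, labels, mask, decision_id = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("accuracy: decision mask is empty", call. = FALSE)
  if (is.null(decision_id)) {
    decision_id <- integer(length(mask))
    decision_id[mask] <- seq_len(sum(mask))
  }
  ids <- setdiff(unique(decision_id[mask]), 0L)
  hits <- vapply(ids, function(r) {
    idx <- which(decision_id == r)
    pred <- which.max(colMeans(scores[idx, , drop = FALSE])) - 1L
    pred == labels[idx[1]]
  }, logical(1))
  100 * mean(hits)
}

# decision-level accuracy for a whole batch of samples from the prob cube
batch_accuracy <- function(probs, samples) {
  hits <- 0L; total <- 0L
  for (b in seq_along(samples)) {
    s <- samples[[b]]
    ids <- setdiff(unique(s$decision_id), 0L)
    for (r in ids) {
      idx <- which(s$decision_id == r)
      p <- rowMeans(probs[, b, idx, drop = FALSE][, 1, ])
      if ((which.max(p) - 1L) == s$decision_labels[r]) hits <- hits + 1L
      total <- total + 1L
    }
  }
  100 * hits / total
}

#' Evaluate a model on a set of samples
#'
#' @param model a `dh_model` with `linear_per_step` readout.
#' @param samples list of `xor_sample`s sharing one temporal layout.
#' @param batch_size samples per kernel call.
#' @return list with `accuracy` (percent, per decision), `loss` (mean masked
#'   cross-entropy).
#' @export
evaluate <- function(model, samples, batch_size = 256) {
  losses <- numeric(0); accs <- numeric(0); ns <- numeric(0)
  for (start in seq(1, length(samples), by = batch_size)) {
    chunk <- samples[start:min(start + batch_size - 1, length(samples))]
    res <- run_batch(model, chunk, grad = FALSE)
    losses <- c(losses, res$loss)
    accs <- c(accs, batch_accuracy(res$probs, chunk))
    ns <- c(ns, length(chunk))
  }
  list(accuracy = sum(accs * ns) / sum(ns), loss = sum(losses * ns) / sum(ns))
}

#' Optimize a model on a training set
#'
#' Mini-batch surrogate-gradient BPTT with Adam (initial learning rate 1e-2)
#' and a step scheduler that halves the rate every `lr_every` epochs. A
#' non-finite loss aborts with an error of class `dh_divergence`.
#'
#' @param model a `dh_model` (`linear_per_step` readout).
#' @param train_samples,test_samples lists of `xor_sample`s (test optional).
#' @param epochs,batch_size optimization budget.
#' @param lr,lr_decay,lr_every Adam initial rate and step schedule.
#' @param eval_every evaluate on `test_samples` every this many epochs.
#' @param verbose print per-epoch progress to stderr.
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, lr, train_loss, and test loss/accuracy where evaluated).
#' @export
train_network <- function(model, train_samples, test_samples = NULL,
                          epochs = 50, batch_size = 64, lr = 1e-2,
                          lr_decay = 0.5, lr_every = 10, eval_every = 10,
                          verbose = FALSE) {
  theta <- flatten_params(model)
  opt <- adam_new(length(theta))
  history <- data.frame()
  n <- length(train_samples)
  for (e in seq_len(epochs)) {
    lr_e <- lr * lr_decay^((e - 1) %/% lr_every)
    order <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- order[start:min(start + batch_size - 1, n)]
      res <- run_batch(model, train_samples[idx], grad = TRUE)
      if (!is.finite(res$loss)) {
        stop(structure(class = c("dh_divergence", "error", "condition"),
                       list(message = sprintf("non-finite loss at epoch %d", e),
                            call = sys.call())))
      }
      g <- flatten_grads(model, res$grads)
      opt <- adam_step(opt, g, lr_e)
      theta <- theta + opt$delta
      model <- unflatten_params(model, theta)
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    row <- data.frame(epoch = e, lr = lr_e, train_loss = ep_loss / ep_n,
                      test_loss = NA_real_, test_accuracy = NA_real_)
    if (!is.null(test_samples) && (e %% eval_every == 0 || e == epochs)) {
      ev <- evaluate(model, test_samples)
      row$test_loss <- ev$loss
      row$test_accuracy <- ev$accuracy
    }
    history <- rbind(history, row)
    if (verbose) {
      message(sprintf("epoch %3d | lr %.2e | train loss %.4f%s", e, lr_e,
                      row$train_loss,
                      if (!is.na(row$test_accuracy))
                        sprintf(" | test acc %.2f%%", row$test_accuracy) else ""))
    }
  }
  list(model = model, history = history)
}

#' Run a full multi-trial experiment
#'
#' For each trial: generate fresh train/test data, build a model, optimize the
#' masked cross-entropy, and evaluate per-decision test accuracy. Reports the
#' mean and standard deviation over trials plus firing-rate and cost
#' accounting, all reproducible from the seed.
#'
#' @param config a [network_config()] (its `seed` is overridden per trial).
#' @param task `"multiscale"` or `"delayed"`.
#' @param n_trials independent repetitions.
#' @param n_train,n_test samples generated per trial.
#' @param params a [task_params()].
#' @param seed base seed; trial `k` derives `seed + 1000 * k`.
#' @param task_args extra arguments for the sample generator.
#' @param ... passed to [train_network()].
#' @return a `dh_train_report`.
#' @export
train <- function(config, task = c("multiscale", "delayed"), n_trials = 3,
                  n_train = 5000, n_test = 1000, params = task_params(),
                  seed = 1, task_args = list(), ...) {
  task <- match.arg(task)
  trial_acc <- rep(NA_real_, n_trials)
  trial_hist <- vector("list", n_trials)
  failures <- character(0)
  model_last <- NULL
  test_last <- NULL
  for (k in seq_len(n_trials)) {
    trial_seed <- seed + 1000L * k
    out <- tryCatch(
      withr::with_seed(trial_seed, {
        train_set <- do.call(xor_dataset,
                             c(list(n_train, task = task, params = params),
                               task_args))
        test_set <- do.call(xor_dataset,
                            c(list(n_test, task = task, params = params),
                              task_args))
        cfg <- config
        cfg$seed <- NULL            # RNG already seeded for this trial
        model <- build_network(cfg)
        fit <- train_network(model, train_set, test_set, ...)
        list(acc = evaluate(fit$model, test_set)$accuracy,
             history = fit$history, model = fit$model,
             test_set = test_set)
      }),
      dh_divergence = function(e) e
    )
    if (inherits(out, "dh_divergence")) {
      failures <- c(failures, sprintf("trial %d: %s", k, conditionMessage(out)))
      next
    }
    trial_acc[k] <- out$acc
    trial_hist[[k]] <- out$history
    model_last <- out$model
    test_last <- out$test_set
  }
  rates <- NULL
  counts <- NULL
  if (!is.null(model_last) && !is.null(test_last)) {
    sub <- test_last[seq_len(min(64, length(test_last)))]
    res <- run_batch(model_last, sub, grad = FALSE, record = TRUE)
    rates <- vapply(res$rasters, mean, numeric(1))
    counts <- list(params = count_params(model_last),
                   synops = count_synops(model_last, sub[[1]]$spikes))
  }
  structure(list(
    task = task, n_trials = n_trials, seeds = seed + 1000L * seq_len(n_trials),
    accuracy = trial_acc,
    accuracy_mean = mean(trial_acc, na.rm = TRUE),
    accuracy_sd = stats::sd(trial_acc[!is.na(trial_acc)]),
    history = trial_hist, firing_rates = rates, counts = counts,
    failures = failures, config = config, params = params,
    model = model_last
  ), class = "dh_train_report")
}

#' @export
print.dh_train_report <- function(x, ...) {
  cat(sprintf("<dh_train_report> %s XOR | %d trial(s) | accuracy %.2f%% +/- %.2f%%\n",
              x$task, x$n_trials, x$accuracy_mean,
              ifelse(is.na(x$accuracy_sd), 0, x$accuracy_sd)))
  if (length(x$failures)) cat("  failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}
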