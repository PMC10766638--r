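#' Branch partitions: which inputs each dendritic branch sees
#'
#' A branch partition assigns every presynaptic input index to one (or, under
#' a sparsity ratio, possibly several) of the `D` dendritic branches of each
#' postsynaptic neuron. Partitions are drawn independently per neuron, so the
#' wiring is heterogeneous across the layer.
#'
#' @name branch_partition
#' @keywords internal
NULL

new_branch_partition <- function(P, M, D, n_neurons, mode) {
  structure(
    list(P = P, M = M, D = D, n_neurons = n_neurons, mode = mode),
    class = "branch_partition"
  )
}

#' @export
print.branch_partition <- function(x, ...) {
  cat(sprintf("<branch_partition> mode=%s, %d neurons, %d inputs, %d branches\n",
              x$mode, x$n_neurons, x$M, x$D))
  invisible(x)
}

# split sizes: remainder M %% D goes to the first branches
balanced_sizes <- function(M, D) {
  sz <- rep(M %/% D, D)
  r <- M %% D
  if (r > 0) sz[seq_len(r)] <- sz[seq_len(r)] + 1L
  sz
}

#' Balanced disjoint branch partition
#'
#' For each neuron independently, the `M` input indices are randomly permuted
#' and split into `D` contiguous chunks of near-equal size, so the branch
#' index sets are pairwise disjoint, cover all inputs, and differ in size by
#' at most one. Under this restriction the number of nonzero synapses per
#' layer equals `N * M` regardless of `D`.
#'
#' @param M number of presynaptic inputs.
#' @param D number of dendritic branches per neuron.
#' @param n_neurons number of postsynaptic neurons (one draw each).
#' @return a `branch_partition` with mode `"balanced_disjoint"`.
#' @export
partition_balanced <- function(M, D, n_neurons = 1L) {
  if (D < 1L || D > M) {
    stop("partition_balanced: need 1 <= D <= M (every branch must see an input)",
         call. = FALSE)
  }
  sz <- balanced_sizes(M, D)
  ends <- cumsum(sz)
  starts <- c(1L, ends[-D] + 1L)
  P <- lapply(seq_len(n_neurons), function(nn) {
    perm <- sample.int(M)
    lapply(seq_len(D), function(dd) sort(perm[starts[dd]:ends[dd]]))
  })
  new_branch_partition(P, M, D, n_neurons, "balanced_disjoint")
}

#' Sparsity-ratio branch partition
#'
#' Each branch connects to `round(M * s)` inputs. Per neuron a random
#' permutation `L` of the input indices is drawn; branch `d` (0-based) takes
#' the window of that length starting at offset `floor(M / D) * d`, reading
#' circularly past the end. With `s <= 1/D` the windows are disjoint (and
#' `s = 1/D` recovers a balanced partition); with `s > 1/D` adjacent branches
#' overlap; `s = 1` connects every branch to all inputs.
#'
#' @param M number of inputs.
#' @param D branches per neuron.
#' @param s connection sparsity ratio in `(0, 1]`.
#' @param n_neurons number of neurons.
#' @return a `branch_partition` with mode `"sparsity_ratio"`.
#' @export
partition_sparsity <- function(M, D, s, n_neurons = 1L) {
  if (!is.numeric(s) || s <= 0 || s > 1) {
    stop("partition_sparsity: s must lie in (0, 1]", call. = FALSE)
  }
  k <- round(M * s)
  if (k < 1) stop("partition_sparsity: round(M * s) must be >= 1", call. = FALSE)
  step <- M %/% D
  P <- lapply(seq_len(n_neurons), function(nn) {
    L <- sample.int(M)
    lapply(seq_len(D), function(dd) {
      offset <- step * (dd - 1L)
      idx <- ((offset + seq_len(k) - 1L) %% M) + 1L   # circular window into L
      sort(L[idx])
    })
  })
  out <- new_branch_partition(P, M, D, n_neurons, "sparsity_ratio")
  out$s <- s
  out
}

#' Grouped branch partition (hardware-friendly)
#'
#' One balanced partition is drawn per contiguous group of `group_size`
#' neurons and reused by all neurons of the group, so that equal branch
#' indices within a group share identical synaptic input sets. `group_size = 1`
#' degenerates to [partition_balanced()].
#'
#' @param n_neurons number of neurons in the layer.
#' @param M number of inputs.
#' @param D branches per neuron.
#' @param group_size neurons per shared-pattern group (default 32).
#' @return a `branch_partition` with mode `"grouped"`.
#' @export
partition_grouped <- function(n_neurons, M, D, group_size = 32L) {
  if (group_size < 1L) stop("partition_grouped: group_size must be >= 1", call. = FALSE)
  n_groups <- ceiling(n_neurons / group_size)
  group_patterns <- lapply(seq_len(n_groups), function(g) {
    partition_balanced(M, D, n_neurons = 1L)$P[[1L]]
  })
  P <- lapply(seq_len(n_neurons), function(nn) {
    group_patterns[[((nn - 1L) %/% group_size) + 1L]]
  })
  out <- new_branch_partition(P, M, D, n_neurons, "grouped")
  out$group_size <- as.integer(group_size)
  out
}

#' Materialize binary weight masks from a branch partition
#'
#' Returns one `n_neurons x M` 0/1 matrix per branch with
#' `mask[[d]][n, m] == 1` iff input `m` belongs to branch `d` of neuron `n`.
#' Masks are applied multiplicatively to the weights on every forward pass and
#' after every gradient update, so pruned entries stay exactly zero at all
#' times.
#'
#' @param partition a `branch_partition`.
#' @return list of `D` binary matrices.
#' @export
materialize_masks <- function(partition) {
  stopifnot(inherits(partition, "branch_partition"))
  lapply(seq_len(partition$D), function(dd) {
    mask <- matrix(0, nrow = partition$n_neurons, ncol = partition$M)
    for (nn in seq_len(partition$n_neurons)) {
      mask[nn, partition$P[[nn]][[dd]]] <- 1
    }
    mask
  })
}

#' Export / import branch partitions as JSON
#'
#' Partitions are serialized as per-neuron lists of 0-based index vectors so
#' that experiments can be reproduced exactly across runs and languages.
#'
#' @param partition a `branch_partition`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `export_partition_json`: the path (or JSON string) invisibly;
#'   `import_partition_json`: the reconstructed `branch_partition`.
#' @export
export_partition_json <- function(partition, path = NULL) {
  stopifnot(inherits(partition, "branch_partition"))
  payload <- list(
    mode = partition$mode,
    M = partition$M, D = partition$D, n_neurons = partition$n_neurons,
    s = partition$s, group_size = partition$group_size,
    P = lapply(partition$P, function(sets) lapply(sets, function(v) v - 1L))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname export_partition_json
#' @param x path to a JSON file, or a JSON string.
#' @export
import_partition_json <- function(x) {
  payload <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  P <- lapply(payload$P, function(sets) {
    lapply(sets, function(v) as.integer(unlist(v)) + 1L)
  })
  out <- new_branch_partition(P, payload$M, payload$D, payload$n_neurons,
                              payload$mode)
  out$s <- payload$s
  out$group_size <- payload$group_size
  out
}
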