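# Minimal reverse-mode autodiff over rank-4 arrays.  A tape records nodes in
# creation order; backward() walks them in reverse, calling each node's
# backfn(grad) which returns one gradient per parent.  Heavy kernels live in
# C++; the tape itself is a handful of environments per batch, so its R-level
# overhead is negligible next to the GEMM cost.

tape_new <- function(precision = "single") {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$single <- identical(precision, "single")
  t
}

# A node is an environment: $value (array), $parents (list of nodes),
# $backfn (function(grad) -> list of parent grads), $grad, $leaf.
nd <- function(tape, value, parents = list(), backfn = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$leaf <- leaf
  if (!is.null(tape)) {
    e$parents <- parents
    e$backfn <- backfn
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- e
  }
  e
}

# Wraps a trainable parameter (its gradient is collected after backward).
nd_param <- function(tape, value) nd(tape, value, leaf = TRUE)

# Wraps raw input data (no gradient needed below this point).
nd_input <- function(tape, value) {
  e <- nd(tape, value, leaf = TRUE)
  e$stop <- TRUE
  e
}

needs_grad <- function(node) !isTRUE(node$stop)

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    pg <- node$backfn(node$grad)
    for (k in seq_along(node$parents)) {
      if (!is.null(pg[[k]])) acc_grad(node$parents[[k]], pg[[k]])
    }
    # free intermediate gradients early; parameters and leaves keep theirs
    if (!node$leaf) node$grad <- NULL
  }
  invisible(NULL)
}
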