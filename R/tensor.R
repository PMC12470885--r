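# Minimal reverse-mode automatic differentiation over 4-d arrays.
#
# A "dtensor" is an environment holding a value, an (initially NULL)
# gradient, its parent nodes and a backward closure.  Nodes created while a
# tape is active are recorded in creation order; because the graph is built
# by executing the forward pass, creation order is a topological order and
# the backward sweep simply walks the tape in reverse.

.tape <- new.env(parent = emptyenv())
.tape$active <- FALSE
.tape$nodes <- list()
.tape$n <- 0L

tape_begin <- function() {
  .tape$active <- TRUE
  .tape$nodes <- vector("list", 256L)
  .tape$n <- 0L
  invisible(NULL)
}

tape_end <- function() {
  .tape$active <- FALSE
  .tape$nodes <- list()
  .tape$n <- 0L
  invisible(NULL)
}

tape_record <- function(node) {
  n <- .tape$n + 1L
  if (n > length(.tape$nodes))
    length(.tape$nodes) <- 2L * length(.tape$nodes)
  .tape$nodes[[n]] <- node
  .tape$n <- n
  invisible(NULL)
}

#' @keywords internal
new_dtensor <- function(val, parents = list(), bw = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$bw <- bw
  class(node) <- "dtensor"
  if (.tape$active && !is.null(bw)) tape_record(node)
  node
}

# Trainable leaf.  Never recorded on the tape: gradients are accumulated
# into it by child nodes and cleared by zero_grad().
ad_param <- function(val) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- list()
  node$bw <- NULL
  node$is_param <- TRUE
  class(node) <- "dtensor"
  node
}

ad_const <- function(val) new_dtensor(val)

is_dtensor <- function(x) inherits(x, "dtensor")

accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g
  else node$grad <- node$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar loss node.
backward <- function(loss) {
  stopifnot(is_dtensor(loss), length(loss$val) == 1L)
  loss_val <- loss$val
  loss$grad <- 1
  nodes <- .tape$nodes
  for (i in seq(.tape$n, 1L)) {
    node <- nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$bw)) node$bw(node$grad)
    # free values and gradients of consumed intermediates as we go
    if (!isTRUE(node$is_param)) {
      node$grad <- NULL
      node$val <- NULL
      node$bw <- NULL
      node$parents <- NULL
    }
  }
  loss$val <- loss_val
  invisible(NULL)
}
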