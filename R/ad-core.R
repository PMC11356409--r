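#' @useDynLib sats, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal reverse-mode automatic differentiation on R matrices.
#
# A "tape" records every operation applied to tracked values; backward()
# replays it in reverse to accumulate gradients. Values are plain numeric
# matrices/vectors/scalars. Each recorded node keeps a closure that maps the
# incoming gradient to gradients for its parents. Operations dispatch on
# whether any argument is tracked, so the same network code runs both in
# plain numeric (inference, unit tests) and tracked (training) mode.

# Nodes live in a hashed environment keyed by id: assigning into a list
# bound in an environment would duplicate the accumulated tape on every
# recorded operation.
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- new.env(parent = emptyenv())
  t$n <- 0L
  t
}

is_ad <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (is_ad(x)) x$v else x

ad_tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  stop("no tracked argument")
}

ad_record <- function(tape, value, parents, backfn) {
  id <- tape$n + 1L
  node <- structure(
    list(id = id, v = value, parents = parents, back = backfn, tape = tape),
    class = "adnode")
  assign(as.character(id), node, envir = tape$nodes)
  tape$n <- id
  node
}

ad_leaf <- function(tape, value) ad_record(tape, value, list(), NULL)

# Backward pass from a scalar node; returns a list of gradients indexed by
# node id (query with `grads[[node$id]]`).
ad_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq(tape$n, 1L)) {
    node <- get(as.character(id), envir = tape$nodes)
    g <- grads[[id]]
    if (is.null(g) || is.null(node$back)) next
    pg <- node$back(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!is_ad(p) || is.null(pg[[j]])) next
      grads[[p$id]] <- if (is.null(grads[[p$id]])) pg[[j]] else grads[[p$id]] + pg[[j]]
    }
  }
  grads
}
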