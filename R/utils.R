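## Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats cor rnorm runif binom.test
NULL

## Derive a child seed from a base seed and an integer tag so that every
## fold / epoch / site has its own reproducible stream. Kept below 2^31.
.deriveSeed <- function(seed, tag) {
  s <- (as.double(seed) %% 1000003) + 1
  as.integer((s * 48271 + as.double(tag) * 7919) %% 2147483587) + 1L
}

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Row-wise numerically stable softmax.
.softmaxRows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)   # column-major recycling subtracts mx from every column
  e / rowSums(e)
}

## Broadcast a length-d vector across the rows of an n x d matrix.
.addRow <- function(m, v) m + rep(v, rep.int(nrow(m), length(v)))
.mulRow <- function(m, v) m * rep(v, rep.int(nrow(m), length(v)))

.assertScalarNumber <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop(sprintf("'%s' must be a finite number >= %s", name, lower),
         call. = FALSE)
  invisible(x)
}

## Recursively apply f over the numeric leaves of up to three parallel
## nested lists (parameters / gradients / optimizer state share a shape).
.mapLeaves <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- .mapLeaves(f, a[[i]],
                             if (is.null(b)) NULL else b[[i]],
                             if (is.null(c)) NULL else c[[i]])
    out
  } else {
    f(a, b, c)
  }
}

## Sum of |leaf| differences; used by freeze-contract checks.
.leafIdentical <- function(a, b) {
  ok <- TRUE
  walk <- function(x, y) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], y[[i]])
    } else if (!identical(x, y)) ok <<- FALSE
  }
  walk(a, b)
  ok
}
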