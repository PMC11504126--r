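# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded generation does not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Ensure a [H,W,C] or [H,W,C,N] array; promote [H,W] to one channel and
# [H,W,C] to batch size one when `batch = TRUE`.
as_hwcn <- function(x, batch = TRUE) {
  d <- dim(x)
  if (is.null(d)) stopf("expected an array, got a vector")
  if (length(d) == 2) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (length(d) == 3 && batch) dim(x) <- c(d, 1L)
  x
}

# Concatenate two [H,W,C,N] arrays along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(dy[, , seq_len(c1), , drop = FALSE],
       dy[, , (c1 + 1):d[3], , drop = FALSE])
}
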