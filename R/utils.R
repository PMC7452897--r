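# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so generators are pure
#' functions of their `seed` argument.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a 3D array circularly along one axis
#' @noRd
circshift3d <- function(x, axis, by = 1L) {
  d <- dim(x)
  idx <- ((seq_len(d[axis]) - 1L + by) %% d[axis]) + 1L
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Stop unless condition holds
#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Validate a survival record table has the columns an estimator needs
#' @noRd
check_records <- function(records, cols = c("time_months", "event")) {
  assert_that(is.data.frame(records), "`records` must be a data frame")
  missing <- setdiff(cols, names(records))
  assert_that(length(missing) == 0L,
              paste("`records` is missing columns:",
                    paste(missing, collapse = ", ")))
  if ("time_months" %in% cols) {
    assert_that(all(is.finite(records$time_months)) &&
                  all(records$time_months >= 0),
                "`time_months` must be finite and non-negative")
  }
  if ("event" %in% cols)
    assert_that(all(records$event %in% c(0, 1)), "`event` must be 0/1")
  invisible(records)
}
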