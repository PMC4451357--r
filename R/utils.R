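#' @keywords internal
"_PACKAGE"

# Shared input checks. Errors carry the offending value so pipeline-stage
# wrappers can re-raise with stage context.

stop_eb <- function(..., class = "eb_error", data = NULL) {
  cond <- structure(
    class = c(class, "eb_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_eb(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_eb(name, " must be in [", lower, ", ", upper, "], got ", x)
  if (integer && x != round(x))
    stop_eb(name, " must be an integer, got ", x)
  invisible(x)
}

# sample SD with the N-1 denominator, column-wise over a matrix
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop_eb("need at least 2 rows for a sample SD")
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
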