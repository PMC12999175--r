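# shared argument checks

as_frames_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", name, "` must be a numeric frames x channels matrix")
  }
  if (anyNA(x)) stop("`", name, "` contains missing values")
  x
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop("`", name, "` = ", x, " is outside its allowed range")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
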