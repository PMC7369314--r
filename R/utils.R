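# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their spec.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min
}

# Micrometres to millimetres; the single place where the 10^3 lives.
um_to_mm <- function(x) x / 1000

check_image_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L)
    stop(sprintf("'%s' must be a non-empty numeric matrix", name), call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop(sprintf("'%s' must have finite intensities in [0, 255]", name), call. = FALSE)
  invisible(x)
}

check_congruent <- function(a, b, names = c("image", "mask")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("'%s' (%s) and '%s' (%s) must have the same dimensions",
                 names[1], paste(dim(a)[1:2], collapse = "x"),
                 names[2], paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
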