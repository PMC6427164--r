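#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run code with a fixed RNG state, restoring the caller's state afterwards.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Euclidean distance between two (x, y) rows.
euclid <- function(p, q) sqrt(sum((p - q)^2))

# Coerce a data.frame / matrix of positions to an n x 2 numeric matrix.
as_xy_matrix <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("x", "y"))))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y") %in% names(x)))
    return(cbind(x = as.numeric(x$x), y = as.numeric(x$y)))
  }
  m <- as.matrix(x)
  if (length(m) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("x", "y"))))
  }
  if (is.null(dim(m)) || ncol(m) != 2L) {
    stop("positions must be an n x 2 matrix or a data.frame with x, y",
         call. = FALSE)
  }
  colnames(m) <- c("x", "y")
  storage.mode(m) <- "double"
  m
}
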