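# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make top-set sizes depend on the parity of N*k).
round_half_up <- function(x) floor(x + 0.5)

# Tolerance used when comparing confidence scores against a threshold grid
# value theta = h/100; absorbs decimal-printing round trips.
.score_eps <- 1e-9

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current `.Random.seed`, seeds the generator, evaluates `expr`
#' and restores the previous RNG state, so seeded draws inside the package
#' never perturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed for a (metric, threshold) cell
#'
#' Tie-breaking draws must be independent across metrics and thresholds and
#' independent of computation order, so each cell gets its own seed derived
#' deterministically from a master seed, the metric name and the threshold.
#'
#' @param master integer master seed.
#' @param metric metric name (character scalar).
#' @param theta threshold in hundredths (integer), 0 for threshold-free uses.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, metric, theta = 0L) {
  p <- 2147483629 # large prime below 2^31
  h <- as.double(abs(as.integer(master))) %% p
  for (ch in utf8ToInt(as.character(metric))) h <- (h * 131 + ch) %% p
  h <- (h * 131 + as.double(theta) + 17) %% p
  as.integer(h)
}

# theta in hundredths -> semantic threshold value
theta_value <- function(theta) as.integer(theta) / 100

check_hundredths <- function(theta, what = "theta") {
  if (length(theta) != 1L || is.na(theta) || theta != as.integer(theta))
    stop(sprintf("%s must be a single integer number of hundredths", what),
         call. = FALSE)
  as.integer(theta)
}
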