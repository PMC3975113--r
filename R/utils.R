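# Shared low-level helpers: amino-acid tables, seeded RNG scoping,
# string/interval utilities.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy index.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Background amino-acid frequencies (Robinson & Robinson composition),
# used both by the synthetic generator and as the null model of the LRR
# position-weight matrix.
AA_BACKGROUND <- c(
  A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
  Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
  L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
  S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0653
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never perturbs user-level
#' reproducibility.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
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
  set.seed(as.integer(seed))
  expr
}

# Deterministically fork a sub-seed from a master seed; one stream per
# generated artifact, so adding genes does not perturb expression draws.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) + as.numeric(k) * 10007) %% 2147483629
  as.integer(s + 1)
}

# Case-insensitive, whitespace-normalised description matching.
norm_desc <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

# seq must be a single string of one-letter amino-acid codes.
aa_vec <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Rolling mean of hydropathy over windows of length w; returns one value
# per window start (length n - w + 1), NA-free.
kd_window_means <- function(seq, w) {
  v <- KD_SCALE[aa_vec(seq)]
  v[is.na(v)] <- 0
  n <- length(v)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open interval as c(start, end); length helper.
iv_len <- function(iv) if (is.null(iv)) 0L else iv[2] - iv[1]

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Format a percentage to one decimal place
#'
#' @param num numerator count.
#' @param den denominator count.
#' @return Character scalar, e.g. `"23.2"`; `"-"` when the denominator is 0.
#' @export
pct1 <- function(num, den) {
  if (den == 0) return("-")
  sprintf("%.1f", 100 * num / den)
}

#' Percentage rounded to the nearest integer
#'
#' @param num numerator count.
#' @param den denominator count.
#' @return Numeric scalar percentage (0 when the denominator is 0).
#' @export
pct_int <- function(num, den) {
  if (den == 0) return(0)
  round(100 * num / den)
}
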