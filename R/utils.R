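#' @importFrom stats approx median quantile rnorm rlnorm rpois runif
#'   sd t.test setNames
#' @importFrom utils read.csv write.csv
NULL

# typed condition helper: all user-facing errors carry class "embryokin_error"
ek_stop <- function(..., class = "embryokin_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

ek_assert <- function(cond, ...) {
  if (!isTRUE(cond)) ek_stop(...)
}

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards so generators never disturb the session stream.
with_seed <- function(seed, expr) {
  ek_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with edge replication; window forced odd.
moving_average <- function(x, win) {
  win <- max(1L, as.integer(win))
  if (win %% 2L == 0L) win <- win + 1L
  if (win == 1L || length(x) < win) return(x)
  half <- (win - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / win, win), sides = 2))[
    (half + 1L):(half + length(x))]
}

# Linear interpolation across interior missing values; leading/trailing NAs
# are left missing (there is no data to anchor them).
bridge_na <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  span <- ok[1L]:ok[length(ok)]
  x[span] <- approx(ok, x[ok], xout = span)$y
  x
}

first_run_of <- function(cond, len) {
  # first index starting a run of `len` consecutive TRUEs, or NA
  if (len <= 1L) return(if (any(cond)) which(cond)[1L] else NA_integer_)
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= len)
  if (!length(i)) return(NA_integer_)
  ends[i[1L]] - r$lengths[i[1L]] + 1L
}
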