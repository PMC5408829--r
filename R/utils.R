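# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never disturb the user's random stream.
#' @noRd
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
  code
}

#' Signal a validation error (condition class "waterdiet_validation_error")
#' @noRd
stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg,
                      class = c("waterdiet_validation_error", "validationError")))
}

#' Draw deterministic child seeds (kept below 2^31) from the current stream
#' @noRd
child_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Sample from a normal distribution truncated below at zero
#'
#' Inverse-CDF sampling; degenerate (sd = 0) draws return the mean.
#' @noRd
rnorm_trunc0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmax(out, 0)
}

# Format numeric columns losslessly for CSV round-trips.
format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.17g", df[[j]])
    }
  }
  df
}

write_csv_exact <- function(df, path) {
  utils::write.csv(format_numeric_cols(df), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
}
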