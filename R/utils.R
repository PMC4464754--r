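# internal helpers shared across modules

# scalar numeric check with informative error naming the argument
check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", arg),
          class = "vasckill_domain_error")
  }
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    abort(sprintf("`%s` = %g is outside its valid range %s%g, %g%s.",
                  arg, x,
                  if (allow_boundary) "[" else "(", lower, upper,
                  if (allow_boundary) "]" else ")"),
          class = "vasckill_domain_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, arg = "data") {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(missing_cols, collapse = ", ")),
          class = "vasckill_validation_error")
  }
  invisible(df)
}

# Truncated-normal sampler by inverse-CDF so draws are a deterministic
# function of the RNG stream (no rejection loop of data-dependent length).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  u <- runif(n) # always consume n draws so the stream layout is stable
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- pnorm(lower, mean[pos], sd[pos])
    phi <- pnorm(upper, mean[pos], sd[pos])
    out[pos] <- qnorm(plo + u[pos] * (phi - plo), mean[pos], sd[pos])
  }
  out
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (fit/simulation determinism).
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
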