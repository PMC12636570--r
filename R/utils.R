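# internal argument checks -----------------------------------------------

stop_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop_bad_arg(name, "must be a single number")
  }
  if (strict_min && x <= min) {
    stop_bad_arg(name, sprintf("must be > %s", format(min)))
  }
  if (!strict_min && x < min) {
    stop_bad_arg(name, sprintf("must be >= %s", format(min)))
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x)) {
    stop_bad_arg(name, sprintf(
      "must be a numeric vector of length >= %d with no missing values",
      min_len
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Restore the caller's RNG state on exit so seeded helpers do not
# perturb the global random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
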