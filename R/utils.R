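# Internal helpers shared across modules.

#' @importFrom stats median mad rnorm rlnorm runif prop.test quantile lm coef
#'   resid setNames
#' @importFrom utils read.table write.table packageVersion
NULL

stopf <- function(fmt, ..., class) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "flaps_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero; base round() rounds half to even, which would
# make planted truth counts depend on the fraction's parity.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Wilson 95% score interval for a binomial proportion
#'
#' Thin wrapper over [stats::prop.test()] without continuity correction,
#' which yields the Wilson score interval.
#'
#' @param n_success number of successes.
#' @param n_total number of trials (> 0).
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
wilson_ci <- function(n_success, n_total) {
  if (n_total <= 0) return(c(NA_real_, NA_real_))
  # suppress the chi-squared small-count warning: only the interval is used
  suppressWarnings(
    as.numeric(stats::prop.test(n_success, n_total, correct = FALSE)$conf.int))
}

# Shortest decimal representation that round-trips exactly; keeps delimited
# outputs human-readable without losing precision.
format_exact <- function(x) {
  if (is.double(x)) {
    vapply(x, function(v) {
      if (is.na(v)) return("NA")
      s <- as.character(v)
      if (!is.na(as.numeric(s)) && as.numeric(s) == v) s else sprintf("%.17g", v)
    }, character(1))
  } else {
    as.character(x)
  }
}

# Tab-delimited writer with exact numeric round-trip and stable column order.
write_exact_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- format_exact(out[[j]])
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing", path, class = "flaps_io_error"))
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path))
    stopf("file not found: '%s'", path, class = "flaps_io_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
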