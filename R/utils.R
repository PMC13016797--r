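# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kinpref <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_kinpref("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_kinpref("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x))
    stop_kinpref("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

#' Spawn reproducible child seeds from a master seed
#'
#' One master seed deterministically generates independent integer seeds for
#' per-trial simulation streams, so whole-study scenarios are reproducible
#' while each trial remains independently seeded.
#'
#' @param master_seed single integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  check_number(master_seed, "master_seed")
  check_number(n, "n", lower = 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Polynomial rolling hash of a config object (over its deparsed form); used
# to stamp output tables so reruns are attributable to an exact configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Write a table as CSV with a provenance comment line (config hash + seed).
# Read back with `read.csv(path, comment.char = "#")`.
write_stamped_csv <- function(df, path, hash = NULL, seed = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(hash))
    writeLines(sprintf("# kinpref config_hash=%s seed=%s", hash,
                       as.character(seed %||% "NA")), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}
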