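# Internal helpers shared across modules.

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

# Hazards are floored/ceilinged so downstream survival products and
# log-scale work stay finite.
clamp_prob <- function(p, floor = 1e-12) {
  pmin(pmax(p, floor), 1 - floor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seeds that stay inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483629L)
}

assert_cols <- function(dt, cols, what = "input") {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Empirical quantiles use the linear-interpolation (type 7) convention
# throughout the package; stated here once for reproducibility. Draws for
# which a cell had no expected entrants are undefined and excluded.
q_lower <- function(x) {
  if (all(is.na(x))) return(NA_real_)
  stats::quantile(x, 0.025, names = FALSE, type = 7, na.rm = TRUE)
}
q_upper <- function(x) {
  if (all(is.na(x))) return(NA_real_)
  stats::quantile(x, 0.975, names = FALSE, type = 7, na.rm = TRUE)
}
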