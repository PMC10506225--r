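#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never clobber the
# user's stream.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise log-sum-exp of a matrix; guards against all -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  mx[bad] <- 0
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_count_vector <- function(y, name = "y") {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(y != floor(y))) {
    stop_domain(sprintf("`%s` must contain nonnegative integer counts", name))
  }
  invisible(y)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be positive and finite", name))
  }
  invisible(x)
}

assert_beta_params <- function(mu, kappa) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop_domain("`mu` must lie strictly in (0, 1)")
  }
  assert_positive(kappa, "kappa")
  if (length(mu) != length(kappa) && length(mu) != 1L && length(kappa) != 1L) {
    stop_domain("`mu` and `kappa` must have compatible lengths")
  }
  invisible(NULL)
}
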