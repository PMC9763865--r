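`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Log-normal draws with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Log-normal draws with median `med` and coefficient of variation cv.
rlnorm_med <- function(n, med, cv) {
  if (med == 0) return(rep(0, n))
  if (cv == 0) return(rep(med, n))
  rlnorm(n, meanlog = log(med), sdlog = sqrt(log(1 + cv^2)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
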