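## internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL means: use the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed derived from a user seed; kept strictly below 2^31.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(tag)) %% 2147483629)
}

# Probability clipping bound used everywhere a logistic probability enters a
# log or a denominator.
PROB_EPS <- 1e-10

clip_prob <- function(p) {
  pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
}

# Bernoulli deviance contributions, probabilities pre-clipped.
bernoulli_deviance <- function(y, prob) {
  prob <- clip_prob(prob)
  -(y * log(prob) + (1 - y) * log(1 - prob))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
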