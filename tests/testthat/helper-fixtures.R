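# Shared fixture builders: everything is generated in code at test time.

# Tiny deterministic labeled matrix with a visible signal in column 1.
toy_data <- function(n = 8, p = 2, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- matrix(rnorm(n * p), n, p)
    y <- as.integer(X[, 1] + 0.3 * rnorm(n) > 0)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    labeled_matrix(X, y)
  })
}

# Small contaminated instance used by the search tests.
small_instance <- function(n = 60, p = 20, q = 4, epsilon = 0.1, seed = 1) {
  generate_synthetic(n = n, p = p, q = q, effect = 2, rho = 0.2,
                     epsilon = epsilon, seed = seed)
}

# Instance for oracle comparisons; guarantees at least min_class samples per
# class by walking the seed deterministically.
oracle_instance <- function(n = 12, p = 3, seed = 1, min_class = 4) {
  s <- seed
  repeat {
    ds <- generate_synthetic(n = n, p = p, q = 1, effect = 2, rho = 0,
                             epsilon = 0.1, seed = s)
    if (min(ds$data$n1, ds$data$n0) >= min_class) return(ds)
    s <- s + 1000L
  }
}

# A random stratified 6-sample start (3 per class).
six_start <- function(data) {
  sort(c(sample(which(data$y == 1L), 3L), sample(which(data$y == 0L), 3L)))
}

# Direct minimization of the penalized trimmed objective by a generic
# optimizer -- the independent oracle for the inner solver. Operates on the
# same standardized design the solver sees.
optim_en_logistic <- function(x, y, lam, alpha, par0 = NULL, restarts = 4) {
  nobs <- nrow(x)
  obj <- function(par) {
    eta <- par[1] + x %*% par[-1]
    p <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    sum(-(y * log(p) + (1 - y) * log(1 - p))) +
      nobs * lam * sum((1 - alpha) * par[-1]^2 / 2 + alpha * abs(par[-1]))
  }
  best <- NULL
  starts <- c(list(par0 %||% rep(0, ncol(x) + 1)),
              lapply(seq_len(restarts), function(i) rnorm(ncol(x) + 1, sd = 0.5)))
  for (par0i in starts) {
    res <- optim(par0i, obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    res <- optim(res$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
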