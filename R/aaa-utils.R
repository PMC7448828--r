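# Internal helpers shared across modules.

MRS_ALIVE <- paste0("mrs", 0:5)
MRS_ALL <- paste0("mrs", 0:6)
STATES <- c(MRS_ALIVE, "dead")
STRATEGIES <- c("MT_SMC", "SMC")
TRIALS <- c("DAWN", "DEFUSE3")

abort_validation <- function(field, message) {
  abort(paste0(field, ": ", message), class = "cea_validation_error", field = field)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_validation(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort_validation(field, "must be non-negative")
  }
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    abort_validation(field, "must be strictly positive")
  }
  invisible(x)
}

# Dirichlet draws via normalized gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Classic PERT (shape 4) on [min, max] with the given mode.
rpert <- function(n, min, mode, max) {
  if (max == min) {
    return(rep(mode, n))
  }
  a <- 1 + 4 * (mode - min) / (max - min)
  b <- 1 + 4 * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, a, b)
}

qpert <- function(p, min, mode, max) {
  if (max == min) {
    return(rep(mode, length(p)))
  }
  a <- 1 + 4 * (mode - min) / (max - min)
  b <- 1 + 4 * (max - mode) / (max - min)
  min + (max - min) * qbeta(p, a, b)
}

# Beta(mean * nu, (1 - mean) * nu) whose central 95% interval has the width
# of the stated [low, high] range; used for utilities given only base + range.
solve_beta_range <- function(mean, low, high, field = "beta") {
  width <- high - low
  if (width <= 0 || width >= 1) {
    abort_validation(field, "range must have positive width below 1")
  }
  f <- function(nu) {
    a <- mean * nu
    b <- (1 - mean) * nu
    (qbeta(0.975, a, b) - qbeta(0.025, a, b)) - width
  }
  nu <- uniroot(f, c(1.02, 1e7), tol = 1e-10)$root
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}
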