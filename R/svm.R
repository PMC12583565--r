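# Linear SVM via L2-regularised squared-hinge loss, minimised with L-BFGS.
# No SVM package is assumed; the squared hinge makes the objective smooth so
# a quasi-Newton solve from a zero start is deterministic and exact enough
# for the small-n / moderate-p regime episignatures live in.

.svm_fit <- function(X, y, cost = 1) {
  stopifnot(all(y %in% c(-1, 1)))
  p <- ncol(X)
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1L]
    f <- drop(X %*% w) + b
    m <- pmax(0, 1 - y * f)
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1L]
    f <- drop(X %*% w) + b
    m <- pmax(0, 1 - y * f)
    gw <- w - 2 * cost * drop(crossprod(X, y * m))
    gb <- -2 * cost * sum(y * m)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 1000L, factr = 1e4))
  list(weights = fit$par[1:p], intercept = fit$par[p + 1L],
       converged = fit$convergence == 0L)
}

# Platt sigmoid calibration with regularised targets; maps decision values
# f to probabilities P(case) = 1 / (1 + exp(A f + B)). With z = A f + B the
# cross-entropy against targets t is sum(log(1 + e^z) - (1 - t) z), whose
# z-gradient is sigmoid(z) - (1 - t); both are evaluated overflow-safely.
.platt_fit <- function(f, y) {
  np <- sum(y == 1); nn <- sum(y == -1)
  t <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1L] * f + par[2L]
    sum(pmax(z, 0) + log1p(exp(-abs(z))) - (1 - t) * z)
  }
  gr <- function(par) {
    z <- par[1L] * f + par[2L]
    dz <- stats::plogis(z) - (1 - t)
    c(sum(dz * f), sum(dz))
  }
  init <- c(0, log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, gr, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  list(A = fit$par[1L], B = fit$par[2L])
}

.platt_prob <- function(f, A, B) 1 / (1 + exp(A * f + B))
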