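# Circuit-parameter optimization: adaptive-step gradient descent with
# central-difference gradients for noiseless costs, and a derivative-free
# Nelder-Mead simplex for noisy costs.

#' Optimize circuit parameters
#'
#' Noiseless path (`method = "gradient_descent"`): adaptive-step gradient
#' descent with central finite-difference gradients (h = 1e-4), step growth
#' on accepted moves and backtracking on rejected ones; accepted costs are
#' non-increasing, and iteration stops when `|Delta cost| < tol` or
#' `max_iter` is reached.  Noisy path (`method = "nelder_mead"`): a
#' derivative-free simplex search; every evaluation is recorded.
#'
#' @param cost_fn function mapping an angle vector to a scalar cost.
#' @param theta0 starting angles (radians).
#' @param settings list overriding defaults: `method`, `max_iter` (500),
#'   `tol` (1e-8), `step0` (0.5), `fd_h` (1e-4).
#' @return List: `theta` (optimum), `value`, `history` (data frame with
#'   iteration, cost, grad_norm), `converged`, `n_iter`.
#' @export
optimize_circuit <- function(cost_fn, theta0, settings = list()) {
  s <- modifyList(list(method = "gradient_descent", max_iter = 500L,
                       tol = 1e-8, step0 = 0.5, fd_h = 1e-4), settings)
  theta <- as.numeric(theta0)
  if (!length(theta)) {
    v <- cost_fn(theta)
    return(list(theta = theta, value = v,
                history = data.frame(iteration = 0L, cost = v,
                                     grad_norm = NA_real_),
                converged = TRUE, n_iter = 0L))
  }
  if (identical(s$method, "nelder_mead")) {
    evals <- new.env(); evals$cost <- numeric(0)
    wrapped <- function(th) {
      v <- cost_fn(th)
      evals$cost <- c(evals$cost, v)
      v
    }
    res <- optim(theta, wrapped, method = "Nelder-Mead",
                 control = list(maxit = s$max_iter, reltol = s$tol))
    return(list(theta = res$par, value = res$value,
                history = data.frame(iteration = seq_along(evals$cost),
                                     cost = evals$cost,
                                     grad_norm = NA_real_),
                converged = res$convergence == 0L,
                n_iter = length(evals$cost)))
  }
  grad <- function(th) {
    h <- s$fd_h
    vapply(seq_along(th), function(k) {
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      (cost_fn(tp) - cost_fn(tm)) / (2 * h)
    }, 0)
  }
  cost <- cost_fn(theta)
  if (!is.finite(cost)) stop("non-finite cost at the starting point")
  eta <- s$step0
  hist <- data.frame(iteration = 0L, cost = cost, grad_norm = NA_real_)
  converged <- FALSE; it <- 0L
  while (it < s$max_iter) {
    it <- it + 1L
    g <- grad(theta)
    gn <- sqrt(sum(g^2))
    if (!all(is.finite(g))) stop("non-finite gradient at iteration ", it)
    accepted <- FALSE
    for (try in 1:40) {
      cand <- theta - eta * g
      cc <- cost_fn(cand)
      if (is.finite(cc) && cc <= cost) {
        theta <- cand
        dcost <- cost - cc
        cost <- cc
        eta <- min(eta * 1.25, 10)
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    hist <- rbind(hist, data.frame(iteration = it, cost = cost, grad_norm = gn))
    if (!accepted || dcost < s$tol) { converged <- TRUE; break }
  }
  list(theta = theta, value = cost, history = hist,
       converged = converged, n_iter = it)
}
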