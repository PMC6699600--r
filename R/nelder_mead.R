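## Two-dimensional Nelder-Mead (downhill simplex) minimizer.
##
## Hand-rolled rather than stats::optim because the pathway sweep contract
## requires (a) an explicit, reproducible initial simplex tied to the probe
## step and (b) iteration-count semantics that allow a documented
## convergence study (profile at n_iter vs a high-iteration reference).
## Standard coefficients: reflection 1, expansion 2, contraction 0.5,
## shrink 0.5.  The best vertex is never discarded, so the returned value
## is never worse than the best initial vertex (which includes the seed).

.nelder_mead_2d <- function(f, x0, step, n_iter,
                            tol_f = 1e-14, tol_x = 1e-12) {
  V <- rbind(x0,
             x0 + c(step, 0),
             x0 + c(0, step))
  fv <- c(f(V[1L, ]), f(V[2L, ]), f(V[3L, ]))
  if (n_iter <= 0L)
    return(list(x = x0, f = fv[1L], iterations = 0L))

  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    ord <- order(fv)       # stable: ties broken by first index
    V <- V[ord, , drop = FALSE]
    fv <- fv[ord]
    # degenerate simplex: further iterations cannot move, stop early
    if ((fv[3L] - fv[1L]) < tol_f &&
        max(abs(V[2L, ] - V[1L, ]), abs(V[3L, ] - V[1L, ])) < tol_x)
      break
    ctr <- (V[1L, ] + V[2L, ]) / 2
    xr <- ctr + alpha * (ctr - V[3L, ])
    fr <- f(xr)
    if (fr < fv[1L]) {
      xe <- ctr + gamma * (ctr - V[3L, ])
      fe <- f(xe)
      if (fe < fr) { V[3L, ] <- xe; fv[3L] <- fe }
      else         { V[3L, ] <- xr; fv[3L] <- fr }
    } else if (fr < fv[2L]) {
      V[3L, ] <- xr; fv[3L] <- fr
    } else if (fr < fv[3L]) {
      xc <- ctr + rho * (xr - ctr)          # outside contraction
      fc <- f(xc)
      if (fc <= fr) { V[3L, ] <- xc; fv[3L] <- fc }
      else {
        for (j in 2:3) { V[j, ] <- V[1L, ] + sigma * (V[j, ] - V[1L, ]); fv[j] <- f(V[j, ]) }
      }
    } else {
      xc <- ctr - rho * (ctr - V[3L, ])     # inside contraction
      fc <- f(xc)
      if (fc < fv[3L]) { V[3L, ] <- xc; fv[3L] <- fc }
      else {
        for (j in 2:3) { V[j, ] <- V[1L, ] + sigma * (V[j, ] - V[1L, ]); fv[j] <- f(V[j, ]) }
      }
    }
  }
  best <- which.min(fv)
  list(x = V[best, ], f = fv[best], iterations = it)
}
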