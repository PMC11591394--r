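# Independent minimizer of the OWL objective, used to cross-check the
# package's SMO dual solver: an adaptive-target (Polyak step) subgradient
# phase followed by BFGS refinement on a Huberized hinge with vanishing
# smoothing.  Shares no code or algorithm with the dual solver.

owl_objective <- function(th, Z, a, w, lambda) {
  mean(w * pmax(0, 1 - a * (th[1] + drop(Z %*% th[-1])))) +
    lambda * sum(th[-1]^2)
}

subgradient_owl <- function(Z, a, w, lambda, iters = 20000) {
  p <- ncol(Z)
  th <- rep(0, p + 1)
  fb <- owl_objective(th, Z, a, w, lambda)
  tb <- th
  delta <- 0.1 * max(1, fb)
  since <- 0
  for (t in seq_len(iters)) {
    act <- (1 - a * (th[1] + drop(Z %*% th[-1]))) > 0
    g <- c(-mean(w * a * act),
           -colMeans(Z * (w * a * act)) + 2 * lambda * th[-1])
    gn2 <- sum(g^2)
    if (gn2 < 1e-24) break
    ft <- owl_objective(th, Z, a, w, lambda)
    if (ft < fb - 1e-14 * max(1, abs(fb))) {
      fb <- ft; tb <- th; since <- 0
    } else since <- since + 1
    if (since > 150) { delta <- delta / 2; since <- 0 }
    th <- th - ((ft - (fb - delta)) / gn2) * g
  }

  huber_obj <- function(th, mu) {
    m <- 1 - a * (th[1] + drop(Z %*% th[-1]))
    h <- ifelse(m <= 0, 0, ifelse(m < mu, m^2 / (2 * mu), m - mu / 2))
    mean(w * h) + lambda * sum(th[-1]^2)
  }
  huber_grad <- function(th, mu) {
    m <- 1 - a * (th[1] + drop(Z %*% th[-1]))
    dh <- ifelse(m <= 0, 0, ifelse(m < mu, m / mu, 1))
    c(-mean(w * dh * a), -colMeans(Z * (w * dh * a)) + 2 * lambda * th[-1])
  }
  for (mu in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    o <- stats::optim(tb, huber_obj, huber_grad, mu = mu, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    f2 <- owl_objective(o$par, Z, a, w, lambda)
    if (f2 < fb) { fb <- f2; tb <- o$par }
  }
  list(par = tb, value = fb)
}

# random weighted-classification instance on p covariates (slots beyond p
# padded with zeros so fit_owl's six-slope rule applies)
random_owl_instance <- function(n, p = 6) {
  list(Z = matrix(rnorm(n * p), n),
       a = sample(c(-1, 1), n, replace = TRUE),
       w = runif(n, 0, 100) * rbinom(n, 1, 0.85))
}

# separable instance: arms on the two sides of a random linear boundary
separable_instance <- function(n) {
  Z <- matrix(rnorm(n * 2), n)
  b <- rnorm(3)
  list(Z = Z, A = as.integer(b[1] + Z %*% b[-1] >= 0), w = runif(n, 1, 10))
}

pad6 <- function(Z) cbind(Z, matrix(0, nrow(Z), 6 - ncol(Z)))

# analysis pieces assembled from a simulated trial, shared across tests
prepare_analysis <- function(config, seed = config$seed) {
  trial <- simulate_trial(config, seed = seed)
  ds <- assemble_analysis_dataset(trial)
  model <- fit_observation_model(ds)
  r <- suppressMessages(observation_weights(model, ds))
  w <- owl_weights(compute_rewards(ds$Y), r, ds$A)
  list(trial = trial, ds = ds, model = model, r = r, w = w)
}

no_missingness <- function() {
  c(intercept = 20, age = 0, white = 0, disability = 0, rural = 0,
    low_income = 0, pcl_baseline = 0, arm = 0)
}
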