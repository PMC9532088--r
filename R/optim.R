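# First-order optimizers over named lists of parameter arrays.

optim_init <- function(params, config) {
  switch(config$optimizer,
    adam = list(t = 0,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0)),
    rmsprop = list(v = lapply(params, function(p) p * 0)),
    sgd = list(u = lapply(params, function(p) p * 0))
  )
}

optim_step <- function(params, grads, state, config) {
  lr <- config$learning_rate
  switch(config$optimizer,
    adam = {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      state$t <- state$t + 1
      bc1 <- 1 - b1^state$t
      bc2 <- 1 - b2^state$t
      for (k in names(params)) {
        g <- grads[[k]]
        state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
        state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
        params[[k]] <- params[[k]] -
          lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
      }
    },
    rmsprop = {
      rho <- 0.9; eps <- 1e-8
      for (k in names(params)) {
        g <- grads[[k]]
        state$v[[k]] <- rho * state$v[[k]] + (1 - rho) * g^2
        params[[k]] <- params[[k]] - lr * g / (sqrt(state$v[[k]]) + eps)
      }
    },
    sgd = {
      mu <- config$momentum
      for (k in names(params)) {
        state$u[[k]] <- mu * state$u[[k]] + grads[[k]]
        params[[k]] <- params[[k]] - lr * state$u[[k]]
      }
    }
  )
  list(params = params, state = state)
}
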