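# Adam optimiser over a flat list of parameter nodes.

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim_or_len(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim_or_len(p$value)))
  st
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (st$wd > 0) g <- g + st$wd * p$value
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    upd <- st$lr * mhat / (sqrt(vhat) + st$eps)
    dim(upd) <- dim(p$value)          # keep the parameter's own shape
    p$value <- p$value - upd
  }
  invisible(NULL)
}
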