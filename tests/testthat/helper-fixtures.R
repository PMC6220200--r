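# shared fixtures: everything is generated in code at test time

# desk-scale phantom that fits a 32x32x16 grid (fast unit-test geometry)
small_phantom_params <- function(...) {
  args <- list(grid_shape = c(32L, 32L, 16L), spacing = c(1, 1, 1.5),
               head_radius = 5.5, neck_radius = 3, neck_length = 6,
               shaft_radius = 4, shaft_length = 10, neck_shaft_angle = 130,
               trabecular_scale = 2)
  do.call(phantom_params, utils::modifyList(args, list(...)))
}

# a random blob-ish binary mask (seeded)
random_mask <- function(shape, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  label_mask(array(rbinom(prod(shape), 1, p), shape), spacing)
}

# stub model: constant probability c everywhere, spatially shrunk by
# `margin` per side (emulating an unpadded network's valid output)
stub_constant <- function(value, margin = 0L, dims = 2L) {
  structure(list(spec = NULL, norm = NULL,
                 forward_fun = function(x) {
                   d <- dim(x)
                   out <- d[1:2] - 2L * margin
                   matrix(value, out[1L], out[2L])
                 }),
            class = "femur_cnn")
}

# stub model: translation-invariant valid 3x3 mean filter of the center
# channel, squashed into (0, 1)
stub_mean3 <- function() {
  structure(list(spec = NULL, norm = NULL,
                 forward_fun = function(x) {
                   sl <- x[, , 2L]
                   n <- dim(sl)
                   acc <- matrix(0, n[1L] - 2L, n[2L] - 2L)
                   for (a in 0:2) for (b in 0:2) {
                     acc <- acc + sl[a + seq_len(n[1L] - 2L),
                                     b + seq_len(n[2L] - 2L)]
                   }
                   1 / (1 + exp(-acc / 9))
                 }),
            class = "femur_cnn")
}

# finite-difference check of the loss gradient for a built network
max_grad_rel_err <- function(spec, xdim, n_per_param = 2L, seed = 2L) {
  model <- build_network(spec, seed = seed)
  set.seed(seed)
  x <- array(rnorm(prod(xdim)), xdim)
  osp <- output_shape(spec, xdim[seq_len(spec$dims)])
  y <- array(rbinom(prod(osp), 1, 0.4), osp)
  w <- c(w_fg = 0.7, w_bg = 0.3)
  lossfun <- function(m) {
    femurseg:::wce_loss_grad(femurseg:::net_forward(m, x), y, w)$loss
  }
  fw <- femurseg:::net_forward(model, x, tape = TRUE)
  lg <- femurseg:::wce_loss_grad(fw$logits, y, w)
  gr <- femurseg:::net_backward(model, fw, lg$dlogits)
  maxrel <- 0
  for (nm in names(model$params)) {
    for (slot in c("W", "b")) {
      k <- min(n_per_param, length(model$params[[nm]][[slot]]))
      for (i in sample(length(model$params[[nm]][[slot]]), k)) {
        eps <- 1e-5
        mp <- model
        mp$params[[nm]][[slot]][i] <- mp$params[[nm]][[slot]][i] + eps
        mm <- model
        mm$params[[nm]][[slot]][i] <- mm$params[[nm]][[slot]][i] - eps
        fd <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
        an <- gr[[nm]][[slot]][i]
        maxrel <- max(maxrel, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
      }
    }
  }
  maxrel
}
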