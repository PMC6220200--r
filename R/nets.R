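#' Specify an encoder-decoder network architecture
#'
#' The `(dims, F, L, padding, dilation_rates, in_channels)` tuple fully
#' determines a network of the U-net family: `L` contracting levels of two
#' 3^dims convolutions (ReLU) followed by 2^dims max-pooling with stride 2
#' and feature maps doubling across levels; a center level of two
#' convolutions at `2^L`-fold downsampling, optionally replaced by a
#' dilated-convolution pyramid; a mirrored expanding path of 2^dims
#' up-convolutions that halve the feature maps with skip concatenation
#' from the same level (center-cropped when unpadded); and a final
#' 1-voxel convolution to two channels followed by a softmax.
#'
#' @param dims 2 or 3 (2D networks consume three-consecutive-slice stacks,
#'   3D networks whole volumes).
#' @param F number of feature maps in the first (and last) hidden layer.
#' @param L number of levels in the contracting/expanding paths (`L = 0`
#'   is the degenerate center-only net, allowed for shape and
#'   receptive-field analysis but not for [build_network()]).
#' @param padding `"padded"` (output shape = input shape) or `"unpadded"`
#'   (valid convolutions; 2D only, inference via mirrored tiling).
#' @param dilation_rates increasing integer vector starting at 1, e.g.
#'   `c(1, 2, 4, 8)`; empty for the plain two-convolution center.
#' @param in_channels input channels; defaults to 3 for 2D (slice stacks)
#'   and 1 for 3D.
#' @return an `architecture_spec` object.
#' @export
architecture_spec <- function(dims = 3L, F = 32L, L = 4L,
                              padding = c("padded", "unpadded"),
                              dilation_rates = integer(0),
                              in_channels = NULL) {
  dims <- as.integer(dims)
  padding <- match.arg(padding)
  F <- as.integer(F); L <- as.integer(L)
  dilation_rates <- as.integer(unlist(dilation_rates))
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3", call. = FALSE)
  if (F < 1L || L < 0L) stop("F >= 1 and L >= 0 required", call. = FALSE)
  if (padding == "unpadded" && dims != 2L) {
    stop("unpadded convolutions are only supported for dims = 2; the 3D network uses padded convolutions",
         call. = FALSE)
  }
  if (length(dilation_rates) > 0L) {
    if (dilation_rates[1L] != 1L ||
        any(diff(dilation_rates) <= 0L) || any(dilation_rates < 1L)) {
      stop("dilation_rates must start at 1 and be strictly increasing",
           call. = FALSE)
    }
  }
  if (is.null(in_channels)) in_channels <- if (dims == 2L) 3L else 1L
  structure(list(dims = dims, F = F, L = L, padding = padding,
                 dilation_rates = dilation_rates,
                 in_channels = as.integer(in_channels)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %dD %s, F = %d, L = %d, rates = [%s], in_channels = %d\n",
              x$dims, x$padding, x$F, x$L,
              paste(x$dilation_rates, collapse = ", "), x$in_channels))
  invisible(x)
}

is_padded <- function(spec) identical(spec$padding, "padded")
level_width <- function(spec, l) spec$F * 2L^(l - 1L)
center_width <- function(spec) spec$F * 2L^spec$L

#' Build a network from an architecture specification
#'
#' Weights use Xavier (Glorot) uniform initialization, which keeps the
#' scale of the gradients roughly constant across layers; all biases are
#' initialized to 0.10. Two builds with the same seed produce identical
#' parameter tensors.
#'
#' @param spec an [architecture_spec()] with `L >= 1`.
#' @param seed integer seed for the initializer.
#' @return a `femur_cnn` model: `list(spec, params, norm)`.
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$L < 1L) stop("build_network requires L >= 1", call. = FALSE)
  k <- 3L^spec$dims
  k2 <- 2L^spec$dims
  params <- list()
  with_seed(seed, {
    add <- function(name, fan_k, cin, cout) {
      limit <- sqrt(6 / (fan_k * cin + fan_k * cout))
      params[[name]] <<- list(
        W = matrix(stats::runif(fan_k * cin * cout, -limit, limit),
                   fan_k * cin, cout),
        b = rep(0.10, cout))
    }
    cin <- spec$in_channels
    for (l in seq_len(spec$L)) {
      wl <- level_width(spec, l)
      add(sprintf("enc%d_conv1", l), k, cin, wl)
      add(sprintf("enc%d_conv2", l), k, wl, wl)
      cin <- wl
    }
    cw <- center_width(spec)
    if (length(spec$dilation_rates) == 0L) {
      add("center_conv1", k, cin, cw)
      add("center_conv2", k, cw, cw)
      center_out <- cw
    } else {
      for (r in spec$dilation_rates) add(sprintf("center_r%d", r), k, cin, cw)
      center_out <- cw * length(spec$dilation_rates)
    }
    cin <- center_out
    for (l in rev(seq_len(spec$L))) {
      wl <- level_width(spec, l)
      add(sprintf("dec%d_up", l), k2, cin, wl)
      add(sprintf("dec%d_conv1", l), k, 2L * wl, wl)
      add(sprintf("dec%d_conv2", l), k, wl, wl)
      cin <- wl
    }
    add("out", 1L, cin, 2L)
  })
  structure(list(spec = spec, params = params, norm = "zscore"),
            class = "femur_cnn")
}

#' @export
print.femur_cnn <- function(x, ...) {
  cat(sprintf("<femur_cnn> %s  parameters: %d\n",
              format(x$spec$dims), n_parameters(x)))
  print(x$spec)
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1L)))
}

#' Analytic parameter count of an architecture
#'
#' Closed-form count of weights and biases as a function of the
#' specification alone; the built network carries exactly this many
#' parameters. Doubling `F` roughly quadruples the convolutional weight
#' count.
#'
#' @param spec an [architecture_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  k <- 3^spec$dims; k2 <- 2^spec$dims
  F <- spec$F; L <- spec$L
  total <- 0
  cin <- spec$in_channels
  for (l in seq_len(L)) {
    w <- F * 2^(l - 1)
    total <- total + (k * cin * w + w) + (k * w * w + w)
    cin <- w
  }
  cw <- F * 2^L
  nr <- length(spec$dilation_rates)
  if (nr == 0L) {
    total <- total + (k * cin * cw + cw) + (k * cw * cw + cw)
    cout <- cw
  } else {
    total <- total + nr * (k * cin * cw + cw)
    cout <- cw * nr
  }
  cin <- cout
  for (l in rev(seq_len(L))) {
    w <- F * 2^(l - 1)
    total <- total + (k2 * cin * w + w) +
      (k * 2 * w * w + w) + (k * w * w + w)
    cin <- w
  }
  total + (cin * 2 + 2)
}

#' Build the dilated-convolution pyramid center as a standalone component
#'
#' One padded 3^dims convolution per dilation rate, each producing the
#' plain-center feature-map count; outputs are concatenated along the
#' channel axis, preserving the spatial shape. This is the component
#' [build_network()] installs at the center when `dilation_rates` is
#' nonempty.
#'
#' @param spec an [architecture_spec()] with nonempty `dilation_rates`.
#' @param in_channels input channel count (defaults to the width of the
#'   deepest encoder level).
#' @param seed integer seed.
#' @return list with `params` and a `forward(x)` closure.
#' @export
build_dilated_center <- function(spec, in_channels = NULL, seed = 0L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (length(spec$dilation_rates) == 0L) {
    stop("build_dilated_center requires nonempty dilation_rates",
         call. = FALSE)
  }
  if (is.null(in_channels)) {
    in_channels <- if (spec$L >= 1L) level_width(spec, spec$L)
                   else spec$in_channels
  }
  cw <- center_width(spec)
  k <- 3L^spec$dims
  params <- list()
  with_seed(seed, {
    for (r in spec$dilation_rates) {
      limit <- sqrt(6 / (k * in_channels + k * cw))
      params[[sprintf("r%d", r)]] <- list(
        W = matrix(stats::runif(k * in_channels * cw, -limit, limit),
                   k * in_channels, cw),
        b = rep(0.10, cw))
    }
  })
  rates <- spec$dilation_rates
  list(params = params,
       forward = function(x) {
         outs <- lapply(rates, function(r) {
           relu_fwd(conv_fwd(x, params[[sprintf("r%d", r)]],
                             dilation = as.integer(r), pad = TRUE,
                             where = sprintf("dilated center (r = %d)", r)))
         })
         Reduce(concat_channels, outs)
       })
}

#' Spatial output shape of a network
#'
#' Padded networks map any input shape to itself. Unpadded networks
#' follow the U-shaped shrinkage recursion of valid 3x3 convolutions,
#' 2x2 pooling and 2x2 up-convolutions; inadmissible shapes (odd before a
#' pooling, or non-positive anywhere in the U) raise an error naming the
#' level. A dilated center uses padded convolutions and does not shrink.
#'
#' @param spec an [architecture_spec()].
#' @param input_shape integer vector of length `dims`.
#' @return integer output shape; agrees with an actual forward pass.
#' @export
output_shape <- function(spec, input_shape) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != spec$dims) {
    stop("input_shape must have length dims = ", spec$dims, call. = FALSE)
  }
  if (is_padded(spec)) return(input_shape)
  center_shrink <- if (length(spec$dilation_rates) > 0L) 0L else 4L
  rec <- function(s, l) {
    if (l > spec$L) {
      s <- s - center_shrink
      if (any(s < 1L)) {
        stop("output_shape: non-positive shape at the center level",
             call. = FALSE)
      }
      return(s)
    }
    s <- s - 4L
    if (any(s < 1L)) {
      stop("output_shape: non-positive shape after encoder level ", l,
           call. = FALSE)
    }
    if (any(s %% 2L != 0L)) {
      stop("output_shape: odd shape (", paste(s, collapse = "x"),
           ") before pooling at encoder level ", l, call. = FALSE)
    }
    u <- 2L * rec(s %/% 2L, l + 1L)
    u <- u - 4L
    if (any(u < 1L)) {
      stop("output_shape: non-positive shape at decoder level ", l,
           call. = FALSE)
    }
    u
  }
  rec(input_shape, 1L)
}

#' Receptive field of the center-layer units
#'
#' Analytic size, in input voxels per axis, of the region of the input
#' that influences one unit of the center layer, accounting for the
#' dilation rates of a pyramid center (the widest branch dominates).
#'
#' @param spec an [architecture_spec()].
#' @return integer vector of length `dims`.
#' @export
receptive_field <- function(spec) {
  rf <- 1; jump <- 1
  for (l in seq_len(spec$L)) {
    rf <- rf + 2 * jump + 2 * jump        # two 3-voxel convolutions
    rf <- rf + jump                       # 2-voxel pooling window
    jump <- jump * 2                      # stride 2
  }
  if (length(spec$dilation_rates) == 0L) {
    rf <- rf + 2 * jump + 2 * jump
  } else {
    rf <- rf + 2 * max(spec$dilation_rates) * jump
  }
  rep(as.integer(rf), spec$dims)
}

# forward pass; when `tape = TRUE` also returns the op tape and cached
# tensors needed by net_backward()
net_forward <- function(model, x, tape = FALSE) {
  spec <- model$spec
  p <- model$params
  padded <- is_padded(spec)
  d <- spec$dims
  ops <- list(); vals <- list(); nid <- 0L
  push <- function(kind, ins, out_val, pname = NULL, extra = NULL) {
    nid <<- nid + 1L
    id <- sprintf("t%d", nid)
    vals[[id]] <<- out_val
    ops[[length(ops) + 1L]] <<- list(kind = kind, ins = ins, out = id,
                                     pname = pname, extra = extra)
    id
  }
  conv_block <- function(id, pname, dilation = 1L, pad = padded,
                         where = pname) {
    cid <- push("conv", id,
                conv_fwd(vals[[id]], p[[pname]], dilation = dilation,
                         pad = pad, where = where),
                pname = pname, extra = list(dilation = dilation, pad = pad))
    push("relu", cid, relu_fwd(vals[[cid]]))
  }

  a <- push("input", character(0), x)
  skips <- character(spec$L)
  for (l in seq_len(spec$L)) {
    a <- conv_block(a, sprintf("enc%d_conv1", l),
                    where = sprintf("encoder level %d", l))
    a <- conv_block(a, sprintf("enc%d_conv2", l),
                    where = sprintf("encoder level %d", l))
    skips[l] <- a
    pl <- pool_fwd(vals[[a]])
    a <- push("pool", a, pl$y,
              extra = list(argmax = pl$argmax, x_dim = dim(vals[[a]])))
  }
  if (length(spec$dilation_rates) == 0L) {
    a <- conv_block(a, "center_conv1", where = "center level")
    a <- conv_block(a, "center_conv2", where = "center level")
  } else {
    branches <- vapply(spec$dilation_rates, function(r) {
      conv_block(a, sprintf("center_r%d", r), dilation = as.integer(r),
                 pad = TRUE, where = sprintf("center level (r = %d)", r))
    }, character(1L))
    while (length(branches) > 1L) {
      ca <- branches[1L]; cb <- branches[2L]
      merged <- push("concat", c(ca, cb),
                     concat_channels(vals[[ca]], vals[[cb]]),
                     extra = list(c1 = dim(vals[[ca]])[d + 1L]))
      branches <- c(merged, branches[-(1:2)])
    }
    a <- branches
  }
  for (l in rev(seq_len(spec$L))) {
    a <- push("upconv", a, upconv_fwd(vals[[a]], p[[sprintf("dec%d_up", l)]]),
              pname = sprintf("dec%d_up", l))
    s <- skips[l]
    if (!padded) {
      target <- dim(vals[[a]])[seq_len(d)]
      s <- push("crop", s, crop_to(vals[[s]], target),
                extra = list(orig_sp = dim(vals[[skips[l]]])[seq_len(d)]))
    }
    a <- push("concat", c(a, s), concat_channels(vals[[a]], vals[[s]]),
              extra = list(c1 = dim(vals[[a]])[d + 1L]))
    a <- conv_block(a, sprintf("dec%d_conv1", l),
                    where = sprintf("decoder level %d", l))
    a <- conv_block(a, sprintf("dec%d_conv2", l),
                    where = sprintf("decoder level %d", l))
  }
  a <- push("conv1x1", a, conv1_fwd(vals[[a]], p[["out"]]), pname = "out")
  if (tape) list(logits = vals[[a]], ops = ops, vals = vals, out_id = a)
  else vals[[a]]
}

# reverse sweep over the tape; returns parameter gradients
net_backward <- function(model, fw, dlogits) {
  p <- model$params
  vals <- fw$vals
  gt <- list()                            # gradients w.r.t. tensors
  gp <- list()                            # gradients w.r.t. parameters
  gt[[fw$out_id]] <- dlogits
  addg <- function(id, g) {
    gt[[id]] <<- if (is.null(gt[[id]])) g else gt[[id]] + g
  }
  addp <- function(pname, dW, db) {
    if (is.null(gp[[pname]])) gp[[pname]] <<- list(W = dW, b = db)
    else gp[[pname]] <<- list(W = gp[[pname]]$W + dW, b = gp[[pname]]$b + db)
  }
  for (op in rev(fw$ops)) {
    dy <- gt[[op$out]]
    if (is.null(dy)) next
    gt[[op$out]] <- NULL                  # free as we go
    switch(op$kind,
      input = NULL,
      conv = {
        r <- conv_bwd(vals[[op$ins]], p[[op$pname]], dy,
                      dilation = op$extra$dilation, pad = op$extra$pad)
        addp(op$pname, r$dW, r$db)
        addg(op$ins, r$dx)
      },
      conv1x1 = {
        r <- conv1_bwd(vals[[op$ins]], p[[op$pname]], dy)
        addp(op$pname, r$dW, r$db)
        addg(op$ins, r$dx)
      },
      relu = addg(op$ins, relu_bwd(vals[[op$out]], dy)),
      pool = addg(op$ins, pool_bwd(dy, op$extra$argmax, op$extra$x_dim)),
      upconv = {
        r <- upconv_bwd(vals[[op$ins]], p[[op$pname]], dy)
        addp(op$pname, r$dW, r$db)
        addg(op$ins, r$dx)
      },
      concat = {
        d <- length(dim(dy)) - 1L
        c1 <- op$extra$c1
        ctot <- dim(dy)[d + 1L]
        if (d == 2L) {
          addg(op$ins[1L], dy[, , seq_len(c1), drop = FALSE])
          addg(op$ins[2L], dy[, , c1 + seq_len(ctot - c1), drop = FALSE])
        } else {
          addg(op$ins[1L], dy[, , , seq_len(c1), drop = FALSE])
          addg(op$ins[2L], dy[, , , c1 + seq_len(ctot - c1), drop = FALSE])
        }
      },
      crop = addg(op$ins, uncrop_to(dy, op$extra$orig_sp)),
      stop("unknown op kind: ", op$kind))
  }
  gp
}

#' Save / load a model checkpoint
#'
#' The architecture specification is embedded in the checkpoint so
#' inference can rebuild the network exactly.
#'
#' @param model a `femur_cnn`.
#' @param path checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "femur_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "femur_cnn")) {
    stop("load_model: not a femur_cnn checkpoint: ", path, call. = FALSE)
  }
  model
}
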