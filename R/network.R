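# The detection network: a truncated-VGG backbone (stride-1 3x3 convs with
# ReLU, 2x2 max-pooling after layers 2 and 4, so predictions live at 1/4
# resolution), a pyramid pooling module (PPM) injecting global context, and
# a multi-stage module (MSM) of T refinement heads.  Stage 1 sees the PPM
# features; each later stage sees the PPM features concatenated with the
# previous stage's sigmoid confidence map.  Forward and backward passes are
# hand-written on top of the package's C++ tensor primitives.

#' Network architecture configuration
#'
#' Defaults follow the VGG-19-derived plan: eight 3x3 conv layers with
#' filter counts 64,64 | pool | 128,128 | pool | 256,256,256,256, pyramid
#' pooling bins \{1, 2, 3, 6\}, and per-stage heads of three 3x3 layers at
#' 128 filters, one 1x1 layer at 512 and a final 1-filter layer with
#' sigmoid activation.  Two 2x2 poolings fix the output scale at 4.
#'
#' @param channels filter counts of the backbone conv layers.
#' @param pool_after indices of backbone layers followed by 2x2 max-pool;
#'   exactly two (output scale 4).
#' @param ppm_bins pyramid pooling grid sizes.
#' @param stages number of refinement stages T (>= 1).
#' @param head_channels filters of the three 3x3 head layers.
#' @param bottleneck_channels filters of the 1x1 head layer.
#' @param share_stage_weights if TRUE, stages t >= 2 share one set of head
#'   weights.
#' @param in_channels input channels (3 for RGB).
#' @return object of class `network_config`; `output_scale` is always 4.
#' @export
network_config <- function(channels = c(64, 64, 128, 128, 256, 256, 256, 256),
                           pool_after = c(2, 4),
                           ppm_bins = c(1, 2, 3, 6),
                           stages = 4L,
                           head_channels = 128L,
                           bottleneck_channels = 512L,
                           share_stage_weights = FALSE,
                           in_channels = 3L) {
  channels <- as.integer(channels)
  stopifnot(length(channels) >= 1, all(channels > 0),
            length(pool_after) == 2L,
            all(pool_after >= 1), all(pool_after <= length(channels)),
            all(ppm_bins >= 1), stages >= 1,
            head_channels > 0, bottleneck_channels > 0)
  cb <- channels[length(channels)]
  if (cb %% 4L != 0L)
    stop("final backbone channel count must be divisible by 4 (PPM reduction)",
         call. = FALSE)
  structure(
    list(channels = channels, pool_after = as.integer(pool_after),
         ppm_bins = as.integer(ppm_bins), stages = as.integer(stages),
         head_channels = as.integer(head_channels),
         bottleneck_channels = as.integer(bottleneck_channels),
         share_stage_weights = isTRUE(share_stage_weights),
         in_channels = as.integer(in_channels),
         output_scale = 4L),
    class = "network_config")
}

#' A reduced configuration for desk-scale experiments
#'
#' Backbone capped at 32 channels with six conv layers, two stages, small
#' heads — enough capacity to learn the synthetic crowns in minutes on one
#' CPU while exercising every architectural component.
#' @param stages number of refinement stages.
#' @export
reduced_network_config <- function(stages = 2L) {
  network_config(channels = c(8, 8, 16, 16, 32, 32), pool_after = c(2, 4),
                 ppm_bins = c(1, 2, 4), stages = stages,
                 head_channels = 32L, bottleneck_channels = 64L)
}

ppm_red_channels <- function(cfg) cfg$channels[length(cfg$channels)] %/% 4L
ppm_out_channels <- function(cfg) {
  cb <- cfg$channels[length(cfg$channels)]
  cb + length(cfg$ppm_bins) * ppm_red_channels(cfg)
}
stage_in_channels <- function(cfg, t) ppm_out_channels(cfg) + (t > 1L)
stage_param_index <- function(cfg, t)
  if (cfg$share_stage_weights && t >= 2L) 2L else t
n_stage_params <- function(cfg)
  if (cfg$share_stage_weights) min(cfg$stages, 2L) else cfg$stages

init_conv <- function(cin, cout, k, gain = 2) {
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = as.integer(k))
}

#' Build (initialise) the detection network
#'
#' He-initialised weights; the final 1-filter layer of every stage starts
#' with a negative bias so the sigmoid output begins near the background
#' probability, which stabilises the first epochs under the summed
#' squared-error loss.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for the initialisation.
#' @return list of parameter tensors (`backbone`, `ppm`, `stages`).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    cins <- c(config$in_channels, config$channels)
    backbone <- lapply(seq_along(config$channels), function(l)
      init_conv(cins[l], cins[l + 1], 3L))
    cb <- config$channels[length(config$channels)]
    ppm <- lapply(config$ppm_bins, function(g)
      init_conv(cb, ppm_red_channels(config), 1L))
    stages <- lapply(seq_len(n_stage_params(config)), function(t) {
      cin <- stage_in_channels(config, t)
      h <- config$head_channels; bn <- config$bottleneck_channels
      head <- list(init_conv(cin, h, 3L), init_conv(h, h, 3L),
                   init_conv(h, h, 3L), init_conv(h, bn, 1L),
                   init_conv(bn, 1L, 1L, gain = 1))
      head[[5]]$b[] <- -2.9  # sigmoid prior ~ 0.05
      head
    })
    list(backbone = backbone, ppm = ppm, stages = stages)
  })
}

#' Total trainable parameter count
#'
#' @param x a parameter list from [build_network()] or a fitted
#'   `palm_detector`.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "palm_detector")) x <- x$params
  cnt <- 0
  walk <- function(p) {
    if (is.list(p) && !is.null(p$W)) cnt <<- cnt + length(p$W) + length(p$b)
    else if (is.list(p)) lapply(p, walk)
    invisible(NULL)
  }
  walk(x)
  cnt
}

conv_fwd <- function(x, layer) nn_conv_fwd(x, layer$W, layer$b, layer$k,
                                           (layer$k - 1L) %/% 2L)
conv_bwd <- function(x, layer, gy, need_gx = TRUE)
  nn_conv_bwd(x, layer$W, gy, layer$k, (layer$k - 1L) %/% 2L, need_gx)

relu <- function(x) { x[x < 0] <- 0; x }
concat3 <- function(...) {
  parts <- list(...)
  H <- dim(parts[[1]])[1]; W <- dim(parts[[1]])[2]
  array(unlist(parts, use.names = FALSE),
        dim = c(H, W, sum(vapply(parts, function(p) dim(p)[3], 0))))
}

#' Run the network forward
#'
#' @param params parameters from [build_network()].
#' @param x H x W x 3 input array, H and W divisible by 4 and large enough
#'   for the largest pyramid bin.
#' @param cfg the matching [network_config()].
#' @param keep_cache keep intermediate activations (needed for the backward
#'   pass).
#' @return list with `preds` (list of T H/4 x W/4 matrices, sigmoid
#'   activated) and, if requested, `cache`.
#' @export
net_forward <- function(params, x, cfg, keep_cache = FALSE) {
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("input height and width must be divisible by 4", call. = FALSE)
  if (min(H, W) %/% 4L < max(cfg$ppm_bins))
    stop("input too small for the largest pyramid pooling bin", call. = FALSE)
  cache <- list(backbone = vector("list", length(params$backbone)),
                pool = list())
  h <- x
  for (l in seq_along(params$backbone)) {
    xin <- h
    h <- relu(conv_fwd(h, params$backbone[[l]]))
    if (keep_cache) cache$backbone[[l]] <- list(x = xin, a = h)
    if (l %in% cfg$pool_after) {
      pr <- nn_maxpool2_fwd(h)
      if (keep_cache)
        cache$pool[[as.character(l)]] <- list(idx = pr$idx, H = dim(h)[1],
                                              W = dim(h)[2])
      h <- pr$y
    }
  }
  f <- h
  h4 <- dim(f)[1]; w4 <- dim(f)[2]
  branches <- vector("list", length(cfg$ppm_bins))
  if (keep_cache) cache$ppm <- vector("list", length(cfg$ppm_bins))
  for (bi in seq_along(cfg$ppm_bins)) {
    g <- cfg$ppm_bins[bi]
    p <- nn_avgpool_adaptive_fwd(f, g)
    q <- relu(conv_fwd(p, params$ppm[[bi]]))
    branches[[bi]] <- nn_upsample_bilinear_fwd(q, h4, w4)
    if (keep_cache) cache$ppm[[bi]] <- list(p = p, q = q)
  }
  FF <- do.call(concat3, c(list(f), branches))
  if (keep_cache) { cache$f <- f; cache$FF <- FF }
  preds <- vector("list", cfg$stages)
  if (keep_cache) cache$stages <- vector("list", cfg$stages)
  prev <- NULL
  for (t in seq_len(cfg$stages)) {
    s_in <- if (t == 1L) FF else concat3(FF, array(prev, dim = c(h4, w4, 1L)))
    sp <- params$stages[[stage_param_index(cfg, t)]]
    acts <- vector("list", 5L)
    h <- s_in
    for (li in 1:4) {
      xin <- h
      h <- relu(conv_fwd(h, sp[[li]]))
      acts[[li]] <- list(x = xin, a = h)
    }
    z <- conv_fwd(h, sp[[5]])
    Cmap <- 1 / (1 + exp(-z[, , 1]))
    if (keep_cache)
      cache$stages[[t]] <- list(s_in = s_in, acts = acts, x5 = h, C = Cmap)
    preds[[t]] <- Cmap
    prev <- Cmap
  }
  out <- list(preds = preds)
  if (keep_cache) out$cache <- cache
  out
}

zero_like <- function(layer) list(W = layer$W * 0, b = layer$b * 0, k = layer$k)

add_into <- function(acc, g) {
  acc$W <- acc$W + g$gw; acc$b <- acc$b + as.numeric(g$gb); acc
}

# Backward pass: dloss is a list of gradients w.r.t. each stage's sigmoid
# output (from the per-stage loss); the chain through later stages' inputs
# is handled internally.  Returns gradients with the same structure as the
# parameters.
net_backward <- function(params, cfg, cache, dloss) {
  grads <- list(
    backbone = lapply(params$backbone, zero_like),
    ppm = lapply(params$ppm, zero_like),
    stages = lapply(params$stages, function(s) lapply(s, zero_like)))
  h4 <- dim(cache$f)[1]; w4 <- dim(cache$f)[2]
  cf <- dim(cache$FF)[3]
  dFF <- array(0, dim = c(h4, w4, cf))
  dC_next <- NULL
  for (t in rev(seq_len(cfg$stages))) {
    st <- cache$stages[[t]]
    dC <- dloss[[t]]
    if (!is.null(dC_next)) dC <- dC + dC_next
    dz <- dC * st$C * (1 - st$C)
    dz <- array(dz, dim = c(h4, w4, 1L))
    pi <- stage_param_index(cfg, t)
    sp <- params$stages[[pi]]
    g5 <- conv_bwd(st$x5, sp[[5]], dz)
    grads$stages[[pi]][[5]] <- add_into(grads$stages[[pi]][[5]], g5)
    gh <- g5$gx
    for (li in 4:1) {
      a <- st$acts[[li]]
      gh <- gh * (a$a > 0)
      gl <- conv_bwd(a$x, sp[[li]], gh)
      grads$stages[[pi]][[li]] <- add_into(grads$stages[[pi]][[li]], gl)
      gh <- gl$gx
    }
    if (t == 1L) {
      dFF <- dFF + gh
      dC_next <- NULL
    } else {
      dFF <- dFF + gh[, , seq_len(cf), drop = FALSE]
      dC_next <- gh[, , cf + 1L]
    }
  }
  cb <- dim(cache$f)[3]
  df <- dFF[, , seq_len(cb), drop = FALSE]
  off <- cb
  for (bi in seq_along(cfg$ppm_bins)) {
    cr <- ppm_red_channels(cfg)
    du <- dFF[, , off + seq_len(cr), drop = FALSE]
    off <- off + cr
    br <- cache$ppm[[bi]]
    dq <- nn_upsample_bilinear_bwd(du, dim(br$q)[1], dim(br$q)[2])
    dq <- dq * (br$q > 0)
    gp <- conv_bwd(br$p, params$ppm[[bi]], dq)
    grads$ppm[[bi]] <- add_into(grads$ppm[[bi]], gp)
    df <- df + nn_avgpool_adaptive_bwd(gp$gx, h4, w4)
  }
  gh <- df
  for (l in rev(seq_along(params$backbone))) {
    if (l %in% cfg$pool_after) {
      pc <- cache$pool[[as.character(l)]]
      gh <- nn_maxpool2_bwd(pc$idx, gh, pc$H, pc$W)
    }
    bc <- cache$backbone[[l]]
    gh <- gh * (bc$a > 0)
    gl <- conv_bwd(bc$x, params$backbone[[l]], gh, need_gx = l > 1L)
    grads$backbone[[l]] <- add_into(grads$backbone[[l]], gl)
    gh <- gl$gx
  }
  grads
}

#' Per-stage squared-error loss
#'
#' The loss of stage t is the sum over all map cells of the squared
#' difference between the predicted and ground-truth confidence maps.
#'
#' @param pred,target [confidence_map]s or matrices of equal shape.
#' @return non-negative scalar, 0 iff the maps are identical.
#' @export
stage_loss <- function(pred, target) {
  p <- as_grid(pred); t <- as_grid(target)
  if (!all(dim(p) == dim(t)))
    stop("prediction and target shapes differ", call. = FALSE)
  sum((p - t)^2)
}

#' Total multi-stage loss
#'
#' Sum of [stage_loss()] over stages; supervising every stage keeps
#' gradients flowing to the early heads (intermediate supervision).
#'
#' @param preds list of per-stage predictions.
#' @param targets list of per-stage targets (same length).
#' @export
total_loss <- function(preds, targets) {
  if (length(preds) != length(targets))
    stop("stage count mismatch between predictions and targets",
         call. = FALSE)
  sum(mapply(stage_loss, preds, targets))
}
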