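# palm_detector(): the package's fitting function.  Trains the multi-stage
# confidence-map network on annotated scenes with SGD + momentum, rendering
# per-stage Gaussian targets at the network's output scale, and returns a
# classed model object with the usual print/summary/predict/plot methods.

#' Training control parameters
#'
#' Defaults mirror the published training recipe: SGD with momentum 0.9,
#' learning rate 0.001, 100 epochs, and a sigma schedule of 4 -> 1 over 4
#' stages.  The loss is summed (not averaged) over map cells, so the
#' effective step size scales with map area; for small desk-scale
#' experiments a smaller learning rate is usually appropriate.
#'
#' @param learning_rate SGD step size (> 0).
#' @param momentum momentum coefficient in \[0, 1).
#' @param epochs training epochs (>= 0; 0 leaves the model untouched).
#' @param batch_size scenes per gradient step (gradients averaged).
#' @param seed RNG seed for initialisation and shuffling.
#' @param schedule a [make_sigma_schedule()]; its `n_stages` must match the
#'   network's stage count at fit time.
#' @export
train_control <- function(learning_rate = 0.001, momentum = 0.9,
                          epochs = 100L, batch_size = 1L, seed = 1L,
                          schedule = make_sigma_schedule(1, 4, 4)) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 0,
            batch_size >= 1, inherits(schedule, "sigma_schedule"))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), schedule = schedule),
            class = "train_control")
}

scene_input <- function(x) {
  if (inherits(x, "annotated_scene")) x$image
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an annotated_scene or an H x W x 3 array",
            call. = FALSE)
}

# Loss gradients w.r.t. each stage's sigmoid output: d/dp sum((p - t)^2).
loss_grads <- function(preds, targets)
  mapply(function(p, t) 2 * (p - t), preds, targets, SIMPLIFY = FALSE)

sgd_step <- function(params, grads, vel, lr, momentum) {
  step <- function(p, g, v) {
    if (is.list(p) && !is.null(p$W)) {
      v$W <- momentum * v$W - lr * g$W
      v$b <- momentum * v$b - lr * g$b
      p$W <- p$W + v$W
      p$b <- p$b + v$b
      list(p = p, v = v)
    } else {
      res <- mapply(step, p, g, v, SIMPLIFY = FALSE)
      list(p = lapply(res, `[[`, "p"), v = lapply(res, `[[`, "v"))
    }
  }
  step(params, grads, vel)
}

zero_velocity <- function(params) {
  z <- function(p) {
    if (is.list(p) && !is.null(p$W)) list(W = p$W * 0, b = p$b * 0)
    else lapply(p, z)
  }
  z(params)
}

#' Fit the palm-tree confidence-map detector
#'
#' Trains the truncated-VGG + pyramid-pooling + multi-stage network on
#' annotated scenes.  Ground-truth targets are rendered per stage with
#' Gaussian kernels following the control's sigma schedule at the
#' network's output scale (4 input pixels per map cell); every stage is
#' supervised with the summed squared-error loss and the per-stage losses
#' are added (intermediate supervision).
#'
#' @param scenes a [generate_dataset()] result (uses `$train` for fitting
#'   and `$validation` for the validation loss), or a plain list of
#'   `annotated_scene`s used entirely for training.
#' @param net a [network_config()].
#' @param control a [train_control()].
#' @return an object of class `palm_detector` with elements `params`,
#'   `net`, `control`, `schedule` and `history` (data frame with per-epoch
#'   `train_loss` and `val_loss`).
#' @seealso [predict.palm_detector()], [evaluate_detector()],
#'   [extract_detections()]
#' @export
palm_detector <- function(scenes, net = network_config(),
                          control = train_control()) {
  stopifnot(inherits(net, "network_config"),
            inherits(control, "train_control"))
  cl <- match.call()
  if (inherits(scenes, "scene_dataset")) {
    train <- scenes$train; val <- scenes$validation
  } else {
    train <- scenes; val <- list()
  }
  if (!length(train)) stop("training split is empty", call. = FALSE)
  sched <- control$schedule
  if (sched$n_stages != net$stages)
    stop("schedule stage count must match the network's stage count",
         call. = FALSE)
  prep <- function(sc) {
    stopifnot(inherits(sc, "annotated_scene"))
    shape <- dim(sc$image)[1:2]
    targets <- lapply(
      render_stage_targets(sc$annotations, shape, sched, net$output_scale),
      as_grid)
    list(x = sc$image, targets = targets)
  }
  tr <- lapply(train, prep)
  va <- lapply(val, prep)
  params <- build_network(net, seed = control$seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  if (control$epochs > 0) {
    vel <- zero_velocity(params)
    with_seed(control$seed + 1L, {
      for (ep in seq_len(control$epochs)) {
        ord <- sample.int(length(tr))
        ep_loss <- 0
        b0 <- 1L
        while (b0 <= length(ord)) {
          batch <- ord[b0:min(b0 + control$batch_size - 1L, length(ord))]
          b0 <- b0 + control$batch_size
          acc <- NULL
          for (i in batch) {
            fw <- net_forward(params, tr[[i]]$x, net, keep_cache = TRUE)
            li <- total_loss(fw$preds, tr[[i]]$targets)
            if (!is.finite(li))
              stop(sprintf("training diverged (non-finite loss) at epoch %d",
                           ep), call. = FALSE)
            ep_loss <- ep_loss + li
            g <- net_backward(params, net, fw$cache,
                              loss_grads(fw$preds, tr[[i]]$targets))
            acc <- if (is.null(acc)) g else add_grads(acc, g)
          }
          acc <- scale_grads(acc, 1 / length(batch))
          upd <- sgd_step(params, acc, vel, control$learning_rate,
                          control$momentum)
          params <- upd$p; vel <- upd$v
        }
        vl <- if (length(va)) mean(vapply(va, function(s)
          total_loss(net_forward(params, s$x, net)$preds, s$targets),
          0)) else NA_real_
        history <- rbind(history, data.frame(
          epoch = ep, train_loss = ep_loss / length(tr), val_loss = vl))
      }
    })
  }
  structure(list(params = params, net = net, control = control,
                 schedule = sched, history = history,
                 n_train = length(tr), n_val = length(va), call = cl),
            class = "palm_detector")
}

add_grads <- function(a, b) {
  f <- function(p, q) {
    if (is.list(p) && !is.null(p$W))
      list(W = p$W + q$W, b = p$b + q$b, k = p$k)
    else mapply(f, p, q, SIMPLIFY = FALSE)
  }
  f(a, b)
}

scale_grads <- function(g, s) {
  f <- function(p) {
    if (is.list(p) && !is.null(p$W)) list(W = p$W * s, b = p$b * s, k = p$k)
    else lapply(p, f)
  }
  f(g)
}

#' @export
print.palm_detector <- function(x, ...) {
  cat("Multi-stage confidence-map palm detector\n")
  cat(sprintf("  backbone: %s conv layers (%s), pools after %s\n",
              length(x$net$channels),
              paste(x$net$channels, collapse = ","),
              paste(x$net$pool_after, collapse = ",")))
  cat(sprintf("  PPM bins: %s | stages T = %d | output scale %d\n",
              paste(x$net$ppm_bins, collapse = ","), x$net$stages,
              x$net$output_scale))
  cat(sprintf("  sigma schedule: %s\n",
              paste(signif(x$schedule$values, 4), collapse = " -> ")))
  cat(sprintf("  parameters: %s | trained %d epochs on %d scenes\n",
              format(n_parameters(x), big.mark = ","),
              nrow(x$history), x$n_train))
  if (nrow(x$history))
    cat(sprintf("  final train loss %.4g%s\n",
                x$history$train_loss[nrow(x$history)],
                if (is.na(x$history$val_loss[nrow(x$history)])) "" else
                  sprintf(", val loss %.4g",
                          x$history$val_loss[nrow(x$history)])))
  invisible(x)
}

#' @export
summary.palm_detector <- function(object, ...) {
  counts <- c(backbone = n_parameters(object$params["backbone"]),
              ppm = n_parameters(object$params["ppm"]),
              stages = n_parameters(object$params["stages"]))
  structure(list(model = object, param_counts = counts),
            class = "summary.palm_detector")
}

#' @export
print.summary.palm_detector <- function(x, ...) {
  print(x$model)
  cat("  parameter breakdown:\n")
  for (nm in names(x$param_counts))
    cat(sprintf("    %-9s %s\n", nm,
                format(x$param_counts[[nm]], big.mark = ",")))
  invisible(x)
}

#' @export
coef.palm_detector <- function(object, ...) object$params

#' Predict confidence maps or detections for new scenes
#'
#' @param object a fitted [palm_detector()].
#' @param newdata an `annotated_scene`, an H x W x 3 array, or a list of
#'   either.
#' @param type `"detections"` for a data frame of tree centres (input
#'   pixel coordinates, cell-centre convention) or `"confidence"` for the
#'   list of per-stage [confidence_map]s.
#' @param peak [peak_params()] used when `type = "detections"`.
#' @param ... unused.
#' @export
predict.palm_detector <- function(object, newdata,
                                  type = c("detections", "confidence"),
                                  peak = peak_params(), ...) {
  type <- match.arg(type)
  one <- function(x) {
    img <- scene_input(x)
    preds <- net_forward(object$params, img, object$net)$preds
    maps <- lapply(seq_along(preds), function(t)
      confidence_map(preds[[t]], stage = t, scale = object$net$output_scale))
    if (type == "confidence") maps
    else extract_detections(maps[[length(maps)]], peak)
  }
  if (is.list(newdata) && !inherits(newdata, "annotated_scene"))
    lapply(newdata, one)
  else one(newdata)
}

#' Plot a scene with ground truth and detections
#'
#' Renders the RGB scene, overlays ground-truth annotations (circles) and,
#' when a model is supplied, its detections (crosses).
#'
#' @param x a fitted `palm_detector`.
#' @param scene an `annotated_scene`.
#' @param peak [peak_params()] for the detection overlay.
#' @param ... unused.
#' @export
plot.palm_detector <- function(x, scene, peak = peak_params(), ...) {
  img <- scene_input(scene)
  H <- dim(img)[1]; W <- dim(img)[2]
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, W), ylim = c(H, 0), asp = 1)
  graphics::rasterImage(img, 0, H, W, 0)
  if (inherits(scene, "annotated_scene") && nrow(scene$annotations))
    graphics::points(scene$annotations$x, scene$annotations$y, col = "cyan",
                     cex = 1.4)
  det <- predict(x, scene, type = "detections", peak = peak)
  if (nrow(det))
    graphics::points(det$x, det$y, pch = 4, col = "red", lwd = 2)
  graphics::title(sprintf("%d annotated / %d detected",
                          if (inherits(scene, "annotated_scene"))
                            nrow(scene$annotations) else NA_integer_,
                          nrow(det)))
  invisible(x)
}

#' Plot per-epoch loss history
#'
#' @param model a fitted `palm_detector`.
#' @export
plot_history <- function(model) {
  h <- model$history
  if (!nrow(h)) stop("model has no training history", call. = FALSE)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "total loss", main = "training curve")
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(model)
}

#' Save / load a fitted detector as JSON
#'
#' Checkpoints are plain JSON (weights flattened with shapes), with the
#' network configuration, sigma schedule and training history embedded so
#' runs are auditable.
#'
#' @param model a fitted `palm_detector`.
#' @param path destination `.json` file.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "palm_detector"))
  ser <- function(p) {
    if (is.list(p) && !is.null(p$W))
      list(W = as.numeric(p$W), dim = dim(p$W), b = p$b, k = p$k)
    else lapply(p, ser)
  }
  obj <- list(
    format = "buriti-detector-1",
    net = unclass(model$net),
    schedule = unclass(model$schedule),
    control = unclass(model$control[c("learning_rate", "momentum", "epochs",
                                      "batch_size", "seed")]),
    history = model$history,
    n_train = model$n_train,
    params = ser(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(obj$format, "buriti-detector-1"))
  num <- function(x) as.numeric(unlist(x))
  de <- function(p) {
    if (!is.null(p$W)) {
      d <- num(p$dim)
      list(W = matrix(num(p$W), d[1], d[2]), b = num(p$b),
           k = as.integer(num(p$k)))
    } else lapply(p, de)
  }
  net <- network_config(
    channels = num(obj$net$channels), pool_after = num(obj$net$pool_after),
    ppm_bins = num(obj$net$ppm_bins), stages = num(obj$net$stages),
    head_channels = num(obj$net$head_channels),
    bottleneck_channels = num(obj$net$bottleneck_channels),
    share_stage_weights = isTRUE(unlist(obj$net$share_stage_weights)),
    in_channels = num(obj$net$in_channels))
  sched <- make_sigma_schedule(num(obj$schedule$sigma_min),
                               num(obj$schedule$sigma_max),
                               num(obj$schedule$n_stages))
  ctl <- train_control(num(obj$control$learning_rate),
                       num(obj$control$momentum), num(obj$control$epochs),
                       num(obj$control$batch_size),
                       as.integer(num(obj$control$seed)), sched)
  hist <- if (length(obj$history))
    do.call(rbind, lapply(obj$history, function(r) data.frame(
      epoch = as.integer(num(r$epoch)), train_loss = num(r$train_loss),
      val_loss = if (is.null(r$val_loss)) NA_real_ else num(r$val_loss))))
  else data.frame(epoch = integer(0), train_loss = numeric(0),
                  val_loss = numeric(0))
  structure(list(params = de(obj$params), net = net, control = ctl,
                 schedule = sched, history = hist,
                 n_train = num(obj$n_train), n_val = 0L, call = NULL),
            class = "palm_detector")
}
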