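# Point-based evaluation: detections are matched one-to-one to ground-truth
# annotations by minimum-total-distance optimal assignment within a distance
# gate; pooled TP/FP/FN give precision/recall/F1 and per-image count errors
# give the MAE in trees.

# O(n^3) Hungarian algorithm (potentials / shortest augmenting path) on a
# square cost matrix; returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # index j+1 holds column j
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0L) break
    }
  }
  assigned <- integer(n)
  for (j in seq_len(n)) assigned[p[j + 1]] <- j
  assigned
}

#' Match detections to annotations by optimal assignment
#'
#' Finds the one-to-one pairing between detections and annotations that
#' maximises the number of pairs within `max_match_distance` and, among
#' those, minimises the total paired distance (Hungarian algorithm on a
#' padded cost matrix).  Deterministic and order-independent, unlike greedy
#' nearest-first matching.
#'
#' @param detections data frame with `x`, `y` (pixels).
#' @param annotations data frame with `x`, `y` (pixels).
#' @param max_match_distance gate in pixels (> 0): pairs farther apart than
#'   this never match.
#' @return object of class `match_result`: `pairs` (data frame `detection`,
#'   `annotation`, `distance`; 1-based row indices), `n_tp`, `n_fp`,
#'   `n_fn`, `max_match_distance`.
#' @export
match_points <- function(detections, annotations, max_match_distance) {
  stopifnot(max_match_distance > 0)
  det <- as_annotations(detections)
  ann <- as_annotations(annotations)
  nd <- nrow(det); na <- nrow(ann)
  pairs <- data.frame(detection = integer(0), annotation = integer(0),
                      distance = numeric(0))
  if (nd > 0 && na > 0) {
    d <- sqrt(outer(det$x, ann$x, "-")^2 + outer(det$y, ann$y, "-")^2)
    m <- max(nd, na)
    # feasible pairs get cost (distance - M) with M large enough that the
    # minimum-cost assignment always prefers more gated matches; dummy and
    # out-of-gate pairs cost 0.
    M <- max_match_distance * (m + 1) + 1
    cost <- matrix(0, m, m)
    feas <- d <= max_match_distance
    cost[seq_len(nd), seq_len(na)][feas] <- d[feas] - M
    assigned <- solve_assignment(cost)
    for (i in seq_len(nd)) {
      j <- assigned[i]
      if (j <= na && feas[i, j])
        pairs <- rbind(pairs, data.frame(detection = i, annotation = j,
                                         distance = d[i, j]))
    }
  }
  structure(list(pairs = pairs, n_tp = nrow(pairs), n_fp = nd - nrow(pairs),
                 n_fn = na - nrow(pairs),
                 max_match_distance = max_match_distance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("point matching: TP %d, FP %d, FN %d (gate %.3g px)\n",
              x$n_tp, x$n_fp, x$n_fn, x$max_match_distance))
  invisible(x)
}

#' Pool per-image matches into an evaluation report
#'
#' Precision, recall and F1 are micro-averaged over pooled TP/FP/FN; the
#' MAE is the mean over images of the absolute count error (in trees per
#' image).  Degenerate denominators yield 0 by definition.
#'
#' @param matches list of [match_points()] results, one per image.
#' @param counts optional data frame / matrix with per-image `predicted`
#'   and `true` counts; derived from `matches` when omitted.
#' @param image_ids optional identifiers for the per-image table.
#' @return object of class `eval_report` with `mae`, `precision`, `recall`,
#'   `f1` (fractions), pooled `tp`, `fp`, `fn` and a `per_image` table.
#' @export
compute_report <- function(matches, counts = NULL, image_ids = NULL) {
  if (!length(matches)) stop("cannot evaluate an empty image set", call. = FALSE)
  tp <- vapply(matches, function(m) as.numeric(m[["n_tp"]]), 0)
  fp <- vapply(matches, function(m) as.numeric(m[["n_fp"]]), 0)
  fn <- vapply(matches, function(m) as.numeric(m[["n_fn"]]), 0)
  if (is.null(counts))
    counts <- data.frame(predicted = tp + fp, true = tp + fn)
  counts <- as.data.frame(counts)
  stopifnot(nrow(counts) == length(matches))
  if (is.null(image_ids)) image_ids <- seq_along(matches)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(
    list(mae = mean(abs(counts$predicted - counts$true)),
         precision = precision, recall = recall, f1 = f1,
         tp = TP, fp = FP, fn = FN,
         per_image = data.frame(image_id = image_ids, n_tp = tp,
                                n_fp = fp, n_fn = fn)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "detection evaluation over %d images\n  MAE %.3f trees | precision %.1f%% | recall %.1f%% | F1 %.1f%%\n  pooled TP %d / FP %d / FN %d\n",
    nrow(x$per_image), x$mae, 100 * x$precision, 100 * x$recall, 100 * x$f1,
    x$tp, x$fp, x$fn))
  invisible(x)
}

#' Evaluate a trained detector on annotated scenes
#'
#' Runs the detector on each scene, matches detections to the ground truth
#' and pools the metrics.
#'
#' @param model a fitted [palm_detector()].
#' @param scenes list of `annotated_scene`s.
#' @param peak a [peak_params()].
#' @param max_match_distance matching gate in input pixels; defaults to
#'   10 px (about one crown radius, i.e. 1 m at 10 cm GSD).
#' @return an `eval_report`.
#' @export
evaluate_detector <- function(model, scenes, peak = peak_params(),
                              max_match_distance = 10) {
  stopifnot(inherits(model, "palm_detector"))
  matches <- lapply(scenes, function(sc) {
    det <- predict(model, sc, type = "detections", peak = peak)
    match_points(det, sc$annotations, max_match_distance)
  })
  compute_report(matches)
}

#' Hyperparameter sweep over stages and sigma endpoints
#'
#' Trains and evaluates one detector per grid point (Cartesian product of
#' `stages`, `sigma_min`, `sigma_max` values; pairs with
#' `sigma_min > sigma_max` are skipped), evaluating on the validation
#' split.  Configurations that fail to train are recorded as failed rows
#' and the sweep continues.
#'
#' @param scenes a [generate_dataset()] result (uses `$train` and
#'   `$validation`).
#' @param grid list with numeric vectors `stages`, `sigma_min`,
#'   `sigma_max` (each defaulting to the fixed values in `net`/`control`).
#' @param net a [network_config()] used for every run.
#' @param control a [train_control()]; its schedule is overridden per grid
#'   point.
#' @param peak fixed [peak_params()] for evaluation.
#' @param max_match_distance matching gate, pixels.
#' @return data frame sorted by F1 (failed rows last) with columns
#'   `stages`, `sigma_min`, `sigma_max`, `mae`, `precision_pct`,
#'   `recall_pct`, `f1_pct`, `status`.
#' @export
sweep_parameters <- function(scenes, grid, net, control,
                             peak = peak_params(), max_match_distance = 10) {
  stopifnot(inherits(scenes, "scene_dataset"))
  sched0 <- control$schedule
  stages <- grid$stages %||% sched0$n_stages
  smin <- grid$sigma_min %||% sched0$sigma_min
  smax <- grid$sigma_max %||% sched0$sigma_max
  combos <- expand.grid(stages = stages, sigma_min = smin, sigma_max = smax)
  combos <- combos[combos$sigma_min <= combos$sigma_max, , drop = FALSE]
  if (!nrow(combos)) stop("empty sweep grid", call. = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    co <- combos[i, ]
    res <- tryCatch({
      ctl <- control
      ctl$schedule <- make_sigma_schedule(co$sigma_min, co$sigma_max, co$stages)
      cfg <- net
      cfg$stages <- as.integer(co$stages)
      fit <- palm_detector(scenes, net = cfg, control = ctl)
      rep <- evaluate_detector(fit, scenes$validation, peak,
                               max_match_distance)
      data.frame(co, mae = rep$mae, precision_pct = 100 * rep$precision,
                 recall_pct = 100 * rep$recall, f1_pct = 100 * rep$f1,
                 status = "ok")
    }, error = function(e)
      data.frame(co, mae = NA_real_, precision_pct = NA_real_,
                 recall_pct = NA_real_, f1_pct = NA_real_,
                 status = paste("failed:", conditionMessage(e))))
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$f1_pct), -ifelse(is.na(out$f1_pct), -Inf,
                                              out$f1_pct)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a sweep table as CSV
#'
#' @param sweep a [sweep_parameters()] result.
#' @param path destination CSV.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
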