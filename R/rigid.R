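#' Rigid-correction settings
#'
#' @param max_shift largest translation searched, in pixels; `NULL` means
#'   `min(H, W) / 4` (larger shifts are not physiological for head-fixed
#'   imaging).
#' @param levels coarsest pyramid level for hill climbing (default 3, i.e.
#'   1/8 downscale).
#' @param fill out-of-bounds fill policy when resampling, `"edge"`
#'   (replication, the default: avoids dark borders that would bias the
#'   later ECC step) or `"mean"`.
#' @param min_overlap smallest allowed overlap between frame and template at
#'   a candidate shift, as a fraction of the frame area (default 0.25).
#' @return list of settings.
#' @export
rigid_config <- function(max_shift = NULL, levels = 3L, fill = c("edge", "mean"),
                         min_overlap = 0.25) {
  list(max_shift = max_shift, levels = as.integer(levels),
       fill = match.arg(fill), min_overlap = min_overlap)
}

#' Template re-estimation schedule for rigid motion correction
#'
#' The session is split temporally into 5 equal blocks (remainder to the
#' last). The first template T1 is the mean of the middle `template_len`
#' frames; those frames are registered to T1 and averaged again to give the
#' updated template T1', which registers block 3. T2'/T3' are built from
#' the first/last `template_len` corrected frames of block 3 and register
#' blocks 2 and 4; T4'/T5' from the first frames of block 2 and the last
#' frames of block 4 register blocks 1 and 5. Correction thus proceeds
#' bidirectionally from the middle of the session outwards, so each
#' template reflects the slow distortion state of the frames it registers.
#'
#' @param T_ total frame count.
#' @param template_len frames averaged per template (default 2500; clipped
#'   to the available frames).
#' @return object of class `template_schedule` with `n_frames`,
#'   `template_len`, `block_bounds` (5 x 2 matrix of 1-based inclusive
#'   ranges), `mid_window`, and a descriptive `plan` data frame in
#'   execution order.
#' @export
build_schedule <- function(T_, template_len = 2500L) {
  T_ <- as.integer(T_); template_len <- as.integer(template_len)
  if (T_ < 1L) stop("T_ must be >= 1", call. = FALSE)
  base <- T_ %/% 5L
  from <- (0:4) * base + 1L
  to <- c((1:4) * base, T_)
  L <- min(template_len, T_)
  start0 <- (T_ - L) %/% 2L
  mid <- c(start0 + 1L, start0 + L)
  plan <- data.frame(
    template_id = c("T1", "T1'", "T2'", "T3'", "T4'", "T5'"),
    source = c("raw middle window", "corrected middle window",
               "first corrected frames of block 3",
               "last corrected frames of block 3",
               "first corrected frames of block 2",
               "last corrected frames of block 4"),
    target = c("middle window (template build)", "block 3", "block 2",
               "block 4", "block 1", "block 5"),
    stringsAsFactors = FALSE)
  structure(list(n_frames = T_, template_len = template_len,
                 block_bounds = cbind(from = from, to = to),
                 mid_window = mid, plan = plan),
            class = "template_schedule")
}

#' @export
print.template_schedule <- function(x, ...) {
  cat(sprintf("<template_schedule> T=%d, template_len=%d, middle window [%d, %d]\n",
              x$n_frames, x$template_len, x$mid_window[1], x$mid_window[2]))
  print(x$block_bounds)
  invisible(x)
}

# Pearson correlation between template and frame displaced by (sx, sy)
# pixels, evaluated on the valid overlap only; -Inf when the overlap falls
# below min_overlap of the frame area.
shift_corr <- function(frame, template, sx, sy, min_overlap = 0.25) {
  cpp_shift_corr(frame, template, as.integer(sx), as.integer(sy), min_overlap)
}

#' Pyramid hill-climbing estimation of a translational shift
#'
#' Estimates the shift `(dx, dy)` such that `frame(x + dx, y + dy)` best
#' matches `template(x, y)` under Pearson correlation on the valid overlap.
#' Both operands are rank transformed (so the estimate is invariant to
#' monotone intensity remappings), then downscaled to pyramid levels
#' `levels..0` (2x2 block averaging per level, i.e. a 1/8 factor at level
#' 3). At each level a greedy ascent over the 8-neighborhood of integer
#' shifts maximizes the correlation, initialized from twice the previous
#' level's optimum; ties prefer the smaller shift norm, then smaller dy,
#' then dx. A final 1-D parabola fit through the correlation at the level-0
#' optimum and its +/-1 neighbors (independently per axis, offset clamped to
#' (-1, 1)) gives subpixel accuracy.
#'
#' @param frame,template numeric matrices of identical shape.
#' @param max_shift largest |dx|, |dy| searched (default `min(H, W) / 4`).
#' @param rank `"both"` (default) rank transforms both images, `"frame"`
#'   only the frame (template already ranked by the caller), `"none"`.
#' @param levels coarsest pyramid level (default 3).
#' @param min_overlap candidate shifts with less frame/template overlap than
#'   this fraction of the frame area are rejected.
#' @return object of class `translation_estimate`: `dx`, `dy`, `corr` (the
#'   level-0 correlation at the integer optimum), `level_trace`, `failed`.
#' @export
hill_climb_shift <- function(frame, template, max_shift = NULL,
                             rank = c("both", "frame", "none"), levels = 3L,
                             min_overlap = 0.25) {
  rank <- match.arg(rank)
  stopifnot(all(dim(frame) == dim(template)))
  if (is.null(max_shift)) max_shift <- min(dim(frame)) / 4
  if (rank %in% c("both", "frame")) frame <- rank_transform(frame)
  if (rank == "both") template <- rank_transform(template)

  levels <- as.integer(levels)
  while (levels > 0L && min(dim(frame)) / 2^levels < 8) levels <- levels - 1L
  fpyr <- list(frame); tpyr <- list(template)
  if (levels > 0L) for (l in seq_len(levels)) {
    fpyr[[l + 1L]] <- downscale2(fpyr[[l]])
    tpyr[[l + 1L]] <- downscale2(tpyr[[l]])
  }

  s <- c(0L, 0L)
  trace <- list()
  cache <- new.env(hash = TRUE, parent = emptyenv())
  cur_level <- -1L
  corr_at <- function(lv, sx, sy) {
    if (lv != cur_level) { cache <<- new.env(hash = TRUE, parent = emptyenv()); cur_level <<- lv }
    key <- paste0(sx, ",", sy)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- shift_corr(fpyr[[lv + 1L]], tpyr[[lv + 1L]], sx, sy, min_overlap)
      cache[[key]] <- v
    }
    v
  }
  for (lv in seq(levels, 0L)) {
    ms <- ceiling(max_shift / 2^lv)
    s <- pmin(pmax(s, -ms), ms)
    cur <- corr_at(lv, s[1], s[2])
    repeat {
      cand <- expand.grid(dx = s[1] + (-1:1), dy = s[2] + (-1:1))
      best <- s; best_c <- cur
      for (i in seq_len(nrow(cand))) {
        sx <- cand$dx[i]; sy <- cand$dy[i]
        if (abs(sx) > ms || abs(sy) > ms) next
        if (sx == s[1] && sy == s[2]) next
        cc <- corr_at(lv, sx, sy)
        better <- cc > best_c + 1e-15 ||
          (abs(cc - best_c) <= 1e-15 && is.finite(cc) &&
             (sx^2 + sy^2 < best[1]^2 + best[2]^2 ||
                (sx^2 + sy^2 == best[1]^2 + best[2]^2 &&
                   (sy < best[2] || (sy == best[2] && sx < best[1])))))
        if (better) { best <- c(sx, sy); best_c <- cc }
      }
      if (all(best == s)) break
      s <- best; cur <- best_c
    }
    trace[[length(trace) + 1L]] <- c(level = lv, dx = s[1], dy = s[2])
    if (lv > 0L) s <- 2L * s
  }

  c0 <- corr_at(0L, s[1], s[2])
  if (!is.finite(c0)) {
    return(structure(list(dx = 0, dy = 0, corr = shift_corr(frame, template, 0L, 0L, 0),
                          level_trace = trace, failed = TRUE),
                     class = "translation_estimate"))
  }
  subpix <- function(cm, c0, cp) {
    if (!is.finite(cm) || !is.finite(cp)) return(0)
    a2 <- cm + cp - 2 * c0
    if (a2 >= 0) return(0)
    min(max((cm - cp) / (2 * a2), -1 + 1e-9), 1 - 1e-9)
  }
  ddx <- subpix(corr_at(0L, s[1] - 1L, s[2]), c0, corr_at(0L, s[1] + 1L, s[2]))
  ddy <- subpix(corr_at(0L, s[1], s[2] - 1L), c0, corr_at(0L, s[1], s[2] + 1L))
  structure(list(dx = s[1] + ddx, dy = s[2] + ddy, corr = c0,
                 level_trace = trace, failed = FALSE),
            class = "translation_estimate")
}

#' Apply a (possibly subpixel) translation to a frame
#'
#' Resamples the frame at the shifted grid by bilinear interpolation:
#' `out(x, y) = frame(x + dx, y + dy)`, i.e. the correction of a shift
#' estimated by [hill_climb_shift()]. Out-of-bounds samples follow the fill
#' policy (edge replication by default).
#'
#' @param frame numeric matrix.
#' @param dx,dy shift in pixels; must satisfy `|dx|, |dy| < min(H, W) / 2`.
#' @param fill `"edge"` or `"mean"`.
#' @return shifted matrix of the same size.
#' @export
apply_shift <- function(frame, dx, dy, fill = c("edge", "mean")) {
  fill <- match.arg(fill)
  if (max(abs(c(dx, dy))) >= min(dim(frame)) / 2) {
    stop("shift too large relative to frame size", call. = FALSE)
  }
  if (dx == 0 && dy == 0) return(frame)
  p <- c(1, 0, dx, 0, 1, dy)
  w <- cpp_warp_affine(frame, p, nrow(frame), ncol(frame), 0, 0,
                       fill == "edge", FALSE)
  out <- w$image
  if (fill == "mean" && !all(w$support)) out[!w$support] <- mean(frame)
  out
}

#' Rigid motion correction of a whole session
#'
#' Executes the template re-estimation plan of [build_schedule()]: the
#' middle window is registered to its own raw mean (T1) and re-averaged
#' into T1', which registers block 3; T2'/T3' (from the corrected edges of
#' block 3) register blocks 2 and 4; T4'/T5' register blocks 1 and 5.
#' Templates are plain (unranked) mean images of already-corrected frames;
#' the rank transform is applied to both operands inside the shift
#' estimation. Frame count and order are never altered.
#'
#' @param stack a [frame_stack()].
#' @param schedule a [build_schedule()] for `n_frames(stack)` (default:
#'   built here with a 2500-frame template).
#' @param config a [rigid_config()].
#' @return list with `stack` (corrected, `origin = "rigid"`) and
#'   `estimates` (one `translation_estimate` per frame). Errors if more
#'   than half the frames fail shift estimation.
#' @export
rigid_correct_session <- function(stack, schedule = NULL, config = rigid_config()) {
  T_ <- n_frames(stack)
  if (is.null(schedule)) schedule <- build_schedule(T_)
  if (schedule$n_frames != T_) stop("schedule was built for a different frame count", call. = FALSE)
  d <- dim(stack$frames)
  if (is.null(config$max_shift)) config$max_shift <- min(d[1], d[2]) / 4
  out <- stack$frames
  estimates <- vector("list", T_)

  correct_range <- function(idx, template) {
    tr <- rank_transform(template)
    for (t in idx) {
      est <- hill_climb_shift(stack$frames[, , t], tr,
                              max_shift = config$max_shift, rank = "frame",
                              levels = config$levels,
                              min_overlap = config$min_overlap)
      out[, , t] <<- apply_shift(stack$frames[, , t], est$dx, est$dy,
                                 fill = config$fill)
      estimates[[t]] <<- est
    }
  }

  bb <- schedule$block_bounds
  mid <- schedule$mid_window
  # T1 -> register middle window -> T1'
  T1 <- mean_frames(stack, mid[1], mid[2])
  correct_range(mid[1]:mid[2], T1)
  T1p <- rowMeans(out[, , mid[1]:mid[2], drop = FALSE], dims = 2L)

  block_idx <- function(b) if (bb[b, 1] > bb[b, 2]) integer(0) else bb[b, 1]:bb[b, 2]
  tpl_from_corrected <- function(idx, take = c("first", "last")) {
    take <- match.arg(take)
    L <- min(schedule$template_len, length(idx))
    sel <- if (take == "first") idx[seq_len(L)] else idx[seq.int(length(idx) - L + 1L, length(idx))]
    rowMeans(out[, , sel, drop = FALSE], dims = 2L)
  }

  if (nrow(bb) == 5L && all(bb[, 2] >= bb[, 1])) {
    correct_range(block_idx(3L), T1p)
    T2p <- tpl_from_corrected(block_idx(3L), "first")
    T3p <- tpl_from_corrected(block_idx(3L), "last")
    correct_range(block_idx(2L), T2p)
    correct_range(block_idx(4L), T3p)
    T4p <- tpl_from_corrected(block_idx(2L), "first")
    T5p <- tpl_from_corrected(block_idx(4L), "last")
    correct_range(block_idx(1L), T4p)
    correct_range(block_idx(5L), T5p)
  } else {
    # degenerate tiny session: a single pass with T1'
    correct_range(seq_len(T_), T1p)
  }

  flagged <- vapply(estimates, function(e) isTRUE(e$failed), logical(1))
  if (mean(flagged) > 0.5) {
    stop("rigid correction failed on more than half of the frames", call. = FALSE)
  }
  list(stack = frame_stack(out, frame_rate_hz = stack$frame_rate_hz, origin = "rigid"),
       estimates = estimates)
}

#' Write per-frame shift estimates as CSV
#'
#' @param estimates the `estimates` element of [rigid_correct_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(estimates, path) {
  df <- data.frame(
    frame_index = seq_along(estimates),
    dx = vapply(estimates, function(e) e$dx, numeric(1)),
    dy = vapply(estimates, function(e) e$dy, numeric(1)),
    corr = vapply(estimates, function(e) e$corr, numeric(1)),
    flagged = vapply(estimates, function(e) isTRUE(e$failed), logical(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
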