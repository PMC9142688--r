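#' ECC optimizer settings
#'
#' Tolerances and guards for [ecc_maximize()]. The iteration stops when the
#' ECC improvement falls below `tol_rho`, the parameter update norm falls
#' below `tol_p`, or `max_iter` is reached. A result is flagged `converged`
#' only if its final ECC reaches `rho_floor` and the determinant of the 2x2
#' linear part stays within `[det_lo, det_hi]` (degeneracy guard). Images
#' are pre-smoothed with a Gaussian of `smooth_sigma` pixels before the
#' gradients are taken, which stabilizes the step on photon-noise images.
#'
#' @param max_iter maximum iterations (default 50).
#' @param tol_rho ECC-improvement stopping tolerance (default 1e-6).
#' @param tol_p parameter-update-norm stopping tolerance (default 1e-8).
#' @param rho_floor minimum final ECC for a converged result (default 0.3).
#' @param det_lo,det_hi accepted range for the linear-part determinant.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (default 1).
#' @param min_support minimum number of valid pixels (default 16).
#' @return a list of settings.
#' @export
ecc_config <- function(max_iter = 50L, tol_rho = 1e-6, tol_p = 1e-8,
                       rho_floor = 0.3, det_lo = 0.2, det_hi = 5,
                       smooth_sigma = 1, min_support = 16L) {
  list(max_iter = as.integer(max_iter), tol_rho = tol_rho, tol_p = tol_p,
       rho_floor = rho_floor, det_lo = det_lo, det_hi = det_hi,
       smooth_sigma = smooth_sigma, min_support = as.integer(min_support))
}

#' Enhanced correlation coefficient between two images
#'
#' Zero-centers both pixel vectors over the support and returns their
#' normalized inner product
#' `rho = (t - mean t) . (w - mean w) / (||t - mean t|| ||w - mean w||)`.
#' The associated alignment loss is `L = 2 - 2 rho` by construction, and the
#' score is invariant to any gain/bias change `w -> a w + b` with `a > 0`.
#'
#' @param template,warped numeric matrices of equal size.
#' @param support logical matrix marking valid pixels (default: all).
#' @return ECC in `[-1, 1]`; 0 with attribute `degenerate = TRUE` if either
#'   operand has zero variance on the support.
#' @export
ecc_score <- function(template, warped, support = NULL) {
  if (is.null(support)) support <- matrix(TRUE, nrow(template), ncol(template))
  if (sum(support) < 16L) stop("support must contain at least 16 pixels", call. = FALSE)
  tv <- template[support]
  wv <- warped[support]
  if (!all(is.finite(tv)) || !all(is.finite(wv))) {
    stop("non-finite values on support", call. = FALSE)
  }
  tv <- tv - mean(tv)
  wv <- wv - mean(wv)
  nt <- sqrt(sum(tv^2)); nw <- sqrt(sum(wv^2))
  if (nt == 0 || nw == 0) return(structure(0, degenerate = TRUE))
  sum(tv * wv) / (nt * nw)
}

#' Warp an image by an affine or Euclidean transform
#'
#' Inverse-mapping resampling: every output pixel takes the bilinearly
#' interpolated value of the input at the transform-mapped coordinate
#' `(x', y') = A (x, y, 1)'`. The support mask marks output pixels whose
#' sample lies inside the input; unsupported pixels are 0.
#'
#' @param image numeric matrix.
#' @param transform an [affine_matrix()] or [euclidean_matrix()] (or 3x3
#'   matrix); must be invertible.
#' @param out_shape integer length-2 `(H, W)` of the output (default: input
#'   shape).
#' @param interp `"bilinear"` or `"nearest"`.
#' @return list with `image` (warped matrix) and `support` (logical matrix).
#' @export
warp_image <- function(image, transform, out_shape = dim(image),
                       interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  m <- if (is.matrix(transform)) transform else as.matrix(transform)
  if (abs(det(m)) < 1e-12) stop("singular transform", call. = FALSE)
  p <- c(m[1, ], m[2, ])
  cpp_warp_affine(image, p, out_shape[1], out_shape[2], 0, 0, FALSE,
                  interp == "nearest")
}

# parameter vector <-> transform object
ecc_pvec <- function(transform, model) {
  if (model == "euclidean") c(transform$theta, transform$e1, transform$e2)
  else transform$params
}

ecc_pvec_to_transform <- function(p, model) {
  if (model == "euclidean") euclidean_matrix(p[1], p[2], p[3])
  else affine_matrix(p)
}

ecc_p6 <- function(p, model) {
  if (model == "euclidean") {
    c(cos(p[1]), -sin(p[1]), p[2], sin(p[1]), cos(p[1]), p[3])
  } else p
}

#' Gradient-based ECC maximization
#'
#' Iterative forward-additive maximization of the enhanced correlation
#' coefficient between a template and a warped target over affine (6
#' parameters) or Euclidean (theta, e1, e2) transforms. Each iteration
#' warps the (pre-smoothed) target and its spatial gradients to the current
#' estimate, builds the Jacobian of pixel values with respect to the
#' parameters on the valid support, solves the closed-form ECC update step,
#' and re-evaluates rho; the best iterate is kept and returned if a step
#' ever decreases rho. The pipeline always feeds locally normalized images
#' (see [local_normalize()]), so rho reflects geometry, not brightness.
#'
#' @param template,target numeric matrices of equal size.
#' @param model `"affine"` or `"euclidean"`.
#' @param init initial transform (default identity).
#' @param config an [ecc_config()].
#' @param mask optional logical matrix marking the valid pixels of
#'   `target` (its own domain); it is warped alongside the target every
#'   iteration, so invalid regions (e.g. borders introduced by an earlier
#'   resampling) never contribute to the objective.
#' @return object of class `ecc_result`: `transform`, `rho` (final ECC of
#'   the raw images at the returned transform), `iterations`, `converged`,
#'   `rho_trace` (best-so-far internal ECC per iteration), `failed`.
#' @export
ecc_maximize <- function(template, target, model = c("affine", "euclidean"),
                         init = NULL, config = ecc_config(), mask = NULL) {
  model <- match.arg(model)
  stopifnot(all(dim(template) == dim(target)))
  if (is.null(init)) {
    init <- if (model == "euclidean") euclidean_matrix() else affine_matrix()
  }
  H <- nrow(template); W <- ncol(template)
  mask_num <- if (is.null(mask)) NULL else mask * 1

  tpl_s <- gaussian_smooth(template, config$smooth_sigma)
  tgt_s <- gaussian_smooth(target, config$smooth_sigma)
  gr <- image_gradients(tgt_s)

  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), times = W), H, W)

  p <- ecc_pvec(init, model)
  rho_trace <- numeric(0)
  iterations <- 0L
  failed <- FALSE

  warped_support <- function(p6, base_support) {
    if (is.null(mask_num)) return(base_support)
    mv <- cpp_warp_affine(mask_num, p6, H, W, 0, 0, FALSE, FALSE)
    base_support & (mv$image > 0.999)
  }

  eval_state <- function(p) {
    p6 <- ecc_p6(p, model)
    w <- cpp_warp_affine(tgt_s, p6, H, W, 0, 0, FALSE, FALSE)
    sup <- warped_support(p6, w$support)
    if (sum(sup) < config$min_support) return(NULL)
    iw <- w$image[sup]
    tv <- tpl_s[sup]
    iw <- iw - mean(iw); tv <- tv - mean(tv)
    ni <- sqrt(sum(iw^2)); nt <- sqrt(sum(tv^2))
    if (ni == 0 || nt == 0) return(NULL)
    list(sup = sup, iw = iw, tv = tv, rho = sum(iw * tv) / (ni * nt), p6 = p6)
  }

  st <- eval_state(p)
  if (is.null(st)) failed <- TRUE else rho_trace <- st$rho
  while (!failed && iterations < config$max_iter) {
    iterations <- iterations + 1L
    gxw <- cpp_warp_affine(gr$gx, st$p6, H, W, 0, 0, FALSE, FALSE)$image
    gyw <- cpp_warp_affine(gr$gy, st$p6, H, W, 0, 0, FALSE, FALSE)$image
    gxv <- gxw[st$sup]; gyv <- gyw[st$sup]
    xv <- X[st$sup];   yv <- Y[st$sup]
    G <- if (model == "affine") {
      cbind(gxv * xv, gxv * yv, gxv, gyv * xv, gyv * yv, gyv)
    } else {
      th <- p[1]
      jth <- gxv * (-sin(th) * xv - cos(th) * yv) +
             gyv * ( cos(th) * xv - sin(th) * yv)
      cbind(jth, gxv, gyv)
    }
    G <- sweep(G, 2L, colMeans(G))               # work in zero-mean subspace
    if (!all(is.finite(G))) { failed <- TRUE; break }
    Hm <- crossprod(G)
    sol <- tryCatch(solve(Hm, cbind(crossprod(G, st$iw), crossprod(G, st$tv))),
                    error = function(e) NULL)
    if (is.null(sol)) break
    Hi <- sol[, 1]; Ht <- sol[, 2]
    num <- sum(st$iw^2) - sum(crossprod(G, st$iw) * Hi)
    den <- sum(st$tv * st$iw) - sum(crossprod(G, st$tv) * Hi)
    if (!is.finite(num) || !is.finite(den) || den <= 0) break
    lambda <- num / den
    dp <- as.numeric(lambda * Ht - Hi)
    if (!all(is.finite(dp))) { failed <- TRUE; break }

    # backtracking: accept the step only if it does not decrease rho,
    # halving it up to 5 times; otherwise we are at a local optimum
    alpha <- 1
    st_new <- NULL
    for (h in 0:5) {
      p_try <- p + alpha * dp
      dtr <- linear_det(ecc_pvec_to_transform(p_try, model))
      cand <- if (dtr < 0.05 || dtr > 20) NULL else eval_state(p_try)
      if (!is.null(cand) && cand$rho >= st$rho - 1e-13) {
        p <- p_try; st_new <- cand; break
      }
      alpha <- alpha / 2
    }
    if (is.null(st_new)) break
    gain <- st_new$rho - st$rho
    st <- st_new
    rho_trace <- c(rho_trace, st$rho)
    if (gain < config$tol_rho) break
    if (sqrt(sum((alpha * dp)^2)) < config$tol_p) break
  }
  best_p <- p

  final <- ecc_pvec_to_transform(best_p, model)
  mfin <- as.matrix(final)
  p6_fin <- c(mfin[1, ], mfin[2, ])
  w_fin <- cpp_warp_affine(target, p6_fin, H, W, 0, 0, FALSE, FALSE)
  sup_fin <- warped_support(p6_fin, w_fin$support)
  rho_raw <- if (sum(sup_fin) >= config$min_support) {
    as.numeric(ecc_score(template, w_fin$image, sup_fin))
  } else NA_real_

  # never return something worse than the starting point on the raw images
  minit <- as.matrix(init)
  p6_init <- c(minit[1, ], minit[2, ])
  w_init <- cpp_warp_affine(target, p6_init, H, W, 0, 0, FALSE, FALSE)
  sup_init <- warped_support(p6_init, w_init$support)
  rho_init <- if (sum(sup_init) >= config$min_support) {
    as.numeric(ecc_score(template, w_init$image, sup_init))
  } else NA_real_
  if (is.na(rho_raw) || (!is.na(rho_init) && rho_raw < rho_init)) {
    final <- init
    rho_raw <- rho_init
    failed <- TRUE
  }

  dtr <- linear_det(final)
  converged <- !failed && !is.na(rho_raw) && rho_raw >= config$rho_floor &&
    dtr >= config$det_lo && dtr <= config$det_hi
  structure(list(transform = final, rho = rho_raw, iterations = iterations,
                 converged = converged, rho_trace = rho_trace,
                 failed = failed, model = model),
            class = "ecc_result")
}

#' @export
print.ecc_result <- function(x, ...) {
  cat(sprintf("<ecc_result> model=%s rho=%.4f iterations=%d converged=%s\n",
              x$model, x$rho, x$iterations, x$converged))
  invisible(x)
}

#' Pyramid-initialized ECC maximization
#'
#' Runs [ecc_maximize()] from the coarsest pyramid level (default level 3,
#' a 1/8 downscale by repeated 2x2 block averaging) down to the original
#' resolution, doubling the translation components between levels and
#' carrying the remaining parameters unchanged. This makes the gradient
#' step robust to large displacements (tens of pixels), as arise between
#' imaging sessions. Levels are dropped automatically if the images would
#' fall below 16 pixels on a side.
#'
#' @inheritParams ecc_maximize
#' @param levels coarsest pyramid level (default 3).
#' @return the level-0 `ecc_result`, with attribute `level_rhos`.
#' @export
ecc_maximize_pyramid <- function(template, target, model = c("euclidean", "affine"),
                                 init = NULL, levels = 3L, config = ecc_config(),
                                 mask = NULL) {
  model <- match.arg(model)
  if (is.null(init)) {
    init <- if (model == "euclidean") euclidean_matrix() else affine_matrix()
  }
  levels <- as.integer(levels)
  while (levels > 0L && min(dim(template)) / 2^levels < 16) levels <- levels - 1L

  tpls <- list(template); tgts <- list(target); masks <- list(mask)
  if (levels > 0L) {
    for (l in seq_len(levels)) {
      tpls[[l + 1L]] <- downscale2(tpls[[l]])
      tgts[[l + 1L]] <- downscale2(tgts[[l]])
      masks[l + 1L] <- if (is.null(mask)) list(NULL) else {
        list(downscale2(masks[[l]] * 1) > 0.999)
      }
    }
  }

  scale_p <- function(p, f, model) {
    if (model == "euclidean") c(p[1], p[2] * f, p[3] * f)
    else c(p[1], p[2], p[3] * f, p[4], p[5], p[6] * f)
  }
  p <- scale_p(ecc_pvec(init, model), 1 / 2^levels, model)
  res <- NULL
  level_rhos <- numeric(0)
  for (l in seq(levels, 0L)) {
    res <- ecc_maximize(tpls[[l + 1L]], tgts[[l + 1L]], model = model,
                        init = ecc_pvec_to_transform(p, model),
                        config = config, mask = masks[[l + 1L]])
    level_rhos <- c(level_rhos, res$rho)
    p <- ecc_pvec(res$transform, model)
    if (l > 0L) p <- scale_p(p, 2, model)
  }
  attr(res, "level_rhos") <- level_rhos
  res
}
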