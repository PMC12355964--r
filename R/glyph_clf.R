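# Synthetic glyph disambiguation: distinguishing the micro sign (mu) from a
# lower-case "m" in printed units, where a misread shifts a concentration by
# a factor of 1000. The renderer draws parametric stroke templates (the
# "fonts" are stylistic parameter sets: stroke width, slant, proportions)
# and the classifier is a small multinomial network trained with Adam.
# Everything is synthetic and deterministic for a fixed seed.

GLYPH_SIZE <- 32L

# run code under a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- stroke templates ----------------------------------------------------

# polylines in the unit square, y increasing downward; baseline at y = 0.85
arc_pts <- function(cx, cy, rx, ry, from, to, n = 24) {
  t <- seq(from, to, length.out = n)
  cbind(cx + rx * cos(t), cy + ry * sin(t))
}
seg_pts <- function(x0, y0, x1, y1, n = 24) {
  cbind(seq(x0, x1, length.out = n), seq(y0, y1, length.out = n))
}

# y increases downward: arcs with t in (pi, 2pi) bow upward (arches of m/n),
# t in (0, pi) bow downward (bowls of u/mu)
glyph_strokes <- function(glyph) {
  switch(glyph,
    m = list(
      seg_pts(0.15, 0.40, 0.15, 0.85),
      arc_pts(0.30, 0.52, 0.15, 0.12, pi, 2 * pi),
      seg_pts(0.45, 0.52, 0.45, 0.85),
      arc_pts(0.60, 0.52, 0.15, 0.12, pi, 2 * pi),
      seg_pts(0.75, 0.52, 0.75, 0.85)
    ),
    mu = list(
      seg_pts(0.22, 0.40, 0.22, 0.78),
      arc_pts(0.44, 0.64, 0.22, 0.16, 0, pi),    # bottom bowl
      seg_pts(0.66, 0.40, 0.66, 0.85),
      seg_pts(0.22, 0.78, 0.15, 1.00)            # descender below baseline
    ),
    u = list(
      seg_pts(0.25, 0.40, 0.25, 0.64),
      arc_pts(0.45, 0.64, 0.20, 0.16, 0, pi),    # bottom bowl
      seg_pts(0.65, 0.40, 0.65, 0.85)
    ),
    n = list(
      seg_pts(0.25, 0.40, 0.25, 0.85),
      arc_pts(0.45, 0.55, 0.20, 0.15, pi, 2 * pi),
      seg_pts(0.65, 0.55, 0.65, 0.85)
    ),
    rn = list(
      seg_pts(0.12, 0.40, 0.12, 0.85),
      arc_pts(0.22, 0.50, 0.10, 0.10, pi, 1.6 * pi),
      seg_pts(0.42, 0.40, 0.42, 0.85),
      arc_pts(0.58, 0.55, 0.16, 0.15, pi, 2 * pi),
      seg_pts(0.74, 0.55, 0.74, 0.85)
    ),
    stop("unknown glyph template: ", glyph)
  )
}

#' Default synthetic glyph "fonts"
#'
#' Each font is a stylistic parameter set (stroke width in pixels, shear
#' slant, vertical scale) applied to the stroke templates.
#'
#' @return a named list of font parameter lists.
#' @export
default_glyph_fonts <- function() {
  list(
    regular = list(lw = 1.3, slant = 0.00, yscale = 1.00),
    bold    = list(lw = 2.1, slant = 0.00, yscale = 1.00),
    italic  = list(lw = 1.3, slant = 0.18, yscale = 1.00),
    narrow  = list(lw = 1.1, slant = 0.00, yscale = 0.90)
  )
}

rasterize_strokes <- function(strokes, lw = 1.4, slant = 0, yscale = 1,
                              rot = 0, dx = 0, dy = 0, size = GLYPH_SIZE) {
  # template polylines are pre-densified (point spacing well under the
  # stroke sigma), so the points can be stamped directly
  pts <- do.call(rbind, strokes)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  # affine: shear, vertical scale, rotation about glyph center, jitter
  x <- pts[, 1] - 0.45; y <- (pts[, 2] - 0.62) * yscale
  x <- x + slant * (-y)
  xr <- x * cos(rot) - y * sin(rot)
  yr <- x * sin(rot) + y * cos(rot)
  px <- (xr + 0.45 + dx) * (size - 1) + 1
  py <- (yr + 0.62 + dy) * (size - 1) + 1
  img <- matrix(0, size, size)
  sigma <- lw / 1.8
  r <- ceiling(sigma * 2.5)
  for (k in seq_along(px)) {
    cx <- px[k]; cy <- py[k]
    i0 <- max(1L, floor(cy - r)); i1 <- min(size, ceiling(cy + r))
    j0 <- max(1L, floor(cx - r)); j1 <- min(size, ceiling(cx + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dist2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
    patch <- exp(-dist2 / (2 * sigma^2))
    img[ii, jj] <- pmax(img[ii, jj], patch)
  }
  img
}

#' Render a balanced synthetic glyph sample set
#'
#' Draws `n_per_class` samples for each of the three classes `m`, `mu` and
#' `other` (the confusable set: u, n, rn). Augmentations: rotation up to
#' +/- 5 degrees, sub-pixel translation, additive Gaussian noise at the
#' given levels. Deterministic for a fixed seed.
#'
#' @param n_per_class samples per class (>= 1).
#' @param fonts list of font parameter sets; at least one required.
#' @param noise_levels Gaussian noise standard deviations to sample from.
#' @param seed RNG seed.
#' @return a tibble with list-column `pixels` (32 x 32 matrices in \[0, 1\]),
#'   `label`, `font`, `noise`, `seed`.
#' @export
render_glyphs <- function(n_per_class, fonts = default_glyph_fonts(),
                          noise_levels = c(0, 0.05, 0.1), seed = 1L) {
  stopifnot(n_per_class >= 1L)
  if (!length(fonts)) {
    stop("no usable glyph font: supply at least one font parameter set ",
         "(see default_glyph_fonts())")
  }
  other_pool <- c("u", "n", "rn")
  with_local_seed(seed, {
    rows <- list()
    for (label in c("m", "mu", "other")) {
      for (i in seq_len(n_per_class)) {
        glyph <- if (label == "other") other_pool[sample.int(3L, 1L)] else label
        fi <- sample.int(length(fonts), 1L)
        f <- fonts[[fi]]
        noise <- noise_levels[sample.int(length(noise_levels), 1L)]
        rot <- runif(1, -5, 5) * pi / 180
        img <- rasterize_strokes(
          glyph_strokes(glyph), lw = f$lw, slant = f$slant,
          yscale = f$yscale, rot = rot,
          dx = runif(1, -0.03, 0.03), dy = runif(1, -0.03, 0.03)
        )
        if (noise > 0) {
          img <- img + matrix(rnorm(length(img), 0, noise),
                              nrow(img), ncol(img))
        }
        img <- pmin(pmax(img, 0), 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pixels = list(img), label = label,
          font = names(fonts)[fi] %||% as.character(fi),
          noise = noise, seed = as.integer(seed)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Glyph training configuration
#'
#' @param epochs training epochs (>= 1, default 10).
#' @param learning_rate Adam step size (default 0.001).
#' @param optimizer only `"adam"` is implemented.
#' @param hidden hidden-layer width (default 64).
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed for initialization and shuffling.
#' @return a list of class `glyph_train_config`.
#' @export
glyph_train_config <- function(epochs = 10L, learning_rate = 0.001,
                               optimizer = "adam", hidden = 64L,
                               batch_size = 32L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "glyph_train_config")
}

samples_to_xy <- function(samples) {
  X <- t(vapply(samples$pixels, function(p) as.numeric(p),
                numeric(GLYPH_SIZE * GLYPH_SIZE)))
  y <- as.character(samples$label)
  list(X = X, y = y)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the glyph classifier
#'
#' A single-hidden-layer network (ReLU, softmax output) trained with
#' minibatch Adam on the flattened 32 x 32 images. The architecture is
#' deliberately small enough to train on a desktop CPU in seconds; swap in
#' any other classifier honoring `classify(pixels)` if a deeper model is
#' wanted.
#'
#' @param samples a sample tibble from [render_glyphs()].
#' @param cfg a [glyph_train_config()].
#' @return a list of class `glyph_model`.
#' @export
train_glyph_model <- function(samples, cfg = glyph_train_config()) {
  xy <- samples_to_xy(samples)
  classes <- sort(unique(xy$y))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  Y <- outer(xy$y, classes, "==") * 1
  n <- nrow(xy$X); d <- ncol(xy$X); k <- length(classes); h <- cfg$hidden
  with_local_seed(cfg$seed, {
    W1 <- matrix(rnorm(d * h, 0, sqrt(2 / d)), d, h); b1 <- rep(0, h)
    W2 <- matrix(rnorm(h * k, 0, sqrt(2 / h)), h, k); b2 <- rep(0, k)
    ms <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
    vs <- ms
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- xy$X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        m <- nrow(Xb)
        H <- pmax(Xb %*% W1 + matrix(b1, m, h, byrow = TRUE), 0)
        P <- softmax_rows(H %*% W2 + matrix(b2, m, k, byrow = TRUE))
        dZ2 <- (P - Yb) / m
        gW2 <- t(H) %*% dZ2; gb2 <- colSums(dZ2)
        dH <- dZ2 %*% t(W2); dH[H <= 0] <- 0
        gW1 <- t(Xb) %*% dH; gb1 <- colSums(dH)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        t <- t + 1
        for (nm in names(params)) {
          ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * grads[[nm]]
          vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- ms[[nm]] / (1 - beta1^t)
          vhat <- vs[[nm]] / (1 - beta2^t)
          params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        W1 <- params$W1; b1 <- params$b1; W2 <- params$W2; b2 <- params$b2
      }
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   classes = classes, config = cfg),
              class = "glyph_model")
  })
}

#' Classify glyph images
#'
#' @param model a `glyph_model`.
#' @param pixels one 32 x 32 matrix, or a list of them.
#' @return for one image, `list(label, probs)` with probabilities summing to
#'   1; for a list, a tibble with `label` and a probability column per class.
#' @export
predict_glyph <- function(model, pixels) {
  single <- is.matrix(pixels)
  plist <- if (single) list(pixels) else pixels
  X <- t(vapply(plist, as.numeric, numeric(GLYPH_SIZE * GLYPH_SIZE)))
  m <- nrow(X); h <- length(model$b1); k <- length(model$b2)
  H <- pmax(X %*% model$W1 + matrix(model$b1, m, h, byrow = TRUE), 0)
  P <- softmax_rows(H %*% model$W2 + matrix(model$b2, m, k, byrow = TRUE))
  colnames(P) <- model$classes
  labels <- model$classes[max.col(P, ties.method = "first")]
  if (single) {
    list(label = labels[1], probs = P[1, ])
  } else {
    dplyr::bind_cols(tibble::tibble(label = labels), tibble::as_tibble(P))
  }
}

#' Evaluate a glyph model on labeled samples
#'
#' @param model a `glyph_model`.
#' @param samples labeled sample tibble.
#' @return `list(accuracy, confusion)` where `confusion` has true labels as
#'   rows and predicted labels as columns over the model's classes.
#' @export
evaluate_glyph_model <- function(model, samples) {
  if (!nrow(samples)) stop("cannot evaluate on an empty sample list")
  pred <- predict_glyph(model, samples$pixels)$label
  truth <- as.character(samples$label)
  classes <- model$classes
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  list(accuracy = mean(pred == truth),
       confusion = unclass(confusion))
}

#' Serialize / restore a glyph model (single JSON file, config embedded)
#'
#' @param model a `glyph_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_glyph_model <- function(model, path) {
  out <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              classes = model$classes, config = unclass(model$config))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Persist glyph samples as PNG images plus a labels CSV
#'
#' @param samples tibble from [render_glyphs()].
#' @param dir output directory (created if needed).
#' @return the labels CSV path, invisibly.
#' @export
write_glyph_samples <- function(samples, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required to write PNG samples")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("glyph_%05d.png", seq_len(nrow(samples)))
  for (i in seq_len(nrow(samples))) {
    png::writePNG(samples$pixels[[i]], file.path(dir, files[i]))
  }
  labels <- tibble::tibble(file = files, label = samples$label,
                           font = samples$font, noise = samples$noise)
  out <- file.path(dir, "labels.csv")
  readr::write_csv(labels, out)
  invisible(out)
}

#' @rdname write_glyph_model
#' @export
read_glyph_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(glyph_train_config, as.list(x$config))
  structure(list(W1 = x$W1, b1 = as.numeric(x$b1), W2 = x$W2,
                 b2 = as.numeric(x$b2), classes = as.character(x$classes),
                 config = cfg),
            class = "glyph_model")
}
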