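#' Spatiotemporal network configuration
#'
#' Configures the two-slice spatiotemporal classifier. Each slice is processed
#' by a submodel with identical architecture (independent weights): a spatial
#' feature extractor applied to every frame with shared weights produces a
#' `n_frames x feature_dim` matrix; temporal feature extraction then runs a
#' global pathway (1D convolution, `temporal_filters` filters, kernel
#' `kernel_global`, global max pooling over time) and a local pathway (kernel
#' `kernel_local`), whose outputs are concatenated and passed through a dense
#' layer with `dense_units` units. The two slice vectors are concatenated,
#' fully connected, and squashed by a sigmoid into one probability that the
#' sample is large-core.
#'
#' Backbones: `"vgg19"` is the VGG19 convolutional stack (feature dim 512,
#' single-channel frames replicated to its 3 input channels, global average
#' pooling over the final feature maps); weights are randomly initialized
#' unless a pretrained weight list is supplied at build time. `"tiny"` is a
#' desk-scale backbone: a fixed average-pooling stem (default factor 8)
#' followed by three conv(3x3)-ReLU-maxpool blocks with 16/32/`feature_dim`
#' channels and global average pooling; `feature_dim` defaults to 64. The
#' stem reflects that the discriminative CTP signal is regional enhancement
#' dynamics rather than fine anatomy, and it keeps single-CPU training
#' budgets; lower the factor for higher working resolution.
#'
#' @param backbone `"tiny"` or `"vgg19"`.
#' @param feature_dim Per-frame spatial feature length (tiny backbone only;
#'   vgg19 is fixed at 512).
#' @param n_frames Frames per slice (32 on the standard grid).
#' @param input_px In-plane input size in pixels.
#' @param n_slices Number of slice submodels.
#' @param temporal_filters Filters of each temporal 1D convolution.
#' @param kernel_global,kernel_local Temporal kernel sizes (global > local).
#' @param dense_units Units of the per-slice dense layer.
#' @param pathways `"both"`, `"global_only"` or `"local_only"` (ablations).
#' @param stem_pool Fixed average-pooling factor in front of the tiny
#'   backbone's first convolution.
#' @param lr Adam learning rate.
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(backbone = c("tiny", "vgg19"), feature_dim = 64,
                         n_frames = 32, input_px = 128, n_slices = 2,
                         temporal_filters = 3, kernel_global = 11,
                         kernel_local = 3, dense_units = 32,
                         pathways = c("both", "global_only", "local_only"),
                         stem_pool = 8, lr = 1e-3, seed = 1L) {
  backbone <- match.arg(backbone)
  pathways <- match.arg(pathways)
  if (kernel_global <= kernel_local)
    stop("'kernel_global' must exceed 'kernel_local'")
  if (backbone == "vgg19") feature_dim <- 512L
  structure(list(backbone = backbone, feature_dim = as.integer(feature_dim),
                 n_frames = as.integer(n_frames),
                 input_px = as.integer(input_px),
                 n_slices = as.integer(n_slices),
                 temporal_filters = as.integer(temporal_filters),
                 kernel_global = as.integer(kernel_global),
                 kernel_local = as.integer(kernel_local),
                 dense_units = as.integer(dense_units), pathways = pathways,
                 stem_pool = as.integer(stem_pool), lr = lr,
                 seed = as.integer(seed)),
            class = "model_config")
}

# backbone layer plan: stem pooling factor, input channels, conv channel list
backbone_plan <- function(config) {
  if (config$backbone == "tiny") {
    list(stem_pool = config$stem_pool, in_channels = 1L,
         blocks = list(16L, 32L, config$feature_dim))
  } else {
    # VGG19 convolutional stack; each element is one max-pooled block
    list(stem_pool = 1L, in_channels = 3L,
         blocks = list(c(64L, 64L), c(128L, 128L), rep(256L, 4),
                       rep(512L, 4), rep(512L, 4)))
  }
}

#' Per-slice feature matrix shape
#'
#' Shape of the `n_frames x feature_dim` matrix produced by the spatial
#' extractor for one slice, derived from the configured architecture by shape
#' inference (vgg19 mode: 32 x 512 on the standard grid).
#'
#' @param config A [model_config()].
#' @return Integer vector `c(n_frames, feature_dim)`.
#' @export
model_feature_shape <- function(config) {
  plan <- backbone_plan(config)
  px <- config$input_px %/% plan$stem_pool
  f <- plan$in_channels
  for (blk in plan$blocks) {
    f <- blk[length(blk)]
    px <- px %/% 2L                     # one 2x2 max pool per block
    if (px < 1) stop("input too small for the configured backbone")
  }
  c(config$n_frames, as.integer(f))
}

#' Build the spatiotemporal classifier
#'
#' Initializes all weights (He-normal, seeded) and returns a trainable model
#' handle. Pretrained backbone weights can be supplied as a list matching the
#' parameter structure (`weights$slice1$convs`, ...), e.g. ImageNet VGG19
#' weights converted to this layout; by default weights are random.
#'
#' @param config A [model_config()].
#' @param weights Optional parameter list to start from.
#' @return An object of class `ctp_model` with elements `config` and `params`.
#' @export
build_model <- function(config = model_config(), weights = NULL) {
  stopifnot(inherits(config, "model_config"))
  plan <- backbone_plan(config)
  F <- model_feature_shape(config)[2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  mk_backbone <- function() {
    convs <- list()
    cin <- plan$in_channels
    for (blk in plan$blocks)
      for (cout in blk) {
        convs[[length(convs) + 1]] <- list(w = he_init(cout, cin * 9),
                                           b = numeric(cout))
        cin <- cout
      }
    convs
  }
  n_path <- if (config$pathways == "both") 2L else 1L
  # Temporal filters are initialized zero-mean along the time axis: any
  # feature component that is constant over a sample's frames (e.g. the
  # border offsets that spatial augmentation introduces identically in every
  # frame) is nulled at initialization, so early training sees the dynamic
  # enhancement signal rather than static per-sample offsets.
  zero_sum_taps <- function(w, k) {
    F <- ncol(w) / k
    for (r in seq_len(nrow(w))) {
      m <- matrix(w[r, ], F, k)
      w[r, ] <- as.vector(m - rowMeans(m))
    }
    w
  }
  mk_slice <- function() {
    sl <- list(convs = mk_backbone())
    if (config$pathways != "local_only")
      sl$tg <- list(w = zero_sum_taps(he_init(config$temporal_filters,
                                              config$kernel_global * F),
                                      config$kernel_global),
                    b = numeric(config$temporal_filters))
    if (config$pathways != "global_only")
      sl$tl <- list(w = zero_sum_taps(he_init(config$temporal_filters,
                                              config$kernel_local * F),
                                      config$kernel_local),
                    b = numeric(config$temporal_filters))
    sl$d1 <- list(w = he_init(config$dense_units,
                              n_path * config$temporal_filters),
                  b = numeric(config$dense_units))
    sl
  }
  params <- list()
  for (s in seq_len(config$n_slices)) params[[paste0("slice", s)]] <- mk_slice()
  # zero-initialized head: training starts from calibrated p = 0.5 and the
  # first optimizer steps set the direction from data, not from random fan-in
  params$head <- list(w = matrix(0, 1, config$n_slices * config$dense_units),
                      b = numeric(1))
  if (!is.null(weights)) params <- utils::modifyList(params, weights)
  structure(list(config = config, params = params), class = "ctp_model")
}

#' @export
print.ctp_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  fs <- model_feature_shape(x$config)
  cat(sprintf(paste0("<ctp_model> backbone=%s pathways=%s, feature matrix ",
                     "%d x %d per slice, %d parameters\n"),
              x$config$backbone, x$config$pathways, fs[1], fs[2], np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `ctp_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

# ---- forward / backward -----------------------------------------------------

# spatial extractor over a stack of frames: x (Cin, H, W, N) -> list with the
# (F x N) feature matrix and an opaque cache for the backward pass. The whole
# conv stack runs fused in C++ (single precision, activations cached on the
# C++ heap).
backbone_fwd <- function(convs, plan, x, keep_cache = TRUE) {
  .cpp_backbone_fwd(x, dim(x), convs,
                    as.integer(lengths(plan$blocks)),
                    as.integer(plan$stem_pool), keep_cache)
}

backbone_bwd <- function(convs, plan, dfeat, fwd) {
  .cpp_backbone_bwd(fwd$cache, convs, as.integer(lengths(plan$blocks)), dfeat)
}

# temporal head for one slice: feat (F, T, n) -> list(h (dense_units x n),
# cache)
temporal_fwd <- function(sl, config, feat) {
  paths <- list()
  cache <- list(feat = feat)
  # the temporal convolutions are linear; the global max pool over time
  # supplies the nonlinearity (and cannot silence a filter the way a ReLU
  # preceding a global max can)
  if (!is.null(sl$tg)) {
    zg <- conv1d_fwd(feat, sl$tg$w, sl$tg$b, config$kernel_global)
    mg <- gmaxpool_fwd(zg)
    cache$g <- list(idx = mg$idx, dims = dim(zg))
    paths$g <- mg$out
  }
  if (!is.null(sl$tl)) {
    zl <- conv1d_fwd(feat, sl$tl$w, sl$tl$b, config$kernel_local)
    ml <- gmaxpool_fwd(zl)
    cache$l <- list(idx = ml$idx, dims = dim(zl))
    paths$l <- ml$out
  }
  v <- do.call(rbind, paths)              # (n_path*nf) x n
  zd <- sl$d1$w %*% v + sl$d1$b           # dense_units x n
  h <- relu(zd)
  cache$v <- v; cache$zd <- zd
  list(h = h, cache = cache)
}

temporal_bwd <- function(sl, config, dh, cache) {
  dzd <- dh * (cache$zd > 0)
  g <- list(d1 = list(w = dzd %*% t(cache$v), b = rowSums(dzd)))
  dv <- t(sl$d1$w) %*% dzd
  nf <- config$temporal_filters
  dfeat <- 0
  row0 <- 0L
  if (!is.null(sl$tg)) {
    dmg <- dv[row0 + seq_len(nf), , drop = FALSE]
    dzg <- gmaxpool_bwd(dmg, cache$g$idx, cache$g$dims)
    bg <- conv1d_bwd(cache$feat, sl$tg$w, dzg, config$kernel_global)
    g$tg <- list(w = bg$dw, b = bg$db)
    dfeat <- dfeat + bg$dfeat
    row0 <- row0 + nf
  }
  if (!is.null(sl$tl)) {
    dml <- dv[row0 + seq_len(nf), , drop = FALSE]
    dzl <- gmaxpool_bwd(dml, cache$l$idx, cache$l$dims)
    bl <- conv1d_bwd(cache$feat, sl$tl$w, dzl, config$kernel_local)
    g$tl <- list(w = bl$dw, b = bl$db)
    dfeat <- dfeat + bl$dfeat
  }
  list(grads = g, dfeat = dfeat)
}

# full forward pass; x is (H, W, T, S, n). Returns probabilities and, when
# keep_cache, everything needed for model_backward.
model_forward <- function(model, x, keep_cache = FALSE) {
  config <- model$config
  plan <- backbone_plan(config)
  d <- dim(x)
  H <- d[1]; W <- d[2]; T <- d[3]; S <- d[4]; n <- d[5]
  F <- model_feature_shape(config)[2]
  hs <- vector("list", S)
  caches <- if (keep_cache) vector("list", S) else NULL
  for (s in seq_len(S)) {
    xs <- x[, , , s, , drop = FALSE]
    frames <- array(xs, dim = c(1L, H, W, T * n))
    if (plan$in_channels > 1L) {
      frames <- array(rep(frames, each = plan$in_channels),
                      dim = c(plan$in_channels, H, W, T * n))
    }
    bb <- backbone_fwd(model$params[[s]]$convs, plan, frames,
                       keep_cache = keep_cache)
    feat <- array(bb$feat, dim = c(F, T, n))
    tp <- temporal_fwd(model$params[[s]], config, feat)
    hs[[s]] <- tp$h
    if (keep_cache) caches[[s]] <- list(bb = bb, tp = tp$cache)
  }
  h <- do.call(rbind, hs)                 # (S*dense_units) x n
  logit <- as.vector(model$params$head$w %*% h + model$params$head$b)
  list(prob = sigmoid(logit), logit = logit, h = h, caches = caches)
}

# backward pass from dlogit (length n); returns grads with params structure
model_backward <- function(model, x, fwd, dlogit) {
  config <- model$config
  plan <- backbone_plan(config)
  d <- dim(x)
  H <- d[1]; W <- d[2]; T <- d[3]; S <- d[4]; n <- d[5]
  grads <- list()
  dl <- matrix(dlogit, 1, n)
  grads$head <- list(w = dl %*% t(fwd$h), b = sum(dlogit))
  dh_all <- t(model$params$head$w) %*% dl   # (S*du) x n
  du <- config$dense_units
  for (s in seq_len(S)) {
    dh <- dh_all[(s - 1) * du + seq_len(du), , drop = FALSE]
    tb <- temporal_bwd(model$params[[s]], config, dh, fwd$caches[[s]]$tp)
    F <- dim(tb$dfeat)[1]
    dfeat_mat <- matrix(tb$dfeat, F, T * n)
    gb <- backbone_bwd(model$params[[s]]$convs, plan, dfeat_mat,
                       fwd$caches[[s]]$bb)
    g <- tb$grads
    g$convs <- gb
    grads[[paste0("slice", s)]] <- g
  }
  # match the parameter ordering (slice1..S, head) and inner names
  grads <- grads[c(paste0("slice", seq_len(S)), "head")]
  for (s in seq_len(S)) {
    ord <- names(model$params[[s]])
    grads[[s]] <- grads[[s]][ord]
  }
  grads
}

# one gradient-descent step on a batch; returns updated model+state and loss
train_step <- function(model, opt_state, x, y) {
  fwd <- model_forward(model, x, keep_cache = TRUE)
  n <- length(y)
  loss <- bce_loss(fwd$prob, y)
  dlogit <- (fwd$prob - y) / n
  grads <- model_backward(model, x, fwd, dlogit)
  upd <- adam_step(model$params, grads, opt_state)
  model$params <- upd$params
  list(model = model, state = upd$state, loss = loss)
}
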