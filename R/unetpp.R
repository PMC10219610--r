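# U-Net++ with nested dense skip connections, implemented directly on the
# package's conv/pool/upsample kernels with hand-derived backpropagation.
#
# Node X^{i,j} (i = down-sampling level, j = position along the skip chain):
#   j = 0 : X^{i,0} = H(down(X^{i-1,0}))            (encoder backbone)
#   j > 0 : X^{i,j} = H([X^{i,0..j-1}, up(X^{i+1,j-1})])
# where H is a [conv3x3 -> norm -> ReLU] x2 block, down is 2x2 max pooling and
# up is bilinear 2x upsampling followed by a 1x1 conv to match channel widths.
# Nodes exist for i + j <= depth - 1, giving depth*(depth+1)/2 nodes.

#' Configure a U-Net++ segmentation model
#'
#' @param depth number of resolution levels (>= 2); inputs must have spatial
#'   dimensions divisible by `2^(depth-1)`.
#' @param base_channels feature width at the top level (>= 1).
#' @param channel_multiplier per-level width growth factor (level `i` has
#'   `base_channels * channel_multiplier^i` channels).
#' @param deep_supervision attach a prediction head to every top-row node
#'   `X^{0,j}` (j >= 1); training averages the per-head losses and inference
#'   uses the final head only.  Off by default.
#' @param encoder `"plain"` for the built-in per-level double-conv encoder, or
#'   the name of an encoder registered with [register_encoder()] (hook for
#'   plugging in pretrained backbones without code change).
#' @param in_channels input channels (1 for grayscale radiographs).
#' @param norm use batch normalization inside conv blocks (recommended; can be
#'   disabled for very small batches).
#' @param head_bias_prior initializes every prediction head's bias to
#'   `qlogis(head_bias_prior)`, so the untrained model starts near the
#'   foreground class prior instead of probability 0.5 — the standard
#'   stabilizer for training under extreme foreground/background imbalance.
#'   The default 0.1 is deliberately above the exact foreground fraction:
#'   at the exact prior the plain-BCE loss starts in a flat region and can
#'   fail to escape within a short epoch budget, while starting at 0.5
#'   destabilizes the set-statistic (MCC/region) losses.  Set `NULL` for a
#'   generic random bias.
#' @param seed integer seed fixing the Kaiming-uniform weight initialization.
#' @return A `unetpp_config` object for [build_unetpp()].
#' @export
unetpp_config <- function(depth = 3, base_channels = 8, channel_multiplier = 2,
                          deep_supervision = FALSE, encoder = "plain",
                          in_channels = 1, norm = TRUE,
                          head_bias_prior = 0.1, seed = 42) {
  if (!is.numeric(depth) || depth < 2 || depth != round(depth))
    stop("configuration error: `depth` must be an integer >= 2")
  if (!is.numeric(base_channels) || base_channels < 1 ||
      base_channels != round(base_channels))
    stop("configuration error: `base_channels` must be an integer >= 1")
  if (channel_multiplier < 1)
    stop("configuration error: `channel_multiplier` must be >= 1")
  if (in_channels < 1)
    stop("configuration error: `in_channels` must be >= 1")
  if (!is.null(head_bias_prior) &&
      (head_bias_prior <= 0 || head_bias_prior >= 1))
    stop("configuration error: `head_bias_prior` must be in (0, 1) or NULL")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 channel_multiplier = channel_multiplier,
                 deep_supervision = isTRUE(deep_supervision),
                 encoder = encoder, in_channels = as.integer(in_channels),
                 norm = isTRUE(norm), head_bias_prior = head_bias_prior,
                 seed = as.integer(seed)),
            class = "unetpp_config")
}

# Registry for pluggable encoder constructors.
.encoders <- new.env(parent = emptyenv())

#' Register a named encoder constructor
#'
#' The encoder of a U-Net++ is its backbone column `X^{i,0}`.  A registered
#' constructor is called as `constructor(config)` and must return a list of
#' three functions replacing the built-in double-conv block for every
#' backbone node:
#'
#' * `init(cin, cout)` — returns a named list of parameter arrays for one
#'   level's block mapping `cin` input to `cout` output channels;
#' * `forward(x, params, train)` — consumes a `(H, W, cin, N)` array and the
#'   block's parameters and returns `list(y, cache)` with `y` of shape
#'   `(H, W, cout, N)` (`cache` is handed back to `backward`);
#' * `backward(dy, params, cache)` — returns `list(dx, grads)` with `grads`
#'   named like the block's parameters.
#'
#' Down-sampling between levels, all decoder/skip nodes and the prediction
#' heads stay as in the plain model.  Custom encoder blocks manage any
#' internal normalization statistics themselves.  This is the seam through
#' which pretrained backbones (RegNet/ResNet class) can be attached without
#' touching the graph code; the package itself ships only from-scratch
#' encoders.
#'
#' @param name encoder name used in [unetpp_config()].
#' @param constructor function implementing the contract above.
#' @export
register_encoder <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .encoders)
  invisible(name)
}

encoder_fns <- function(config) {
  if (config$encoder == "plain") return(NULL)
  get(config$encoder, envir = .encoders)(config)
}

node_params <- function(params, prefix) {
  nm <- names(params)[startsWith(names(params), prefix)]
  out <- params[nm]
  names(out) <- substring(nm, nchar(prefix) + 1)
  out
}

level_channels <- function(cfg) {
  as.integer(round(cfg$base_channels * cfg$channel_multiplier^(0:(cfg$depth - 1))))
}

node_key <- function(i, j) paste0("x", i, "_", j)

# Enumerate nodes in forward (computable) order with their wiring.
node_table <- function(cfg) {
  d <- cfg$depth
  ch <- level_channels(cfg)
  rows <- list()
  for (j in 0:(d - 1)) for (i in 0:(d - 1 - j)) {
    in_ch <- if (j == 0) {
      if (i == 0) cfg$in_channels else ch[i]      # ch[i] = level i-1 width
    } else (j + 1L) * ch[i + 1]
    rows[[length(rows) + 1]] <- data.frame(
      i = i, j = j, key = node_key(i, j), in_ch = in_ch, out_ch = ch[i + 1],
      n_inputs = if (j == 0) 1L else j + 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(runif(prod(dims), -bound, bound), dim = dims)
}

init_conv <- function(k, cin, cout) {
  fan_in <- k * k * cin
  bb <- 1 / sqrt(fan_in)
  list(w = kaiming_uniform(c(k, k, cin, cout), fan_in),
       b = runif(cout, -bb, bb))
}

#' Build a U-Net++ model
#'
#' Instantiates the nested dense-skip computation graph described in
#' [unetpp_config()] and initializes all weights (Kaiming-uniform, seeded).
#'
#' @param config a [unetpp_config()].
#' @return A `unetpp` model object with elements `config`, `params` (named
#'   list of weight arrays), `bn_state` (running batch-norm statistics) and
#'   `nodes` (a data frame describing the node graph: indices `i`, `j`,
#'   input/output channel counts and input arity).
#' @examples
#' m <- build_unetpp(unetpp_config(depth = 2, base_channels = 4))
#' nrow(m$nodes)  # 3 nodes: X^{0,0}, X^{1,0}, X^{0,1}
#' @export
build_unetpp <- function(config) {
  if (!inherits(config, "unetpp_config")) config <- do.call(unetpp_config, config)
  if (config$encoder != "plain" && !exists(config$encoder, envir = .encoders))
    stop("configuration error: unknown `encoder` '", config$encoder,
         "' (register it with register_encoder())")
  set.seed(config$seed)
  nodes <- node_table(config)
  ch <- level_channels(config)
  params <- list()
  bn_state <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- rep(0, c)
    bn_state[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  enc <- encoder_fns(config)
  for (r in seq_len(nrow(nodes))) {
    key <- nodes$key[r]; cin <- nodes$in_ch[r]; cout <- nodes$out_ch[r]
    if (nodes$j[r] > 0) {            # 1x1 conv on the up-sampled input
      up <- init_conv(1, ch[nodes$i[r] + 2], ch[nodes$i[r] + 1])
      params[[paste0(key, ".up.w")]] <- up$w
      params[[paste0(key, ".up.b")]] <- up$b
    }
    if (!is.null(enc) && nodes$j[r] == 0) {   # pluggable backbone block
      ep <- enc$init(cin, cout)
      for (pn in names(ep)) params[[paste0(key, ".", pn)]] <- ep[[pn]]
      next
    }
    c1 <- init_conv(3, cin, cout)
    params[[paste0(key, ".conv1.w")]] <- c1$w
    params[[paste0(key, ".conv1.b")]] <- c1$b
    if (config$norm) add_bn(paste0(key, ".bn1"), cout)
    c2 <- init_conv(3, cout, cout)
    params[[paste0(key, ".conv2.w")]] <- c2$w
    params[[paste0(key, ".conv2.b")]] <- c2$b
    if (config$norm) add_bn(paste0(key, ".bn2"), cout)
  }
  for (j in head_indices(config)) {
    h <- init_conv(1, ch[1], 1)
    params[[paste0("head", j, ".w")]] <- h$w
    params[[paste0("head", j, ".b")]] <-
      if (is.null(config$head_bias_prior)) h$b
      else stats::qlogis(config$head_bias_prior)
  }
  structure(list(config = config, params = params, bn_state = bn_state,
                 nodes = nodes),
            class = "unetpp")
}

head_indices <- function(cfg) {
  if (cfg$deep_supervision) seq_len(cfg$depth - 1) else cfg$depth - 1L
}

#' @export
print.unetpp <- function(x, ...) {
  cat(sprintf("<unetpp> depth %d, base %d, %d nodes, %d parameters%s\n",
              x$config$depth, x$config$base_channels, nrow(x$nodes),
              n_parameters(x),
              if (x$config$deep_supervision) ", deep supervision" else ""))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `unetpp` model.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- batch-norm helpers (channel = 3rd margin of (H,W,C,N)) -------------

bn_forward <- function(x, gamma, beta, state, train, eps = 1e-5,
                       momentum = 0.1) {
  if (train) {
    st <- cpp_bn_stats(x)
    mu <- st$mean; v <- st$var
    m <- prod(dim(x)[c(1, 2, 4)])
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- state$mean; v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  ap <- cpp_bn_apply(x, gamma, beta, mu, invstd, keep_xhat = train)
  list(y = ap$y, cache = list(xhat = ap$xhat, invstd = invstd),
       state = state)
}

bn_backward <- function(dy, cache, gamma) {
  cpp_bn_backward(dy, cache$xhat, gamma, cache$invstd)
}

concat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (p in parts) {
    k <- dim(p)[3]
    out[, , at + seq_len(k), ] <- p
    at <- at + k
  }
  out
}

# ---- forward / backward --------------------------------------------------

conv_block_forward <- function(x, params, bn_state, key, norm, train,
                               slot = -1L) {
  cache <- list(x = x)
  h <- cpp_conv2d_forward(x, params[[paste0(key, ".conv1.w")]],
                          params[[paste0(key, ".conv1.b")]], 1L,
                          if (train) 2L * slot else -1L)
  if (norm) {
    bn <- bn_forward(h, params[[paste0(key, ".bn1.gamma")]],
                     params[[paste0(key, ".bn1.beta")]],
                     bn_state[[paste0(key, ".bn1")]], train)
    cache$h1 <- h; cache$bn1 <- bn$cache
    bn_state[[paste0(key, ".bn1")]] <- bn$state
    h <- bn$y
  }
  cache$a1 <- h > 0
  h <- h * cache$a1
  cache$r1 <- h
  h2 <- cpp_conv2d_forward(h, params[[paste0(key, ".conv2.w")]],
                           params[[paste0(key, ".conv2.b")]], 1L,
                           if (train) 2L * slot + 1L else -1L)
  if (norm) {
    bn <- bn_forward(h2, params[[paste0(key, ".bn2.gamma")]],
                     params[[paste0(key, ".bn2.beta")]],
                     bn_state[[paste0(key, ".bn2")]], train)
    cache$h2 <- h2; cache$bn2 <- bn$cache
    bn_state[[paste0(key, ".bn2")]] <- bn$state
    h2 <- bn$y
  }
  cache$a2 <- h2 > 0
  h2 <- h2 * cache$a2
  list(y = h2, cache = cache, bn_state = bn_state)
}

conv_block_backward <- function(dy, params, cache, key, norm, grads,
                                slot = -1L, want_dx = TRUE) {
  dy <- dy * cache$a2
  if (norm) {
    bb <- bn_backward(dy, cache$bn2, params[[paste0(key, ".bn2.gamma")]])
    grads[[paste0(key, ".bn2.gamma")]] <- bb$dgamma
    grads[[paste0(key, ".bn2.beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cb <- cpp_conv2d_backward(cache$r1, params[[paste0(key, ".conv2.w")]],
                            dy, 1L, 2L * slot + 1L)
  grads[[paste0(key, ".conv2.w")]] <- cb$dw
  grads[[paste0(key, ".conv2.b")]] <- cb$db
  dy <- cb$dx * cache$a1
  if (norm) {
    bb <- bn_backward(dy, cache$bn1, params[[paste0(key, ".bn1.gamma")]])
    grads[[paste0(key, ".bn1.gamma")]] <- bb$dgamma
    grads[[paste0(key, ".bn1.beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cb <- cpp_conv2d_backward(cache$x, params[[paste0(key, ".conv1.w")]],
                            dy, 1L, 2L * slot, want_dx)
  grads[[paste0(key, ".conv1.w")]] <- cb$dw
  grads[[paste0(key, ".conv1.b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

check_input <- function(model, x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array")
  if (length(d) == 2) {
    x <- array(x, c(d, 1, 1))
    d <- dim(x)
  } else if (length(d) == 3) {       # (H, W, N) single-channel batch
    x <- array(x, c(d[1], d[2], 1, d[3]))
    d <- dim(x)
  }
  div <- 2^(model$config$depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("input spatial dimensions (", d[1], "x", d[2],
         ") must be divisible by 2^(depth-1) = ", div)
  if (d[3] != model$config$in_channels)
    stop("input has ", d[3], " channels; model expects ",
         model$config$in_channels)
  x
}

# Full forward pass.  Returns per-head logits plus (when train = TRUE) the
# caches needed by unetpp_backward and updated BN running statistics.
unetpp_forward_full <- function(model, x, train = FALSE) {
  x <- check_input(model, x)
  cfg <- model$config
  d <- cfg$depth
  enc <- encoder_fns(cfg)
  params <- model$params
  bn_state <- model$bn_state
  outs <- list(); caches <- list(); pools <- list(); ups <- list()
  for (j in 0:(d - 1)) for (i in 0:(d - 1 - j)) {
    key <- node_key(i, j)
    if (j == 0) {
      if (i == 0) inp <- x
      else {
        mp <- cpp_maxpool2_forward(outs[[node_key(i - 1, 0)]])
        pools[[key]] <- list(idx = mp$idx,
                             xdim = dim(outs[[node_key(i - 1, 0)]]))
        inp <- mp$y
      }
    } else {
      below <- outs[[node_key(i + 1, j - 1)]]
      u <- cpp_upsample2_forward(below)
      uc <- cpp_conv2d_forward(u, params[[paste0(key, ".up.w")]],
                               params[[paste0(key, ".up.b")]], 0L)
      ups[[key]] <- list(u = u, xdim = dim(below))
      skips <- lapply(0:(j - 1), function(k) outs[[node_key(i, k)]])
      inp <- concat_channels(c(skips, list(uc)))
    }
    if (!is.null(enc) && j == 0) {
      eb <- enc$forward(inp, node_params(params, paste0(key, ".")), train)
      outs[[key]] <- eb$y
      if (train) caches[[key]] <- eb$cache
    } else {
      cb <- conv_block_forward(inp, params, bn_state, key, cfg$norm, train,
                               slot = match(key, model$nodes$key))
      outs[[key]] <- cb$y
      bn_state <- cb$bn_state
      if (train) caches[[key]] <- cb$cache
    }
  }
  logits <- list()
  for (j in head_indices(cfg)) {
    logits[[as.character(j)]] <-
      cpp_conv2d_forward(outs[[node_key(0, j)]],
                         params[[paste0("head", j, ".w")]],
                         params[[paste0("head", j, ".b")]], 0L)
  }
  list(logits = logits, outs = if (train) outs else NULL,
       caches = caches, pools = pools, ups = ups, bn_state = bn_state)
}

#' Run a model on an image batch
#'
#' @param model a [build_unetpp()] model.
#' @param x input: matrix `(H, W)`, array `(H, W, N)` or `(H, W, C, N)`;
#'   spatial dimensions must be divisible by `2^(depth-1)`.
#' @param type `"prob"` for sigmoid probabilities (default) or `"logits"`.
#' @return Array shaped like the input (channel margin = 1) with per-pixel
#'   tube probabilities (or logits); inference always reads the final head
#'   `X^{0,depth-1}`.
#' @export
unetpp_predict <- function(model, x, type = c("prob", "logits")) {
  type <- match.arg(type)
  fw <- unetpp_forward_full(model, x, train = FALSE)
  out <- fw$logits[[as.character(model$config$depth - 1)]]
  if (type == "prob") out <- plogis(out)
  dim(out) <- dim(out)
  out
}

# Backward pass: dlogits is a named list (head index -> gradient array).
# Returns a named list of parameter gradients.
unetpp_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  d <- cfg$depth
  enc <- encoder_fns(cfg)
  params <- model$params
  grads <- list()
  dnode <- list()
  acc <- function(key, g) {
    dnode[[key]] <<- if (is.null(dnode[[key]])) g else dnode[[key]] + g
  }
  for (j in names(dlogits)) {
    key <- node_key(0, as.integer(j))
    hb <- cpp_conv2d_backward(fw$outs[[key]],
                              params[[paste0("head", j, ".w")]],
                              dlogits[[j]], 0L)
    grads[[paste0("head", j, ".w")]] <- hb$dw
    grads[[paste0("head", j, ".b")]] <- hb$db
    acc(key, hb$dx)
  }
  order <- expand_order(d)
  for (r in rev(seq_len(nrow(order)))) {
    i <- order$i[r]; j <- order$j[r]
    key <- node_key(i, j)
    g <- dnode[[key]]
    if (is.null(g)) next
    if (!is.null(enc) && j == 0) {
      eb <- enc$backward(g, node_params(params, paste0(key, ".")),
                         fw$caches[[key]])
      for (pn in names(eb$grads))
        grads[[paste0(key, ".", pn)]] <- eb$grads[[pn]]
      dinp <- eb$dx
    } else {
      bb <- conv_block_backward(g, params, fw$caches[[key]], key, cfg$norm,
                                grads, slot = match(key, model$nodes$key),
                                want_dx = !(i == 0 && j == 0))
      grads <- bb$grads
      dinp <- bb$dx
    }
    if (j == 0) {
      if (i > 0) {
        acc(node_key(i - 1, 0),
            cpp_maxpool2_backward(fw$pools[[key]]$idx, dinp,
                                  fw$pools[[key]]$xdim))
      }
    } else {
      ch_i <- dim(fw$outs[[node_key(i, 0)]])[3]
      for (k in 0:(j - 1)) {
        sl <- dinp[, , k * ch_i + seq_len(ch_i), , drop = FALSE]
        acc(node_key(i, k), sl)
      }
      du <- dinp[, , j * ch_i + seq_len(ch_i), , drop = FALSE]
      ub <- cpp_conv2d_backward(fw$ups[[key]]$u,
                                params[[paste0(key, ".up.w")]], du, 0L)
      grads[[paste0(key, ".up.w")]] <- ub$dw
      grads[[paste0(key, ".up.b")]] <- ub$db
      acc(node_key(i + 1, j - 1),
          cpp_upsample2_backward(ub$dx, fw$ups[[key]]$xdim))
    }
  }
  grads
}

expand_order <- function(d) {
  rows <- list()
  for (j in 0:(d - 1)) for (i in 0:(d - 1 - j))
    rows[[length(rows) + 1]] <- data.frame(i = i, j = j)
  do.call(rbind, rows)
}

# ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration, weights and batch-norm
#' running statistics, so it reloads without external context.
#'
#' @param model a `unetpp` model.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               bn_state = model$bn_state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_unetpp(do.call(unetpp_config, ck$config))
  model$params <- ck$params
  model$bn_state <- ck$bn_state
  model
}
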