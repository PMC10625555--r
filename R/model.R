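# The dual-headed volumetric encoder-decoder family. One shared encoder
# distills context from a cubic CT chunk; two structurally identical
# decoders (segmentation head with a sigmoid output, heatmap head with three
# linear output channels) upsample back to full resolution using skip
# connections, optionally filtered by additive attention gates, with
# optional deep-supervision outputs at the lower decoder levels.

#' Network configuration
#'
#' The default mirrors the working architecture for 128-voxel chunks: four
#' downsampling levels with the channel cascade 32, 64, 128, 256, 320, a
#' double-convolution block (normalisation, 3x3x3 convolution, nonlinearity,
#' applied twice) per level, kernel-2 stride-2 downsampling convolutions and
#' transposed-convolution upsampling. Channel counts are held constant
#' across a level transition; the increase happens inside the next block.
#'
#' @param levels number of downsampling steps.
#' @param channels per-level feature counts, length `levels + 1`.
#' @param norm `"instance"` or `"batch"` (identical for a batch of one
#'   chunk, which is the training regime here).
#' @param activation one of leaky_relu, relu, prelu, gelu, silu, mish.
#' @param act_slope negative slope of leaky_relu.
#' @param attention `"none"`, `"seg_head"`, `"heatmap_head"` or `"global"`.
#' @param deep_supervision attach auxiliary outputs at decoder levels
#'   2..min(levels, 4) (resolutions 1/2, 1/4, 1/8)?
#' @param seg_channels,heatmap_channels output channels (fixed 1 and 3).
#' @return A `network_config` object.
#' @export
network_config <- function(levels = 4L, channels = c(32, 64, 128, 256, 320),
                           norm = c("instance", "batch"),
                           activation = ACTIVATIONS, act_slope = 0.025,
                           attention = c("none", "seg_head", "heatmap_head", "global"),
                           deep_supervision = TRUE,
                           seg_channels = 1L, heatmap_channels = 3L) {
  norm <- match.arg(norm)
  activation <- match.arg(activation)
  attention <- match.arg(attention)
  levels <- as.integer(levels)
  if (length(channels) != levels + 1L)
    stop("channels must have length levels + 1 (got ", length(channels),
         " for ", levels, " levels)")
  if (seg_channels != 1L) stop("seg_channels is fixed at 1")
  if (heatmap_channels != 3L) stop("heatmap_channels is fixed at 3")
  structure(list(levels = levels, channels = as.integer(channels),
                 norm = norm, activation = activation, act_slope = act_slope,
                 attention = attention,
                 deep_supervision = isTRUE(deep_supervision),
                 seg_channels = 1L, heatmap_channels = 3L),
            class = "network_config")
}

#' Trace the spatial/channel shapes of a configuration
#'
#' Pure arithmetic on the architecture contract: each downsampling halves
#' the spatial edge and moves one step along the channel cascade. Errors if
#' the chunk edge is not divisible by `2^levels`.
#'
#' @param config a [network_config()].
#' @param edge cubic chunk edge length in voxels.
#' @return data.frame with one row per encoder stage: `level`, `edge`
#'   (spatial edge after the stage's downsampling), `channels`.
#' @export
network_shapes <- function(config, edge) {
  if (edge %% 2^config$levels != 0)
    stop("chunk edge ", edge, " is not divisible by 2^levels = ",
         2^config$levels)
  lv <- seq_len(config$levels)
  data.frame(level = lv, edge = edge / 2^lv,
             channels = config$channels[lv + 1L])
}

init_uniform <- function(n, fan_in) runif(n, -1, 1) / sqrt(fan_in)

conv_param <- function(params, name, ic, oc, k) {
  params[[paste0(name, "_w")]] <- matrix(init_uniform(oc * ic * k^3, ic * k^3),
                                         oc, ic * k^3)
  params[[paste0(name, "_b")]] <- numeric(oc)
  params
}

tconv_param <- function(params, name, ic, oc, k) {
  params[[paste0(name, "_w")]] <- matrix(init_uniform(ic * oc * k^3, ic),
                                         ic, oc * k^3)
  params[[paste0(name, "_b")]] <- numeric(oc)
  params
}

norm_param <- function(params, name, c_) {
  params[[paste0(name, "_gamma")]] <- rep(1, c_)
  params[[paste0(name, "_beta")]] <- rep(0, c_)
  params
}

prelu_param <- function(params, name, c_) {
  params[[paste0(name, "_a")]] <- rep(0.25, c_)
  params
}

block_params <- function(params, name, ic, oc, cfg) {
  params <- norm_param(params, paste0(name, "_norm1"), ic)
  params <- conv_param(params, paste0(name, "_conv1"), ic, oc, 3L)
  params <- norm_param(params, paste0(name, "_norm2"), oc)
  params <- conv_param(params, paste0(name, "_conv2"), oc, oc, 3L)
  if (cfg$activation == "prelu") {
    params <- prelu_param(params, paste0(name, "_act1"), oc)
    params <- prelu_param(params, paste0(name, "_act2"), oc)
  }
  params
}

att_params <- function(params, name, skip_c, gate_c) {
  fint <- max(1L, skip_c %/% 2L)
  params <- conv_param(params, paste0(name, "_wx"), skip_c, fint, 1L)
  params <- conv_param(params, paste0(name, "_wg"), gate_c, fint, 1L)
  params <- conv_param(params, paste0(name, "_psi"), fint, 1L, 1L)
  params
}

head_wants_attention <- function(cfg, head) {
  cfg$attention == "global" ||
    (cfg$attention == "seg_head" && head == "seg") ||
    (cfg$attention == "heatmap_head" && head == "hm")
}

#' Build a dual-headed network
#'
#' Allocates and deterministically initialises all parameters (uniform
#' distribution, fan-in scaling) for the configured architecture.
#'
#' @param config a [network_config()].
#' @param seed integer seed for the initialisation.
#' @param in_channels input channels (1 for CT intensity chunks).
#' @return A `network` object: list with `config`, `params` (named list of
#'   arrays), `seed`, `in_channels`.
#' @export
build_network <- function(config, seed = 1L, in_channels = 1L) {
  stopifnot(inherits(config, "network_config"))
  ch <- config$channels
  L <- config$levels
  params <- with_seed(seed, {
    p <- list()
    ic <- in_channels
    for (i in seq_len(L)) {
      p <- block_params(p, paste0("enc", i), ic, ch[i], config)
      p <- conv_param(p, paste0("down", i), ch[i], ch[i], 2L)  # constant across transition
      ic <- ch[i]
    }
    p <- block_params(p, "bottleneck", ch[L], ch[L + 1L], config)
    for (head in c("seg", "hm")) {
      cur <- ch[L + 1L]
      for (j in rev(seq_len(L))) {
        p <- tconv_param(p, paste0(head, "_up", j), cur, cur, 2L)
        if (head_wants_attention(config, head))
          p <- att_params(p, paste0(head, "_att", j), ch[j], cur)
        p <- block_params(p, paste0(head, "_dec", j), cur + ch[j], ch[j], config)
        cur <- ch[j]
      }
      oc <- if (head == "seg") config$seg_channels else config$heatmap_channels
      p <- conv_param(p, paste0(head, "_out"), ch[1], oc, 1L)
      if (config$deep_supervision) {
        for (j in 2:min(L, 4L)) {
          if (j > L) next
          p <- conv_param(p, paste0(head, "_ds", j), ch[j], oc, 1L)
        }
      }
    }
    p
  })
  structure(list(config = config, params = params, seed = as.integer(seed),
                 in_channels = as.integer(in_channels)),
            class = "network")
}

#' Total trainable parameter count
#' @param net a [build_network()] object.
#' @return Integer count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, numeric(1)))

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %d levels, channels [%s], %s norm, %s, attention=%s, %s parameters\n",
              x$config$levels, paste(x$config$channels, collapse = ","),
              x$config$norm, x$config$activation, x$config$attention,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

ag_act_cfg <- function(x, cfg, pn, name) {
  if (cfg$activation == "prelu") ag_prelu(x, pn[[paste0(name, "_a")]])
  else ag_activation(x, cfg$activation, cfg$act_slope)
}

ag_block <- function(x, name, cfg, pn) {
  x <- ag_instance_norm(x, pn[[paste0(name, "_norm1_gamma")]],
                        pn[[paste0(name, "_norm1_beta")]])
  x <- ag_conv3d(x, pn[[paste0(name, "_conv1_w")]], pn[[paste0(name, "_conv1_b")]], 3L)
  x <- ag_act_cfg(x, cfg, pn, paste0(name, "_act1"))
  x <- ag_instance_norm(x, pn[[paste0(name, "_norm2_gamma")]],
                        pn[[paste0(name, "_norm2_beta")]])
  x <- ag_conv3d(x, pn[[paste0(name, "_conv2_w")]], pn[[paste0(name, "_conv2_b")]], 3L)
  ag_act_cfg(x, cfg, pn, paste0(name, "_act2"))
}

ag_attention_gate <- function(skip, gate, name, pn) {
  g_up <- ag_upsample_nn(gate, 2L)
  xs <- ag_conv3d(skip, pn[[paste0(name, "_wx_w")]], pn[[paste0(name, "_wx_b")]], 1L, pad = 0L)
  gs <- ag_conv3d(g_up, pn[[paste0(name, "_wg_w")]], pn[[paste0(name, "_wg_b")]], 1L, pad = 0L)
  a <- ag_activation(ag_add(xs, gs), "relu")
  a <- ag_conv3d(a, pn[[paste0(name, "_psi_w")]], pn[[paste0(name, "_psi_b")]], 1L, pad = 0L)
  a <- ag_sigmoid(a)
  ag_gate_mul(skip, a)
}

#' Forward pass of the network
#'
#' Runs a cubic chunk through encoder and both decoder heads on the autograd
#' tape. The forward is deterministic: there is no dropout and
#' normalisation statistics are computed from the chunk itself, so training
#' and evaluation mode coincide.
#'
#' @param net a [build_network()] network.
#' @param chunk 3D array (or `(in_channels, edge^3)` 4D array) with edge
#'   divisible by `2^levels`.
#' @param heads `"both"` (default), or `"seg"` / `"hm"` to run a single
#'   decoder only (the single-task variants of the ablation study); the
#'   other head's outputs are `NULL`.
#' @return A prediction bundle: list with `seg` (probabilities in `[0,1]`,
#'   node), `heatmaps` (3-channel node), `aux` (list of
#'   `(seg, heatmaps, level)` nodes when deep supervision is on) and
#'   `params` (named list of parameter leaf nodes carrying gradients after
#'   [ag_backward()]).
#' @export
network_forward <- function(net, chunk, heads = c("both", "seg", "hm")) {
  heads <- match.arg(heads)
  run_heads <- if (heads == "both") c("seg", "hm") else
    c(seg = "seg", hm = "hm")[heads]
  cfg <- net$config
  if (length(dim(chunk)) == 3L) dim(chunk) <- c(1L, dim(chunk))
  edge <- dim(chunk)[2]
  if (!all(dim(chunk)[2:4] == edge))
    stop("chunk must be cubic (got ", paste(dim(chunk)[2:4], collapse = "x"), ")")
  network_shapes(cfg, edge)  # validates divisibility
  pn <- lapply(net$params, ag_leaf)
  L <- cfg$levels
  x <- ag_leaf(chunk)
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    x <- ag_block(x, paste0("enc", i), cfg, pn)
    skips[[i]] <- x
    x <- ag_conv3d(x, pn[[paste0("down", i, "_w")]], pn[[paste0("down", i, "_b")]],
                   2L, stride = 2L, pad = 0L)
  }
  x <- ag_block(x, "bottleneck", cfg, pn)
  outputs <- list()
  for (head in run_heads) {
    g <- x
    feats <- vector("list", L)
    for (j in rev(seq_len(L))) {
      up <- ag_tconv3d(g, pn[[paste0(head, "_up", j, "_w")]],
                       pn[[paste0(head, "_up", j, "_b")]], 2L)
      skip <- skips[[j]]
      if (head_wants_attention(cfg, head))
        skip <- ag_attention_gate(skip, g, paste0(head, "_att", j), pn)
      g <- ag_block(ag_concat(up, skip), paste0(head, "_dec", j), cfg, pn)
      feats[[j]] <- g
    }
    out <- ag_conv3d(feats[[1]], pn[[paste0(head, "_out_w")]],
                     pn[[paste0(head, "_out_b")]], 1L, pad = 0L)
    if (head == "seg") out <- ag_sigmoid(out)
    aux <- list()
    if (cfg$deep_supervision && L >= 2L) {
      for (j in 2:min(L, 4L)) {
        a <- ag_conv3d(feats[[j]], pn[[paste0(head, "_ds", j, "_w")]],
                       pn[[paste0(head, "_ds", j, "_b")]], 1L, pad = 0L)
        if (head == "seg") a <- ag_sigmoid(a)
        aux[[length(aux) + 1L]] <- list(node = a, level = j)
      }
    }
    outputs[[head]] <- list(out = out, aux = aux)
  }
  aux <- list()
  if (cfg$deep_supervision && L >= 2L) {
    n_aux <- length(outputs[[run_heads[1]]]$aux)
    for (i in seq_len(n_aux)) {
      aux[[i]] <- list(seg = outputs$seg$aux[[i]]$node,
                       heatmaps = outputs$hm$aux[[i]]$node,
                       level = outputs[[run_heads[1]]]$aux[[i]]$level)
    }
  }
  list(seg = outputs$seg$out, heatmaps = outputs$hm$out, aux = aux,
       params = pn)
}
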