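# Optimizers and the trapezoidal learning-rate schedule. AdamW uses
# decoupled weight decay (the zero-mean Gaussian prior over the weights is
# applied directly to the parameters at each step, scaled by the current
# learning rate, not mixed into the gradient moments).

#' Trapezoidal learning-rate schedule
#'
#' Linear warmup from 0 to `peak_lr`, a constant plateau, then linear
#' annealing back towards 0. The three phase lengths must sum to the total
#' iteration count.
#'
#' @param iterations total training iterations.
#' @param peak_lr plateau learning rate.
#' @param warmup_frac,plateau_frac,anneal_frac phase lengths as fractions
#'   of `iterations` (must sum to 1).
#' @return An `lr_schedule` object with integer phase lengths
#'   (warmup gets any rounding remainder subtracted).
#' @export
lr_schedule <- function(iterations, peak_lr = 1e-3, warmup_frac = 0.1,
                        plateau_frac = 0.6, anneal_frac = 0.3) {
  if (abs(warmup_frac + plateau_frac + anneal_frac - 1) > 1e-9)
    stop("warmup, plateau and anneal fractions must sum to 1")
  warmup <- round(iterations * warmup_frac)
  anneal <- round(iterations * anneal_frac)
  plateau <- iterations - warmup - anneal
  if (plateau < 0) stop("phase lengths exceed the iteration budget")
  structure(list(iterations = as.integer(iterations), peak_lr = peak_lr,
                 warmup = as.integer(warmup), plateau = as.integer(plateau),
                 anneal = as.integer(anneal)),
            class = "lr_schedule")
}

#' Learning rate at an iteration
#'
#' @param sched an [lr_schedule()].
#' @param iteration 0-based iteration in `[0, iterations)`.
#' @return The learning rate.
#' @export
lr_at <- function(sched, iteration) {
  if (iteration < 0 || iteration >= sched$iterations)
    stop("iteration ", iteration, " outside [0, ", sched$iterations, ")")
  w <- sched$warmup; p <- sched$plateau
  if (iteration < w) return(sched$peak_lr * iteration / w)
  if (iteration < w + p) return(sched$peak_lr)
  sched$peak_lr * (sched$iterations - iteration) / sched$anneal
}

#' Create an optimizer
#'
#' @param kind `"adamw"` (decoupled weight decay) or `"sgd"` (momentum).
#' @param weight_decay lambda of the weight-decay functional (AdamW).
#' @param betas AdamW running-average coefficients.
#' @param eps AdamW denominator floor.
#' @param momentum SGD momentum coefficient.
#' @return An `optimizer` state object.
#' @export
optimizer <- function(kind = c("adamw", "sgd"), weight_decay = 0.025,
                      betas = c(0.9, 0.999), eps = 1e-8, momentum = 0.9) {
  kind <- match.arg(kind)
  structure(list(kind = kind, weight_decay = weight_decay, betas = betas,
                 eps = eps, momentum = momentum, t = 0L, state = list()),
            class = "optimizer")
}

#' Apply one optimizer step
#'
#' @param opt an [optimizer()].
#' @param params named list of parameter arrays.
#' @param grads named list of gradients (same names/shapes).
#' @param lr learning rate for this step.
#' @return List `(params, opt)` with updated parameters and state.
#' @export
optimizer_step <- function(opt, params, grads, lr) {
  if (opt$kind == "adamw") {
    opt$t <- opt$t + 1L
    b1 <- opt$betas[1]; b2 <- opt$betas[2]
    bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      st <- opt$state[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      opt$state[[nm]] <- st
      step <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      params[[nm]] <- params[[nm]] - lr * step -
        lr * opt$weight_decay * params[[nm]]
    }
  } else {
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      v <- opt$state[[nm]]
      if (is.null(v)) v <- g * 0
      v <- opt$momentum * v + g
      opt$state[[nm]] <- v
      params[[nm]] <- params[[nm]] - lr * v
    }
  }
  list(params = params, opt = opt)
}

# collect parameter gradients from a forward bundle after ag_backward
collect_grads <- function(bundle) {
  lapply(bundle$params, function(n) {
    if (is.null(n$grad)) NULL else n$grad
  })
}

# elementwise running sum of two grad lists (NULL-safe)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    if (is.null(b[[nm]])) next
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

scale_grads <- function(g, s) lapply(g, function(x) if (is.null(x)) NULL else x * s)
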