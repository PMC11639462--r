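# Lightweight module system: a module is a list with named parameter leaves
# (agTensor), optional non-trainable buffers/state, child modules, and a
# forward function `fn(self, x, train)`.

.aviscan$grad_on <- TRUE

# group-normalisation group count: at most `want` groups, each with at least
# 4 channels where the width allows, and always a divisor of the width
gn_pick <- function(ch, want = 16L) {
  g <- min(want, max(1L, ch %/% 4L))
  while (ch %% g != 0L) g <- g - 1L
  g
}

#' Evaluate an expression with gradient taping disabled
#' @param expr expression to evaluate
#' @export
ag_no_grad <- function(expr) {
  old <- .aviscan$grad_on
  .aviscan$grad_on <- FALSE
  on.exit(.aviscan$grad_on <- old)
  expr
}

new_module <- function(type, params = list(), children = list(), fn = NULL, ...) {
  st <- new.env(parent = emptyenv())
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = st)
  structure(list(type = type,
                 params = lapply(params, ag_leaf),
                 children = children,
                 state = st,
                 fn = fn),
            class = "ag_module")
}

#' Run a module forward
#' @param m module
#' @param x input feature map(s)
#' @param train logical, training mode (batch statistics, taping)
#' @export
module_forward <- function(m, x, train = FALSE) m$fn(m, x, train)

#' Flat named list of a module's trainable parameter leaves
#' @param m module
#' @param prefix name prefix used during recursion
#' @export
module_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    nm <- paste0(prefix, names(m$params))
    out <- m$params
    names(out) <- nm
  }
  for (cn in names(m$children)) {
    out <- c(out, module_params(m$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

#' Count trainable scalars of a module
#' @param m module (or model, see [build_model()])
#' @return integer parameter count
#' @export
count_params <- function(m) {
  if (inherits(m, "aviscan_model")) m <- m$net
  sum(vapply(module_params(m), function(p) length(p$value), numeric(1)))
}

# uniform init with torch-style 1/sqrt(fan_in) bound
winit <- function(dims, fan_in) {
  array(stats::runif(prod(dims), -1, 1) / sqrt(fan_in), dim = dims)
}

# ---- standard convolution block (conv [+ norm] [+ activation]) --------------

#' Convolution block: conv2d plus optional normalisation and activation
#'
#' @param cin,cout channel counts
#' @param k kernel size
#' @param stride,pad,groups convolution hyper-parameters
#' @param bias add a bias vector
#' @param norm "bn", "gn" or "none"
#' @param act "silu", "relu" or "none"
#' @param gn_groups group count when norm = "gn"
#' @export
mod_conv <- function(cin, cout, k = 1L, stride = 1L, pad = k %/% 2L, groups = 1L,
                     bias = FALSE, norm = "bn", act = "silu", gn_groups = 16L) {
  fan_in <- (cin %/% groups) * k * k
  params <- list(w = winit(c(k, k, cin %/% groups, cout), fan_in))
  if (bias) params$b <- winit(cout, fan_in)
  if (norm != "none") {
    params$gamma <- rep(1, cout)
    params$beta <- rep(0, cout)
  }
  gn_groups <- gn_pick(cout, gn_groups)
  m <- new_module("conv", params, fn = function(self, x, train) {
    y <- ag_conv2d(x, self$params$w, self$params[["b"]], stride = stride,
                   pad = pad, groups = groups)
    if (norm == "bn") {
      y <- ag_batchnorm(y, self$params$gamma, self$params$beta, self$state,
                        training = train)
    } else if (norm == "gn") {
      y <- ag_groupnorm(y, self$params$gamma, self$params$beta, gn_groups)
    }
    switch(act, silu = ag_silu(y), relu = ag_relu(y), none = y)
  })
  m$state$running_mean <- rep(0, cout)
  m$state$running_var <- rep(1, cout)
  m
}

# ---- C2f block (split, stacked bottlenecks, merge) --------------------------

mod_bottleneck <- function(c1, c2, shortcut = TRUE) {
  new_module("bottleneck",
             children = list(cv1 = mod_conv(c1, c2, 3L),
                             cv2 = mod_conv(c2, c2, 3L)),
             fn = function(self, x, train) {
               y <- module_forward(self$children$cv2,
                                   module_forward(self$children$cv1, x, train), train)
               if (shortcut && c1 == c2) x + y else y
             })
}

#' Cross-stage-partial block with two-way fusion (C2f)
#' @param c1,c2 in/out channels
#' @param n number of stacked bottlenecks
#' @param shortcut residual connections inside bottlenecks
#' @export
mod_c2f <- function(c1, c2, n = 1L, shortcut = FALSE) {
  ch <- c2 %/% 2L
  kids <- list(cv1 = mod_conv(c1, 2L * ch, 1L),
               cv2 = mod_conv((2L + n) * ch, c2, 1L))
  for (i in seq_len(n)) kids[[paste0("m", i)]] <- mod_bottleneck(ch, ch, shortcut)
  new_module("c2f", children = kids, fn = function(self, x, train) {
    y <- module_forward(self$children$cv1, x, train)
    parts <- list(ag_channels(y, 1L, ch), ag_channels(y, ch + 1L, 2L * ch))
    for (i in seq_len(n)) {
      parts[[length(parts) + 1L]] <-
        module_forward(self$children[[paste0("m", i)]], parts[[length(parts)]], train)
    }
    module_forward(self$children$cv2, ag_concat(parts), train)
  })
}

#' Spatial pyramid pooling (fast variant): three chained 5x5 max pools
#' @param c1,c2 in/out channels
#' @export
mod_sppf <- function(c1, c2) {
  ch <- c1 %/% 2L
  new_module("sppf",
             children = list(cv1 = mod_conv(c1, ch, 1L),
                             cv2 = mod_conv(ch * 4L, c2, 1L)),
             fn = function(self, x, train) {
               y0 <- module_forward(self$children$cv1, x, train)
               y1 <- ag_maxpool(y0, 5L, 1L, 2L)
               y2 <- ag_maxpool(y1, 5L, 1L, 2L)
               y3 <- ag_maxpool(y2, 5L, 1L, 2L)
               module_forward(self$children$cv2, ag_concat(list(y0, y1, y2, y3)), train)
             })
}

# sequential composition helper
mod_seq <- function(...) {
  kids <- list(...)
  names(kids) <- paste0("s", seq_along(kids))
  new_module("seq", children = kids, fn = function(self, x, train) {
    for (k in self$children) x <- module_forward(k, x, train)
    x
  })
}
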