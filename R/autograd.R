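# Minimal tape-based reverse-mode automatic differentiation over dense R
# arrays. Feature maps use dim (H, W, C, N). Every op accepts either plain
# numeric arrays or `agTensor` nodes; a node is only created when at least one
# input is a tensor that requires gradients, so inference runs tape-free.

.aviscan <- new.env(parent = emptyenv())
.aviscan$flops <- NULL   # when numeric, parameterised conv/affine ops add 2*MAC
.aviscan$grad_on <- TRUE

#' Is an object an autodiff tensor?
#' @param x object
#' @return logical
#' @export
is_ag <- function(x) inherits(x, "agTensor")

#' Extract the numeric value of a tensor (identity on plain arrays)
#' @param x array or agTensor
#' @return numeric array
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

#' Create a leaf tensor whose gradient is tracked
#' @param value numeric array
#' @param name optional label
#' @return agTensor
#' @export
ag_leaf <- function(value, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$leaf <- TRUE
  e$name <- name
  class(e) <- "agTensor"
  e
}

ag_node <- function(value, parents, backfn) {
  if (!isTRUE(.aviscan$grad_on)) return(value)
  if (!any(vapply(parents, is_ag, logical(1)))) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$leaf <- FALSE
  class(e) <- "agTensor"
  e
}

#' @export
print.agTensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<agTensor", if (is.null(d)) paste0("len ", length(x$value)) else
    paste(d, collapse = "x"), if (isTRUE(x$leaf)) "(leaf)" else "", ">\n")
  invisible(x)
}

# accumulate gradient g into node n (shapes already match)
acc_grad <- function(n, g) {
  if (is.null(n$grad)) n$grad <- g else n$grad <- n$grad + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation from a scalar tensor
#'
#' Accumulates gradients into the `$grad` field of every reachable leaf.
#' @param t scalar agTensor
#' @export
ag_backward <- function(t) {
  stopifnot(is_ag(t), length(t$value) == 1L)
  # iterative topological order (post-order DFS over agTensor parents)
  topo <- vector("list", 64L); ntopo <- 0L
  stack <- list(list(node = t, i = 0L)); ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    if (fr$i == 0L && isTRUE(node$..visited)) { stack[[ns]] <- NULL; ns <- ns - 1L; next }
    node$..visited <- TRUE
    if (fr$i < length(node$parents)) {
      stack[[ns]]$i <- fr$i + 1L
      child <- node$parents[[fr$i + 1L]]
      if (is_ag(child) && !isTRUE(child$..visited)) {
        ns <- ns + 1L
        stack[[ns]] <- list(node = child, i = 0L)
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[ns]] <- NULL; ns <- ns - 1L
    }
  }
  t$grad <- if (is.null(dim(t$value))) 1 else array(1, dim = dim(t$value))
  for (i in seq.int(ntopo, 1L)) {
    node <- topo[[i]]
    node$..visited <- NULL
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_ag(p) && !is.null(gs[[j]])) acc_grad(p, gs[[j]])
    }
    if (!isTRUE(node$leaf)) node$grad <- NULL  # free intermediate grads
  }
  invisible(t)
}

# --- shape helpers -----------------------------------------------------------

# reduce gradient g to the shape of operand value v (scalar broadcast only)
reduce_to <- function(g, v) {
  if (length(v) == 1L && length(g) > 1L) sum(g) else g
}

bin_op <- function(a, b, fwd, bwd_a, bwd_b) {
  av <- ag_value(a); bv <- ag_value(b)
  # length-1 operands broadcast as plain scalars (dim attributes dropped)
  if (length(av) == 1L) av <- as.vector(av)
  if (length(bv) == 1L) bv <- as.vector(bv)
  ag_node(fwd(av, bv), list(a, b), function(g) {
    list(if (is_ag(a)) reduce_to(bwd_a(g, av, bv), av) else NULL,
         if (is_ag(b)) reduce_to(bwd_b(g, av, bv), bv) else NULL)
  })
}

#' @export
Ops.agTensor <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(ag_node(-ag_value(e1), list(e1), function(g) list(-g)))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not supported for agTensor")
  }
  switch(.Generic,
    "+" = bin_op(e1, e2, `+`, function(g, a, b) g, function(g, a, b) g),
    "-" = bin_op(e1, e2, `-`, function(g, a, b) g, function(g, a, b) -g),
    "*" = bin_op(e1, e2, `*`, function(g, a, b) g * b, function(g, a, b) g * a),
    "/" = bin_op(e1, e2, `/`, function(g, a, b) g / b,
                 function(g, a, b) -g * a / (b * b)),
    "^" = bin_op(e1, e2, `^`, function(g, a, b) g * b * a^(b - 1),
                 function(g, a, b) g * a^b * log(a)),
    ">" = ag_value(e1) > ag_value(e2),
    "<" = ag_value(e1) < ag_value(e2),
    ">=" = ag_value(e1) >= ag_value(e2),
    "<=" = ag_value(e1) <= ag_value(e2),
    "==" = ag_value(e1) == ag_value(e2),
    stop(.Generic, " not supported for agTensor")
  )
}

# --- elementwise ops ---------------------------------------------------------

#' Elementwise exp with gradient tracking
#' @param x array or agTensor
#' @export
ag_exp <- function(x) {
  v <- exp(ag_value(x))
  ag_node(v, list(x), function(g) list(g * v))
}

#' Elementwise natural log
#' @param x array or agTensor
#' @export
ag_log <- function(x) {
  xv <- ag_value(x)
  ag_node(log(xv), list(x), function(g) list(g / xv))
}

#' Elementwise square root
#' @param x array or agTensor
#' @export
ag_sqrt <- function(x) {
  v <- sqrt(ag_value(x))
  ag_node(v, list(x), function(g) list(g / (2 * v)))
}

#' Elementwise absolute value (subgradient sign(x) at 0)
#' @param x array or agTensor
#' @export
ag_abs <- function(x) {
  xv <- ag_value(x)
  ag_node(abs(xv), list(x), function(g) list(g * sign(xv)))
}

#' Elementwise maximum of two operands (ties take the first operand's gradient)
#' @param a,b arrays or agTensors (same shape, or one scalar)
#' @export
ag_pmax <- function(a, b) {
  bin_op(a, b, pmax,
         function(g, av, bv) g * (av >= bv),
         function(g, av, bv) g * (av < bv))
}

#' Elementwise minimum of two operands
#' @param a,b arrays or agTensors (same shape, or one scalar)
#' @export
ag_pmin <- function(a, b) {
  bin_op(a, b, pmin,
         function(g, av, bv) g * (av <= bv),
         function(g, av, bv) g * (av > bv))
}

#' Rectified linear unit
#' @param x array or agTensor
#' @export
ag_relu <- function(x) {
  xv <- ag_value(x)
  ag_node(pmax(xv, 0), list(x), function(g) list(g * (xv > 0)))
}

#' Logistic sigmoid
#' @param x array or agTensor
#' @export
ag_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ag_value(x)))
  ag_node(v, list(x), function(g) list(g * v * (1 - v)))
}

#' SiLU (sigmoid-weighted linear unit), the network's default activation
#' @param x array or agTensor
#' @export
ag_silu <- function(x) {
  xv <- ag_value(x)
  s <- 1 / (1 + exp(-xv))
  ag_node(xv * s, list(x), function(g) list(g * (s + xv * s * (1 - s))))
}

#' Sum of all elements
#' @param x array or agTensor
#' @export
ag_sum <- function(x) {
  xv <- ag_value(x)
  ag_node(sum(xv), list(x), function(g) list(array(g, dim = dim(xv) %||% length(xv))))
}

#' Mean of all elements
#' @param x array or agTensor
#' @export
ag_mean <- function(x) {
  xv <- ag_value(x)
  n <- length(xv)
  ag_node(mean(xv), list(x), function(g) list(array(g / n, dim = dim(xv) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gather elements by index (flat indexing); backward scatter-adds
#' @param x array or agTensor
#' @param idx integer indices
#' @export
ag_gather <- function(x, idx) {
  xv <- ag_value(x)
  ag_node(xv[idx], list(x), function(g) {
    gx <- array(0, dim = dim(xv) %||% length(xv))
    # scatter-add (idx may repeat)
    gs <- rowsum(as.numeric(g), group = idx)
    gx[as.integer(rownames(gs))] <- gs[, 1L]
    list(gx)
  })
}

#' Concatenate 4-D feature maps along the channel axis
#' @param xs list of (H,W,C,N) arrays or agTensors
#' @export
ag_concat <- function(xs) {
  vs <- lapply(xs, ag_value)
  d <- dim(vs[[1L]])
  cs <- vapply(vs, function(v) dim(v)[3L], numeric(1))
  out <- array(0, dim = c(d[1L], d[2L], sum(cs), d[4L]))
  at <- 0L
  for (i in seq_along(vs)) {
    out[, , at + seq_len(cs[i]), ] <- vs[[i]]
    at <- at + cs[i]
  }
  ag_node(out, xs, function(g) {
    at <- 0L
    lapply(seq_along(xs), function(i) {
      sl <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <<- at + cs[i]
      if (is_ag(xs[[i]])) sl else NULL
    })
  })
}

#' Slice a channel range of a 4-D feature map
#' @param x (H,W,C,N) array or agTensor
#' @param from,to channel range (inclusive)
#' @export
ag_channels <- function(x, from, to) {
  xv <- ag_value(x)
  ag_node(xv[, , from:to, , drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = dim(xv))
    gx[, , from:to, ] <- g
    list(gx)
  })
}

#' Apply a fixed bijective permutation of elements
#'
#' `idx` maps output position i to input position idx[i]; used for the
#' receptive-field rearrangement. Backward applies the inverse permutation.
#' @param x array or agTensor
#' @param idx integer permutation (length == length(x))
#' @param out_dim dim of the output array
#' @export
ag_permute <- function(x, idx, out_dim) {
  xv <- ag_value(x)
  v <- array(xv[idx], dim = out_dim)
  ag_node(v, list(x), function(g) {
    gx <- numeric(length(xv))
    gx[idx] <- as.numeric(g)
    list(array(gx, dim = dim(xv)))
  })
}
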