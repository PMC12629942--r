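# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every operation accepts either plain numeric matrices or `adnode` objects
# and only builds a tape node when at least one argument is a node, so the
# same model code serves both plain evaluation (prediction, standalone
# penalty functions) and gradient-based training. Values are always stored as
# matrices; gradients have the shape of the value they correspond to.
#
# Backward rules are shared top-level functions taking `(g, ctx)` rather than
# per-node closures: fresh closures would be byte-compiled individually on
# first call, which dominates runtime on tapes with thousands of nodes.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_is <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (ad_is(x)) x$value else x

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(value, parents = list(), backward = NULL, ctx = NULL) {
  .ad$counter <- .ad$counter + 1L
  out <- list(value = value, parents = parents, backward = backward,
              ctx = ctx, id = .ad$counter)
  class(out) <- "adnode"
  out
}

ad_leaf <- function(value) ad_node(.as_mat(value))

.any_node <- function(...) {
  for (x in list(...)) if (ad_is(x)) return(TRUE)
  FALSE
}

# Length-1 operands act as scalars in elementwise ops.
.sc <- function(x) if (length(x) == 1L) as.numeric(x) else x

# Reduce a gradient back to the shape of the original operand (scalar
# operands receive the summed gradient).
.shrink <- function(g, v) {
  if (length(v) == 1L && length(g) > 1L) matrix(sum(g), 1L, 1L) else g
}

.bw_add <- function(g, ctx) list(.shrink(g, ctx$a), .shrink(g, ctx$b))
ad_add <- function(a, b) {
  av <- .sc(ad_value(a)); bv <- .sc(ad_value(b))
  v <- unclass(av + bv)
  if (!.any_node(a, b)) return(v)
  ad_node(v, list(a, b), .bw_add, list(a = av, b = bv))
}

.bw_sub <- function(g, ctx) list(.shrink(g, ctx$a), .shrink(-g, ctx$b))
ad_sub <- function(a, b) {
  av <- .sc(ad_value(a)); bv <- .sc(ad_value(b))
  v <- unclass(av - bv)
  if (!.any_node(a, b)) return(v)
  ad_node(v, list(a, b), .bw_sub, list(a = av, b = bv))
}

.bw_neg <- function(g, ctx) list(-g)
ad_neg <- function(a) {
  av <- ad_value(a)
  if (!ad_is(a)) return(-av)
  ad_node(-av, list(a), .bw_neg)
}

.bw_mul <- function(g, ctx)
  list(.shrink(g * ctx$b, ctx$a), .shrink(g * ctx$a, ctx$b))
# Elementwise product; shapes must match or one operand is scalar.
ad_mul <- function(a, b) {
  av <- .sc(ad_value(a)); bv <- .sc(ad_value(b))
  v <- unclass(av * bv)
  if (!.any_node(a, b)) return(v)
  ad_node(v, list(a, b), .bw_mul, list(a = av, b = bv))
}

.bw_div <- function(g, ctx)
  list(.shrink(g / ctx$b, ctx$a),
       .shrink(-g * ctx$a / (ctx$b * ctx$b), ctx$b))
ad_div <- function(a, b) {
  av <- .sc(ad_value(a)); bv <- .sc(ad_value(b))
  v <- unclass(av / bv)
  if (!.any_node(a, b)) return(v)
  ad_node(v, list(a, b), .bw_div, list(a = av, b = bv))
}

.bw_matmul <- function(g, ctx)
  list(tcrossprod(g, ctx$b), crossprod(ctx$a, g))
ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- av %*% bv
  if (!.any_node(a, b)) return(v)
  ad_node(v, list(a, b), .bw_matmul, list(a = av, b = bv))
}

.bw_t <- function(g, ctx) list(t(g))
ad_t <- function(a) {
  av <- ad_value(a)
  if (!ad_is(a)) return(t(av))
  ad_node(t(av), list(a), .bw_t)
}

.bw_addrow <- function(g, ctx) list(g, matrix(colSums(g), 1L))
# Add a 1 x d row vector to every row of an n x d matrix.
ad_addrow <- function(x, b) {
  xv <- ad_value(x); bv <- as.vector(ad_value(b))
  v <- xv + rep(bv, each = nrow(xv))
  if (!.any_node(x, b)) return(v)
  ad_node(v, list(x, b), .bw_addrow)
}

.bw_mulcol <- function(g, ctx)
  list(g * ctx$v, matrix(rowSums(g * ctx$x), ncol = 1L))
# Scale row i of x by v[i] (v is n x 1).
ad_mulcol <- function(x, v) {
  xv <- ad_value(x); vv <- ad_value(v)
  out <- xv * as.vector(vv)
  if (!.any_node(x, v)) return(out)
  ad_node(out, list(x, v), .bw_mulcol, list(x = xv, v = as.vector(vv)))
}

.bw_tanh <- function(g, ctx) list(g * (1 - ctx * ctx))
ad_tanh <- function(a) {
  av <- ad_value(a)
  v <- tanh(av)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_tanh, v)
}

.bw_sigmoid <- function(g, ctx) list(g * ctx * (1 - ctx))
ad_sigmoid <- function(a) {
  av <- ad_value(a)
  v <- 1 / (1 + exp(-av))
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_sigmoid, v)
}

.bw_gelu <- function(g, ctx)
  list(g * (ctx$s + ctx$x * 1.702 * ctx$s * (1 - ctx$s)))
# Smooth GELU-style activation: x * sigmoid(1.702 x).
ad_gelu <- function(a) {
  av <- ad_value(a)
  s <- 1 / (1 + exp(-1.702 * av))
  v <- av * s
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_gelu, list(x = av, s = s))
}

.bw_exp <- function(g, ctx) list(g * ctx)
ad_exp <- function(a) {
  av <- ad_value(a)
  v <- exp(av)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_exp, v)
}

.bw_log <- function(g, ctx) list(g / ctx)
ad_log <- function(a) {
  av <- ad_value(a)
  v <- log(av)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_log, av)
}

.bw_sqrt <- function(g, ctx) list(g / (2 * ctx))
ad_sqrt <- function(a) {
  av <- ad_value(a)
  v <- sqrt(av)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_sqrt, v)
}

.bw_relu <- function(g, ctx) list(g * ctx)
# max(x, 0); subgradient 0 at the kink.
ad_relu <- function(a) {
  av <- ad_value(a)
  v <- pmax(av, 0)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_relu, (av > 0) * 1)
}

.bw_sum <- function(g, ctx) list(array(as.numeric(g), dim = ctx))
ad_sum <- function(a) {
  av <- ad_value(a)
  v <- matrix(sum(av), 1L, 1L)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_sum, dim(.as_mat(av)))
}

.bw_mean <- function(g, ctx)
  list(array(as.numeric(g) / prod(ctx), dim = ctx))
ad_mean <- function(a) {
  av <- ad_value(a)
  v <- matrix(sum(av) / length(av), 1L, 1L)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_mean, dim(.as_mat(av)))
}

.bw_rowsums <- function(g, ctx)
  list(matrix(as.vector(g), ctx[1L], ctx[2L]))
ad_rowsums <- function(a) {
  av <- ad_value(a)
  v <- matrix(rowSums(av), ncol = 1L)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_rowsums, dim(av))
}

.bw_rbind <- function(g, ctx)
  lapply(seq_along(ctx$starts), function(j)
    g[ctx$starts[j]:ctx$ends[j], , drop = FALSE])
ad_rbind <- function(lst) {
  vals <- lapply(lst, ad_value)
  v <- do.call(rbind, vals)
  if (!any(vapply(lst, ad_is, logical(1L)))) return(v)
  nr <- vapply(vals, nrow, integer(1L))
  ends <- cumsum(nr)
  ad_node(v, lst, .bw_rbind, list(starts = ends - nr + 1L, ends = ends))
}

.bw_cbind <- function(g, ctx)
  lapply(seq_along(ctx$starts), function(j)
    g[, ctx$starts[j]:ctx$ends[j], drop = FALSE])
ad_cbind <- function(lst) {
  vals <- lapply(lst, ad_value)
  v <- do.call(cbind, vals)
  if (!any(vapply(lst, ad_is, logical(1L)))) return(v)
  nc <- vapply(vals, ncol, integer(1L))
  ends <- cumsum(nc)
  ad_node(v, lst, .bw_cbind, list(starts = ends - nc + 1L, ends = ends))
}

.bw_rows <- function(g, ctx) {
  full <- matrix(0, ctx$nr, ctx$nc)
  acc <- rowsum(g, group = ctx$idx)
  full[as.integer(rownames(acc)), ] <- acc
  list(full)
}
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  v <- av[idx, , drop = FALSE]
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_rows,
          list(nr = nrow(av), nc = ncol(av), idx = idx))
}

.bw_cols <- function(g, ctx) {
  full <- matrix(0, ctx$nr, ctx$nc)
  acc <- t(rowsum(t(g), group = ctx$idx))
  full[, as.integer(colnames(acc))] <- acc
  list(full)
}
ad_cols <- function(a, idx) {
  av <- ad_value(a)
  v <- av[, idx, drop = FALSE]
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_cols,
          list(nr = nrow(av), nc = ncol(av), idx = idx))
}

.bw_softmax_rows <- function(g, ctx) list(ctx * (g - rowSums(g * ctx)))
ad_softmax_rows <- function(a) {
  av <- ad_value(a)
  rmax <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - rmax)
  v <- e / rowSums(e)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), .bw_softmax_rows, v)
}

# Backpropagate from a scalar-valued node; returns an environment mapping
# node id (as character) to accumulated gradient.
ad_backward <- function(node) {
  stopifnot(ad_is(node), length(ad_value(node)) == 1L)
  nodes <- vector("list", 1024L)
  n_nodes <- 0L
  # parents always carry smaller ids than their children, so a logical
  # vector up to the root id covers every reachable node. (An environment
  # keyed by id strings would intern one permanent symbol per node.)
  seen <- logical(node$id)
  stack <- vector("list", 1024L)
  stack[1L] <- list(node)
  sp <- 1L
  while (sp > 0L) {
    cur <- stack[[sp]]
    sp <- sp - 1L
    if (seen[cur$id]) next
    seen[cur$id] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[n_nodes] <- list(cur)   # x[i] <- list(v): avoids the slow
    for (p in cur$parents) {      # classed-RHS [[<- assignment path
      if (!ad_is(p)) next
      sp <- sp + 1L
      if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[sp] <- list(p)
    }
  }
  nodes <- nodes[seq_len(n_nodes)]
  ids <- vapply(nodes, function(n) n$id, numeric(1L))
  ord <- order(ids, decreasing = TRUE)
  # gradients stored in a list indexed by (id - offset + 1)
  offset <- min(ids)
  grads <- vector("list", max(ids) - offset + 1L)
  grads[[node$id - offset + 1L]] <- matrix(1, 1L, 1L)
  for (i in ord) {
    cur <- nodes[[i]]
    g <- grads[[cur$id - offset + 1L]]
    if (is.null(g) || is.null(cur$backward)) next
    pg <- cur$backward(g, cur$ctx)
    parents <- cur$parents
    for (j in seq_along(parents)) {
      p <- parents[[j]]
      if (!ad_is(p) || is.null(pg[[j]])) next
      key <- p$id - offset + 1L
      old <- grads[[key]]
      grads[[key]] <- if (is.null(old)) pg[[j]] else old + pg[[j]]
    }
  }
  structure(list(grads = grads, offset = offset), class = "ad_gradients")
}

ad_grad <- function(grads, node) {
  key <- node$id - grads$offset + 1L
  g <- if (key >= 1L && key <= length(grads$grads)) grads$grads[[key]]
  if (is.null(g)) matrix(0, nrow(ad_value(node)), ncol(ad_value(node)))
  else g
}
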